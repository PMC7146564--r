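# Slaughterhouse-phase KPI records.
#
# On arrival, operators inspect a random sample of birds (200 by default)
# and record 19 indicators per flock on a fixed template: carcass weights,
# injury and processing-defect counts, lot-level counts, and a binary final
# meat-quality grade.  This module reads, validates and writes that
# template as CSV.

# the 19 template fields, in canonical column order
SLAUGHTER_FIELDS <- c(
  "weight_range", "farm_weight",
  "total_hematoms", "broken_wing", "hematoma_wings", "hematoma_armpit",
  "breast", "broken_bones", "overscalded", "bad_extraction_viscera",
  "bad_plucked", "bad_wash", "scab", "crops", "knuckles",
  "dead_in_transport", "confiscated", "numbers_of_chickens", "meat_quality"
)

# counts assessed on the inspected sample (bounded by sample_size) vs the
# whole lot (bounded by numbers_of_chickens)
SLAUGHTER_SAMPLE_COUNTS <- c(
  "total_hematoms", "broken_wing", "hematoma_wings", "hematoma_armpit",
  "breast", "broken_bones", "overscalded", "bad_extraction_viscera",
  "bad_plucked", "bad_wash", "scab", "crops", "knuckles"
)
SLAUGHTER_LOT_COUNTS <- c("dead_in_transport", "confiscated")

#' Names of the 19 slaughterhouse KPI fields
#'
#' @return character vector of length 19, in template column order.
#' @export
slaughter_kpi_fields <- function() SLAUGHTER_FIELDS

#' Construct a validated slaughterhouse record
#'
#' One row per inspected flock.  `weight_range` and `farm_weight` are in kg
#' (note: the source template records `weight_range` as a single scalar, not
#' an interval); the defect fields are counts over the inspected sample;
#' `dead_in_transport`, `confiscated` and `numbers_of_chickens` refer to the
#' whole lot; `meat_quality` is `"A"` (majority high grade) or `"B"`.
#'
#' @param flock_id non-empty chain/flock identifier.
#' @param sample_size number of birds inspected (default 200).
#' @param ... the 19 KPI fields by name (all required).
#' @return a one-row data.frame of class `slaughter_record`.
#' @export
slaughter_record <- function(flock_id, sample_size = 200, ...) {
  vals <- list(...)
  miss <- setdiff(SLAUGHTER_FIELDS, names(vals))
  if (length(miss)) {
    err_schema(paste("missing KPI field(s):", paste(miss, collapse = ", ")))
  }
  df <- data.frame(flock_id = as.character(flock_id),
                   sample_size = as.numeric(sample_size),
                   stringsAsFactors = FALSE)
  for (f in SLAUGHTER_FIELDS) {
    df[[f]] <- if (f == "meat_quality") as.character(vals[[f]]) else as.numeric(vals[[f]])
  }
  validate_slaughter(df)
  class(df) <- c("slaughter_record", "data.frame")
  df
}

# validates a (possibly multi-row) slaughter-record data.frame
validate_slaughter <- function(df) {
  if (any(is.na(df$flock_id) | !nzchar(df$flock_id))) {
    err_value("flock_id must be non-empty (each flock must be identifiable)")
  }
  if (anyDuplicated(df$flock_id)) err_value("duplicate flock_id in record set")
  if (any(!df$meat_quality %in% c("A", "B"))) {
    bad <- setdiff(unique(df$meat_quality), c("A", "B"))
    err_value(sprintf("meat_quality must be 'A' or 'B', got: %s",
                      paste(bad, collapse = ", ")))
  }
  counts <- c(SLAUGHTER_SAMPLE_COUNTS, SLAUGHTER_LOT_COUNTS,
              "numbers_of_chickens", "sample_size")
  for (f in counts) {
    v <- df[[f]]
    if (any(is.na(v) | v < 0)) err_value(sprintf("'%s' must be a non-negative count", f))
    if (any(v != round(v))) err_value(sprintf("'%s' must be an integer count", f))
  }
  for (f in c("weight_range", "farm_weight")) {
    if (any(is.na(df[[f]]) | df[[f]] <= 0)) {
      err_value(sprintf("'%s' must be a positive weight in kg", f))
    }
  }
  for (f in SLAUGHTER_SAMPLE_COUNTS) {
    if (any(df[[f]] > df$sample_size)) {
      err_value(sprintf("'%s' exceeds the inspected sample size", f))
    }
  }
  for (f in SLAUGHTER_LOT_COUNTS) {
    if (any(df[[f]] > df$numbers_of_chickens)) {
      err_value(sprintf("'%s' exceeds the lot size", f))
    }
  }
  invisible(df)
}

#' Parse a slaughterhouse template CSV
#'
#' The template header is `flock_id`, `sample_size` plus the 19 field names
#' of [slaughter_kpi_fields()], in any column order; one row per flock.
#' Parsing is locale-independent (decimal point).  Validation errors name
#' the offending column.
#'
#' @param file path to a CSV file following the template.
#' @return a data.frame of class `slaughter_record`, one row per flock.
#' @export
parse_slaughter_csv <- function(file) {
  if (!file.exists(file)) err_schema(paste("no such file:", file))
  df <- utils::read.csv(file, stringsAsFactors = FALSE,
                        colClasses = c(flock_id = "character"))
  need <- c("flock_id", "sample_size", SLAUGHTER_FIELDS)
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    err_schema(paste("missing column(s):", paste(miss, collapse = ", ")))
  }
  extra <- setdiff(names(df), need)
  if (length(extra)) {
    err_schema(paste("unexpected column(s):", paste(extra, collapse = ", ")))
  }
  df <- df[, need]
  for (f in setdiff(need, c("flock_id", "meat_quality"))) {
    df[[f]] <- as.numeric(df[[f]])
  }
  df$meat_quality <- as.character(df$meat_quality)
  validate_slaughter(df)
  class(df) <- c("slaughter_record", "data.frame")
  df
}

#' Write slaughterhouse records to the template CSV
#'
#' Round-trip guarantee: `parse_slaughter_csv(write_slaughter_csv(r, f))`
#' reproduces `r` exactly.
#'
#' @param records a `slaughter_record` data.frame.
#' @param file destination path.
#' @return the file path, invisibly.
#' @export
write_slaughter_csv <- function(records, file) {
  validate_slaughter(records)
  out <- as.data.frame(records)[, c("flock_id", "sample_size", SLAUGHTER_FIELDS)]
  utils::write.csv(out, file, row.names = FALSE)
  invisible(file)
}
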