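# The KPI registry and the JSON-lines KPI store.
#
# Thirty-two indicators are defined across the chain: 5 in the breeding
# phase, 3 in loading, 5 in transport and 19 in the slaughterhouse phase.
# Computed values are appended to a JSON-lines store (one record per line),
# keyed by chain, phase, KPI name and a digest of the configuration that
# produced them, so reruns are idempotent.

#' The canonical KPI registry
#'
#' @return data.frame with columns `phase`, `kpi_name` and `unit`; exactly
#'   32 rows split 5/3/5/19 across the breeding, loading, transport and
#'   slaughterhouse phases.
#' @export
kpi_registry <- function() {
  rbind(
    data.frame(phase = "breeding",
               kpi_name = c("temperature_warning", "temperature_alarm",
                            "alert_situation", "danger_situation",
                            "emergency_situation"),
               unit = "%", stringsAsFactors = FALSE),
    data.frame(phase = "loading",
               kpi_name = c("saturation_rate", "mean_accumulation",
                            "std_accumulation"),
               unit = c("1/min", "g.s/min", "g.s/min"),
               stringsAsFactors = FALSE),
    data.frame(phase = "transport",
               kpi_name = c("low_temperature", "high_temperature",
                            "low_relative_humidity", "high_relative_humidity",
                            "abrupt_movements"),
               unit = "%", stringsAsFactors = FALSE),
    data.frame(phase = "slaughterhouse",
               kpi_name = slaughter_kpi_fields(),
               unit = c("kg", "kg", rep("count", 16), "grade"),
               stringsAsFactors = FALSE)
  )
}

#' Construct KPI records
#'
#' @param chain_id chain identifier.
#' @param phase one of `"breeding"`, `"loading"`, `"transport"`,
#'   `"slaughterhouse"`.
#' @param values named vector/list of KPI values; names must be registry
#'   KPI names of that phase.
#' @param digest configuration digest (see [params_digest()]).
#' @param computed_at timestamp (default now, UTC).
#' @return data.frame of KPI records.
#' @export
kpi_records <- function(chain_id, phase, values, digest = params_digest(list()),
                        computed_at = Sys.time()) {
  reg <- kpi_registry()
  phase <- match.arg(phase, unique(reg$phase))
  known <- reg[reg$phase == phase, ]
  bad <- setdiff(names(values), known$kpi_name)
  if (length(bad)) {
    err_value(paste("not registry KPIs for phase", phase, ":",
                    paste(bad, collapse = ", ")))
  }
  data.frame(chain_id = as.character(chain_id), phase = phase,
             kpi_name = names(values),
             value = vapply(values, as.character, character(1)),
             unit = known$unit[match(names(values), known$kpi_name)],
             computed_at = iso8601(computed_at),
             params_digest = digest,
             stringsAsFactors = FALSE, row.names = NULL)
}

record_key <- function(df) {
  paste(df$chain_id, df$phase, df$kpi_name, df$params_digest, sep = "\r")
}

#' Append KPI records to a JSON-lines store
#'
#' One JSON object per line.  Records whose (chain, phase, KPI, digest) key
#' already exists in the store are skipped, making reruns idempotent.
#'
#' @param records data.frame as produced by [kpi_records()].
#' @param store path to the JSON-lines store file (created if absent).
#' @return invisibly, the number of records actually appended.
#' @export
append_kpi_records <- function(records, store) {
  existing <- if (file.exists(store)) read_kpi_store(store) else NULL
  keys <- if (is.null(existing) || nrow(existing) == 0) character(0) else record_key(existing)
  new <- records[!record_key(records) %in% keys, , drop = FALSE]
  if (nrow(new) > 0) {
    lines <- vapply(seq_len(nrow(new)), function(i) {
      jsonlite::toJSON(as.list(new[i, ]), auto_unbox = TRUE, digits = NA)
    }, character(1))
    con <- file(store, open = "a")
    on.exit(close(con))
    writeLines(lines, con)
  }
  invisible(nrow(new))
}

#' Read a JSON-lines KPI store
#'
#' @param store path to the store file.
#' @return data.frame of KPI records (zero rows if the store is empty).
#' @export
read_kpi_store <- function(store) {
  lines <- readLines(store, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    return(data.frame(chain_id = character(), phase = character(),
                      kpi_name = character(), value = character(),
                      unit = character(), computed_at = character(),
                      params_digest = character(), stringsAsFactors = FALSE))
  }
  rows <- lapply(lines, function(l) {
    as.data.frame(jsonlite::fromJSON(l), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
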