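# Phase runners tying readers, KPI engines and the store into one
# chain-level pipeline.

#' Read a comfort-profile CSV
#'
#' Columns: `start_timestamp` (ISO-8601 UTC or numeric seconds),
#' `optimal_temp_c`.
#'
#' @param file path to a CSV file.
#' @return a [comfort_profile()].
#' @export
read_profile_csv <- function(file) {
  df <- utils::read.csv(file, stringsAsFactors = FALSE)
  need <- c("start_timestamp", "optimal_temp_c")
  miss <- setdiff(need, names(df))
  if (length(miss)) err_schema(paste("missing column(s):", paste(miss, collapse = ", ")))
  comfort_profile(parse_iso8601(df$start_timestamp), df$optimal_temp_c)
}

#' @rdname read_profile_csv
#' @param profile a [comfort_profile()] to write.
#' @export
write_profile_csv <- function(profile, file) {
  df <- data.frame(start_timestamp = iso8601(profile$start),
                   optimal_temp_c = profile$optimal_temp_c)
  utils::write.csv(df, file, row.names = FALSE)
  invisible(file)
}

#' Run one phase of the KPI pipeline
#'
#' Reads the phase's inputs, computes all of that phase's registry KPIs and
#' (optionally) appends them to a JSON-lines store.  Input files per phase:
#' \describe{
#'   \item{breeding}{`temps`, `rhs` (sensor CSVs), `profile` (profile CSV)}
#'   \item{loading}{`accel` (accelerometer CSV)}
#'   \item{transport}{`journey` (journey CSV)}
#'   \item{slaughterhouse}{`slaughter` (template CSV; `chain_id` is taken
#'     from each row's `flock_id`)}
#' }
#' Already-parsed objects may be passed in place of file paths.
#'
#' @param phase one of `"breeding"`, `"loading"`, `"transport"`,
#'   `"slaughterhouse"`.
#' @param inputs named list of file paths (or parsed objects) as above.
#' @param chain_id chain identifier for the records.
#' @param config named list of phase parameters (e.g. `zpeak` for
#'   transport, `sd_type`/`epsilon` for loading, `his` for breeding); also
#'   hashed into the records' `params_digest`.
#' @param store optional path to a JSON-lines store to append to.
#' @return the phase's KPI records, invisibly if a store was written.
#' @export
run_phase <- function(phase, inputs, chain_id, config = list(), store = NULL) {
  phase <- match.arg(phase, c("breeding", "loading", "transport", "slaughterhouse"))
  digest <- params_digest(config)
  recs <- switch(
    phase,
    breeding = {
      temps <- if (inherits(inputs$temps, "sensor_series")) inputs$temps
               else read_sensor_csv(inputs$temps)
      rhs <- if (inherits(inputs$rhs, "sensor_series")) inputs$rhs
             else read_sensor_csv(inputs$rhs)
      profile <- if (inherits(inputs$profile, "comfort_profile")) inputs$profile
                 else read_profile_csv(inputs$profile)
      his <- if (is.null(config$his)) his_config() else config$his
      kpis <- breeding_kpis(temps, rhs, profile, his)
      message(sprintf("breeding: %d samples, %d missing", length(temps),
                      sum(is.na(temps$values))))
      kpi_records(chain_id, phase, kpis, digest)
    },
    loading = {
      stream <- if (inherits(inputs$accel, "accel_stream")) inputs$accel
                else read_accel_csv(inputs$accel)
      eps <- if (is.null(config$epsilon)) 0 else config$epsilon
      sdt <- if (is.null(config$sd_type)) "sample" else config$sd_type
      kpis <- loading_kpis(stream, epsilon = eps, sd_type = sdt)
      message(sprintf("loading: %d samples over %d complete minute(s)",
                      length(stream), length(complete_minutes(stream))))
      kpi_records(chain_id, phase, kpis, digest)
    },
    transport = {
      j <- if (is.list(inputs$journey) && !is.character(inputs$journey)) inputs$journey
           else read_journey_csv(inputs$journey)
      params <- if (is.null(config$zpeak)) zpeak_params() else config$zpeak
      kpis <- transport_kpis(j$temps, j$rhs, j$stream, params)
      message(sprintf("transport: %d samples, lag %d", length(j$temps), params$lag))
      kpi_records(chain_id, phase, kpis, digest)
    },
    slaughterhouse = {
      rec <- if (inherits(inputs$slaughter, "slaughter_record")) inputs$slaughter
             else parse_slaughter_csv(inputs$slaughter)
      out <- lapply(seq_len(nrow(rec)), function(i) {
        vals <- as.list(rec[i, slaughter_kpi_fields()])
        kpi_records(rec$flock_id[i], phase, vals, digest)
      })
      do.call(rbind, out)
    }
  )
  if (!is.null(store)) {
    n <- append_kpi_records(recs, store)
    message(sprintf("%s: %d record(s) appended to %s", phase, n, store))
    return(invisible(recs))
  }
  recs
}

#' Run a whole chain from a manifest
#'
#' The manifest names the four phases' inputs for one chain: a list (or a
#' YAML file) with a `chain_id` and entries `breeding`, `loading`,
#' `transport`, `slaughterhouse`, each an input list as accepted by
#' [run_phase()].
#'
#' @param manifest list or path to a YAML manifest.
#' @param config as in [run_phase()] (shared across phases).
#' @param store optional JSON-lines store path.
#' @param strict if `TRUE` (default), a missing phase is an error; if
#'   `FALSE`, missing phases are skipped with a warning.
#' @return data.frame of all computed records (32 per fully specified
#'   chain).  A summary table is printed via `message()`.
#' @export
run_chain <- function(manifest, config = list(), store = NULL, strict = TRUE) {
  if (is.character(manifest)) manifest <- yaml::read_yaml(manifest)
  if (is.null(manifest$chain_id)) err_config("manifest must name a chain_id")
  phases <- c("breeding", "loading", "transport", "slaughterhouse")
  out <- list()
  for (ph in phases) {
    if (is.null(manifest[[ph]])) {
      if (strict) err_config(sprintf("manifest is missing the '%s' phase", ph))
      warning(sprintf("manifest is missing the '%s' phase; skipping", ph))
      next
    }
    out[[ph]] <- run_phase(ph, manifest[[ph]], manifest$chain_id, config, store)
  }
  recs <- do.call(rbind, unname(out))
  tab <- table(recs$phase)
  message(paste0("chain ", manifest$chain_id, ": ",
                 paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
                 " (", nrow(recs), " records)"))
  invisible(recs)
}
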