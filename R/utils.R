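# Internal helpers: classed error conditions, seeded evaluation, hashing.

#' Signal a classed package error
#'
#' All user-facing validation failures are signalled as classed conditions
#' so callers (and tests) can distinguish, e.g., an empty input from a
#' misconfiguration.
#'
#' @param message error message.
#' @param class condition subclass, e.g. "poultrykpi_empty_input".
#' @noRd
pk_abort <- function(message, class) {
  cond <- structure(
    class = c(class, "poultrykpi_error", "error", "condition"),
    list(message = message, call = sys.call(-1))
  )
  stop(cond)
}

# shorthands for the condition classes used across modules
err_invalid_input <- function(msg) pk_abort(msg, "poultrykpi_invalid_input")
err_empty_input <- function(msg) pk_abort(msg, "poultrykpi_empty_input")
err_insufficient_data <- function(msg) pk_abort(msg, "poultrykpi_insufficient_data")
err_config <- function(msg) pk_abort(msg, "poultrykpi_configuration_error")
err_schema <- function(msg) pk_abort(msg, "poultrykpi_schema_error")
err_value <- function(msg) pk_abort(msg, "poultrykpi_value_error")
err_alignment <- function(msg) pk_abort(msg, "poultrykpi_alignment_error")
err_missing_feature <- function(msg) pk_abort(msg, "poultrykpi_missing_feature")

#' Evaluate code under a fixed RNG seed, restoring the caller's RNG state
#' @noRd
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had_seed) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (had_seed) {
        assign(".Random.seed", old, envir = globalenv())
      } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(code)
}

#' Short deterministic digest of a parameter list
#'
#' Used to key KPI records by the configuration that produced them.  A
#' simple 31-bit rolling hash of the deparsed, name-sorted parameter list
#' is enough to tell configurations apart in a store.
#'
#' @param params a list (possibly nested) of parameters.
#' @return an 8-character hexadecimal string.
#' @export
params_digest <- function(params) {
  if (is.list(params) && !is.null(names(params))) {
    params <- params[order(names(params))]
  }
  txt <- paste(deparse(params), collapse = "\n")
  bytes <- utf8ToInt(txt)
  h <- 7
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}

# ISO-8601 UTC formatting/parsing used by every CSV interface
iso8601 <- function(t, digits = 0L) {
  fmt <- if (digits > 0L) paste0("%Y-%m-%dT%H:%M:%OS", digits) else "%Y-%m-%dT%H:%M:%S"
  format(as.POSIXct(t, origin = "1970-01-01", tz = "UTC"), fmt, tz = "UTC")
}

parse_iso8601 <- function(x) {
  if (is.numeric(x)) return(as.numeric(x))
  t <- as.POSIXct(x, format = "%Y-%m-%dT%H:%M:%OS", tz = "UTC")
  bad <- is.na(t) & !is.na(x)
  if (any(bad)) {
    t2 <- as.POSIXct(x[bad], format = "%Y-%m-%d %H:%M:%OS", tz = "UTC")
    t[bad] <- t2
  }
  if (anyNA(t[!is.na(x)])) err_value("timestamps must be ISO-8601 (YYYY-MM-DDTHH:MM:SS)")
  as.numeric(t)
}
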