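# Shared time-series containers and interval-fraction arithmetic.
#
# Everything downstream (breeding, loading, transport KPIs) is built on two
# containers: a uniformly sampled scalar series with an explicit unit, and a
# tri-axial accelerometer stream with a known measurable range.  Missing
# samples are kept as NA, never dropped, so "% of time" KPIs can exclude
# outages from both numerator and denominator.

SENSOR_UNITS <- c("degC", "%RH", "g", "ppm")

normalize_unit <- function(unit) {
  u <- gsub("°C", "degC", unit)
  if (!u %in% SENSOR_UNITS) {
    err_value(sprintf("unknown unit '%s'; expected one of %s",
                      unit, paste(SENSOR_UNITS, collapse = ", ")))
  }
  u
}

#' Uniformly sampled sensor series
#'
#' A time-stamped series of scalar measurements with a declared unit and
#' nominal sample period.  Timestamps must be strictly increasing; missing
#' measurements are represented as `NA` values, never silently dropped.
#'
#' @param timestamps strictly increasing times, either numeric seconds since
#'   the epoch or `POSIXct`.
#' @param values numeric measurements, `NA` for missing samples.
#' @param unit one of `"degC"`, `"%RH"`, `"g"`, `"ppm"` (the degree sign is
#'   accepted and normalised to `degC`).
#' @param sample_period nominal sampling period in seconds; defaults to the
#'   median timestamp difference.
#' @return an object of class `sensor_series`.
#' @examples
#' s <- sensor_series(0:9 * 30, rnorm(10, 25), "degC", 30)
#' length(s)
#' @export
sensor_series <- function(timestamps, values, unit, sample_period = NULL) {
  t <- as.numeric(timestamps)
  v <- as.numeric(values)
  if (length(t) != length(v)) {
    err_invalid_input("timestamps and values must have the same length")
  }
  if (anyNA(t)) err_invalid_input("timestamps must not contain NA")
  if (length(t) > 1 && any(diff(t) <= 0)) {
    err_invalid_input("timestamps must be strictly increasing")
  }
  if (is.null(sample_period)) {
    sample_period <- if (length(t) > 1) stats::median(diff(t)) else 1
  }
  if (!is.finite(sample_period) || sample_period <= 0) {
    err_invalid_input("sample_period must be > 0")
  }
  structure(
    list(timestamps = t, values = v, unit = normalize_unit(unit),
         sample_period = as.numeric(sample_period)),
    class = "sensor_series"
  )
}

#' @export
length.sensor_series <- function(x) length(x$timestamps)

#' @export
print.sensor_series <- function(x, ...) {
  cat(sprintf("<sensor_series> %d samples [%s], period %gs, %d missing\n",
              length(x), x$unit, x$sample_period, sum(is.na(x$values))))
  invisible(x)
}

#' @export
as.data.frame.sensor_series <- function(x, ...) {
  data.frame(timestamp = x$timestamps, value = x$values,
             unit = x$unit, stringsAsFactors = FALSE)
}

is_regular <- function(series, tol = 1e-6) {
  n <- length(series)
  if (n < 3) return(TRUE)
  all(abs(diff(series$timestamps) - series$sample_period) <= tol)
}

#' Resample a series onto its nominal regular grid
#'
#' Irregular series are snapped to a regular grid from the first to the last
#' timestamp at `sample_period`.  Each grid point takes the most recent
#' observed value, carried across gaps of at most `max_gap` seconds
#' (default twice the sample period); grid points further from any
#' observation become missing (`NA`).
#'
#' @param series a [sensor_series()].
#' @param max_gap maximum age, in seconds, a value may be carried forward.
#' @return a regular `sensor_series`.
#' @export
regularize_series <- function(series, max_gap = 2 * series$sample_period) {
  stopifnot(inherits(series, "sensor_series"))
  if (is_regular(series)) return(series)
  sp <- series$sample_period
  grid <- seq(series$timestamps[1], series$timestamps[length(series)], by = sp)
  idx <- findInterval(grid, series$timestamps)
  val <- series$values[pmax(idx, 1L)]
  age <- grid - series$timestamps[pmax(idx, 1L)]
  val[idx == 0L | age > max_gap] <- NA_real_
  sensor_series(grid, val, series$unit, sp)
}

#' Fraction of time a series spends inside a value band
#'
#' The common kernel of every "% of the time" KPI: the percentage of
#' non-missing samples whose value lies in the interval
#' `[lower, upper]`, with each bound optionally open.  Under uniform
#' sampling the sample-count fraction equals the time fraction; irregular
#' series are first passed through [regularize_series()].
#'
#' @param series a [sensor_series()].
#' @param lower,upper band bounds (may be `-Inf`/`Inf`).
#' @param include_lower,include_upper whether each bound belongs to the band.
#' @return a percentage in \[0, 100\].
#' @examples
#' s <- sensor_series(1:10, c(1:5, 21:25), "degC", 1)
#' fraction_of_time(s, 20, 30)  # 50
#' @export
fraction_of_time <- function(series, lower = -Inf, upper = Inf,
                             include_lower = TRUE, include_upper = TRUE) {
  stopifnot(inherits(series, "sensor_series"))
  if (!is_regular(series)) series <- regularize_series(series)
  v <- series$values[!is.na(series$values)]
  if (length(v) == 0) {
    err_empty_input("series has no non-missing samples; KPI is undefined")
  }
  lo <- if (include_lower) v >= lower else v > lower
  hi <- if (include_upper) v <= upper else v < upper
  100 * sum(lo & hi) / length(v)
}

#' Tri-axial accelerometer stream
#'
#' High-rate wristband/truck accelerometer log in g units.  The measurable
#' range defaults to the wristband hardware rails of -8.00 g and +7.98 g;
#' raw samples pinned at a rail are how sensor saturation manifests.
#'
#' @param timestamps strictly increasing sample times (numeric seconds or
#'   `POSIXct`).
#' @param ax,ay,az per-axis acceleration in g.
#' @param sample_rate nominal sample rate in Hz; defaults to the reciprocal
#'   median timestamp difference.
#' @param range_low,range_high measurable range in g.
#' @return an object of class `accel_stream`.
#' @export
accel_stream <- function(timestamps, ax, ay, az, sample_rate = NULL,
                         range_low = -8.00, range_high = 7.98) {
  t <- as.numeric(timestamps)
  n <- length(t)
  if (!all(lengths(list(ax, ay, az)) == n)) {
    err_invalid_input("ax, ay, az must match the number of timestamps")
  }
  if (n == 0) err_empty_input("accelerometer stream is empty")
  if (n > 1 && any(diff(t) <= 0)) {
    err_invalid_input("timestamps must be strictly increasing")
  }
  if (range_low >= range_high) err_invalid_input("range_low must be < range_high")
  axes <- cbind(ax = as.numeric(ax), ay = as.numeric(ay), az = as.numeric(az))
  if (anyNA(axes) || !all(is.finite(axes))) {
    err_invalid_input("axis values must be finite")
  }
  if (any(axes < range_low - 1e-9) || any(axes > range_high + 1e-9)) {
    err_invalid_input("axis values outside the measurable range")
  }
  if (is.null(sample_rate)) {
    sample_rate <- if (n > 1) 1 / stats::median(diff(t)) else 1
  }
  if (sample_rate <= 0) err_invalid_input("sample_rate must be > 0")
  structure(
    list(timestamps = t, ax = axes[, "ax"], ay = axes[, "ay"], az = axes[, "az"],
         sample_rate = as.numeric(sample_rate),
         range_low = range_low, range_high = range_high),
    class = "accel_stream"
  )
}

#' @export
length.accel_stream <- function(x) length(x$timestamps)

#' @export
print.accel_stream <- function(x, ...) {
  cat(sprintf("<accel_stream> %d samples, %g Hz, range [%.2f, %.2f] g\n",
              length(x), x$sample_rate, x$range_low, x$range_high))
  invisible(x)
}

#' Acceleration module (Euclidean norm of the three axes)
#'
#' `sqrt(ax^2 + ay^2 + az^2)`, the magnitude of the measured acceleration
#' vector in g.  Vectorised over samples.
#'
#' @param ax,ay,az per-axis acceleration in g; must be finite.
#' @return non-negative module in g.
#' @examples
#' accel_module(3, 4, 0)  # 5
#' @export
accel_module <- function(ax, ay, az) {
  if (!all(is.finite(ax), is.finite(ay), is.finite(az))) {
    err_invalid_input("accel_module requires finite inputs")
  }
  sqrt(ax^2 + ay^2 + az^2)
}

# module of every sample in a stream
stream_module <- function(stream) {
  accel_module(stream$ax, stream$ay, stream$az)
}

#' Per-second maximum of the acceleration module
#'
#' Aggregates a raw stream to one value per wall-clock second: the maximum
#' acceleration module over the samples falling in that second.  Seconds are
#' half-open intervals `[s, s+1)` aligned to integer epoch seconds; covered
#' seconds with no samples are flagged missing.
#'
#' @param stream an [accel_stream()].
#' @return a 1 Hz [sensor_series()] in g.
#' @export
per_second_max_module <- function(stream) {
  stopifnot(inherits(stream, "accel_stream"))
  if (length(stream) == 0) err_empty_input("accelerometer stream is empty")
  mod <- stream_module(stream)
  sec <- floor(stream$timestamps)
  grid <- seq(min(sec), max(sec))
  agg <- tapply(mod, sec, max)
  val <- rep(NA_real_, length(grid))
  val[match(as.numeric(names(agg)), grid)] <- as.numeric(agg)
  sensor_series(grid, val, "g", 1)
}

#' Check that two series share one clock
#'
#' Paired KPIs (e.g. heat-stress index from temperature and humidity) need
#' sample-wise aligned series; this verifies identical timestamps.
#'
#' @param a,b [sensor_series()] objects.
#' @return invisibly `TRUE`; signals an alignment error otherwise.
#' @export
check_aligned <- function(a, b) {
  if (length(a) != length(b) ||
      any(abs(a$timestamps - b$timestamps) > 1e-6)) {
    err_alignment("series are not time-aligned (timestamps differ)")
  }
  invisible(TRUE)
}

## ---- CSV interfaces ------------------------------------------------------

#' Read / write a sensor series CSV
#'
#' Columns: `timestamp` (ISO-8601 UTC or numeric seconds), `value`, `unit`.
#'
#' @param file path to a CSV file.
#' @param sample_period optional nominal period override (seconds).
#' @return [sensor_series()] for the reader; the file path, invisibly, for
#'   the writer.
#' @export
read_sensor_csv <- function(file, sample_period = NULL) {
  df <- utils::read.csv(file, stringsAsFactors = FALSE)
  need <- c("timestamp", "value", "unit")
  miss <- setdiff(need, names(df))
  if (length(miss)) err_schema(paste("missing column(s):", paste(miss, collapse = ", ")))
  if (nrow(df) == 0) err_empty_input(paste("no rows in", file))
  sensor_series(parse_iso8601(df$timestamp), df$value, df$unit[1], sample_period)
}

#' @rdname read_sensor_csv
#' @param series a [sensor_series()] to write.
#' @export
write_sensor_csv <- function(series, file) {
  stopifnot(inherits(series, "sensor_series"))
  digits <- if (series$sample_period < 1) 3L else 0L
  df <- data.frame(timestamp = iso8601(series$timestamps, digits),
                   value = series$values, unit = series$unit)
  utils::write.csv(df, file, row.names = FALSE)
  invisible(file)
}

#' Read / write an accelerometer CSV
#'
#' Columns: `timestamp` (ISO-8601 UTC with fractional seconds, or numeric
#' seconds), `ax`, `ay`, `az` -- mirroring the wristband CSV export.
#'
#' @param file path to a CSV file.
#' @param ... passed on to [accel_stream()] (e.g. `range_low`, `range_high`).
#' @return [accel_stream()] for the reader; the file path, invisibly, for
#'   the writer.
#' @export
read_accel_csv <- function(file, ...) {
  df <- utils::read.csv(file, stringsAsFactors = FALSE)
  need <- c("timestamp", "ax", "ay", "az")
  miss <- setdiff(need, names(df))
  if (length(miss)) err_schema(paste("missing column(s):", paste(miss, collapse = ", ")))
  if (nrow(df) == 0) err_empty_input(paste("no rows in", file))
  accel_stream(parse_iso8601(df$timestamp), df$ax, df$ay, df$az, ...)
}

#' @rdname read_accel_csv
#' @param stream an [accel_stream()] to write.
#' @export
write_accel_csv <- function(stream, file) {
  stopifnot(inherits(stream, "accel_stream"))
  df <- data.frame(timestamp = sprintf("%.4f", stream$timestamps),
                   ax = stream$ax, ay = stream$ay, az = stream$az)
  utils::write.csv(df, file, row.names = FALSE)
  invisible(file)
}
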