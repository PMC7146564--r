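# Transport-phase KPIs.
#
# Four thermal-comfort time fractions from the truck's temperature and
# humidity sensors, plus an "abrupt movements" score: the fraction of the
# journey during which the smoothed z-score peak detector flags the
# acceleration module as unstable, i.e. the driver brakes or accelerates
# suddenly.

#' Smoothed z-score peak-detector parameters
#'
#' @param lag moving-window length in samples (>= 2).  Controls both how
#'   much history is smoothed over and how quickly the detector adapts to
#'   changes in the long-run level.
#' @param threshold z-score at which a sample is signalled: the number of
#'   moving standard deviations a new point must exceed the moving mean by.
#' @param influence in \[0, 1\]: weight of signalled points in the moving
#'   filters.  0 means signals leave the detection threshold untouched.
#' @return an object of class `zpeak_params`.
#' @export
zpeak_params <- function(lag = 25L, threshold = 5, influence = 0) {
  lag <- as.integer(lag)
  if (is.na(lag) || lag < 2L) err_config("lag must be an integer >= 2")
  if (!is.finite(threshold) || threshold <= 0) err_config("threshold must be > 0")
  if (!is.finite(influence) || influence < 0 || influence > 1) {
    err_config("influence must lie in [0, 1]")
  }
  structure(list(lag = lag, threshold = threshold, influence = influence),
            class = "zpeak_params")
}

#' @export
print.zpeak_params <- function(x, ...) {
  cat(sprintf("<zpeak_params> lag=%d, threshold=%g, influence=%g\n",
              x$lag, x$threshold, x$influence))
  invisible(x)
}

#' Smoothed z-score peak detection
#'
#' Streams through `x` keeping a moving mean and standard deviation of the
#' previous `lag` *filtered* values.  A new point more than
#' `threshold` moving standard deviations away from the moving mean is
#' signalled (+1 above, -1 below); a signalled point enters the filtered
#' series as `influence * x[i] + (1 - influence) * filtered[i-1]`, so with
#' `influence = 0` signals never move the detection threshold.  Unsignalled
#' points enter unchanged.  The first `lag` samples seed the filters and
#' receive signal 0.  A tie at exactly `threshold` standard deviations is
#' not signalled.
#'
#' @param x numeric vector, length greater than `lag`.
#' @param params a [zpeak_params()].
#' @param sd_type denominator of the moving standard deviation:
#'   `"population"` (n, the default; the filter is a descriptive moving
#'   estimate) or `"sample"` (n-1).
#' @return an object of class `zpeak_result`: a list of three vectors of
#'   `length(x)` -- `signals` in \{-1, 0, +1\}, `avg_filter` and
#'   `std_filter` (the moving estimates; `NA` before the seed window is
#'   full).
#' @examples
#' x <- c(rep(1, 40), 5, rep(1, 19))
#' r <- zpeak(x, zpeak_params(25, 5, 0))
#' which(r$signals != 0)  # 41
#' @export
zpeak <- function(x, params = zpeak_params(), sd_type = c("population", "sample")) {
  stopifnot(inherits(params, "zpeak_params"))
  sd_type <- match.arg(sd_type)
  x <- as.numeric(x)
  n <- length(x)
  lag <- params$lag
  if (n <= lag) {
    err_insufficient_data(sprintf("need more than lag = %d samples, got %d", lag, n))
  }
  if (anyNA(x) || !all(is.finite(x))) err_invalid_input("series must be finite")

  mov_sd <- function(w) {
    if (sd_type == "population") sqrt(mean((w - mean(w))^2)) else stats::sd(w)
  }

  signals <- integer(n)
  filtered <- x
  avg_f <- rep(NA_real_, n)
  std_f <- rep(NA_real_, n)
  avg_f[lag] <- mean(x[1:lag])
  std_f[lag] <- mov_sd(x[1:lag])
  for (i in (lag + 1L):n) {
    dev <- x[i] - avg_f[i - 1L]
    if (abs(dev) > params$threshold * std_f[i - 1L]) {
      signals[i] <- if (dev > 0) 1L else -1L
      filtered[i] <- params$influence * x[i] +
        (1 - params$influence) * filtered[i - 1L]
    } else {
      signals[i] <- 0L
      filtered[i] <- x[i]
    }
    w <- filtered[(i - lag + 1L):i]
    avg_f[i] <- mean(w)
    std_f[i] <- mov_sd(w)
  }
  structure(list(signals = signals, avg_filter = avg_f, std_filter = std_f),
            class = "zpeak_result", params = params)
}

#' @export
print.zpeak_result <- function(x, ...) {
  p <- attr(x, "params")
  cat(sprintf("<zpeak_result> %d samples, %d signalled (lag=%d, threshold=%g, influence=%g)\n",
              length(x$signals), sum(x$signals != 0), p$lag, p$threshold, p$influence))
  invisible(x)
}

#' Transport thermal-comfort KPIs
#'
#' Percentages of journey time the flock spends outside the thermal comfort
#' window: temperature above 31 degC or below 18 degC, relative humidity
#' above 80% or below 60%.
#'
#' @param temps,rhs time-aligned [sensor_series()] from one journey (degC
#'   and %RH).
#' @param temp_high,temp_low,rh_high,rh_low comfort bounds; a sample counts
#'   when strictly beyond the bound.
#' @return named numeric (percent): `low_temperature`, `high_temperature`,
#'   `low_relative_humidity`, `high_relative_humidity`.
#' @export
thermal_comfort_kpis <- function(temps, rhs, temp_high = 31, temp_low = 18,
                                 rh_high = 80, rh_low = 60) {
  check_aligned(temps, rhs)
  if (temps$unit != "degC" || rhs$unit != "%RH") {
    err_invalid_input("expected a degC series and a %RH series")
  }
  c(low_temperature = fraction_of_time(temps, -Inf, temp_low, include_upper = FALSE),
    high_temperature = fraction_of_time(temps, temp_high, Inf, include_lower = FALSE),
    low_relative_humidity = fraction_of_time(rhs, -Inf, rh_low, include_upper = FALSE),
    high_relative_humidity = fraction_of_time(rhs, rh_high, Inf, include_lower = FALSE))
}

#' Abrupt movements KPI
#'
#' Applies the smoothed z-score peak detector to the acceleration module of
#' the journey stream and returns the percentage of evaluated samples (the
#' warm-up window of `lag` samples is excluded from the denominator, since
#' no signal is defined there) that are signalled in either direction.
#'
#' @param stream the journey [accel_stream()].
#' @param params a [zpeak_params()].
#' @param sd_type passed to [zpeak()].
#' @return a percentage in \[0, 100\].
#' @export
abrupt_movements_kpi <- function(stream, params = zpeak_params(),
                                 sd_type = "population") {
  stopifnot(inherits(stream, "accel_stream"))
  mod <- stream_module(stream)
  r <- zpeak(mod, params, sd_type = sd_type)
  evaluated <- r$signals[-seq_len(params$lag)]
  100 * sum(evaluated != 0) / length(evaluated)
}

#' All five transport-phase KPIs
#'
#' @inheritParams thermal_comfort_kpis
#' @inheritParams abrupt_movements_kpi
#' @return named numeric of length 5 (percent).
#' @export
transport_kpis <- function(temps, rhs, stream, params = zpeak_params()) {
  c(thermal_comfort_kpis(temps, rhs),
    abrupt_movements = abrupt_movements_kpi(stream, params))
}

#' Read / write a journey CSV bundle
#'
#' One file per journey with columns `timestamp`, `temp_c`, `rh`, `ax`,
#' `ay`, `az`.
#'
#' @param file path to a CSV file.
#' @param ... passed to [accel_stream()].
#' @return a list with elements `temps`, `rhs` ([sensor_series()]) and
#'   `stream` ([accel_stream()]).
#' @export
read_journey_csv <- function(file, ...) {
  df <- utils::read.csv(file, stringsAsFactors = FALSE)
  need <- c("timestamp", "temp_c", "rh", "ax", "ay", "az")
  miss <- setdiff(need, names(df))
  if (length(miss)) err_schema(paste("missing column(s):", paste(miss, collapse = ", ")))
  if (nrow(df) == 0) err_empty_input(paste("no rows in", file))
  t <- parse_iso8601(df$timestamp)
  list(temps = sensor_series(t, df$temp_c, "degC"),
       rhs = sensor_series(t, df$rh, "%RH"),
       stream = accel_stream(t, df$ax, df$ay, df$az, ...))
}

#' @rdname read_journey_csv
#' @param journey a list as returned by [read_journey_csv()].
#' @export
write_journey_csv <- function(journey, file) {
  check_aligned(journey$temps, journey$rhs)
  df <- data.frame(timestamp = iso8601(journey$temps$timestamps),
                   temp_c = journey$temps$values, rh = journey$rhs$values,
                   ax = journey$stream$ax, ay = journey$stream$ay,
                   az = journey$stream$az)
  utils::write.csv(df, file, row.names = FALSE)
  invisible(file)
}
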