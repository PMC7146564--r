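# Loading-phase KPIs from wristband accelerometer streams.
#
# Operators load birds into transport cages by hand; a wrist-worn
# accelerometer records arm-sway acceleration.  Three indicators summarise
# a loading session: how often the sensor saturates (a proxy for forces
# beyond its measurable range), and the mean and spread of the per-minute
# accumulated acceleration.

# seconds covered by the stream, as integer epoch seconds
covered_seconds <- function(stream) {
  seq(floor(min(stream$timestamps)), floor(max(stream$timestamps)))
}

# epoch-minute blocks fully inside the covered second span; a minute m is
# complete iff seconds 60m .. 60m+59 all lie within the span (partial
# leading and trailing minutes are excluded to avoid biased accumulations)
complete_minutes <- function(stream) {
  secs <- covered_seconds(stream)
  m_lo <- ceiling(secs[1] / 60)
  m_hi <- floor((secs[length(secs)] + 1) / 60) - 1
  if (m_hi < m_lo) return(numeric(0))
  m_lo:m_hi
}

#' Per-second sensor-saturation flags
#'
#' A wall-clock second is flagged saturated iff any raw sample within it has
#' any axis pinned at a rail of the measurable range.  Clipping is the only
#' footprint an out-of-range force leaves, so rail equality (within
#' `epsilon`) is how "exceeds the range" is detected.
#'
#' @param stream an [accel_stream()].
#' @param epsilon tolerance around the rails, g (default exact equality).
#' @return data.frame with columns `second` (epoch s) and `saturated`
#'   (logical), one row per covered second.
#' @export
saturation_flags <- function(stream, epsilon = 0) {
  stopifnot(inherits(stream, "accel_stream"))
  sat <- stream$ax <= stream$range_low + epsilon |
    stream$ax >= stream$range_high - epsilon |
    stream$ay <= stream$range_low + epsilon |
    stream$ay >= stream$range_high - epsilon |
    stream$az <= stream$range_low + epsilon |
    stream$az >= stream$range_high - epsilon
  sec <- floor(stream$timestamps)
  grid <- covered_seconds(stream)
  agg <- tapply(sat, sec, any)
  flags <- rep(FALSE, length(grid))
  flags[match(as.numeric(names(agg)), grid)] <- as.logical(agg)
  data.frame(second = grid, saturated = flags)
}

#' Saturation rate (saturated seconds per minute)
#'
#' Mean, over complete minutes, of the number of saturated seconds in the
#' minute.  A value of 0.98 reads as "the sensor saturates almost once per
#' minute".
#'
#' @inheritParams saturation_flags
#' @return saturated seconds per minute, in \[0, 60\].
#' @export
saturation_rate <- function(stream, epsilon = 0) {
  mins <- complete_minutes(stream)
  if (length(mins) == 0) {
    err_insufficient_data("stream must cover at least one full minute")
  }
  flags <- saturation_flags(stream, epsilon)
  per_min <- vapply(mins, function(m) {
    sum(flags$saturated[flags$second >= m * 60 & flags$second < (m + 1) * 60])
  }, numeric(1))
  mean(per_min)
}

#' Per-minute accumulated acceleration
#'
#' For each complete minute, the sum of the 60 per-second maxima of the
#' acceleration module (g.s per minute).  Seconds with no samples contribute
#' 0 and are reported via a message.
#'
#' @param stream an [accel_stream()].
#' @return named numeric vector of accumulations, one per complete minute;
#'   names are the epoch seconds the minutes start at.
#' @export
accumulation_per_minute <- function(stream) {
  mins <- complete_minutes(stream)
  if (length(mins) == 0) {
    err_insufficient_data("stream must cover at least one full minute")
  }
  psm <- per_second_max_module(stream)
  n_missing <- sum(is.na(psm$values))
  if (n_missing > 0) {
    message(sprintf("accumulation_per_minute: %d empty second(s) contribute 0",
                    n_missing))
  }
  v <- psm$values
  v[is.na(v)] <- 0
  acc <- vapply(mins, function(m) {
    sum(v[psm$timestamps >= m * 60 & psm$timestamps < (m + 1) * 60])
  }, numeric(1))
  names(acc) <- mins * 60
  acc
}

#' The three loading-phase KPIs
#'
#' Saturation rate plus the mean and standard deviation of the per-minute
#' accumulated acceleration.
#'
#' @inheritParams saturation_flags
#' @param sd_type `"sample"` (n-1 denominator, the default) or
#'   `"population"` for the accumulation standard deviation.
#' @return named numeric: `saturation_rate` (per min), `mean_accumulation`
#'   and `std_accumulation` (g.s per minute).
#' @export
loading_kpis <- function(stream, epsilon = 0, sd_type = c("sample", "population")) {
  sd_type <- match.arg(sd_type)
  acc <- accumulation_per_minute(stream)
  s <- if (length(acc) > 1) stats::sd(acc) else 0
  if (sd_type == "population") s <- s * sqrt((length(acc) - 1) / length(acc))
  c(saturation_rate = saturation_rate(stream, epsilon),
    mean_accumulation = mean(acc),
    std_accumulation = s)
}
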