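# Breeding-phase KPIs.
#
# Five indicators summarise the rearing climate: two temperature-deviation
# fractions against a farmer-provided optimal-temperature profile, and three
# heat-stress-index (HIS) exposure fractions combining temperature and
# relative humidity.

#' Optimal-temperature comfort profile
#'
#' Farmers set discrete temperature setpoints that change as the flock
#' grows; the profile is a step function: each segment's setpoint holds from
#' its start until the next segment begins (the last segment extends to the
#' end of the rearing period).
#'
#' @param start strictly increasing segment start times (numeric seconds or
#'   `POSIXct`).
#' @param optimal_temp_c optimal temperature per segment, degrees Celsius.
#' @param range sanity range for setpoints, degrees Celsius.
#' @return an object of class `comfort_profile`.
#' @export
comfort_profile <- function(start, optimal_temp_c, range = c(10, 40)) {
  s <- as.numeric(start)
  o <- as.numeric(optimal_temp_c)
  if (length(s) == 0 || length(s) != length(o)) {
    err_config("profile needs matching, non-empty start and temperature vectors")
  }
  if (length(s) > 1 && any(diff(s) <= 0)) {
    err_config("profile segment starts must be strictly increasing")
  }
  if (any(!is.finite(o)) || any(o < range[1]) || any(o > range[2])) {
    err_config(sprintf("optimal temperatures must lie in [%g, %g] degC",
                       range[1], range[2]))
  }
  structure(list(start = s, optimal_temp_c = o), class = "comfort_profile")
}

#' @export
print.comfort_profile <- function(x, ...) {
  cat(sprintf("<comfort_profile> %d segment(s), setpoints %s degC\n",
              length(x$start), paste(x$optimal_temp_c, collapse = ", ")))
  invisible(x)
}

#' Optimal temperature at given times
#'
#' @param profile a [comfort_profile()].
#' @param t times (numeric seconds or `POSIXct`).
#' @return the setpoint in force at each time.
#' @export
optimal_at <- function(profile, t) {
  stopifnot(inherits(profile, "comfort_profile"))
  t <- as.numeric(t)
  i <- findInterval(t, profile$start)
  if (any(i == 0)) {
    err_config("comfort profile does not cover the start of the series")
  }
  profile$optimal_temp_c[i]
}

#' Temperature warning and alarm KPIs
#'
#' `temperature_warning_kpi()` is the percentage of (non-missing) rearing
#' time with an absolute deviation from the optimal temperature between
#' 1.5 and 3 degC inclusive (mild discomfort); `temperature_alarm_kpi()`
#' the percentage with a deviation strictly greater than 3 degC (severe
#' discomfort).  The 3 degC boundary belongs to the warning band, so no
#' sample contributes to both.
#'
#' @param temps a [sensor_series()] in degC.
#' @param profile a [comfort_profile()] covering the series' span.
#' @param warn_band deviation band (degC) counted as a warning, inclusive.
#' @return a percentage in \[0, 100\].
#' @export
temperature_warning_kpi <- function(temps, profile, warn_band = c(1.5, 3)) {
  dev <- temperature_deviation(temps, profile)
  fraction_of_time(dev, warn_band[1], warn_band[2])
}

#' @rdname temperature_warning_kpi
#' @param alarm_above deviation (degC) strictly above which a sample is an
#'   alarm.
#' @export
temperature_alarm_kpi <- function(temps, profile, alarm_above = 3) {
  dev <- temperature_deviation(temps, profile)
  fraction_of_time(dev, alarm_above, Inf, include_lower = FALSE)
}

# |T - optimal(t)| as a sensor series (unit kept as degC)
temperature_deviation <- function(temps, profile) {
  stopifnot(inherits(temps, "sensor_series"))
  if (temps$unit != "degC") err_invalid_input("temperature series must be in degC")
  opt <- optimal_at(profile, temps$timestamps)
  sensor_series(temps$timestamps, abs(temps$values - opt), "degC",
                temps$sample_period)
}

## ---- heat-stress index ---------------------------------------------------

# registry of HIS formulas; any registered formula must be monotonically
# non-decreasing in temperature (fixed RH) and in RH (fixed temperature)
.his_registry <- new.env(parent = emptyenv())

#' Register a heat-stress-index formula
#'
#' The package ships `"thi_default"`, the livestock temperature-humidity
#' index `THI = 0.8 T + (RH/100) (T - 14.4) + 46.4` (T in degC), which
#' yields values on the 70--81 scale the stress bands are defined on.
#' Alternative formulas (e.g. a lookup-table digitisation of a published
#' chart) can be registered under their own id and selected via
#' [his_config()].
#'
#' @param id formula identifier.
#' @param fn `function(temp, rh)` returning the index; must be monotone
#'   non-decreasing in both arguments (spot-checked on a coarse grid).
#' @export
register_his_formula <- function(id, fn) {
  stopifnot(is.character(id), length(id) == 1, is.function(fn))
  tg <- seq(10, 40, by = 5)
  rg <- seq(0, 100, by = 20)
  for (r in rg) {
    v <- fn(tg, rep(r, length(tg)))
    if (any(diff(v) < -1e-9)) err_config("HIS formula must be monotone in temperature")
  }
  for (t in tg) {
    v <- fn(rep(t, length(rg)), rg)
    if (any(diff(v) < -1e-9)) err_config("HIS formula must be monotone in humidity")
  }
  assign(id, fn, envir = .his_registry)
  invisible(id)
}

#' Heat-stress configuration
#'
#' Stress bands over the index value: alert `[70, 76)`, danger `[76, 81]`,
#' emergency `(81, Inf)`.  The bands are disjoint and ordered.
#'
#' @param formula_id id of a registered HIS formula.
#' @param alert_band half-open `[lo, hi)` alert band.
#' @param danger_band closed `[lo, hi]` danger band; emergency is everything
#'   strictly above its upper edge.
#' @return an object of class `his_config`.
#' @export
his_config <- function(formula_id = "thi_default",
                       alert_band = c(70, 76), danger_band = c(76, 81)) {
  if (!(alert_band[1] < alert_band[2] && alert_band[2] <= danger_band[1] &&
        danger_band[1] < danger_band[2])) {
    err_config("stress bands must be ordered and non-overlapping")
  }
  structure(list(formula_id = formula_id, alert_band = as.numeric(alert_band),
                 danger_band = as.numeric(danger_band)),
            class = "his_config")
}

his_formula <- function(config) {
  if (!exists(config$formula_id, envir = .his_registry)) {
    err_config(sprintf("unknown HIS formula '%s'", config$formula_id))
  }
  get(config$formula_id, envir = .his_registry)
}

#' Heat-stress index value
#'
#' @param temp temperature in degC.
#' @param rh relative humidity in \[0, 100\].
#' @param config a [his_config()].
#' @return the index value (vectorised).
#' @examples
#' his_value(25, 50)  # 71.7, inside the alert band
#' @export
his_value <- function(temp, rh, config = his_config()) {
  if (any(rh < 0 | rh > 100, na.rm = TRUE)) {
    err_invalid_input("relative humidity must lie in [0, 100]")
  }
  his_formula(config)(temp, rh)
}

#' HIS situation KPIs: alert, danger, emergency exposure
#'
#' Fractions of (non-missing, pairwise complete) rearing time the flock
#' spends in each stress band of the heat-stress index.  The bands are
#' disjoint, so the three percentages sum to at most 100.
#'
#' @param temps,rhs time-aligned [sensor_series()] (degC and %RH).
#' @param config a [his_config()].
#' @return named numeric: `alert_situation`, `danger_situation`,
#'   `emergency_situation` (percent).
#' @export
his_situation_kpis <- function(temps, rhs, config = his_config()) {
  check_aligned(temps, rhs)
  if (temps$unit != "degC" || rhs$unit != "%RH") {
    err_invalid_input("expected a degC series and a %RH series")
  }
  ok <- !is.na(temps$values) & !is.na(rhs$values)
  if (!any(ok)) err_empty_input("no complete (temperature, humidity) pairs")
  h <- his_value(temps$values[ok], rhs$values[ok], config)
  n <- length(h)
  ab <- config$alert_band
  db <- config$danger_band
  c(alert_situation = 100 * sum(h >= ab[1] & h < ab[2]) / n,
    danger_situation = 100 * sum(h >= db[1] & h <= db[2]) / n,
    emergency_situation = 100 * sum(h > db[2]) / n)
}

#' All five breeding-phase KPIs
#'
#' @inheritParams his_situation_kpis
#' @inheritParams temperature_warning_kpi
#' @return named numeric of length 5 (percent): `temperature_warning`,
#'   `temperature_alarm`, `alert_situation`, `danger_situation`,
#'   `emergency_situation`.
#' @export
breeding_kpis <- function(temps, rhs, profile, config = his_config()) {
  c(temperature_warning = temperature_warning_kpi(temps, profile),
    temperature_alarm = temperature_alarm_kpi(temps, profile),
    his_situation_kpis(temps, rhs, config))
}
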