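# Seeded generators with planted ground truth for every pipeline input.
#
# Band-occupancy KPIs (temperature deviation, heat stress, transport
# humidity) are planted by stratified construction: the generator decides
# exactly which samples fall in which band and then jitters values strictly
# inside the band, so the KPI engine must reproduce the planted fractions
# up to rounding of counts.  Algorithm-mediated quantities (the abrupt
# movements score, wristband aggregates) are planted approximately and
# recovered within a stated Monte-Carlo tolerance.  Every generator is a
# pure function of its scenario, including the seed.

# epoch of 2019-04-30T00:00:00Z; an arbitrary fixed chain start date
.T0 <- 1556582400

#' Breeding-phase scenario
#'
#' Describes one simulated rearing period: its duration, sensor sampling
#' period, comfort profile, and the planted fractions of time to spend in
#' each temperature-deviation and heat-stress band.  The planted defaults
#' reproduce the magnitudes of a real rearing period (warning 18.31%,
#' alarm 34.48%, alert 7.89%, danger 5.62%, emergency 68.30%).
#'
#' The generator inverts the default temperature-humidity index to place
#' each sample's humidity, which is feasible for every band combination
#' only when the optimal-temperature setpoints lie in \[28, 29\] degC; the
#' default profile steps from 29 to 28.3 degC halfway through.
#'
#' @param duration_days rearing duration (default 49 days, about 7 weeks).
#' @param sample_period sensor period in seconds (default 30 s).
#' @param profile optional [comfort_profile()]; segment starts are relative
#'   to the scenario start.
#' @param warning,alarm planted temperature-deviation fractions (percent).
#' @param alert,danger,emergency planted heat-stress fractions (percent).
#' @param seed integer RNG seed.
#' @param mode `"stratified"` plants exact band counts; `"iid"` draws each
#'   sample's band independently (for statistical tests).
#' @return an object of class `farm_scenario`.
#' @export
farm_scenario <- function(duration_days = 49, sample_period = 30,
                          profile = NULL,
                          warning = 18.31, alarm = 34.48,
                          alert = 7.89, danger = 5.62, emergency = 68.30,
                          seed = 1L, mode = c("stratified", "iid")) {
  mode <- match.arg(mode)
  fr <- c(warning = warning, alarm = alarm, alert = alert, danger = danger,
          emergency = emergency)
  if (any(fr < 0 | fr > 100)) err_config("planted fractions must lie in [0, 100]")
  if (warning + alarm > 100) err_config("warning + alarm must be <= 100")
  if (alert + danger + emergency > 100) {
    err_config("alert + danger + emergency must be <= 100")
  }
  dur <- duration_days * 86400
  if (is.null(profile)) {
    profile <- comfort_profile(.T0 + c(0, dur / 2), c(29, 28.3))
  } else {
    if (any(profile$optimal_temp_c < 28 | profile$optimal_temp_c > 29)) {
      err_config("generator setpoints must lie in [28, 29] degC for all bands to be feasible")
    }
  }
  structure(list(duration_days = duration_days, sample_period = sample_period,
                 profile = profile, warning = warning, alarm = alarm,
                 alert = alert, danger = danger, emergency = emergency,
                 seed = as.integer(seed), mode = mode),
            class = "farm_scenario")
}

# allocate n samples to bands: exact rounded counts (stratified) or
# independent draws (iid); returns an integer band index per sample
allocate_bands <- function(n, fractions, mode) {
  p <- fractions / 100
  rest <- 1 - sum(p)
  probs <- c(p, rest)
  if (mode == "iid") {
    sample.int(length(probs), n, replace = TRUE, prob = probs)
  } else {
    counts <- round(n * probs[-length(probs)])
    counts <- c(counts, n - sum(counts))
    if (counts[length(counts)] < 0) err_config("planted fractions are infeasible at this n")
    sample(rep.int(seq_along(probs), counts))
  }
}

# invert THI = 0.8 T + (RH/100)(T - 14.4) + 46.4 for RH at a given T
rh_for_thi <- function(thi, temp) 100 * (thi - 0.8 * temp - 46.4) / (temp - 14.4)

#' Generate a rearing-period climate with planted KPI fractions
#'
#' Produces time-aligned temperature and relative-humidity series whose
#' five breeding KPIs reproduce the scenario's planted fractions (exactly,
#' up to count rounding, in stratified mode).  Each sample is assigned a
#' temperature-deviation band and a heat-stress band; the temperature is
#' the profile setpoint plus a within-band deviation (hot deviations for
#' danger/emergency samples, cool ones otherwise), and the humidity is
#' obtained by inverting the default temperature-humidity index at a target
#' value strictly inside the sample's stress band.
#'
#' @param scenario a [farm_scenario()].
#' @return list with elements `temps` and `rhs` ([sensor_series()]) and
#'   `profile` (the [comfort_profile()] used).
#' @export
gen_farm_climate <- function(scenario) {
  stopifnot(inherits(scenario, "farm_scenario"))
  with_seed(scenario$seed, {
    sp <- scenario$sample_period
    n <- floor(scenario$duration_days * 86400 / sp)
    t <- .T0 + (seq_len(n) - 1) * sp
    opt <- optimal_at(scenario$profile, t)

    # 1 = warning, 2 = alarm, 3 = comfortable
    dev_band <- allocate_bands(n, c(scenario$warning, scenario$alarm), scenario$mode)
    dev <- numeric(n)
    dev[dev_band == 1] <- stats::runif(sum(dev_band == 1), 1.6, 2.9)
    dev[dev_band == 2] <- stats::runif(sum(dev_band == 2), 3.1, 6.0)
    dev[dev_band == 3] <- stats::runif(sum(dev_band == 3), 0.0, 1.4)

    # 1 = alert, 2 = danger, 3 = emergency, 4 = none
    his_band <- allocate_bands(n, c(scenario$alert, scenario$danger,
                                    scenario$emergency), scenario$mode)
    # hot deviations keep the index high enough for danger/emergency;
    # cool ones keep it low enough for alert/none
    sign <- ifelse(his_band %in% c(2, 3), 1, -1)
    temp <- opt + sign * dev

    thi_lo <- 0.8 * temp + 46.4          # RH = 0
    thi_hi <- 1.8 * temp + 32            # RH = 100
    target <- numeric(n)
    pick <- function(idx, lo, hi) {
      if (!length(idx)) return()
      if (any(hi <= lo)) err_config("infeasible stress band for generated temperature")
      target[idx] <<- stats::runif(length(idx), lo, hi)
    }
    i <- which(his_band == 1)            # alert: [70, 76)
    pick(i, pmax(70.05, thi_lo[i] + 0.05), pmin(75.95, thi_hi[i] - 0.05))
    i <- which(his_band == 2)            # danger: [76, 81]
    pick(i, pmax(76.05, thi_lo[i] + 0.05), pmin(80.95, thi_hi[i] - 0.05))
    i <- which(his_band == 3)            # emergency: > 81
    pick(i, pmax(81.10, thi_lo[i] + 0.05), pmin(86.00, thi_hi[i] - 0.05))
    i <- which(his_band == 4)            # no stress: < 70
    pick(i, pmax(58.00, thi_lo[i] + 0.05), pmin(69.90, thi_hi[i] - 0.05))

    rh <- rh_for_thi(target, temp)
    if (any(rh < 0 | rh > 100)) err_config("internal: humidity left [0, 100]")
    list(temps = sensor_series(t, temp, "degC", sp),
         rhs = sensor_series(t, rh, "%RH", sp),
         profile = scenario$profile)
  })
}

#' Generate a transport journey with planted KPI fractions
#'
#' Temperature stays inside the comfort window; a planted fraction of the
#' humidity samples exceeds 80% (stratified, exact up to count rounding).
#' The acceleration stream is a smooth unit-g base module with Gaussian
#' noise plus inserted spike episodes sized to be signalled by the peak
#' detector at the given parameters; the episodes cover approximately the
#' planted fraction of evaluated (post-warm-up) samples, detection itself
#' being algorithmic.
#'
#' @param duration_s journey length in seconds (default one hour).
#' @param high_rh planted high-relative-humidity fraction, percent.
#' @param abrupt planted abrupt-movements fraction, percent.
#' @param params a [zpeak_params()].
#' @param sample_period sensor period, seconds (default 1 s).
#' @param seed integer RNG seed.
#' @param noise_sd standard deviation of the base-module noise, g.
#' @return a journey list (`temps`, `rhs`, `stream`) as read by
#'   [read_journey_csv()].
#' @export
gen_transport <- function(duration_s = 3600, high_rh = 17, abrupt = 9.32,
                          params = zpeak_params(), sample_period = 1,
                          seed = 1L, noise_sd = 0.02) {
  n <- floor(duration_s / sample_period)
  if (n <= params$lag + 1) err_config("journey shorter than the detector lag")
  if (high_rh < 0 || high_rh > 100 || abrupt < 0 || abrupt > 100) {
    err_config("planted fractions must lie in [0, 100]")
  }
  evaluated <- n - params$lag
  n_spike <- round(evaluated * abrupt / 100)
  if (n_spike > evaluated * 0.8) {
    err_config("planted abrupt fraction infeasible at this lag/duration")
  }
  with_seed(seed, {
    t <- .T0 + (seq_len(n) - 1) * sample_period

    temp <- stats::runif(n, 23, 27)
    rh <- stats::runif(n, 62, 78)
    k <- round(n * high_rh / 100)
    if (k > 0) {
      idx <- sample.int(n, k)
      rh[idx] <- stats::runif(k, 81, 95)
    }

    mod <- 1 + stats::rnorm(n, 0, noise_sd)
    if (n_spike > 0) {
      # split the spike budget into short episodes and scatter them after
      # the warm-up window, keeping at least a few quiet samples between
      lens <- integer(0)
      left <- n_spike
      while (left > 0) {
        l <- min(left, sample(5:15, 1))
        lens <- c(lens, l)
        left <- left - l
      }
      gap_total <- evaluated - n_spike
      n_ep <- length(lens)
      cuts <- sort(sample.int(gap_total - 2 * (n_ep + 1), n_ep, replace = TRUE))
      gaps <- diff(c(0, cuts)) + 2
      pos <- params$lag + cumsum(gaps) + cumsum(c(0, lens[-n_ep]))
      for (e in seq_len(n_ep)) {
        idx <- pos[e] + seq_len(lens[e])
        mod[idx] <- mod[idx] + stats::runif(lens[e], 1, 2)
      }
    }
    # spread the module over three axes with a random direction per sample
    u <- matrix(stats::rnorm(3 * n), ncol = 3)
    u <- u / sqrt(rowSums(u^2))
    list(temps = sensor_series(t, temp, "degC", sample_period),
         rhs = sensor_series(t, rh, "%RH", sample_period),
         stream = accel_stream(t, u[, 1] * mod, u[, 2] * mod, u[, 3] * mod,
                               sample_rate = 1 / sample_period))
  })
}

#' Generate a wristband loading stream with planted aggregates
#'
#' Builds a stream whose loading KPIs recover the planted values: sensor
#' saturations are inserted as a per-minute Poisson process of rail-pinned
#' samples, and each minute's per-second maxima are constructed to sum to a
#' Gaussian draw around the planted accumulation mean/sd (so the recovered
#' mean and standard deviation match the planted ones up to Monte-Carlo
#' error over minutes).
#'
#' @param duration_s stream length in seconds; whole minutes (default
#'   10 min).
#' @param rate sample rate in Hz (desk-scale default 100; at most 1000).
#' @param sat_per_min planted Poisson rate of saturated seconds per minute.
#' @param accum_mean,accum_sd planted per-minute accumulation mean and
#'   standard deviation, g.s.
#' @param seed integer RNG seed.
#' @return an [accel_stream()].
#' @export
gen_wristband <- function(duration_s = 600, rate = 100, sat_per_min = 0.98,
                          accum_mean = 121.67, accum_sd = 48.99, seed = 1L) {
  if (rate > 1000) err_config("rate must be at most 1000 Hz")
  if (duration_s %% 60 != 0 || duration_s < 60) {
    err_config("duration_s must be a positive whole number of minutes")
  }
  rail <- 7.98
  # per-second maxima are kept below the rail so that an arbitrary 3-D
  # direction never pushes a single axis out of the measurable range
  max_accum <- 60 * 7.8
  if (accum_mean > max_accum) {
    err_config("planted accumulation mean exceeds what the range allows")
  }
  n_min <- duration_s / 60
  with_seed(seed, {
    sec_targets <- numeric(duration_s)    # per-second max-module targets
    rail_secs <- logical(duration_s)
    rail_mod <- numeric(duration_s)

    for (m in seq_len(n_min)) {
      secs <- (m - 1) * 60 + seq_len(60)
      k <- min(stats::rpois(1, sat_per_min), 59)
      r_mod <- numeric(0)
      if (k > 0) {
        rs <- sample(secs, k)
        rail_secs[rs] <- TRUE
        # rail-pinned sample: one axis at a rail, the others small
        r_mod <- vapply(rs, function(s) {
          other <- stats::runif(2, -0.5, 0.5)
          rail_mod[s] <<- accel_module(rail, other[1], other[2])
          rail_mod[s]
        }, numeric(1))
      }
      lo <- sum(r_mod) + (60 - k) * 0.25
      a_m <- if (accum_sd > 0) {
        v <- -Inf
        while (v < lo + 3 || v > max_accum) {
          v <- stats::rnorm(1, accum_mean, accum_sd)
        }
        v
      } else {
        if (accum_mean < lo + 3) err_config("planted accumulation too small for saturations")
        accum_mean
      }
      base <- (a_m - sum(r_mod)) / (60 - k)
      if (base + 0.05 > 7.9) err_config("per-second accumulation target exceeds the rail")
      e <- stats::runif(60 - k, -0.05, 0.05)
      e <- e - mean(e)                     # zero-sum jitter keeps the sum exact
      sec_targets[secs[!rail_secs[secs]]] <- base + e
    }

    # raw samples: per second `rate` samples; one carries the target max
    n <- duration_s * rate
    t <- .T0 + (seq_len(n) - 1) / rate
    sec_of <- rep(seq_len(duration_s), each = rate)
    frac <- stats::runif(n, 0.25, 0.95)
    mod <- frac * sec_targets[sec_of]
    peak_idx <- (seq_len(duration_s) - 1) * rate + sample.int(rate, duration_s,
                                                             replace = TRUE)
    mod[peak_idx] <- sec_targets[sec_of[peak_idx]]

    u <- matrix(stats::rnorm(3 * n), ncol = 3)
    u <- u / sqrt(rowSums(u^2))
    ax <- u[, 1] * mod
    ay <- u[, 2] * mod
    az <- u[, 3] * mod

    # overwrite one sample in each rail second with the pinned sample
    for (s in which(rail_secs)) {
      i <- (s - 1) * rate + sample.int(rate, 1)
      # place the pinned sample so its module equals the one recorded for
      # this second when the accumulation was allocated
      off <- sqrt(max(rail_mod[s]^2 - rail^2, 0))
      ang <- stats::runif(1, 0, 2 * pi)
      ax[i] <- rail
      ay[i] <- off * cos(ang)
      az[i] <- off * sin(ang)
    }
    accel_stream(t, ax, ay, az, sample_rate = rate)
  })
}

#' Chain-table scenario
#'
#' Describes a simulated set of completed production chains: how many, the
#' planted rule set labelling them, the label-noise probability, and the
#' feature marginals.  The default marginals place each feature on both
#' sides of its planted threshold with exceedance probabilities (ES 0.4,
#' AM 0.5, HH 0.9, HT 0.1, LT 0.05) chosen so that greedy Gini splitting
#' recovers the planted tree shape.
#'
#' @param n_chains number of simulated chains.
#' @param thresholds planted thresholds, as in [planted_quality_tree()].
#' @param label_noise probability in \[0, 0.5) of flipping a chain's label.
#' @param exceed named exceedance probabilities for the five features.
#' @param seed integer RNG seed.
#' @return an object of class `chain_scenario`.
#' @export
chain_scenario <- function(n_chains = 2000, thresholds = c(ES = 65, AM = 40,
                                                           HH = 20, HT = 50,
                                                           LT = 35),
                           label_noise = 0,
                           exceed = c(ES = 0.4, AM = 0.5, HH = 0.9,
                                      HT = 0.1, LT = 0.05),
                           seed = 1L) {
  if (label_noise < 0 || label_noise >= 0.5) {
    err_config("label_noise must lie in [0, 0.5)")
  }
  need <- c("ES", "AM", "HH", "HT", "LT")
  if (!all(need %in% names(exceed)) || !all(need %in% names(thresholds))) {
    err_config(paste("thresholds and exceed must name", paste(need, collapse = ", ")))
  }
  structure(list(n_chains = as.integer(n_chains), thresholds = thresholds,
                 label_noise = label_noise, exceed = exceed,
                 seed = as.integer(seed)),
            class = "chain_scenario")
}

#' Generate a historical chain-KPI table with planted labels
#'
#' Each feature is drawn on either side of its planted threshold with the
#' scenario's exceedance probability (uniform within the side, spanning a
#' realistic percentage range), the meat-quality label is assigned by the
#' planted rules, and finally flipped with probability `label_noise`.
#'
#' @param scenario a [chain_scenario()].
#' @return data.frame with columns `chain_id`, `ES`, `AM`, `HH`, `HT`,
#'   `LT`, `meat_quality`.
#' @export
gen_chain_dataset <- function(scenario) {
  stopifnot(inherits(scenario, "chain_scenario"))
  thr <- scenario$thresholds
  span <- c(ES = 30, AM = 40, HH = 20, HT = 40, LT = 35)
  with_seed(scenario$seed, {
    n <- scenario$n_chains
    draw <- function(f) {
      hi <- stats::runif(n) < scenario$exceed[[f]]
      lo_side <- stats::runif(n, max(0, thr[[f]] - span[[f]]), thr[[f]])
      hi_side <- stats::runif(n, thr[[f]], min(100, thr[[f]] + span[[f]]))
      ifelse(hi, hi_side, lo_side)
    }
    tab <- data.frame(chain_id = sprintf("chain-%04d", seq_len(n)),
                      ES = draw("ES"), AM = draw("AM"), HH = draw("HH"),
                      HT = draw("HT"), LT = draw("LT"),
                      stringsAsFactors = FALSE)
    tree <- planted_quality_tree(thr)
    lab <- predict(tree, tab[, c("ES", "AM", "HH", "HT", "LT")])
    if (scenario$label_noise > 0) {
      flip <- stats::runif(n) < scenario$label_noise
      lab[flip] <- ifelse(lab[flip] == "A", "B", "A")
    }
    tab$meat_quality <- lab
    tab
  })
}
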