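# Transport-phase KPIs and the smoothed z-score peak detector.

test_that("thermal comfort KPIs count strict threshold crossings", {
  t <- 0:99
  mk <- function(temp, rh) {
    list(t = sensor_series(t, rep(temp, 100), "degC", 1),
         r = sensor_series(t, rep(rh, 100), "%RH", 1))
  }
  a <- mk(25, 70)
  expect_equal(unname(thermal_comfort_kpis(a$t, a$r)), c(0, 0, 0, 0))

  b <- mk(25, 85)
  kb <- thermal_comfort_kpis(b$t, b$r)
  expect_equal(kb[["high_relative_humidity"]], 100)
  expect_equal(sum(kb), 100)

  # boundary values are comfortable (strict comparisons)
  c_ <- mk(31, 80)
  expect_equal(unname(thermal_comfort_kpis(c_$t, c_$r)),
               c(0, 0, 0, 0))

  set.seed(2)
  temp <- sensor_series(t, runif(100, 10, 40), "degC", 1)
  rh <- sensor_series(t, runif(100, 40, 100), "%RH", 1)
  k <- thermal_comfort_kpis(temp, rh)
  expect_true(all(k >= 0 & k <= 100))
  expect_equal(k[["high_temperature"]], 100 * mean(temp$values > 31))
  expect_equal(k[["low_temperature"]], 100 * mean(temp$values < 18))
})

test_that("zpeak handles constant series and isolated spikes", {
  p <- zpeak_params(25, 5, 0)
  r <- zpeak(rep(1, 60), p)
  expect_equal(sum(r$signals != 0), 0)
  expect_equal(unname(r$std_filter[26:60]), rep(0, 35))
  expect_equal(length(r$signals), 60)
  expect_true(all(r$signals[1:25] == 0))

  # flat series with one isolated spike: +1 exactly at the spike, and with
  # influence = 0 the moving mean is unchanged after it
  x <- rep(1, 60)
  x[31] <- 8
  r2 <- zpeak(x, p)
  expect_equal(which(r2$signals != 0), 31L)
  expect_equal(r2$signals[31], 1L)
  expect_equal(r2$avg_filter[60], r2$avg_filter[30])

  # a downward spike signals -1
  x3 <- rep(5, 60); x3[40] <- 0
  r3 <- zpeak(x3, p)
  expect_equal(r3$signals[40], -1L)

  expect_error(zpeak(rep(1, 25), p), class = "poultrykpi_insufficient_data")
  expect_error(zpeak_params(1, 5, 0), class = "poultrykpi_configuration_error")
  expect_error(zpeak_params(25, 0, 0), class = "poultrykpi_configuration_error")
  expect_error(zpeak_params(25, 5, 2), class = "poultrykpi_configuration_error")
})

test_that("zpeak matches the reference implementation on random series", {
  set.seed(1234)
  p <- zpeak_params(25, 5, 0)
  for (i in 1:100) {
    x <- rnorm(500)
    # sprinkle occasional jumps so signals actually occur
    jumps <- sample(30:500, 5)
    x[jumps] <- x[jumps] + sample(c(-8, 8), 5, replace = TRUE)
    got <- zpeak(x, p)
    ref <- zpeak_reference(x, 25, 5, 0)
    expect_identical(as.integer(got$signals), as.integer(ref$signals))
    expect_equal(got$avg_filter, ref$avgFilter)
    expect_equal(got$std_filter, ref$stdFilter)
  }
  # non-zero influence agrees too
  p2 <- zpeak_params(20, 3, 0.4)
  for (i in 1:10) {
    x <- rnorm(300) + c(rep(0, 150), rep(4, 150))
    got <- zpeak(x, p2)
    ref <- zpeak_reference(x, 20, 3, 0.4)
    expect_equal(got$signals, as.integer(ref$signals))
    expect_equal(got$avg_filter, ref$avgFilter)
  }
})

test_that("with influence zero, signalled points never move the filters", {
  set.seed(55)
  x <- rnorm(200)
  x[c(60, 100, 140)] <- 12
  p <- zpeak_params(25, 5, 0)
  r <- zpeak(x, p)
  expect_true(all(r$signals[c(60, 100, 140)] == 1))
  # recompute the filters with each signalled point replaced by the value
  # the filter carried: results must be identical
  filtered <- x
  for (i in 26:200) {
    if (r$signals[i] != 0) filtered[i] <- filtered[i - 1]
  }
  for (i in c(80, 120, 160)) {
    w <- filtered[(i - 24):i]
    expect_equal(r$avg_filter[i], mean(w))
    expect_equal(r$std_filter[i], sqrt(mean((w - mean(w))^2)))
  }
})

test_that("raising the threshold never adds signals", {
  set.seed(77)
  x <- rnorm(400)
  x[sample(50:400, 10)] <- x[sample(50:400, 10)] + 6
  n3 <- sum(zpeak(x, zpeak_params(25, 3, 0))$signals != 0)
  n5 <- sum(zpeak(x, zpeak_params(25, 5, 0))$signals != 0)
  n8 <- sum(zpeak(x, zpeak_params(25, 8, 0))$signals != 0)
  expect_gte(n3, n5)
  expect_gte(n5, n8)
})

test_that("abrupt movements KPI is the signalled share of evaluated samples", {
  st <- constant_stream(120, rate = 1, mod = 1)
  expect_equal(abrupt_movements_kpi(st, zpeak_params(25, 5, 0)), 0)

  # planted spike episodes are recovered near the planted fraction
  j <- gen_transport(duration_s = 3600, high_rh = 17, abrupt = 9.32, seed = 4)
  k <- transport_kpis(j$temps, j$rhs, j$stream)
  expect_equal(k[["high_relative_humidity"]], 17, tolerance = 0.1 / 17)
  expect_lt(abs(k[["abrupt_movements"]] - 9.32), 0.5)
  expect_equal(k[["low_temperature"]], 0)
  expect_equal(k[["high_temperature"]], 0)
  expect_equal(k[["low_relative_humidity"]], 0)

  # planted zero remains zero
  j0 <- gen_transport(duration_s = 1200, high_rh = 0, abrupt = 0, seed = 4)
  expect_equal(abrupt_movements_kpi(j0$stream), 0)
})

test_that("journey CSV bundles round-trip", {
  j <- gen_transport(duration_s = 300, seed = 6)
  f <- withr::local_tempfile(fileext = ".csv")
  write_journey_csv(j, f)
  j2 <- read_journey_csv(f)
  expect_equal(j2$temps$values, j$temps$values, tolerance = 1e-6)
  expect_equal(j2$rhs$values, j$rhs$values, tolerance = 1e-6)
  expect_equal(j2$stream$ax, j$stream$ax, tolerance = 1e-6)
  expect_equal(abrupt_movements_kpi(j2$stream),
               abrupt_movements_kpi(j$stream))
})
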