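# Core containers and interval-fraction arithmetic.

test_that("acceleration module matches closed forms and is symmetric", {
  expect_equal(accel_module(3, 4, 0), 5)
  expect_equal(accel_module(0, 0, 0), 0)
  expect_equal(accel_module(1, 1, 1), sqrt(3))
  expect_error(accel_module(NA, 0, 0), class = "poultrykpi_invalid_input")
  expect_error(accel_module(Inf, 0, 0), class = "poultrykpi_invalid_input")

  # invariance under axis permutation and sign flips
  set.seed(11)
  for (i in 1:20) {
    v <- runif(3, -5, 5)
    p <- sample(3)
    s <- sample(c(-1, 1), 3, replace = TRUE)
    expect_equal(accel_module(v[1], v[2], v[3]),
                 accel_module(s[1] * v[p[1]], s[2] * v[p[2]], s[3] * v[p[3]]))
  }
})

test_that("fraction_of_time counts non-missing samples inside the band", {
  s <- sensor_series(0:9, rep(20, 10), "degC", 1)
  expect_equal(fraction_of_time(s, 25, 30), 0)

  s2 <- sensor_series(0:9, c(1:5, 26:30), "degC", 1)
  expect_equal(fraction_of_time(s2, 25, 30), 50)

  # missing samples are excluded from numerator and denominator
  s3 <- sensor_series(0:9, c(26, NA, NA, NA, NA, 1, 1, 1, NA, NA), "degC", 1)
  expect_equal(fraction_of_time(s3, 25, 30), 25)

  all_na <- sensor_series(0:2, c(NA, NA, NA), "degC", 1)
  expect_error(fraction_of_time(all_na, 0, 1), class = "poultrykpi_empty_input")
})

test_that("fraction_of_time agrees with the binomial rate on random input", {
  set.seed(101)
  v <- runif(1000)
  s <- sensor_series(seq_along(v), v, "%RH", 1)
  got <- fraction_of_time(s, 0, 0.25)
  se <- sqrt(0.25 * 0.75 / 1000) * 100
  expect_lt(abs(got - 25), 4 * se)
  # and exactly matches a direct count
  expect_equal(got, 100 * mean(v >= 0 & v <= 0.25))
})

test_that("fractions over a partition of the line sum to 100", {
  set.seed(7)
  s <- sensor_series(1:500, rnorm(500, 20, 10), "degC", 1)
  cuts <- c(-Inf, 5, 15, 25, Inf)
  parts <- vapply(seq_len(length(cuts) - 1), function(i) {
    fraction_of_time(s, cuts[i], cuts[i + 1], include_lower = FALSE,
                     include_upper = TRUE)
  }, numeric(1))
  expect_equal(sum(parts), 100, tolerance = 1e-9)
})

test_that("open and closed bounds are honoured", {
  s <- sensor_series(1:4, c(1, 2, 3, 4), "g", 1)
  expect_equal(fraction_of_time(s, 2, 3), 50)
  expect_equal(fraction_of_time(s, 2, 3, include_lower = FALSE), 25)
  expect_equal(fraction_of_time(s, 2, 3, include_upper = FALSE), 25)
})

test_that("irregular series are regularised with bounded carry-forward", {
  # samples at 0, 10, 20, then a 40 s outage, then 60
  s <- sensor_series(c(0, 10, 20, 60), c(1, 2, 3, 4), "degC", 10)
  r <- regularize_series(s)
  expect_equal(r$timestamps, seq(0, 60, by = 10))
  # the gap is carried for at most 2 sample periods
  expect_equal(r$values, c(1, 2, 3, 3, 3, NA, 4))
})

test_that("per-second max module equals the brute-force grouping oracle", {
  # 1 Hz stream: output equals the per-sample module series
  t <- 0:9
  st <- accel_stream(t, 1:10 / 10, rep(0, 10), rep(0, 10), sample_rate = 1)
  psm <- per_second_max_module(st)
  expect_equal(psm$values, 1:10 / 10)
  expect_equal(psm$unit, "g")

  # two samples in one second
  st2 <- accel_stream(c(0.1, 0.6), c(1, 2.5), c(0, 0), c(0, 0))
  expect_equal(per_second_max_module(st2)$values, 2.5)

  # random 10 s stream at 100 Hz vs oracle
  set.seed(13)
  n <- 1000
  t3 <- (0:(n - 1)) / 100
  st3 <- accel_stream(t3, runif(n, -2, 2), runif(n, -2, 2), runif(n, -2, 2),
                      sample_rate = 100)
  psm3 <- per_second_max_module(st3)
  oracle <- per_second_max_oracle(st3)
  expect_equal(psm3$values, unname(oracle))
  expect_equal(length(psm3), 10)
  # every output bounds its constituent samples
  mod <- accel_module(st3$ax, st3$ay, st3$az)
  expect_true(all(psm3$values[floor(t3) - psm3$timestamps[1] + 1] >= mod - 1e-12))
})

test_that("per-second grouping flags empty seconds as missing", {
  st <- accel_stream(c(0.5, 3.5), c(1, 2), c(0, 0), c(0, 0), sample_rate = 1)
  psm <- per_second_max_module(st)
  expect_equal(psm$timestamps, 0:3)
  expect_equal(psm$values, c(1, NA, NA, 2))
})

test_that("series constructors validate their invariants", {
  expect_error(sensor_series(c(1, 1), c(1, 2), "degC"),
               class = "poultrykpi_invalid_input")
  expect_error(sensor_series(1:3, 1:2, "degC"),
               class = "poultrykpi_invalid_input")
  expect_error(sensor_series(1:2, 1:2, "furlongs"),
               class = "poultrykpi_value_error")
  expect_error(accel_stream(1:2, c(0, 9), c(0, 0), c(0, 0)),
               class = "poultrykpi_invalid_input")
  s <- sensor_series(1:2, 1:2, "°C")
  expect_equal(s$unit, "degC")
})

test_that("sensor and accelerometer CSVs round-trip", {
  s <- sensor_series(1556582400 + 0:5 * 30, c(25, NA, 26, 27, 28, 29), "degC", 30)
  f <- withr::local_tempfile(fileext = ".csv")
  write_sensor_csv(s, f)
  s2 <- read_sensor_csv(f)
  expect_equal(s2$timestamps, s$timestamps)
  expect_equal(s2$values, s$values)
  expect_equal(s2$unit, "degC")

  st <- constant_stream(2, rate = 4, mod = 1.2, t0 = 1556582400)
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_accel_csv(st, f2)
  st2 <- read_accel_csv(f2)
  expect_equal(st2$timestamps, st$timestamps, tolerance = 1e-4)
  expect_equal(st2$ax, st$ax)

  f3 <- withr::local_tempfile(fileext = ".csv")
  writeLines("timestamp,value\n1,2", f3)
  expect_error(read_sensor_csv(f3), class = "poultrykpi_schema_error")
})
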