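# Independent oracles used across the suite.

# Reference implementation of the smoothed z-score peak detector, written
# as a direct transcription of the published pseudo-code: explicit filtered
# array, moving mean and population standard deviation recomputed from the
# window at every step.  Kept deliberately naive and separate from the
# package's implementation.
zpeak_reference <- function(y, lag, threshold, influence) {
  n <- length(y)
  signals <- rep(0, n)
  filteredY <- y
  avgFilter <- rep(NA_real_, n)
  stdFilter <- rep(NA_real_, n)
  pop_sd <- function(w) {
    m <- sum(w) / length(w)
    sqrt(sum((w - m)^2) / length(w))
  }
  avgFilter[lag] <- mean(y[1:lag])
  stdFilter[lag] <- pop_sd(y[1:lag])
  i <- lag + 1
  while (i <= n) {
    if (abs(y[i] - avgFilter[i - 1]) > threshold * stdFilter[i - 1]) {
      signals[i] <- if (y[i] > avgFilter[i - 1]) 1 else -1
      filteredY[i] <- influence * y[i] + (1 - influence) * filteredY[i - 1]
    } else {
      signals[i] <- 0
      filteredY[i] <- y[i]
    }
    avgFilter[i] <- mean(filteredY[(i - lag + 1):i])
    stdFilter[i] <- pop_sd(filteredY[(i - lag + 1):i])
    i <- i + 1
  }
  list(signals = signals, avgFilter = avgFilter, stdFilter = stdFilter)
}

# brute-force per-second maximum of the acceleration module
per_second_max_oracle <- function(stream) {
  mod <- sqrt(stream$ax^2 + stream$ay^2 + stream$az^2)
  sec <- floor(stream$timestamps)
  sapply(split(mod, sec), max)
}

# brute-force best Gini split of a single numeric feature
best_split_oracle <- function(x, y, min_leaf = 1) {
  gini <- function(v) {
    p <- table(v) / length(v)
    1 - sum(p^2)
  }
  xs <- sort(unique(x))
  best <- list(threshold = NA_real_, decrease = -Inf)
  for (i in seq_len(length(xs) - 1)) {
    thr <- (xs[i] + xs[i + 1]) / 2
    l <- y[x <= thr]
    r <- y[x > thr]
    if (length(l) < min_leaf || length(r) < min_leaf) next
    dec <- gini(y) - length(l) / length(y) * gini(l) -
      length(r) / length(y) * gini(r)
    if (dec > best$decrease + 1e-12) best <- list(threshold = thr, decrease = dec)
  }
  best
}

# a tiny constant-module stream helper: n seconds at `rate` Hz, all axes
# set so the module is `mod`
constant_stream <- function(n_seconds, rate = 10, mod = 1, t0 = 0) {
  n <- n_seconds * rate
  t <- t0 + (seq_len(n) - 1) / rate
  a <- mod / sqrt(3)
  accel_stream(t, rep(a, n), rep(a, n), rep(a, n), sample_rate = rate)
}
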