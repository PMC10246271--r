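test_that("confound regression matches the normal-equations oracle", {
  set.seed(4)
  n <- 60
  ts <- roi_timeseries(matrix(rnorm(n), n, 1), tr_seconds = 2)
  conf <- matrix(rnorm(n * 3), n, 3,
                 dimnames = list(NULL, c("mot1", "mot2", "wm")))
  out <- regress_confounds(ts, conf)
  X <- cbind(1, seq_len(n) - (n + 1) / 2, conf)
  beta <- solve(t(X) %*% X, t(X) %*% ts$data)   # explicit OLS solve
  expect_lt(max(abs(out$data - (ts$data - X %*% beta))), 1e-10)

  # a series equal to a confound column regresses to ~0
  ts2 <- roi_timeseries(cbind(conf[, 1], conf[, 2]), tr_seconds = 2)
  out2 <- regress_confounds(ts2, conf)
  expect_lt(max(abs(out2$data)), 1e-10)

  # collinear confounds are refused with the offending column named
  conf_bad <- cbind(conf, dup = conf[, "wm"])
  err <- expect_error(regress_confounds(ts, conf_bad), "rank-deficient")
  expect_match(conditionMessage(err), "dup|wm")
})

test_that("confounds orthogonal to the signal leave a demeaned detrended series", {
  n <- 200
  t_ <- seq_len(n)
  sig <- sin(2 * pi * 0.05 * t_ * 2)        # 0.05 Hz at tr = 2
  ts <- roi_timeseries(matrix(sig, n, 1), tr_seconds = 2)
  set.seed(8)
  conf <- matrix(rnorm(n), n, 1, dimnames = list(NULL, "x"))
  conf <- stats::residuals(stats::lm(conf ~ sig))  # force orthogonality
  out <- regress_confounds(ts, matrix(conf, n, 1, dimnames = list(NULL, "x")))
  detr <- stats::residuals(stats::lm(sig ~ t_))
  expect_gt(cor(out$data[, 1], detr), 0.999)
})

test_that("band-pass meets its frequency-response contract at tr = 2 s", {
  n <- 500
  tr <- 2
  t_ <- seq_len(n) * tr
  amp_out <- function(f) {
    x <- sin(2 * pi * f * t_)
    y <- bandpass(roi_timeseries(matrix(x, n, 1), tr))$data[, 1]
    # amplitude from the central section (edge transients excluded)
    core <- 100:400
    sqrt(2 * mean(y[core]^2))
  }
  # passband 0.05 Hz: <= 1 dB loss, and within 12% of unit amplitude
  a05 <- amp_out(0.05)
  expect_gt(20 * log10(a05), -1)
  expect_lt(abs(a05 - 1), 0.12)
  # stopband 0.2 Hz: >= 20 dB attenuation
  expect_lt(20 * log10(amp_out(0.2)), -20)
  # realized response matches the analytic |H|^2 of the coefficients
  co <- fcmarker:::butter_bandpass(0.008, 0.1, 1 / tr)
  for (f in c(0.02, 0.05, 0.08)) {
    expect_lt(abs(amp_out(f) - fcmarker:::filter_gain(co$b, co$a, f, 1 / tr)),
              0.03)
  }
  # constant series: DC removed
  dc <- bandpass(roi_timeseries(matrix(5, n, 1), tr))$data
  expect_lt(max(abs(dc)), 1e-6)
  # zero phase: passband sinusoid not lagged (peak cross-correlation at 0)
  x <- sin(2 * pi * 0.05 * t_)
  y <- bandpass(roi_timeseries(matrix(x, n, 1), tr))$data[, 1]
  cc <- stats::ccf(y[100:400], x[100:400], lag.max = 5, plot = FALSE)
  expect_equal(as.numeric(cc$lag[which.max(cc$acf)]), 0)
  # infeasible band for the sampling rate
  expect_error(bandpass(roi_timeseries(matrix(rnorm(n), n, 1), tr),
                        high_hz = 0.3), "configuration error")
})

test_that("0.3 Hz sinusoid is suppressed below 10% at tr = 1 s", {
  n <- 600
  t_ <- seq_len(n)
  x <- sin(2 * pi * 0.3 * t_)
  y <- bandpass(roi_timeseries(matrix(x, n, 1), tr_seconds = 1))$data[, 1]
  expect_lt(sqrt(2 * mean(y[150:450]^2)), 0.1)
})

test_that("scrubbing removes frames strictly above 0.5 mm", {
  X <- matrix(seq_len(9), 3, 3)
  ts <- roi_timeseries(X, 2, fd_trace = c(0.6, 0.1, 0.5))
  out <- scrub_frames(ts, min_frames = 2)
  expect_identical(out$data, X[2:3, ])   # 0.5 survives, 0.6 censored
  expect_identical(attr(out, "n_censored"), 1L)

  ts0 <- roi_timeseries(X, 2, fd_trace = rep(0, 3))
  expect_identical(scrub_frames(ts0, min_frames = 2)$data, X)

  ts_bad <- roi_timeseries(X, 2, fd_trace = rep(1, 3))
  expect_error(scrub_frames(ts_bad, min_frames = 2), "quality error")
  expect_error(scrub_frames(roi_timeseries(X, 2)), "fd trace")
})

test_that("connectivity vector applies Fisher z with clipping in edge order", {
  set.seed(6)
  n <- 400
  a <- rnorm(n)
  b <- 0.5 / sqrt(1 - 0.25) * a + sqrt(1 - 0.25 / (1 - 0.25)) * rnorm(n)
  X <- cbind(a, a, -a, b)
  z <- timeseries_to_fc(roi_timeseries(X, 2))
  expect_length(z, edge_count(4))
  zmax <- atanh(1 - 1e-7)
  expect_equal(unname(z[1]), zmax)                 # identical ROIs, clipped
  expect_equal(unname(z[2]), -zmax)                # anti-correlated pair
  r <- cor(a, b)
  expect_equal(unname(z[3]), atanh(r), tolerance = 1e-12)
  expect_equal(atanh(0.5), 0.5493, tolerance = 1e-4)

  Xz <- cbind(a, rep(1, n))
  expect_error(timeseries_to_fc(roi_timeseries(Xz, 2)), "zero-variance")
})

test_that("edge values are invariant to ROI permutation up to reindexing", {
  set.seed(7)
  R <- 6
  X <- matrix(rnorm(300 * R), 300, R)
  z1 <- timeseries_to_fc(roi_timeseries(X, 2))
  perm <- sample(R)
  z2 <- timeseries_to_fc(roi_timeseries(X[, perm], 2))
  # map each permuted edge back to the original pair
  pairs <- edge_roi_pair(seq_len(edge_count(R)) - 1L, R)
  for (e in seq_len(edge_count(R))) {
    i0 <- perm[pairs[e, "i"] + 1] - 1L
    j0 <- perm[pairs[e, "j"] + 1] - 1L
    orig <- edge_index(min(i0, j0), max(i0, j0), R)
    expect_equal(unname(z2[e]), unname(z1[orig + 1]), tolerance = 1e-12)
  }
})

test_that("the full stage order recovers a planted correlation structure", {
  R <- 8
  target <- diag(R)
  target[1, 2] <- target[2, 1] <- 0.6
  target[3, 4] <- target[4, 3] <- -0.5
  target[5, 6] <- target[6, 5] <- 0.4
  ts <- simulate_roi_timeseries(target, n_frames = 2000, fd_spike_prob = 0.02,
                                seed = 12, tr_seconds = 2)
  z <- ts_pipeline(ts, min_frames = 50)
  zt <- atanh(fcmarker:::upper_tri_vector(target) * (1 - 1e-7))
  expect_gt(cor(z, zt), 0.9)
})
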