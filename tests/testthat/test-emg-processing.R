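make_trial <- function(samples, fs = 2000) {
  if (is.null(rownames(samples))) {
    rownames(samples) <- muscle_codes()[seq_len(nrow(samples))]
  }
  emg_trial(samples, fs = fs)
}

test_that("envelope chain removes DC, keeps zeros at zero and stays non-negative", {
  n <- 4000
  x <- rbind(rep(0.7, n),          # pure DC
             rep(0, n),            # silent channel
             sin(2 * pi * 80 * (0:(n - 1)) / 2000))
  env <- preprocess_emg(make_trial(x))
  expect_lt(max(abs(env$samples[1, ])), 1e-3)
  expect_lt(max(abs(env$samples[2, ])), 1e-12)
  expect_true(all(env$samples >= 0))
})

test_that("zero-phase contract: a symmetric burst keeps its peak sample", {
  n <- 6000
  t <- (0:(n - 1)) / 2000
  burst <- sin(2 * pi * 120 * t) * exp(-(t - 1.5)^2 / (2 * 0.05^2))
  env <- preprocess_emg(make_trial(rbind(burst)))
  expect_equal(which.max(env$samples[1, ]), which.max(exp(-(t - 1.5)^2)),
               tolerance = 2)
})

test_that("sampling rates below the Nyquist bound for the high-pass are rejected", {
  x <- rbind(stats::rnorm(500))
  rownames(x) <- "ME"
  expect_error(preprocess_emg(emg_trial(x, fs = 90)), "Nyquist")
})

test_that("the low-pass stage is idempotent for in-band signals", {
  fs <- 2000
  t <- (0:7999) / fs
  inband <- 0.5 + 0.3 * sin(2 * pi * 3 * t)
  once <- synergait:::zero_phase_butter(inband, fs, 20, "low")
  twice <- synergait:::zero_phase_butter(once, fs, 20, "low")
  core <- 500:7500  # away from filter edge effects
  rel_change <- sqrt(mean((twice[core] - once[core])^2)) /
    sqrt(mean(once[core]^2))
  expect_lt(rel_change, 0.01)
})

test_that("amplitude normalization spans [0,1] per muscle over the whole trial", {
  n <- 1000
  x <- rbind(seq(0.2, 1.2, length.out = n),
             c(seq(0, 1, length.out = n / 2), seq(0, 0.5, length.out = n / 2)))
  norm <- normalize_amplitude(make_trial(x))
  expect_equal(range(norm$samples[1, ]), c(0, 1))
  # a segment whose local max is half the trial max keeps a max of 0.5
  expect_equal(max(norm$samples[2, (n / 2 + 1):n]), 0.5, tolerance = 1e-9)
})

test_that("amplitude normalization is affine-invariant and rejects flat channels", {
  x <- rbind(stats::runif(300))
  rownames(x) <- "TA"
  a <- normalize_amplitude(make_trial(x))
  b <- normalize_amplitude(make_trial(3.7 * x + 2))
  expect_equal(a$samples, b$samples, tolerance = 1e-12)

  flat <- rbind(TA = stats::runif(300), SO = rep(0.4, 300))
  expect_error(normalize_amplitude(make_trial(flat)), "SO")
})

test_that("time normalization emits 200 points with the stance/swing boundary at point 101", {
  fs <- 2000
  n <- 3000
  t <- (0:(n - 1)) / fs
  # signal jumps at lift-off so the phase boundary is visible on the grid
  td <- 0.1; lo <- 0.8; td2 <- 1.2
  x <- rbind(ifelse(t < lo, 0.2, 0.9))
  cyc <- time_normalize_cycle(make_trial(x, fs), td, lo, td2)
  expect_equal(ncol(cyc), 200L)
  expect_equal(attr(cyc, "stance_points"), 100L)
  expect_equal(attr(cyc, "swing_points"), 100L)
  expect_true(all(cyc[1, 1:100] < 0.5))
  expect_true(all(cyc[1, 102:200] > 0.5))
})

test_that("time normalization preserves affine signals within each phase", {
  fs <- 1000
  n <- 2000
  t <- (0:(n - 1)) / fs
  trial <- make_trial(rbind(2 * t + 0.1, rep(0.7, n)), fs)
  cyc <- time_normalize_cycle(trial, 0.2, 0.9, 1.5)
  stance_vals <- cyc[1, 1:100]
  swing_vals <- cyc[1, 101:200]
  expect_equal(max(abs(diff(diff(stance_vals)))), 0, tolerance = 1e-9)
  expect_equal(max(abs(diff(diff(swing_vals)))), 0, tolerance = 1e-9)
  expect_equal(unname(cyc[1, 1]), 2 * 0.2 + 0.1, tolerance = 1e-9)
  expect_equal(unname(cyc[2, ]), rep(0.7, 200))
})

test_that("time normalization validates event order and coverage", {
  trial <- make_trial(rbind(stats::runif(1000)), fs = 1000)
  expect_error(time_normalize_cycle(trial, 0.5, 0.3, 0.9), "out of order")
  expect_error(time_normalize_cycle(trial, 0.1, 0.5, 2.0), "cover")
  expect_error(time_normalize_cycle(trial, 0.1, 0.1005, 0.9), "fewer than 2")
})

test_that("round trip: normalized grid resampled back matches the original envelope", {
  fs <- 2000
  t <- (0:3999) / fs
  sig <- 0.5 + 0.4 * sin(2 * pi * 2 * t)
  trial <- make_trial(rbind(sig), fs)
  td <- 0.2; lo <- 0.85; td2 <- 1.3
  cyc <- time_normalize_cycle(trial, td, lo, td2)
  grid <- synergait:::grid_times(td, lo, td2)
  back <- stats::approx(grid, cyc[1, ], xout = t[t >= td & t < td2])$y
  orig <- sig[t >= td & t < td2]
  expect_lt(max(abs(back - orig), na.rm = TRUE), 1e-3)
})
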