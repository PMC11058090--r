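gauss <- function(t, mu, sd) exp(-(t - mu)^2 / (2 * sd^2))

# trace with smooth planted transients: dip 55 ms before each touchdown, peak
# at the touchdown, AP minimum at each lift-off
planted_trace <- function(tds, los, fs = 143, total = max(tds) + 1) {
  t <- (0:(floor(total * fs) - 1)) / fs
  v <- numeric(length(t)); ap <- numeric(length(t))
  for (td in tds) v <- v + 30 * gauss(t, td, 0.02) - 20 * gauss(t, td - 0.055, 0.02)
  for (lo in los) ap <- ap - 15 * gauss(t, lo, 0.03)
  accel_trace(fs, v, ap)
}

test_that("touchdowns are recovered within one sample from planted transients", {
  tds <- c(1, 2.05, 3.1, 4.15, 5.2)
  los <- tds[-length(tds)] + 0.65
  tr <- planted_trace(tds, los)
  det <- detect_touchdowns(tr)
  expect_length(det, length(tds))
  expect_true(all(abs(det - tds) <= 1 / tr$fs))
})

test_that("a larger vertical maximum outside the search window is ignored", {
  fs <- 143
  t <- (0:(4 * fs)) / fs
  # cycle minimum at t = 1; in-window peak at 1.05; bigger peak at 1.4 (outside +100 ms)
  v <- -10 * gauss(t, 1, 0.02) + 5 * gauss(t, 1.05, 0.02) + 9 * gauss(t, 1.4, 0.02)
  tr <- accel_trace(fs, v, numeric(length(t)))
  det <- detect_touchdowns(tr, min_separation = 2)
  expect_length(det, 1L)
  expect_equal(det, 1.05, tolerance = 1.5 / fs)
})

test_that("a flat trace yields no touchdowns, with a warning", {
  tr <- accel_trace(143, rep(0.3, 500), rep(0, 500))
  expect_warning(det <- detect_touchdowns(tr), "no gait cycles")
  expect_length(det, 0L)
})

test_that("lift-off is the in-window AP minimum plus the 3 ms correction", {
  fs <- 100  # grid-aligned events for an exact check
  t <- (0:(3 * fs)) / fs
  td1 <- 0.5; td2 <- 1.7
  lo_true <- 1.20  # exactly on the sample grid, inside [0.8, 1.5]
  ap <- -8 * gauss(t, lo_true, 0.04)
  tr <- accel_trace(fs, numeric(length(t)), ap)
  det <- detect_liftoffs(tr, c(td1, td2), prefiltered = TRUE)
  expect_equal(det, lo_true + 0.003, tolerance = 1e-12)
  raw <- detect_liftoffs(tr, c(td1, td2), prefiltered = TRUE, correction = 0)
  expect_equal(raw, lo_true, tolerance = 1e-12)
})

test_that("a deeper AP minimum before the window opens is not selected", {
  fs <- 100
  t <- (0:(3 * fs)) / fs
  td1 <- 0.5; td2 <- 1.7
  ap <- -20 * gauss(t, td1 + 0.15, 0.03) - 8 * gauss(t, 1.2, 0.03)
  tr <- accel_trace(fs, numeric(length(t)), ap)
  det <- detect_liftoffs(tr, c(td1, td2), prefiltered = TRUE, correction = 0)
  expect_equal(det, 1.2, tolerance = 1e-12)
})

test_that("short cycles are skipped with a warning and trailing touchdowns emit nothing", {
  fs <- 143
  t <- (0:(2 * fs)) / fs
  tr <- accel_trace(fs, numeric(length(t)), -gauss(t, 0.6, 0.05))
  # cycle of 0.45 s cannot hold the [td+300 ms, td_next-200 ms] window
  expect_warning(det <- detect_liftoffs(tr, c(0.3, 0.75), prefiltered = TRUE),
                 "skipped")
  expect_length(det, 0L)
  # two touchdowns produce at most one lift-off: none for the trailing one
  det2 <- detect_liftoffs(tr, c(0.1, 1.2), prefiltered = TRUE)
  expect_length(det2, 1L)
})

test_that("gait events must interleave strictly", {
  expect_error(gait_events(c(0, 1), c(1.2)), "not interleaved")
  expect_error(gait_events(c(0, 1, 2), c(0.6, 1.5, 2.5, 3.5)), "more lift-offs")
  ev <- gait_events(c(0, 1.1, 2.2), c(0.7, 1.8))
  expect_s3_class(ev, "gait_events")
})

test_that("temporal parameters implement the stance/swing definitions", {
  ev <- gait_events(c(0, 1.0, 2.1), c(0.6, 1.7))
  tp <- temporal_parameters(ev)
  expect_equal(tp$t_st, c(0.6, 0.7))
  expect_equal(tp$t_sw, c(0.4, 0.4))
  expect_equal(tp$duty_factor[1], 0.6)
  expect_equal(tp$cadence[2], 120 / 1.1)  # two steps per cycle
  # limiting behaviour: duty factor rises with stance share
  duties <- vapply(seq(0.1, 0.9, by = 0.1), function(st) {
    temporal_parameters(gait_events(c(0, 1), st))$duty_factor
  }, numeric(1))
  expect_true(all(diff(duties) > 0))
})

test_that("coefficient of variation follows sd/mean and its invariances", {
  expect_equal(coefficient_of_variation(rep(3, 5)), 0)
  expect_equal(coefficient_of_variation(c(1, 2, 3)), 0.5)
  x <- stats::rexp(20) + 0.5
  expect_equal(coefficient_of_variation(x), coefficient_of_variation(7 * x))
  expect_error(coefficient_of_variation(c(-1, 1)), "zero mean")
  expect_error(coefficient_of_variation(2), "at least 2")
})
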