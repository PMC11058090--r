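test_that("default spec yields four unimodal prototypes with the planted timing", {
  spec <- synergy_spec(seed = 42)
  gt <- generate_synergy_prototypes(spec)

  expect_equal(nrow(gt$P_true), 4L)
  expect_equal(gt$labels,
               c("weight_acceptance", "propulsion", "early_swing", "late_swing"))
  expect_true(all(gt$M_true >= 0) && all(gt$P_true >= 0))
  expect_equal(unname(apply(gt$P_true, 1L, max)), rep(1, 4))

  # circular first-moment oracle: CoA of each pattern sits at its phase centre
  centers <- vapply(spec$prototypes, function(p) p$phase_center, numeric(1))
  for (j in 1:4) {
    expect_equal(oracle_coa(gt$P_true[j, ]), 2 * pi * centers[j],
                 tolerance = 1e-6)
    expect_equal(center_of_activity(gt$P_true[j, ]), 2 * pi * centers[j],
                 tolerance = 1e-6)
  }
})

test_that("prototype generation is deterministic and validates its inputs", {
  g1 <- generate_synergy_prototypes(synergy_spec(seed = 9))
  g2 <- generate_synergy_prototypes(synergy_spec(seed = 9))
  expect_identical(g1$M_true, g2$M_true)
  expect_identical(g1$P_true, g2$P_true)

  protos <- default_prototypes()
  protos[[2]]$label <- protos[[1]]$label
  expect_error(synergy_spec(prototypes = protos), "unique")
  expect_error(synergy_spec(noise_sd = -0.1), "noise_sd")
  expect_error(synergy_spec(widen_factor = 0.5), "widen_factor")

  bad <- default_prototypes()
  bad[[1]]$phase_center <- 1.2
  expect_error(synergy_spec(prototypes = bad), "phase_center")
})

test_that("large concentration collapses a prototype towards an impulse", {
  narrow <- bump_pattern(0.25, concentration = 20000)
  expect_equal(sum(narrow > 0.01), 1L)
  expect_equal(which.max(narrow), 0.25 * 200 + 1L)
})

test_that("noiseless unperturbed cycles equal the planted factorization exactly", {
  spec <- synergy_spec(noise_sd = 0, coa_shift = 0, widen_factor = 1, seed = 3)
  tr <- synthesize_trial(spec)
  gt <- tr$ground_truth
  expected <- gt$M_true %*% gt$P_true
  for (V in tr$cycles) {
    expect_equal(unclass(V), expected, ignore_attr = TRUE, tolerance = 0)
  }
})

test_that("planted widening and timing shift show up in the perturbed-cycle prototypes", {
  spec <- synergy_spec(noise_sd = 0, coa_shift = -0.3, widen_factor = 1.5,
                       seed = 5)
  tr <- synthesize_trial(spec)
  gt <- tr$ground_truth
  pc <- spec$perturbed_cycle_index
  for (j in seq_len(nrow(gt$P_true))) {
    base <- gt$P_cycles[[1]][j, ]
    pert <- gt$P_cycles[[pc]][j, ]
    expect_gt(oracle_fwhm(pert), oracle_fwhm(base))
    dcoa <- oracle_coa(pert) - oracle_coa(base)
    dcoa <- ((dcoa + pi) %% (2 * pi)) - pi
    expect_equal(dcoa, -0.3, tolerance = 0.02)
  }
  # effects decay: the last recovery cycles return to baseline
  expect_equal(gt$P_cycles[[spec$n_cycles]], gt$P_cycles[[1]])
})

test_that("trial matrices stay in [0, 1] and are reproducible under a fixed seed", {
  spec <- synergy_spec(noise_sd = 0.05, seed = 11)
  t1 <- synthesize_trial(spec)
  t2 <- synthesize_trial(spec)
  for (i in seq_along(t1$cycles)) {
    expect_identical(unclass(t1$cycles[[i]]), unclass(t2$cycles[[i]]))
    expect_true(all(t1$cycles[[i]] >= 0 & t1$cycles[[i]] <= 1))
  }
})

test_that("synthesized raw EMG carries the planted envelope", {
  spec <- synergy_spec(seed = 7, noise_sd = 0, n_cycles = 6)
  rec <- synthesize_raw_signals(spec)
  env <- preprocess_emg(rec$emg)
  for (m in seq_len(nrow(env$samples))) {
    expect_gt(stats::cor(env$samples[m, ], rec$envelope[m, ]), 0.95)
  }
})

test_that("raw-signal synthesis validates sampling rates", {
  spec <- synergy_spec(seed = 1, n_cycles = 2, perturbed_cycle_index = 2)
  expect_error(synthesize_raw_signals(spec, fs_emg = 400), "fs_emg")
  expect_error(synthesize_raw_signals(spec, fs_accel = 40), "fs_accel")
  expect_error(synthesize_raw_signals(spec, fs_accel = 50, t_stance = 0.02),
               "not representable")
})

test_that("planted gait events are recovered from the synthetic accelerometer", {
  spec <- synergy_spec(seed = 13, n_cycles = 6)
  rec <- synthesize_raw_signals(spec)
  td <- detect_touchdowns(rec$accel)
  expect_length(td, length(rec$events$touchdowns))
  expect_true(all(abs(td - rec$events$touchdowns) <= 1 / rec$accel$fs))
  lo <- detect_liftoffs(rec$accel, td)
  expect_length(lo, length(rec$events$liftoffs))
  expect_true(all(abs(lo - (rec$events$liftoffs + 0.003)) <= 1 / rec$accel$fs))
})
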