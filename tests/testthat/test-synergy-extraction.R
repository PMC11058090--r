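random_nonneg <- function(m, n, seed) {
  synergait:::with_seed(seed, matrix(stats::runif(m * n), m, n))
}

test_that("R^2 matches its definition and a brute-force oracle", {
  V <- random_nonneg(4, 10, 1)
  VR <- random_nonneg(4, 10, 2)
  expect_equal(r_squared(V, V), 1)
  expect_equal(r_squared(V, matrix(mean(V), 4, 10)), 0)
  expect_equal(r_squared(V, VR), oracle_r_squared(V, VR), tolerance = 1e-12)
  expect_error(r_squared(matrix(1, 2, 2), matrix(1, 2, 2)), "constant")
  expect_error(r_squared(V, VR[, 1:5]), "shape")
})

test_that("multiplicative updates fit exact low-rank data and keep non-negativity", {
  M0 <- random_nonneg(6, 2, 3)
  P0 <- random_nonneg(2, 40, 4)
  V <- M0 %*% P0
  fit2 <- nmf_factorize(V, 2, seed = 7)
  expect_gte(fit2$r_squared, 0.999)
  expect_true(all(fit2$M >= 0) && all(fit2$P >= 0))
  # pattern rows are max-normalized with scales folded into the weights
  expect_equal(unname(apply(fit2$P, 1, max)), rep(1, 2))
  expect_equal(r_squared(V, fit2$M %*% fit2$P), fit2$r_squared)

  fit1 <- nmf_factorize(V, 1, seed = 7)
  expect_lt(fit1$r_squared, fit2$r_squared)

  expect_error(nmf_factorize(V - 1, 2), "non-negative")
  expect_error(nmf_factorize(V, 7), "rank")
})

test_that("reconstruction error is monotone non-increasing across iterations", {
  for (seed in 1:5) {
    V <- random_nonneg(8, 30, seed + 10)
    fit <- nmf_factorize(V, 3, seed = seed)
    expect_true(all(diff(fit$error_trace) <= 1e-10))
  }
})

test_that("factorization is deterministic under a fixed seed", {
  V <- random_nonneg(13, 50, 5)
  a <- nmf_factorize(V, 4, seed = 123)
  b <- nmf_factorize(V, 4, seed = 123)
  expect_identical(a$M, b$M)
  expect_identical(a$P, b$P)
})

test_that("component matching undoes column permutations", {
  M <- random_nonneg(13, 4, 6)
  perm <- c(3, 1, 4, 2)
  sim <- synergait:::column_cosine(M[, perm], M)
  idx <- synergait:::match_components(sim)
  expect_equal(M[, perm][, idx], M, ignore_attr = TRUE)
})

test_that("averaging identical repetitions reproduces the single fit", {
  V <- unclass(synthesize_trial(synergy_spec(noise_sd = 0, coa_shift = 0,
                                             widen_factor = 1,
                                             seed = 2))$cycles[[1]])
  single <- nmf_factorize(V, 4, seed = 50)
  avg <- average_repetitions(V, 4, n_rep = 3, seed = 50)
  # different seeds per repetition still land on the same well-separated
  # optimum here, so averaging should not degrade the reconstruction
  expect_gte(avg$r_squared, single$r_squared - 0.01)
  expect_equal(avg$n_repetitions, 3L)
  expect_error(average_repetitions(V, 4, n_rep = 0), "n_rep")
})

test_that("averaged factors recover planted synergies at least as well as a typical single run", {
  tr <- synthesize_trial(synergy_spec(noise_sd = 0.05, coa_shift = 0,
                                      widen_factor = 1, seed = 21))
  V <- tr$cycles[[1]]
  gt <- tr$ground_truth
  singles <- vapply(1:9, function(r) {
    worst_recovery(nmf_factorize(V, 4, seed = 200 + r), gt)
  }, numeric(1))
  avg <- worst_recovery(average_repetitions(V, 4, n_rep = 9, seed = 200), gt)
  expect_gte(avg, stats::median(singles) - 1e-6)
})

test_that("rank selection finds planted ranks and returns audit curves", {
  # exact rank-1 data
  V1 <- random_nonneg(6, 1, 8) %*% random_nonneg(1, 30, 9)
  sel1 <- select_rank(V1, max_rank = 5, seed = 1)
  expect_equal(sel1$rank, 1L)

  # pure noise: total, no error, rank within range
  Vn <- random_nonneg(8, 40, 10)
  seln <- select_rank(Vn, max_rank = 8, seed = 2)
  expect_true(seln$rank >= 1L && seln$rank <= 8L)
  expect_length(seln$r2, 8L)

  # best-of-repetitions R^2 is non-decreasing in rank (within tolerance for
  # local minima)
  tr <- synthesize_trial(synergy_spec(noise_sd = 0.02, coa_shift = 0,
                                      widen_factor = 1, seed = 33))
  sel <- select_rank(tr$cycles[[1]], seed = 3)
  expect_true(all(diff(sel$r2) > -0.01))
  expect_equal(sel$rank, 4L)
})
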