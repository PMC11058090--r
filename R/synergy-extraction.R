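# Gaussian NMF (squared-Frobenius multiplicative updates), repetition
# averaging with component matching, reconstruction R^2 and rank selection.

new_synergy_set <- function(M, P, r_squared, n_repetitions = 1L,
                            cycle_index = NA_integer_, seed = NA_integer_,
                            iterations = NA_integer_, error_trace = NULL) {
  structure(list(M = M, P = P, rank = ncol(M), r_squared = r_squared,
                 n_repetitions = as.integer(n_repetitions),
                 cycle_index = cycle_index, seed = seed,
                 iterations = iterations, error_trace = error_trace),
            class = "synergy_set")
}

#' @export
print.synergy_set <- function(x, ...) {
  cat(sprintf("<synergy_set> rank %d, %d muscles x %d points, R^2 = %.4f (%d repetition%s)\n",
              x$rank, nrow(x$M), ncol(x$P), x$r_squared, x$n_repetitions,
              if (x$n_repetitions == 1L) "" else "s"))
  invisible(x)
}

# Scale each activation-pattern row to max 1, folding the inverse scale into
# the matching muscle-weight column so M %*% P is unchanged.
normalize_synergy_scale <- function(M, P) {
  s <- apply(P, 1L, max)
  s[s <= 0] <- 1
  list(M = sweep(M, 2L, s, `*`), P = sweep(P, 1L, s, `/`))
}

#' Coefficient of determination of a reconstruction
#'
#' `R^2 = 1 - SSE/SST`, where SSE is the summed squared reconstruction error
#' and SST the total sum of squares of `V` around its grand mean.
#'
#' @param V Original matrix.
#' @param V_R Reconstruction, same shape.
#' @return Scalar in `(-Inf, 1]`.
#' @export
r_squared <- function(V, V_R) {
  if (!all(dim(V) == dim(V_R))) stop("shape mismatch", call. = FALSE)
  sst <- sum((V - mean(V))^2)
  if (sst < .Machine$double.eps) {
    stop("R^2 undefined for a constant matrix (SST = 0)", call. = FALSE)
  }
  1 - sum((V - V_R)^2) / sst
}

#' Factorize a gait-cycle matrix with Gaussian NMF
#'
#' Minimizes the squared Frobenius reconstruction error of
#' `V ~ V_R = M %*% P` by multiplicative updates, the classical Gaussian
#' non-negative matrix factorization. `M` (muscles x rank) holds the
#' time-invariant muscle weights and `P` (rank x points) the time-dependent
#' activation patterns. Factors are initialized uniformly on (0, 1] under the
#' given seed; updates keep all entries non-negative and never increase the
#' reconstruction error. Iteration stops when the relative improvement of
#' R^2 over the previous 20 iterations falls below `tol`, or at `max_iter`.
#'
#' @param V Non-negative matrix (muscles x points) or `normalized_cycle`.
#' @param rank Number of synergies, `1 <= rank <= nrow(V)`.
#' @param seed Integer seed for the initialization.
#' @param max_iter Iteration cap (default 1000).
#' @param tol Relative R^2 improvement threshold over a 20-iteration lag
#'   (default 1e-4, i.e. 0.01%).
#' @return A `synergy_set`; pattern rows are max-normalized with compensating
#'   scales folded into the weight columns. `$error_trace` records the squared
#'   Frobenius error per iteration.
#' @export
nmf_factorize <- function(V, rank, seed = 1L, max_iter = 1000L, tol = 1e-4) {
  V <- unclass(V)
  if (any(V < 0)) stop("`V` must be non-negative", call. = FALSE)
  m <- nrow(V); n <- ncol(V)
  if (rank < 1L || rank > m) {
    stop(sprintf("`rank` must be in [1, %d]", m), call. = FALSE)
  }
  eps <- 1e-12
  init <- with_seed(seed, {
    list(M = matrix(1 - stats::runif(m * rank), m, rank),
         P = matrix(1 - stats::runif(rank * n), rank, n))
  })
  M <- init$M; P <- init$P
  sst <- sum((V - mean(V))^2)
  err <- numeric(max_iter)
  r2 <- numeric(max_iter)
  it <- 0L
  repeat {
    it <- it + 1L
    P <- P * (crossprod(M, V)) / (crossprod(M, M) %*% P + eps)
    M <- M * (V %*% t(P)) / (M %*% tcrossprod(P, P) + eps)
    err[it] <- sum((V - M %*% P)^2)
    r2[it] <- 1 - err[it] / sst
    if (it >= max_iter) break
    if (it > 20L) {
      prev <- r2[it - 20L]
      if (prev > 0 && (r2[it] - prev) / prev < tol) break
    }
  }
  nf <- normalize_synergy_scale(M, P)
  rn <- rownames(V)
  if (!is.null(rn)) rownames(nf$M) <- rn
  new_synergy_set(nf$M, nf$P, r_squared = r2[it], n_repetitions = 1L,
                  cycle_index = attr(V, "cycle_index") %||% NA_integer_,
                  seed = seed, iterations = it, error_trace = err[seq_len(it)])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Cosine-similarity matrix between columns of A and columns of B.
column_cosine <- function(A, B) {
  An <- sweep(A, 2L, pmax(sqrt(colSums(A^2)), 1e-12), `/`)
  Bn <- sweep(B, 2L, pmax(sqrt(colSums(B^2)), 1e-12), `/`)
  crossprod(An, Bn)
}

# Optimal one-to-one assignment maximizing total similarity. Exhaustive over
# permutations for p <= 8, greedy beyond. Returns for each column of B the
# matched column of A.
match_components <- function(sim) {
  p <- nrow(sim)
  if (p <= 8L) {
    perms <- permutations_of(p)
    scores <- vapply(perms, function(pm) sum(sim[cbind(pm, seq_len(p))]),
                     numeric(1))
    perms[[which.max(scores)]]
  } else {
    assign <- integer(p)
    taken <- rep(FALSE, p)
    ord <- order(-apply(sim, 2L, max))
    for (j in ord) {
      cand <- order(-sim[, j])
      cand <- cand[!taken[cand]]
      assign[j] <- cand[1L]
      taken[cand[1L]] <- TRUE
    }
    assign
  }
}

permutations_of <- function(p) {
  if (p == 1L) return(list(1L))
  sub <- permutations_of(p - 1L)
  out <- vector("list", p * length(sub))
  k <- 0L
  for (s in sub) {
    for (pos in seq_len(p)) {
      k <- k + 1L
      out[[k]] <- append(s, p, after = pos - 1L)
    }
  }
  out
}

#' Repeat and average NMF factorizations
#'
#' Runs `n_rep` seeded factorizations of the same cycle, aligns the synergies
#' of every repetition to those of the first by optimal one-to-one
#' assignment on the cosine similarity of the muscle-weight columns, averages
#' the aligned factors, renormalizes (pattern rows to max 1) and reports the
#' R^2 of the averaged reconstruction. Repeating and averaging makes the
#' factorization robust to the random initialization.
#'
#' @inheritParams nmf_factorize
#' @param n_rep Number of repetitions (default 20).
#' @return A `synergy_set` with `n_repetitions = n_rep`.
#' @export
average_repetitions <- function(V, rank, n_rep = 20L, seed = 1L,
                                max_iter = 1000L, tol = 1e-4) {
  if (n_rep < 1L) stop("`n_rep` must be >= 1", call. = FALSE)
  reps <- lapply(seq_len(n_rep), function(r) {
    nmf_factorize(V, rank, seed = seed + r - 1L, max_iter = max_iter, tol = tol)
  })
  ref <- reps[[1L]]
  M_sum <- ref$M
  P_sum <- ref$P
  if (n_rep > 1L) {
    for (r in 2L:n_rep) {
      sim <- column_cosine(reps[[r]]$M, ref$M)
      idx <- match_components(sim)
      M_sum <- M_sum + reps[[r]]$M[, idx, drop = FALSE]
      P_sum <- P_sum + reps[[r]]$P[idx, , drop = FALSE]
    }
  }
  nf <- normalize_synergy_scale(M_sum / n_rep, P_sum / n_rep)
  r2 <- r_squared(unclass(V), nf$M %*% nf$P)
  new_synergy_set(nf$M, nf$P, r_squared = r2, n_repetitions = n_rep,
                  cycle_index = ref$cycle_index, seed = seed)
}

#' Select the factorization rank
#'
#' Computes, for each candidate rank, the best R^2 over `n_rep` seeded
#' factorizations, then returns the smallest rank from which the remaining
#' R^2-versus-rank curve is statistically flat-linear: an ordinary
#' least-squares line fitted to the curve on ranks `r..max_rank` leaves a
#' mean squared residual below `mse_threshold`. This is the minimum number of
#' synergies needed to satisfactorily reconstruct the signals; the full curve
#' is returned for audit.
#'
#' @inheritParams nmf_factorize
#' @param max_rank Largest candidate rank (default 10).
#' @param n_rep Repetitions per candidate rank (default 5).
#' @param mse_threshold Flatness threshold on the residual MSE (default 1e-4).
#' @return List with `rank` (selected), `r2` (R^2 per candidate rank) and
#'   `mse` (residual MSE of the trailing-line fit per candidate rank).
#' @export
select_rank <- function(V, max_rank = 10L, n_rep = 5L, seed = 1L,
                        mse_threshold = 1e-4, max_iter = 1000L, tol = 1e-4) {
  V <- unclass(V)
  max_rank <- min(max_rank, nrow(V))
  r2 <- vapply(seq_len(max_rank), function(r) {
    max(vapply(seq_len(n_rep), function(rep) {
      nmf_factorize(V, r, seed = seed + (r - 1L) * n_rep + rep - 1L,
                    max_iter = max_iter, tol = tol)$r_squared
    }, numeric(1)))
  }, numeric(1))

  mse <- vapply(seq_len(max_rank), function(r) {
    ys <- r2[r:max_rank]
    if (length(ys) < 3L) return(0)
    xs <- seq_along(ys)
    fit <- stats::lm.fit(cbind(1, xs), ys)
    mean(fit$residuals^2)
  }, numeric(1))
  sel <- which(mse < mse_threshold)
  rank <- if (length(sel)) min(sel) else max_rank
  list(rank = rank, r2 = r2, mse = mse)
}
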