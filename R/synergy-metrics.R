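# Spatiotemporal synergy metrics: cosine similarity to a reference cycle,
# full width at half maximum, circular center of activity.

#' Cosine similarity of two vectors
#'
#' `dot(A, B) / (|A| |B|)`: 1 means the same direction (identical pattern up
#' to scale), 0 orthogonal, -1 exactly opposite. Scale-invariant.
#'
#' @param a,b Nonzero numeric vectors of equal length.
#' @return Scalar in `[-1, 1]`.
#' @export
cosine_similarity <- function(a, b) {
  if (length(a) != length(b)) stop("length mismatch", call. = FALSE)
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) {
    stop("cosine similarity undefined for a zero vector", call. = FALSE)
  }
  sum(a * b) / (na * nb)
}

#' Full width at half maximum of an activation pattern
#'
#' After subtracting the pattern minimum, counts all grid points whose value
#' exceeds half of the (min-subtracted) maximum. Points need not be
#' contiguous, so a bimodal pattern contributes both lobes. Invariant to
#' positive scaling and to adding a constant.
#'
#' @param pattern Numeric activation pattern (one value per cycle point).
#' @return Integer count of points above the half-maximum (0, with a
#'   warning, for a constant pattern).
#' @export
fwhm <- function(pattern) {
  x <- pattern - min(pattern)
  mx <- max(x)
  if (mx < .Machine$double.eps) {
    warning("constant pattern: FWHM undefined, returning 0")
    return(0L)
  }
  sum(x > mx / 2)
}

#' Circular center of activity of an activation pattern
#'
#' The angle of the polar vector pointing to the center of mass of the
#' pattern laid out on the unit circle, with the cycle's phase as polar
#' direction: point index `i = 0..n-1` maps to `theta_i = 2*pi*i/n`
#' (`theta = 0` at touchdown). Computed from the first trigonometric moment
#' `atan2(sum(a*sin(theta)), sum(a*cos(theta)))`, mapped to `[0, 2*pi)`.
#'
#' @param pattern Non-negative activation pattern with positive total mass.
#' @return Angle in radians in `[0, 2*pi)`; `NA` with a warning when the
#'   resultant vector vanishes (e.g. a uniform pattern).
#' @export
center_of_activity <- function(pattern) {
  if (any(pattern < 0)) stop("`pattern` must be non-negative", call. = FALSE)
  if (sum(pattern) <= 0) stop("`pattern` must have positive mass", call. = FALSE)
  n <- length(pattern)
  theta <- 2 * pi * (seq_len(n) - 1L) / n
  s <- sum(pattern * sin(theta))
  c_ <- sum(pattern * cos(theta))
  if (sqrt(s^2 + c_^2) < 1e-10 * sum(pattern)) {
    warning("vanishing resultant: center of activity undefined")
    return(NA_real_)
  }
  atan2(s, c_) %% (2 * pi)
}

# Difference a - b on the circle, mapped to (-pi, pi].
circular_diff <- function(a, b) {
  d <- (a - b) %% (2 * pi)
  ifelse(d > pi, d - 2 * pi, d)
}

# Align each cycle's synergies to the reference set by optimal one-to-one
# assignment on the cosine similarity of the activation patterns.
match_to_reference <- function(set, ref) {
  sim <- column_cosine(t(set$P), t(ref$P))
  match_components(sim)
}

#' Per-cycle synergy metrics relative to a reference cycle
#'
#' For every cycle's synergy set, computes the cosine similarity of the
#' muscle weights and of the activation patterns against the matched synergy
#' of the reference cycle (by default the first cycle, i.e. the cycle most
#' remote from a perturbation planted later in the series), plus the FWHM
#' and center of activity of each activation pattern. Synergies are matched
#' across cycles either by supplied labels or, failing that, by optimal
#' cosine-similarity assignment of the activation patterns against the
#' reference cycle.
#'
#' @param sets List of `synergy_set` objects, one per cycle, equal rank.
#' @param reference_cycle Index of the reference cycle (default 1).
#' @param labels Optional character vector naming each reference synergy (in
#'   reference column order); recycled onto matched synergies of every cycle.
#' @return Data frame with one row per cycle and synergy: `cycle`, `synergy`,
#'   `cs_weights`, `cs_patterns`, `fwhm_points`, `coa_rad`.
#' @export
similarity_series <- function(sets, reference_cycle = 1L, labels = NULL) {
  stopifnot(length(sets) >= 1L)
  ref <- sets[[reference_cycle]]
  p <- ref$rank
  if (is.null(labels)) labels <- paste0("synergy_", seq_len(p))
  rows <- lapply(seq_along(sets), function(ci) {
    set <- sets[[ci]]
    idx <- match_to_reference(set, ref)
    data.frame(
      cycle = ci,
      synergy = labels,
      cs_weights = vapply(seq_len(p), function(j)
        cosine_similarity(set$M[, idx[j]], ref$M[, j]), numeric(1)),
      cs_patterns = vapply(seq_len(p), function(j)
        cosine_similarity(set$P[idx[j], ], ref$P[j, ]), numeric(1)),
      fwhm_points = vapply(seq_len(p), function(j)
        fwhm(set$P[idx[j], ]), numeric(1)),
      coa_rad = vapply(seq_len(p), function(j)
        center_of_activity(set$P[idx[j], ]), numeric(1))
    )
  })
  do.call(rbind, rows)
}
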