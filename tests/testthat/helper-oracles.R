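# Independent brute-force oracles, kept deliberately naive and separate from
# the package implementations they check.

oracle_r_squared <- function(V, V_R) {
  sse <- 0; sst <- 0; gm <- mean(V)
  for (i in seq_len(nrow(V))) {
    for (j in seq_len(ncol(V))) {
      sse <- sse + (V[i, j] - V_R[i, j])^2
      sst <- sst + (V[i, j] - gm)^2
    }
  }
  1 - sse / sst
}

oracle_cosine <- function(a, b) {
  num <- 0; na <- 0; nb <- 0
  for (i in seq_along(a)) {
    num <- num + a[i] * b[i]
    na <- na + a[i]^2
    nb <- nb + b[i]^2
  }
  num / (sqrt(na) * sqrt(nb))
}

oracle_fwhm <- function(p) {
  x <- p - min(p)
  count <- 0L
  for (v in x) if (v > max(x) / 2) count <- count + 1L
  count
}

# first trigonometric moment over all points
oracle_coa <- function(p) {
  s <- 0; cc <- 0
  n <- length(p)
  for (i in seq_len(n)) {
    th <- 2 * pi * (i - 1) / n
    s <- s + p[i] * sin(th)
    cc <- cc + p[i] * cos(th)
  }
  (atan2(s, cc) + 2 * pi) %% (2 * pi)
}

oracle_cohens_d <- function(x, y) {
  vx <- sum((x - mean(x))^2) / (length(x) - 1)
  vy <- sum((y - mean(y))^2) / (length(y) - 1)
  sp <- sqrt(((length(x) - 1) * vx + (length(y) - 1) * vy) /
               (length(x) + length(y) - 2))
  (mean(x) - mean(y)) / sp
}

# step-up BH by direct enumeration: adjusted_(i) = min_{j >= i} p_(j) * n / j
oracle_bh <- function(p) {
  n <- length(p)
  ord <- order(p)
  ps <- p[ord]
  adj <- numeric(n)
  for (i in seq_len(n)) {
    best <- Inf
    for (j in i:n) best <- min(best, ps[j] * n / j)
    adj[i] <- min(best, 1)
  }
  out <- numeric(n)
  out[ord] <- adj
  out
}

# cosine similarity of matched components against ground truth, worst over
# components, matching via the package's optimal assignment
worst_recovery <- function(set, gt) {
  simM <- synergait:::column_cosine(set$M, gt$M_true)
  idx <- synergait:::match_components(simM)
  simP <- synergait:::column_cosine(t(set$P), t(gt$P_true))
  min(vapply(seq_len(ncol(gt$M_true)), function(j) {
    min(simM[idx[j], j], simP[idx[j], j])
  }, numeric(1)))
}

# a clean unimodal test pattern on the 200-point grid
bump_pattern <- function(center_frac, concentration = 6, n = 200L) {
  th <- 2 * pi * (seq_len(n) - 1L) / n
  exp(concentration * (cos(th - 2 * pi * center_frac) - 1))
}
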