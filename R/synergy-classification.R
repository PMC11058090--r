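# Classification of pooled activation patterns into the four fundamental
# walking synergies via k-means with a WSS-curve cluster-count criterion.

fundamental_labels <- function() {
  c("weight_acceptance", "propulsion", "early_swing", "late_swing")
}

# Conventional phase centres of the four fundamental synergies on the
# 100/100 stance/swing grid, as cycle fractions; used only to anchor cluster
# labels by centroid timing.
fundamental_phase_angles <- function() {
  2 * pi * c(weight_acceptance = 0.10, propulsion = 0.40,
             early_swing = 0.60, late_swing = 0.90)
}

max_normalize_rows <- function(X) {
  mx <- apply(X, 1L, max)
  bad <- mx <= 0
  mx[bad] <- 1
  sweep(X, 1L, mx, `/`)
}

#' Choose the number of pattern clusters from the WSS curve
#'
#' Runs seeded k-means for `k = 1..max_k` clusters of the pooled
#' (max-normalized) activation patterns, recording the within-cluster sum of
#' squares (WSS) at each k. The WSS curve is normalized by the total sum of
#' squares to make the criterion scale-free, and the chosen count is the
#' minimum k from which the remaining curve fits a least-squares line with
#' mean squared error below `mse_threshold`.
#'
#' @param patterns Matrix with one activation pattern per row.
#' @param max_k Largest candidate count (default 13, the number of recorded
#'   muscles); reduced with a warning when fewer patterns are available.
#' @param seed Integer seed for the k-means restarts.
#' @param nstart Random restarts per k (default 10).
#' @param mse_threshold Flatness threshold on the normalized curve
#'   (default 1e-3).
#' @return List with `k` (chosen count), `wss` (normalized WSS per k) and
#'   `mse` (trailing-line MSE per k).
#' @export
choose_cluster_count <- function(patterns, max_k = 13L, seed = 1L,
                                 nstart = 10L, mse_threshold = 1e-3) {
  patterns <- as.matrix(patterns)
  # k-means with random restarts needs k < n patterns
  if (nrow(patterns) <= max_k) {
    warning(sprintf("only %d patterns; reducing max_k from %d",
                    nrow(patterns), max_k))
    max_k <- max(1L, nrow(patterns) - 1L)
  }
  X <- max_normalize_rows(patterns)
  tss <- sum(sweep(X, 2L, colMeans(X))^2)
  if (tss < .Machine$double.eps) {
    return(list(k = 1L, wss = rep(0, max_k), mse = rep(0, max_k)))
  }
  wss <- with_seed(seed, {
    vapply(seq_len(max_k), function(k) {
      if (k == 1L) return(1)
      km <- stats::kmeans(X, centers = k, nstart = nstart, iter.max = 50L)
      km$tot.withinss / tss
    }, numeric(1))
  })
  mse <- vapply(seq_len(max_k), function(k) {
    ys <- wss[k:max_k]
    if (length(ys) < 3L) return(0)
    xs <- seq_along(ys)
    fit <- stats::lm.fit(cbind(1, xs), ys)
    mean(fit$residuals^2)
  }, numeric(1))
  sel <- which(mse < mse_threshold)
  list(k = if (length(sel)) min(sel) else max_k, wss = wss, mse = mse)
}

#' Is an activation pattern a fundamental synergy?
#'
#' A fundamental synergy has a single main activation peak. The pattern is
#' smoothed with a 5-point circular moving average; local maxima at or above
#' half of the global maximum and separated by at least `min_separation`
#' points (circularly; the higher peak wins at closer range) count as main
#' peaks. Exactly one main peak makes the pattern fundamental.
#'
#' @param pattern Non-negative activation pattern.
#' @param min_separation Minimum circular spacing between distinct main
#'   peaks, in grid points (default 20 of 200).
#' @return `TRUE` or `FALSE` (all-zero patterns are `FALSE` with a warning).
#' @export
is_fundamental <- function(pattern, min_separation = 20L) {
  if (max(pattern) <= 0) {
    warning("all-zero pattern is not classifiable")
    return(FALSE)
  }
  n <- length(pattern)
  # 5-point circular moving average
  k <- 5L
  pad <- c(pattern[(n - 1L):n], pattern, pattern[1:2])
  sm <- stats::filter(pad, rep(1 / k, k), sides = 2L)
  sm <- as.numeric(sm[(2L + 1L):(2L + n)])
  prv <- sm[c(n, seq_len(n - 1L))]
  nxt <- sm[c(seq_len(n - 1L) + 1L, 1L)]
  peaks <- which(sm >= prv & sm > nxt & sm >= max(sm) / 2)
  if (!length(peaks)) return(FALSE)
  # merge peaks closer than min_separation on the circle, keeping the higher
  peaks <- peaks[order(-sm[peaks])]
  kept <- integer(0)
  for (p in peaks) {
    d <- abs(p - kept)
    d <- pmin(d, n - d)
    if (!length(kept) || all(d >= min_separation)) kept <- c(kept, p)
  }
  length(kept) == 1L
}

#' Classify pooled synergies into the fundamental walking synergies
#'
#' Pools activation patterns (across participants and/or repetitions of one
#' cycle and condition), max-normalizes them, chooses the cluster count via
#' [choose_cluster_count()], clusters with seeded k-means, and labels
#' clusters as weight acceptance, propulsion, early swing or late swing by
#' the circular timing (center of activity) of their centroids: the four
#' clusters whose centroid timings best match the canonical phase ordering
#' starting at stance onset receive the labels; any extra clusters are
#' non-classifiable. Individual synergies that are not fundamental
#' ([is_fundamental()]) or that resemble their assigned centroid with cosine
#' similarity below `similarity_floor` are marked `non_classifiable`.
#'
#' @param patterns Matrix with one activation pattern per row.
#' @param max_k,seed,nstart,mse_threshold Passed to [choose_cluster_count()].
#' @param similarity_floor Minimum cosine similarity to the assigned cluster
#'   centroid (default 0.75).
#' @return List with `labels` (character, one per pattern; one of the four
#'   fundamental labels or `"non_classifiable"`), `cluster` (k-means cluster
#'   per pattern), `centroid_similarity` (per pattern), `k`,
#'   `cluster_labels`, `centroid_coa` and `fraction_non_classifiable`.
#' @export
classify_synergies <- function(patterns, max_k = 13L, seed = 1L,
                               nstart = 10L, mse_threshold = 1e-3,
                               similarity_floor = 0.75) {
  patterns <- as.matrix(patterns)
  X <- max_normalize_rows(patterns)
  cc <- choose_cluster_count(X, max_k = max_k, seed = seed, nstart = nstart,
                             mse_threshold = mse_threshold)
  k <- cc$k
  if (k == 1L) {
    km <- list(cluster = rep(1L, nrow(X)), centers = matrix(colMeans(X), 1L))
  } else {
    km <- with_seed(seed + 1L, {
      stats::kmeans(X, centers = k, nstart = nstart, iter.max = 50L)
    })
  }
  centroid_coa <- apply(km$centers, 1L, function(ctr) {
    center_of_activity(pmax(ctr, 0))
  })
  cluster_labels <- assign_cluster_labels(centroid_coa)
  if (k != 4L) {
    warning(sprintf("cluster count %d differs from the 4 fundamental synergies; extras are non-classifiable", k))
  }

  n <- nrow(X)
  sim <- vapply(seq_len(n), function(i) {
    cosine_similarity(X[i, ], km$centers[km$cluster[i], ])
  }, numeric(1))
  labels <- cluster_labels[km$cluster]
  labels[is.na(labels)] <- "non_classifiable"
  fundamental <- vapply(seq_len(n), function(i) is_fundamental(X[i, ]),
                        logical(1))
  labels[!fundamental | sim < similarity_floor] <- "non_classifiable"

  list(labels = labels,
       cluster = km$cluster,
       centroid_similarity = sim,
       k = k,
       cluster_labels = cluster_labels,
       centroid_coa = centroid_coa,
       fraction_non_classifiable = mean(labels == "non_classifiable"))
}

# Assign the four fundamental labels to cluster centroids by circular timing:
# the one-to-one assignment of labels to (up to four of) the centroids that
# minimizes the total circular distance to the canonical phase angles.
# Unassigned centroids get NA.
assign_cluster_labels <- function(centroid_coa) {
  k <- length(centroid_coa)
  targets <- fundamental_phase_angles()
  n_lab <- length(targets)
  out <- rep(NA_character_, k)
  if (k <= n_lab) {
    # all centroids labeled: choose the label subset/permutation
    perms <- permutations_of(n_lab)
    best <- NULL; best_cost <- Inf
    for (pm in perms) {
      cost <- sum(vapply(seq_len(k), function(i)
        abs(circular_diff(centroid_coa[i], targets[pm[i]])), numeric(1)))
      if (cost < best_cost) { best_cost <- cost; best <- pm }
    }
    out <- names(targets)[best[seq_len(k)]]
  } else {
    # more clusters than labels: pick the best centroid for each label
    combs <- utils::combn(k, n_lab, simplify = FALSE)
    perms <- permutations_of(n_lab)
    best_cost <- Inf; best_comb <- NULL; best_perm <- NULL
    for (cb in combs) {
      for (pm in perms) {
        cost <- sum(vapply(seq_len(n_lab), function(j)
          abs(circular_diff(centroid_coa[cb[j]], targets[pm[j]])), numeric(1)))
        if (cost < best_cost) {
          best_cost <- cost; best_comb <- cb; best_perm <- pm
        }
      }
    }
    out[best_comb] <- names(targets)[best_perm]
  }
  out
}
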