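# Descriptive and comparison statistics: Cohen's d (pooled SD), effect
# magnitude classes, Benjamini-Hochberg adjustment.

#' Cohen's d with pooled standard deviation
#'
#' `(mean(x) - mean(y)) / s_pooled`, with the pooled SD built from the two
#' sample (n−1) variances weighted by their degrees of freedom.
#'
#' @param x,y Numeric vectors, each of length >= 2.
#' @return Signed effect size (dimensionless).
#' @export
cohens_d <- function(x, y) {
  nx <- length(x); ny <- length(y)
  if (nx < 2L || ny < 2L) stop("each group needs n >= 2", call. = FALSE)
  sp2 <- ((nx - 1) * stats::var(x) + (ny - 1) * stats::var(y)) / (nx + ny - 2)
  if (sp2 <= 0) stop("zero pooled standard deviation", call. = FALSE)
  (mean(x) - mean(y)) / sqrt(sp2)
}

#' Effect-magnitude class of a Cohen's d
#'
#' Standard cutoffs on `|d|`: below 0.2 none, `[0.2, 0.5)` small,
#' `[0.5, 0.8)` moderate, `>= 0.8` large.
#'
#' @param d Effect size(s).
#' @return Character vector over `{"none", "small", "moderate", "large"}`.
#' @export
effect_magnitude <- function(d) {
  a <- abs(d)
  out <- character(length(a))
  out[a < 0.2] <- "none"
  out[a >= 0.2 & a < 0.5] <- "small"
  out[a >= 0.5 & a < 0.8] <- "moderate"
  out[a >= 0.8] <- "large"
  out
}

#' Benjamini-Hochberg adjustment of p-values
#'
#' Step-up false-discovery-rate adjustment; adjusted values are capped at 1,
#' never smaller than the raw values, and monotone in the raw ordering.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same length and order.
#' @export
benjamini_hochberg <- function(p) {
  if (!is.numeric(p) || anyNA(p) || any(p < 0 | p > 1)) {
    stop("p-values must be numbers in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = "BH")
}

#' Compare a metric between two groups
#'
#' Convenience wrapper: Welch t-test p-value, Cohen's d (pooled SD) and its
#' magnitude class for a named contrast.
#'
#' @param x,y Numeric vectors.
#' @param contrast Identifier recorded on the output row.
#' @return One-row data frame: `contrast`, `d`, `magnitude`, `p_raw`.
#' @export
compare_groups <- function(x, y, contrast = "x_vs_y") {
  d <- cohens_d(x, y)
  p <- tryCatch(stats::t.test(x, y)$p.value, error = function(e) NA_real_)
  data.frame(contrast = contrast, d = d,
             magnitude = effect_magnitude(d), p_raw = p)
}
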