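#' Trial-wise outlier rejection at k standard deviations
#'
#' Single-pass rejection over the pooled-across-groups trial distribution:
#' values farther than `k` standard deviations from the pooled mean are
#' removed. The pass is not iterated, and a zero-spread sample removes
#' nothing. `NA` values are never kept.
#'
#' @param values Numeric vector of trial values pooled across subjects and
#'   groups (>= 3 values).
#' @param k Rejection threshold in standard deviations (default 3).
#' @return List with `values` (kept values) and `mask` (logical keep mask,
#'   same length as the input).
#' @export
reject_outliers <- function(values, k = 3) {
  if (sum(is.finite(values)) < 3L) stop("need at least 3 finite values")
  m <- mean(values, na.rm = TRUE)
  s <- stats::sd(values, na.rm = TRUE)
  mask <- if (s == 0) is.finite(values) else
    is.finite(values) & abs(values - m) <= k * s
  list(values = values[mask], mask = mask)
}

#' Two-sample F-test for equal variances
#'
#' Tests whether two independent samples share a population variance using
#' the variance-ratio statistic F = s2_a / s2_b on (n_a - 1, n_b - 1)
#' degrees of freedom. The F reference distribution is asymmetric, so
#' critical values differ by tail; the two-sided p-value is
#' 2 * min(P(F <= f), P(F >= f)), capped at 1. The result also reports the
#' signed distance of F from 1 (the null value) and which sample has the
#' smaller variance.
#'
#' @param sample_a,sample_b Numeric vectors (each >= 2 values).
#' @return An object of class `variance_test`: `statistic`, `df`, `p`,
#'   `direction`, `f_minus_1`, `degenerate`.
#' @export
variance_ftest <- function(sample_a, sample_b) {
  sample_a <- sample_a[is.finite(sample_a)]
  sample_b <- sample_b[is.finite(sample_b)]
  if (length(sample_a) < 2L || length(sample_b) < 2L)
    stop("each sample needs >= 2 values")
  va <- stats::var(sample_a); vb <- stats::var(sample_b)
  if (vb == 0 || va == 0) {
    return(structure(list(statistic = if (vb == 0) Inf else 0,
                          df = c(length(sample_a) - 1L, length(sample_b) - 1L),
                          p = NA_real_, direction = NA_character_,
                          f_minus_1 = NA_real_, degenerate = TRUE),
                     class = "variance_test"))
  }
  ht <- stats::var.test(sample_a, sample_b)
  f <- unname(ht$statistic)
  structure(list(statistic = f,
                 df = unname(ht$parameter),
                 p = ht$p.value,
                 direction = if (f < 1) "a_smaller" else
                   if (f > 1) "b_smaller" else "equal",
                 f_minus_1 = f - 1,
                 degenerate = FALSE),
            class = "variance_test")
}

#' Bartlett's test of variance homogeneity across groups
#'
#' Chi-squared test of equal population variances across k groups on k - 1
#' degrees of freedom. Intended to be run on per-subject day-averages
#' (averaging trials within days first preserves sample independence).
#'
#' @param groups List of numeric vectors, one per group (>= 2 groups, each
#'   with >= 2 values).
#' @return An object of class `variance_test`: `statistic` (chi-squared),
#'   `df`, `p`.
#' @export
bartlett_groups <- function(groups) {
  if (length(groups) < 2L) stop("need >= 2 groups")
  if (any(vapply(groups, function(g) sum(is.finite(g)), 0L) < 2L))
    stop("each group needs >= 2 values")
  ht <- stats::bartlett.test(groups)
  structure(list(statistic = unname(ht$statistic),
                 df = unname(ht$parameter),
                 p = ht$p.value,
                 direction = NA_character_, f_minus_1 = NA_real_,
                 degenerate = FALSE),
            class = "variance_test")
}

#' @export
print.variance_test <- function(x, ...) {
  if (isTRUE(x$degenerate)) {
    cat("Degenerate variance test (zero variance in a sample)\n")
  } else {
    cat(sprintf("statistic = %.4g, df = %s, p = %.4g\n",
                x$statistic, paste(x$df, collapse = ", "), x$p))
  }
  invisible(x)
}

#' Pearson correlation with a two-tier significance convention
#'
#' Correlates paired measurements (complete cases only; mean-imputation of
#' missing neuroimaging subjects happens upstream) and classifies the result
#' under a conservative strict alpha with a relaxed trend tier: p below the
#' strict alpha is `"significant"`, below the trend alpha a `"trend"`,
#' otherwise `"ns"`.
#'
#' @param x,y Numeric vectors of equal length.
#' @param alpha_strict,alpha_trend Significance tiers (defaults 0.001, 0.05).
#' @return List with `r`, `p`, `n`, `tier`.
#' @export
correlate <- function(x, y, alpha_strict = 0.001, alpha_trend = 0.05) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3L) stop("need >= 3 paired complete cases")
  ht <- stats::cor.test(x, y, method = "pearson")
  p <- ht$p.value
  list(r = unname(ht$estimate), p = p, n = length(x),
       tier = if (is.na(p)) "ns" else if (p < alpha_strict) "significant"
       else if (p < alpha_trend) "trend" else "ns")
}
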