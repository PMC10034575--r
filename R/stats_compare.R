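# Nonparametric comparison suite for paired and independent plan metrics.
# Standard tests delegate to base R (wilcox.test, kruskal.test, cor.test,
# lm). The exact signed-rank path is computed in-package by convolution
# over doubled ranks so that tied |differences| still get an exact null
# distribution (stats::wilcox.test falls back to the normal approximation
# under ties).

test_result <- function(statistic, p_value, method, n, exact = NA) {
  tibble::tibble(statistic = unname(statistic), p_value = unname(p_value),
                 method = method, n = n, exact = exact)
}

# Exact null distribution of the signed-rank statistic W = sum of ranks of
# positive differences, allowing midranks. Works on doubled ranks (always
# integers) and convolves the generating function term by term:
# P(W2 = w) with W2 = sum 2*r_i*B_i, B_i iid Bernoulli(1/2).
signed_rank_exact_p <- function(d) {
  r2 <- round(2 * rank(abs(d)))          # doubled midranks, integer
  w2_obs <- sum(r2[d > 0])
  tot <- sum(r2)
  probs <- numeric(tot + 1L)             # index w2 + 1
  probs[1L] <- 1
  for (r in r2) {
    shifted <- c(rep(0, r), probs[seq_len(tot + 1L - r)])
    probs <- (probs + shifted) / 2
  }
  lower <- sum(probs[seq_len(w2_obs + 1L)])            # P(W2 <= obs)
  upper <- sum(probs[(w2_obs + 1L):(tot + 1L)])        # P(W2 >= obs)
  min(1, 2 * min(lower, upper))
}

#' Wilcoxon signed rank test for paired differences
#'
#' Two-sided test of symmetry about zero. Zero differences are discarded
#' (Wilcoxon's original policy). The exact null distribution is used for
#' n <= `exact_max` (computed in-package, valid under tied ranks);
#' otherwise the normal approximation with continuity and tie correction
#' (via [stats::wilcox.test()]).
#'
#' @param paired_diffs numeric vector of paired differences.
#' @param exact `TRUE`/`FALSE` to force a mode, or `NULL` (default) for
#'   the n-based policy.
#' @param exact_max largest n for the exact path (default 25).
#' @return a one-row [tibble::tibble] with `statistic` (V, the positive
#'   rank sum), `p_value`, `method`, `n`, `exact`.
#' @export
wilcoxon_signed_rank <- function(paired_diffs, exact = NULL, exact_max = 25) {
  d <- paired_diffs[!is.na(paired_diffs)]
  d <- d[d != 0]
  if (length(d) == 0L) {
    warning("all paired differences are zero; p = 1")
    return(test_result(0, 1, "wilcoxon_signed_rank", 0L, NA))
  }
  n <- length(d)
  if (is.null(exact)) exact <- n <= exact_max
  v <- sum(rank(abs(d))[d > 0])
  if (exact) {
    p <- signed_rank_exact_p(d)
  } else {
    p <- suppressWarnings(
      stats::wilcox.test(d, exact = FALSE, correct = TRUE))$p.value
  }
  test_result(v, p, "wilcoxon_signed_rank", n, exact)
}

#' Mann-Whitney (Wilcoxon rank sum) test for two independent samples
#'
#' Two-sided. Exact when `min(n, m) <= 8` and there are no ties; normal
#' approximation with tie correction otherwise. Delegates to
#' [stats::wilcox.test()].
#'
#' @param x,y numeric samples.
#' @param exact `TRUE`/`FALSE` to force a mode, or `NULL` for the default
#'   policy.
#' @return a one-row [tibble::tibble]; `statistic` is the Mann-Whitney U.
#' @export
mann_whitney <- function(x, y, exact = NULL) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (!length(x) || !length(y)) stop("both samples must be non-empty")
  ties <- anyDuplicated(c(x, y)) > 0
  if (is.null(exact)) exact <- min(length(x), length(y)) <= 8 && !ties
  ht <- suppressWarnings(
    stats::wilcox.test(x, y, exact = exact, correct = TRUE))
  test_result(ht$statistic, ht$p.value, "mann_whitney",
              length(x) + length(y), exact && !ties)
}

#' Kruskal-Wallis rank test across groups
#'
#' H statistic with tie correction, chi-squared p-value on k - 1 degrees
#' of freedom (via [stats::kruskal.test()]).
#'
#' @param groups list of numeric vectors.
#' @return a one-row [tibble::tibble].
#' @export
kruskal_wallis <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2)
  ht <- stats::kruskal.test(groups)
  test_result(ht$statistic, ht$p.value, "kruskal_wallis",
              sum(lengths(groups)))
}

#' Pearson correlation with two-sided t-test
#'
#' @param x,y numeric vectors of equal length (n >= 3).
#' @return a one-row [tibble::tibble] with the correlation in `statistic`
#'   and the t-test p-value.
#' @export
pearson_r <- function(x, y) {
  ht <- stats::cor.test(x, y, method = "pearson")
  test_result(unname(ht$estimate), ht$p.value, "pearson", length(x))
}

#' Ordinary least squares with confidence and prediction bands
#'
#' Fits `y ~ x` and returns 95% t-based confidence bands for the expected
#' value and prediction bands for individual new estimates.
#'
#' @param x,y numeric vectors.
#' @param newx evaluation points (default: sorted `x`).
#' @param level band level (default 0.95).
#' @return list with `slope`, `intercept`, `fit` (the `lm` object) and a
#'   [tibble::tibble] `bands` with columns `x`, `fit`, `conf_lo`,
#'   `conf_hi`, `pred_lo`, `pred_hi`.
#' @export
linear_fit_with_bands <- function(x, y, newx = sort(x), level = 0.95) {
  if (length(unique(x)) < 2) stop("need at least two distinct x values")
  df <- data.frame(x = x, y = y)
  fit <- stats::lm(y ~ x, data = df)
  nd <- data.frame(x = newx)
  cf <- stats::predict(fit, nd, interval = "confidence", level = level)
  pr <- stats::predict(fit, nd, interval = "prediction", level = level)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       fit = fit,
       bands = tibble::tibble(x = newx, fit = cf[, "fit"],
                              conf_lo = cf[, "lwr"], conf_hi = cf[, "upr"],
                              pred_lo = pr[, "lwr"], pred_hi = pr[, "upr"]))
}
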