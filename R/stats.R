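#' Normality-gated two-group comparison
#'
#' Applies the Shapiro-Wilk test to each group; when both p-values are at or
#' above `alpha_norm` the groups are compared with an unpaired two-sided
#' Student's t-test (pooled variance, the classical form), otherwise with a
#' two-sided Mann-Whitney test (exact for small tie-free samples, normal
#' approximation with tie correction otherwise). A zero-variance sample,
#' for which Shapiro-Wilk is undefined, is routed to Mann-Whitney with a
#' warning. Group means and standard errors of the mean are reported
#' whichever branch is taken.
#'
#' @param a,b Numeric samples, each of length >= 3 (the Shapiro-Wilk
#'   minimum).
#' @param alpha_norm Normality-gate level. Default 0.05.
#' @param var_equal Use the pooled-variance t statistic on the parametric
#'   branch. Default `TRUE`; set `FALSE` for Welch.
#' @return List of class `comparison_result`: `test_used` (`"t_test"` or
#'   `"mann_whitney"`), `normality_p_a`, `normality_p_b`, `statistic`,
#'   `p_two_sided`, `mean_a`, `sem_a`, `mean_b`, `sem_b`, `n_a`, `n_b`.
#' @export
gated_compare <- function(a, b, alpha_norm = 0.05, var_equal = TRUE) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 3 || length(b) < 3)
    stop("each group needs at least 3 values (Shapiro-Wilk minimum)")
  shapiro_p <- function(x) {
    if (stats::sd(x) == 0) return(NA_real_)
    stats::shapiro.test(x)$p.value
  }
  pa <- shapiro_p(a)
  pb <- shapiro_p(b)
  if (is.na(pa) || is.na(pb))
    warning("zero-variance sample: Shapiro-Wilk undefined, using Mann-Whitney")
  use_t <- !is.na(pa) && !is.na(pb) && pa >= alpha_norm && pb >= alpha_norm
  if (use_t) {
    ht <- stats::t.test(a, b, var.equal = var_equal)
    test_used <- "t_test"
  } else if (stats::sd(c(a, b)) == 0) {
    ## every observation identical across both groups: no evidence of any
    ## difference, and the rank test's variance is zero
    ht <- list(statistic = NA_real_, p.value = 1)
    test_used <- "mann_whitney"
  } else {
    ht <- suppressWarnings(stats::wilcox.test(a, b, correct = TRUE))
    test_used <- "mann_whitney"
  }
  sem <- function(x) stats::sd(x) / sqrt(length(x))
  structure(list(test_used = test_used,
                 normality_p_a = pa, normality_p_b = pb,
                 statistic = unname(ht$statistic),
                 p_two_sided = ht$p.value,
                 mean_a = mean(a), sem_a = sem(a),
                 mean_b = mean(b), sem_b = sem(b),
                 n_a = length(a), n_b = length(b)),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("%s: %.2f±%.2f (n=%d) vs %.2f±%.2f (n=%d), p = %.4g\n",
              x$test_used, x$mean_a, x$sem_a, x$n_a,
              x$mean_b, x$sem_b, x$n_b, x$p_two_sided))
  invisible(x)
}

#' Pearson chi-square test on a 2x2 table
#'
#' Uncorrected Pearson chi-square (no Yates continuity correction) with
#' df = 1. The uncorrected form is the dialect that reproduces the printed
#' p-value for the abnormal-apnea proportion table (8/17 vs 2/26 gives
#' a statistic of ~5.33 and p ~ 0.02; the Yates-corrected form gives ~0.05).
#'
#' @param tab 2x2 matrix of counts with positive row and column sums.
#' @return List of class `chisq_result`: `table`, `statistic`, `df`,
#'   `p_two_sided`.
#' @export
chi_square_2x2 <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2, 2))) stop("table must be 2x2")
  if (any(tab < 0)) stop("counts must be non-negative")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("degenerate margins: every row and column sum must be > 0")
  ht <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  structure(list(table = tab, statistic = unname(ht$statistic),
                 df = 1L, p_two_sided = ht$p.value),
            class = "chisq_result")
}

#' Ordinary least-squares regression of y on x
#'
#' Simple linear regression with the squared Pearson correlation as R^2 and
#' a two-sided p-value for slope != 0 from the t distribution on n - 2
#' degrees of freedom. A constant response gives slope 0, R^2 = 0, p = 1;
#' a constant predictor is an error.
#'
#' @param x Predictor (length >= 3, non-constant).
#' @param y Response (same length).
#' @return List of class `regression_result`: `slope`, `intercept`,
#'   `r_squared`, `p_two_sided`, `n`.
#' @export
lin_regress <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need at least 3 complete (x, y) pairs")
  if (length(y) != n) stop("x and y must have equal length")
  if (stats::sd(x) == 0) stop("constant predictor: slope is undefined")
  if (stats::sd(y) == 0)
    return(structure(list(slope = 0, intercept = mean(y), r_squared = 0,
                          p_two_sided = 1, n = n),
                     class = "regression_result"))
  fit <- stats::lm(y ~ x)
  ## summary.lm warns on numerically perfect fits; the p-value is still valid
  sm <- suppressWarnings(summary(fit))
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = stats::cor(x, y)^2,
                 p_two_sided = unname(sm$coefficients[2, 4]),
                 n = n),
            class = "regression_result")
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf("OLS: slope %.4g, intercept %.4g, R^2 = %.3f, p = %.4g (n=%d)\n",
              x$slope, x$intercept, x$r_squared, x$p_two_sided, x$n))
  invisible(x)
}

#' Two-sided standard-normal critical value
#'
#' The quantile `qnorm(1 - alpha/2)`; at the default `alpha = 0.01` this is
#' 2.5758..., the 99% two-sided critical value that the flow-limitation
#' detector rounds to 2.576.
#'
#' @param alpha Two-sided tail mass. Default 0.01.
#' @return The critical value.
#' @export
normal_critical_value <- function(alpha = 0.01) {
  stats::qnorm(1 - alpha / 2)
}
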