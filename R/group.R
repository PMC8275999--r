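# Second-level mediation inference: population test of the indirect effect,
# consistency vs covariance decomposition, and sign-pattern subgrouping.

#' Second-level bootstrap test of a per-subject statistic
#'
#' BCa bootstrap over subjects of the mean of per-subject path estimates
#' (typically the indirect effects a*b); the two-sided p-value comes from
#' CI inversion.
#'
#' @param values Numeric vector of per-subject estimates (>= 3 subjects).
#' @param n_boot Bootstrap resamples.
#' @param seed Integer seed.
#' @param alpha Level of the reported CI.
#' @return A [bca_bootstrap()] result for the mean.
#' @export
second_level_test <- function(values, n_boot = 10000, seed = 1L,
                              alpha = 0.05) {
  values <- as.numeric(values)
  if (length(values) < 3) stop("second-level test needs at least 3 subjects")
  bca_bootstrap(function(d) mean(d[, 1]), matrix(values, ncol = 1),
                n_boot = n_boot, alpha = alpha, seed = seed)
}

#' Consistency / covariance decomposition of the group indirect effect
#'
#' The group-average indirect effect decomposes exactly as
#' `mean(a * b) = mean(a) * mean(b) + cov_pop(a, b)` where `cov_pop` uses
#' divisor n. A group mediation effect can therefore arise from consistent
#' same-sign paths (the product-of-means term) or from subjects' a and b
#' covarying around zero means (the covariance term).
#'
#' @param a_vec,b_vec Per-subject path coefficients, equal length >= 2.
#' @return Named list `mean_ab`, `mean_a_mean_b`, `cov_ab`.
#' @export
decompose_mediation <- function(a_vec, b_vec) {
  n <- length(a_vec)
  if (length(b_vec) != n) stop("a_vec and b_vec must have equal length")
  if (n < 2) stop("need at least 2 subjects")
  cov_pop <- sum((a_vec - mean(a_vec)) * (b_vec - mean(b_vec))) / n
  list(mean_ab = mean(a_vec * b_vec),
       mean_a_mean_b = mean(a_vec) * mean(b_vec),
       cov_ab = cov_pop)
}

#' One-sample consistency tests and a-b correlation
#'
#' Tests whether the a and b paths are consistently signed across subjects
#' (two-sided one-sample t-tests against 0) and whether they covary
#' (Pearson correlation with its two-sided p). A covariance-driven mediator
#' shows non-significant t-tests but a significant positive correlation; a
#' consistent mediator shows the reverse.
#'
#' @param a_vec,b_vec Per-subject path coefficients (n >= 3).
#' @return List of class `consistency_tests`: `t_a`, `p_a`, `t_b`, `p_b`,
#'   `r_ab`, `p_r`, `n`, `degenerate` (TRUE when either vector has zero
#'   variance; the corresponding t is +/-Inf and p is NA).
#' @export
consistency_tests <- function(a_vec, b_vec) {
  n <- length(a_vec)
  if (length(b_vec) != n) stop("a_vec and b_vec must have equal length")
  if (n < 3) stop("need at least 3 subjects")
  one_sample <- function(v) {
    if (stats::sd(v) == 0) {
      t <- if (mean(v) == 0) 0 else sign(mean(v)) * Inf
      return(list(t = t, p = NA_real_, degenerate = TRUE))
    }
    tt <- stats::t.test(v, mu = 0)
    list(t = unname(tt$statistic), p = tt$p.value, degenerate = FALSE)
  }
  ta <- one_sample(a_vec)
  tb <- one_sample(b_vec)
  degen <- ta$degenerate || tb$degenerate
  if (!degen) {
    ct <- stats::cor.test(a_vec, b_vec)
    r <- unname(ct$estimate); pr <- ct$p.value
  } else {
    r <- NA_real_; pr <- NA_real_
  }
  structure(list(t_a = ta$t, p_a = ta$p, t_b = tb$t, p_b = tb$p,
                 r_ab = r, p_r = pr, n = n, degenerate = degen),
            class = "consistency_tests")
}

#' @export
print.consistency_tests <- function(x, digits = 3, ...) {
  cat("Consistency tests (n = ", x$n, ")\n", sep = "")
  cat("  a: t = ", round(x$t_a, digits), ", p = ", format.pval(x$p_a, 3),
      " | b: t = ", round(x$t_b, digits), ", p = ", format.pval(x$p_b, 3),
      "\n  corr(a, b): r = ", round(x$r_ab, digits),
      ", p = ", format.pval(x$p_r, 3), "\n", sep = "")
  if (x$degenerate) cat("  (degenerate: zero-variance path vector)\n")
  invisible(x)
}

#' Sign-pattern subgrouping of subjects
#'
#' Labels each subject POS when both path estimates are strictly positive,
#' NEG when both strictly negative, otherwise NONE (exact zeros map to
#' NONE).
#'
#' @param a_vec,b_vec Per-subject path coefficients, equal length.
#' @return List of class `sign_groups`: `labels` (factor POS/NEG/NONE) and
#'   `counts`.
#' @export
assign_sign_groups <- function(a_vec, b_vec) {
  if (length(b_vec) != length(a_vec))
    stop("a_vec and b_vec must have equal length")
  lab <- ifelse(a_vec > 0 & b_vec > 0, "POS",
                ifelse(a_vec < 0 & b_vec < 0, "NEG", "NONE"))
  labels <- factor(lab, levels = c("POS", "NEG", "NONE"))
  structure(list(labels = labels, counts = table(labels)),
            class = "sign_groups")
}

#' @export
print.sign_groups <- function(x, ...) {
  cat("Sign-pattern groups:\n")
  print(x$counts)
  invisible(x)
}

#' Group-level mediation analysis of per-subject path estimates
#'
#' Convenience wrapper bundling the second-level BCa tests of the mean a, b,
#' and a*b, the consistency/covariance decomposition, the consistency
#' t-tests and a-b correlation, and the sign-pattern subgrouping for one
#' region's per-subject path estimates.
#'
#' @param a_vec,b_vec Per-subject path coefficients (n >= 3).
#' @param n_boot Bootstrap resamples for the second-level tests.
#' @param seed Integer seed.
#' @param alpha CI level for the second-level tests.
#' @return Object of class `mepm_group` with elements `test_a`, `test_b`,
#'   `test_ab` ([bca_bootstrap()] results), `decomposition`, `consistency`,
#'   `groups`, `n`.
#' @export
group_mediation <- function(a_vec, b_vec, n_boot = 10000, seed = 1L,
                            alpha = 0.05) {
  n <- length(a_vec)
  if (length(b_vec) != n) stop("a_vec and b_vec must have equal length")
  if (n < 3) stop("group analysis needs at least 3 subjects")
  ab <- a_vec * b_vec
  structure(list(
    test_a = second_level_test(a_vec, n_boot, seed, alpha),
    test_b = second_level_test(b_vec, n_boot, seed + 1L, alpha),
    test_ab = second_level_test(ab, n_boot, seed + 2L, alpha),
    decomposition = decompose_mediation(a_vec, b_vec),
    consistency = consistency_tests(a_vec, b_vec),
    groups = assign_sign_groups(a_vec, b_vec),
    n = n), class = "mepm_group")
}

#' @export
print.mepm_group <- function(x, digits = 3, ...) {
  cat("Group mediation analysis (n = ", x$n, " subjects)\n", sep = "")
  cat("  mean ab = ", round(x$test_ab$estimate, digits),
      " [", round(x$test_ab$ci[1], digits), ", ",
      round(x$test_ab$ci[2], digits), "], p = ",
      format.pval(x$test_ab$p, 3), "\n", sep = "")
  d <- x$decomposition
  cat("  decomposition: mean(a)*mean(b) = ", round(d$mean_a_mean_b, digits),
      " + cov(a,b) = ", round(d$cov_ab, digits), "\n", sep = "")
  print(x$consistency, digits = digits)
  print(x$groups)
  invisible(x)
}

#' @export
summary.mepm_group <- function(object, ...) object

#' @export
coef.mepm_group <- function(object, ...) {
  c(mean_a = object$test_a$estimate, mean_b = object$test_b$estimate,
    mean_ab = object$test_ab$estimate)
}
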