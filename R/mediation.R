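# First-level mediation: Baron-Kenny path model fitted per voxel across
# trials, with BCa bootstrap inference on the a, b, and a*b paths.

#' Fit the trial-wise mediation path model
#'
#' Ordinary least squares fits of the three-variable path model:
#' `a` from M ~ X, `b` and `c_prime` from Y ~ X + M, and the total effect
#' `c` from Y ~ X (all with intercepts). The indirect effect is `ab = a * b`
#' and the OLS identity `c = c_prime + a * b` holds exactly on a common
#' sample. X is the stimulus code (valence -1/0/+1), M the mediator (trial
#' amplitude), Y the choice code (-1/+1); Y is treated as continuous, the
#' convention of mediation effect parametric mapping.
#'
#' @param X,M,Y Numeric vectors of equal length (>= 4 complete trials).
#' @return Object of class `path_fit`: list with `coefficients` (named
#'   vector a, b, c, c_prime, ab) and `n`.
#' @export
fit_paths <- function(X, M, Y) {
  n <- length(X)
  if (length(M) != n || length(Y) != n) stop("X, M, Y must have equal length")
  if (n < 4) stop("need at least 4 trials")
  if (stats::sd(X) == 0) stop("degenerate input: X is constant")
  if (stats::sd(M) == 0) stop("degenerate input: M is constant")
  cf <- .path_point(X, M, Y)
  if (anyNA(cf)) stop("degenerate input: [X, M] collinear")
  structure(list(coefficients = cf, n = n), class = "path_fit")
}

#' @export
coef.path_fit <- function(object, ...) object$coefficients

#' @export
print.path_fit <- function(x, digits = 4, ...) {
  cat("Mediation path fit (", x$n, " trials)\n", sep = "")
  print(round(x$coefficients, digits))
  invisible(x)
}

# closed-form path coefficients from raw moments (one sample)
.path_point <- function(X, M, Y) {
  n <- length(X)
  sx <- sum(X); sm <- sum(M); sy <- sum(Y)
  cxx <- sum(X * X) - sx * sx / n
  cxm <- sum(X * M) - sx * sm / n
  cmm <- sum(M * M) - sm * sm / n
  cxy <- sum(X * Y) - sx * sy / n
  cmy <- sum(M * Y) - sm * sy / n
  det <- cxx * cmm - cxm * cxm
  if (cxx <= 0 || det <= .Machine$double.eps * cxx * cmm)
    return(c(a = NA_real_, b = NA_real_, c = NA_real_,
             c_prime = NA_real_, ab = NA_real_))
  a <- cxm / cxx
  c_tot <- cxy / cxx
  b <- (cxx * cmy - cxm * cxy) / det
  c_prime <- (cmm * cxy - cxm * cmy) / det
  c(a = a, b = b, c = c_tot, c_prime = c_prime, ab = a * b)
}

# Path statistics under row-resampling expressed through weighted moments.
# W is an n x B matrix of resample counts (each column sums to n, or n-1
# for jackknife columns). Returns a list of length-B vectors.
.path_weighted <- function(X, M, Y, W) {
  nw <- colSums(W)
  Sx <- crossprod(W, X)[, 1];  Sm <- crossprod(W, M)[, 1]
  Sy <- crossprod(W, Y)[, 1]
  Sxx <- crossprod(W, X * X)[, 1]; Sxm <- crossprod(W, X * M)[, 1]
  Smm <- crossprod(W, M * M)[, 1]; Sxy <- crossprod(W, X * Y)[, 1]
  Smy <- crossprod(W, M * Y)[, 1]
  cxx <- Sxx - Sx^2 / nw
  cxm <- Sxm - Sx * Sm / nw
  cmm <- Smm - Sm^2 / nw
  cxy <- Sxy - Sx * Sy / nw
  cmy <- Smy - Sm * Sy / nw
  det <- cxx * cmm - cxm^2
  bad <- cxx <= 0 | det <= 0
  a <- ifelse(bad, NA_real_, cxm / cxx)
  c_tot <- ifelse(bad, NA_real_, cxy / cxx)
  b <- ifelse(bad, NA_real_, (cxx * cmy - cxm * cxy) / det)
  c_prime <- ifelse(bad, NA_real_, (cmm * cxy - cxm * cmy) / det)
  list(a = a, b = b, c = c_tot, c_prime = c_prime, ab = a * b)
}

# BCa interval and CI-inversion p-value from bootstrap and jackknife
# replicates of one statistic. Returns list(ci, p, z0, accel, degenerate).
.bca_core <- function(t0, tb, jack, alpha = 0.05, p_grid = 400,
                      force_z0 = NULL, force_accel = NULL) {
  tb <- tb[is.finite(tb)]
  B <- length(tb)
  if (B < 10 || all(tb == tb[1])) {
    est <- if (B) tb[1] else t0
    p <- if (isTRUE(all.equal(t0, 0)) || t0 == 0) 1 else NA_real_
    return(list(ci = c(t0, t0), p = p, z0 = 0, accel = 0, degenerate = TRUE))
  }
  prop <- sum(tb < t0) / B
  prop <- min(max(prop, 1 / (2 * B)), 1 - 1 / (2 * B))
  z0 <- stats::qnorm(prop)
  if (!is.null(force_z0)) z0 <- force_z0
  jd <- mean(jack) - jack
  denom <- sum(jd^2)^1.5
  accel <- if (denom > 0) sum(jd^3) / (6 * denom) else 0
  if (!is.null(force_accel)) accel <- force_accel
  adj <- function(a_lev) {
    za <- stats::qnorm(a_lev)
    stats::pnorm(z0 + (z0 + za) / (1 - accel * (z0 + za)))
  }
  ci <- unname(stats::quantile(tb, c(adj(alpha / 2), adj(1 - alpha / 2)),
                               type = 7, names = FALSE))
  # p = smallest two-sided alpha at which the BCa CI excludes zero
  alphas <- seq(1 / p_grid, 1 - 1 / p_grid, length.out = p_grid)
  lo <- stats::quantile(tb, pmin(pmax(adj(alphas / 2), 0), 1), type = 7,
                        names = FALSE)
  hi <- stats::quantile(tb, pmin(pmax(adj(1 - alphas / 2), 0), 1), type = 7,
                        names = FALSE)
  excl <- lo > 0 | hi < 0
  p <- if (any(excl)) alphas[which(excl)[1]] else 1
  list(ci = ci, p = p, z0 = z0, accel = accel, degenerate = FALSE)
}

#' Bias-corrected accelerated (BCa) bootstrap of a statistic
#'
#' Resamples the rows of `data` with replacement, computes the statistic on
#' each resample, and forms the BCa confidence interval: the bias correction
#' z0 comes from the proportion of bootstrap replicates below the point
#' estimate, and the acceleration from the jackknife skewness. The two-sided
#' p-value is the smallest alpha at which the BCa interval excludes zero,
#' found on a grid of `p_grid` alpha levels (resolution 1/p_grid).
#'
#' @param statistic_fn Function taking a data subset (same type as `data`)
#'   and returning a scalar.
#' @param data Data frame or matrix whose rows are the resampling units.
#' @param n_boot Number of bootstrap resamples (>= 100).
#' @param alpha Nominal two-sided level for the reported CI.
#' @param seed Integer seed (bootstrap is deterministic given it).
#' @param p_grid Alpha-grid resolution for the p-value inversion.
#' @param force_z0,force_accel Override bias correction / acceleration
#'   (mainly to recover the plain percentile interval by forcing both to 0).
#' @return Object of class `bca_boot`: `estimate`, `ci`, `p`, `alpha`,
#'   `n_boot`, `seed`, `z0`, `accel`, `degenerate`, `replicates`.
#' @export
bca_bootstrap <- function(statistic_fn, data, n_boot = 10000, alpha = 0.05,
                          seed = 1L, p_grid = 400,
                          force_z0 = NULL, force_accel = NULL) {
  data <- as.matrix(data)
  n <- nrow(data)
  if (n < 2) stop("data must have at least 2 rows")
  if (n_boot < 100) stop("n_boot must be at least 100")
  t0 <- statistic_fn(data)
  set.seed(as.integer(seed))
  tb <- vapply(seq_len(n_boot), function(i)
    statistic_fn(data[sample.int(n, n, replace = TRUE), , drop = FALSE]),
    numeric(1))
  jack <- vapply(seq_len(n), function(i)
    statistic_fn(data[-i, , drop = FALSE]), numeric(1))
  core <- .bca_core(t0, tb, jack, alpha = alpha, p_grid = p_grid,
                    force_z0 = force_z0, force_accel = force_accel)
  structure(list(estimate = t0, ci = core$ci, p = core$p, alpha = alpha,
                 n_boot = n_boot, seed = seed, z0 = core$z0,
                 accel = core$accel, degenerate = core$degenerate,
                 replicates = tb),
            class = "bca_boot")
}

#' @export
print.bca_boot <- function(x, digits = 4, ...) {
  cat("BCa bootstrap (", x$n_boot, " resamples)\n", sep = "")
  cat("  estimate:", round(x$estimate, digits),
      " CI[", 100 * (1 - x$alpha), "%]: [",
      round(x$ci[1], digits), ", ", round(x$ci[2], digits), "]",
      "  p = ", format.pval(x$p, digits = 3), "\n", sep = "")
  if (x$degenerate) cat("  (degenerate: statistic constant across resamples)\n")
  invisible(x)
}

#' Voxel-wise mediation with BCa bootstrap inference
#'
#' Fits the path model at every voxel of a trial-by-voxel amplitude matrix
#' and bootstraps the a, b, and a*b paths by resampling trials. One set of
#' trial resamples (drawn from `seed`) is shared across voxels, so the map
#' is a coherent resampling of the subject's trials; replicate statistics
#' are evaluated through closed-form weighted moments, which makes
#' whole-map bootstrapping fast. A voxel is flagged as a first-level
#' mediator when a, b, and a*b are all significant at `alpha` and the
#' direct effect strictly decreases: `|c_prime| < |c|`. Zero-variance
#' voxels are skipped and marked.
#'
#' @param betas Trials x voxels amplitude matrix (QC-excluded trials already
#'   removed), or a vector for a single voxel.
#' @param X,Y Stimulus (-1/0/+1) and response (-1/+1) codes aligned with the
#'   rows of `betas`.
#' @param n_boot Bootstrap resamples, default 10000.
#' @param alpha Significance level for the joint flag, default 0.05.
#' @param seed Integer master seed.
#' @param p_grid Alpha-grid resolution for p-values.
#' @return Object of class `mepm_fit`: data frame `paths` (one row per
#'   voxel: a, b, c, c_prime, ab, p_a, p_b, p_ab, CI bounds for ab,
#'   `mediator` flag, `skipped`), plus `n_trials`, `n_boot`, `alpha`,
#'   `seed`.
#' @export
voxelwise_mediation <- function(betas, X, Y, n_boot = 10000, alpha = 0.05,
                                seed = 1L, p_grid = 400) {
  betas <- as.matrix(betas)
  n <- nrow(betas)
  if (length(X) != n || length(Y) != n)
    stop("X and Y must align with the rows of betas")
  if (stats::sd(X) == 0) stop("degenerate input: X is constant")
  nv <- ncol(betas)
  set.seed(as.integer(seed))
  W <- vapply(seq_len(n_boot), function(i)
    tabulate(sample.int(n, n, replace = TRUE), n), numeric(n))
  # jackknife weights: leave-one-out
  Wj <- matrix(1, n, n); diag(Wj) <- 0

  res <- vector("list", nv)
  for (v in seq_len(nv)) {
    M <- betas[, v]
    if (stats::sd(M) == 0) {
      res[[v]] <- data.frame(a = NA, b = NA, c = NA, c_prime = NA, ab = NA,
                             p_a = NA, p_b = NA, p_ab = NA,
                             ab_lo = NA, ab_hi = NA,
                             mediator = FALSE, skipped = TRUE)
      next
    }
    t0 <- .path_point(X, M, Y)
    tb <- .path_weighted(X, M, Y, W)
    tj <- .path_weighted(X, M, Y, Wj)
    ra <- .bca_core(t0["a"], tb$a, tj$a, alpha = alpha, p_grid = p_grid)
    rb <- .bca_core(t0["b"], tb$b, tj$b, alpha = alpha, p_grid = p_grid)
    rab <- .bca_core(t0["ab"], tb$ab, tj$ab, alpha = alpha, p_grid = p_grid)
    sig <- !is.na(ra$p) && !is.na(rb$p) && !is.na(rab$p) &&
      ra$p < alpha && rb$p < alpha && rab$p < alpha
    flag <- sig && abs(t0["c_prime"]) < abs(t0["c"])
    res[[v]] <- data.frame(a = t0["a"], b = t0["b"], c = t0["c"],
                           c_prime = t0["c_prime"], ab = t0["ab"],
                           p_a = ra$p, p_b = rb$p, p_ab = rab$p,
                           ab_lo = rab$ci[1], ab_hi = rab$ci[2],
                           mediator = unname(flag), skipped = FALSE)
  }
  paths <- do.call(rbind, res)
  paths$voxel <- seq_len(nv)
  rownames(paths) <- NULL
  paths <- paths[, c("voxel", setdiff(names(paths), "voxel"))]
  structure(list(paths = paths, n_trials = n, n_boot = n_boot,
                 alpha = alpha, seed = seed),
            class = "mepm_fit")
}

#' @export
print.mepm_fit <- function(x, ...) {
  cat("Voxel-wise mediation fit: ", nrow(x$paths), " voxels, ",
      x$n_trials, " trials, ", x$n_boot, " bootstrap resamples\n", sep = "")
  cat("  mediator voxels flagged (alpha = ", x$alpha, "): ",
      sum(x$paths$mediator, na.rm = TRUE),
      " | skipped: ", sum(x$paths$skipped), "\n", sep = "")
  invisible(x)
}

#' @export
coef.mepm_fit <- function(object, ...) {
  as.matrix(object$paths[, c("a", "b", "c", "c_prime", "ab")])
}

#' @export
summary.mepm_fit <- function(object, ...) {
  p <- object$paths
  out <- list(n_voxels = nrow(p), n_trials = object$n_trials,
              n_mediators = sum(p$mediator, na.rm = TRUE),
              n_skipped = sum(p$skipped),
              mediators = p[which(p$mediator), , drop = FALSE],
              alpha = object$alpha)
  class(out) <- "summary.mepm_fit"
  out
}

#' @export
print.summary.mepm_fit <- function(x, digits = 4, ...) {
  cat("Voxel-wise mediation summary\n")
  cat("  voxels:", x$n_voxels, " trials:", x$n_trials,
      " flagged mediators:", x$n_mediators, " skipped:", x$n_skipped, "\n")
  if (nrow(x$mediators)) {
    cat("  flagged voxels (a, b, ab significant at alpha = ", x$alpha,
        " and |c'| < |c|):\n", sep = "")
    print(round(x$mediators[, c("voxel", "a", "b", "ab", "p_a", "p_b", "p_ab")],
                digits))
  }
  invisible(x)
}
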