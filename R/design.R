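#' Framewise displacement and motion outlier detection
#'
#' Computes a composite framewise displacement (FD) series from six rigid-body
#' realignment parameters (3 translations in mm, 3 rotations in radians) and
#' flags scans whose FD exceeds `mean(FD) + threshold_sd * sd(FD)`. FD is the
#' sum of absolute backward differences of the six parameters, with rotations
#' converted to arc length on a sphere of radius `rotation_radius` mm. The
#' first scan has no predecessor and its FD is defined as 0.
#'
#' @param motion_params Numeric matrix with one row per scan and 6 columns
#'   (x, y, z, pitch, roll, yaw).
#' @param threshold_sd Number of standard deviations above the mean FD beyond
#'   which a scan is declared an outlier. Default 3.
#' @param rotation_radius Sphere radius (mm) used to convert rotations to
#'   displacements. Default 50.
#' @return A list of class `motion_qc` with elements `fd` (mm, per scan),
#'   `outliers` (integer scan indices), `cutoff` (the mm threshold applied),
#'   and `threshold_sd`.
#' @export
detect_outlier_scans <- function(motion_params, threshold_sd = 3,
                                 rotation_radius = 50) {
  motion_params <- as.matrix(motion_params)
  if (ncol(motion_params) != 6L)
    stop("motion_params must have exactly 6 columns (3 translations, 3 rotations)")
  if (nrow(motion_params) < 2L)
    stop("need at least 2 scans to compute framewise displacement")
  d <- abs(diff(motion_params))
  d[, 4:6] <- d[, 4:6] * rotation_radius
  fd <- c(0, rowSums(d))
  mu <- mean(fd)
  sdev <- stats::sd(fd)
  cutoff <- mu + threshold_sd * sdev
  outliers <- if (sdev > 0) which(fd > cutoff) else integer(0)
  structure(list(fd = fd, outliers = as.integer(outliers),
                 cutoff = cutoff, threshold_sd = threshold_sd),
            class = "motion_qc")
}

#' Cosine drift basis (discrete cosine transform high-pass set)
#'
#' Returns the DCT regressors equivalent to a high-pass filter with the given
#' cutoff period; used to absorb slow scanner drift when fitting raw series.
#'
#' @param n_scans Number of scans.
#' @param TR Repetition time (s).
#' @param cutoff High-pass cutoff period (s), default 128.
#' @return Matrix `n_scans x K` (K may be 0 for short runs), columns unit-norm.
#' @export
cosine_drift_basis <- function(n_scans, TR, cutoff = 128) {
  K <- max(0L, floor(2 * n_scans * TR / cutoff))
  t_idx <- seq_len(n_scans) - 1
  B <- matrix(0, n_scans, K)
  for (k in seq_len(K)) {
    v <- cos(pi * (2 * t_idx + 1) * k / (2 * n_scans))
    B[, k] <- v / sqrt(sum(v^2))
  }
  if (K > 0) colnames(B) <- paste0("drift_", seq_len(K))
  B
}

#' Build the single-trial GLM design matrix
#'
#' Each trial is modelled by its own boxcar (stimulus onset to button press)
#' convolved at microtime resolution with the canonical HRF and, optionally,
#' its temporal derivative, then sampled at scan acquisition times
#' (mid-TR reference). A nuisance block is appended: the 6 motion parameters
#' and their squares (12 regressors), one-hot indicators for outlier scans,
#' optional cosine drift regressors, and an intercept column of ones.
#'
#' @param trial_table Data frame with at least `onset` and `duration` columns
#'   (seconds; duration is the reaction time).
#' @param n_scans,TR Scan count and repetition time (s).
#' @param spec An [hrf_spec()]; its `sampling_dt` is overridden by
#'   `TR / microtime_bins`.
#' @param motion_params Optional `n_scans x 6` motion matrix; zeros if NULL.
#' @param outlier_indices Optional integer scan indices modelled as one-hot
#'   nuisance columns.
#' @param microtime_bins Oversampling factor per TR for convolution, default 16.
#' @param drift_cutoff If non-NULL, append [cosine_drift_basis()] regressors
#'   with this cutoff (s).
#' @return An object of class `trial_design`: list with the design matrix `X`
#'   (labelled columns), `blocks` (named list of column indices:
#'   `trial_canonical`, `trial_derivative`, `motion`, `outlier`, `drift`,
#'   `intercept`), `n_trials`, `TR`, `n_scans`.
#' @export
build_single_trial_design <- function(trial_table, n_scans, TR,
                                      spec = hrf_spec(),
                                      motion_params = NULL,
                                      outlier_indices = integer(0),
                                      microtime_bins = 16L,
                                      drift_cutoff = NULL) {
  stopifnot(is.data.frame(trial_table),
            all(c("onset", "duration") %in% names(trial_table)),
            n_scans >= 1, TR > 0, microtime_bins >= 1)
  onset <- trial_table$onset
  dur <- trial_table$duration
  n_trials <- length(onset)
  if (n_trials == 0L) stop("trial_table has no rows")
  if (any(dur <= 0)) stop("all trial durations must be positive")
  run_len <- n_scans * TR
  if (any(onset + dur > run_len))
    stop("trial extends past the last scan (onset + duration > n_scans * TR)")
  if (any(onset < 0)) stop("negative onsets are not allowed")

  dt <- TR / microtime_bins
  spec$sampling_dt <- dt
  basis <- canonical_hrf(spec)
  use_deriv <- isTRUE(spec$include_time_derivative)

  n_micro <- n_scans * microtime_bins
  micro_t <- (seq_len(n_micro) - 1) * dt
  # sample convolved regressors at the middle of each TR
  samp_idx <- (seq_len(n_scans) - 1L) * microtime_bins + microtime_bins %/% 2L + 1L

  # Riemann-sum convolution at microtime resolution: invariant to the
  # oversampling factor
  conv_sample <- function(u, kern) {
    v <- stats::convolve(u, rev(kern), type = "open")[seq_len(n_micro)] * dt
    v[samp_idx]
  }

  canon <- matrix(0, n_scans, n_trials)
  deriv <- if (use_deriv) matrix(0, n_scans, n_trials) else NULL
  for (i in seq_len(n_trials)) {
    u <- as.numeric(micro_t >= onset[i] & micro_t < onset[i] + dur[i])
    if (!any(u > 0))
      stop("trial ", i, " produces an all-zero boxcar at the microtime grid")
    canon[, i] <- conv_sample(u, basis$hrf)
    if (use_deriv) deriv[, i] <- conv_sample(u, basis$dhrf)
  }
  if (any(colSums(abs(canon)) == 0))
    stop("a trial regressor is identically zero after sampling at scan times")

  if (is.null(motion_params)) motion_params <- matrix(0, n_scans, 6)
  motion_params <- as.matrix(motion_params)
  if (nrow(motion_params) != n_scans || ncol(motion_params) != 6L)
    stop("motion_params must be an n_scans x 6 matrix")
  motion_block <- cbind(motion_params, motion_params^2)

  outlier_indices <- sort(unique(as.integer(outlier_indices)))
  if (length(outlier_indices) && (min(outlier_indices) < 1 ||
                                  max(outlier_indices) > n_scans))
    stop("outlier_indices out of scan range")
  out_block <- matrix(0, n_scans, length(outlier_indices))
  for (j in seq_along(outlier_indices)) out_block[outlier_indices[j], j] <- 1

  drift_block <- if (!is.null(drift_cutoff))
    cosine_drift_basis(n_scans, TR, drift_cutoff) else matrix(0, n_scans, 0)

  X <- cbind(canon,
             if (use_deriv) deriv,
             motion_block, out_block, drift_block,
             matrix(1, n_scans, 1))
  labels <- c(paste0("trial_", seq_len(n_trials), "_canonical"),
              if (use_deriv) paste0("trial_", seq_len(n_trials), "_derivative"),
              c("mot_x", "mot_y", "mot_z", "mot_pitch", "mot_roll", "mot_yaw"),
              paste0("mot_", c("x", "y", "z", "pitch", "roll", "yaw"), "_sq"),
              if (length(outlier_indices))
                paste0("outlier_scan_", outlier_indices),
              colnames(drift_block),
              "intercept")
  colnames(X) <- labels

  k <- 0L
  blocks <- list(trial_canonical = seq_len(n_trials))
  k <- n_trials
  if (use_deriv) { blocks$trial_derivative <- k + seq_len(n_trials); k <- k + n_trials }
  else blocks$trial_derivative <- integer(0)
  blocks$motion <- k + seq_len(12L); k <- k + 12L
  blocks$outlier <- k + seq_len(length(outlier_indices)); k <- k + length(outlier_indices)
  blocks$drift <- k + seq_len(ncol(drift_block)); k <- k + ncol(drift_block)
  blocks$intercept <- k + 1L

  structure(list(X = X, blocks = blocks, n_trials = n_trials,
                 TR = TR, n_scans = n_scans,
                 outlier_indices = outlier_indices),
            class = "trial_design")
}

#' @export
print.trial_design <- function(x, ...) {
  cat("Single-trial GLM design:", x$n_scans, "scans x", ncol(x$X), "columns\n")
  cat("  trials:", x$n_trials,
      "| derivative basis:", length(x$blocks$trial_derivative) > 0,
      "| outlier scans:", length(x$blocks$outlier),
      "| drift:", length(x$blocks$drift), "\n")
  invisible(x)
}

# R-squared of y regressed on the columns of Z (intercept added)
.rsq <- function(y, Z) {
  Z <- cbind(1, Z)
  fit <- stats::lm.fit(Z, y)
  tss <- sum((y - mean(y))^2)
  if (tss == 0) return(NA_real_)
  max(0, 1 - sum(fit$residuals^2) / tss)
}

#' Trial-wise variance inflation factors
#'
#' Measures the collinearity of each trial's canonical regressor with the
#' nuisance block (motion, outlier indicators, drift, intercept):
#' VIF = 1 / (1 - R^2) from regressing the trial column on the nuisance
#' columns. Trials with VIF above the threshold are marked excluded;
#' perfect collinearity yields an infinite VIF and exclusion.
#'
#' @param design A `trial_design`.
#' @param threshold Exclusion threshold, default 2.
#' @return Data frame of class `trial_qc` with columns `trial`, `vif`,
#'   `excluded`.
#' @export
trial_vifs <- function(design, threshold = 2) {
  stopifnot(inherits(design, "trial_design"))
  nuis_idx <- c(design$blocks$motion, design$blocks$outlier, design$blocks$drift)
  if (!length(nuis_idx)) stop("design has an empty nuisance block")
  Z <- design$X[, nuis_idx, drop = FALSE]
  vif <- vapply(design$blocks$trial_canonical, function(j) {
    r2 <- .rsq(design$X[, j], Z)
    if (is.na(r2)) return(NA_real_)
    if (r2 >= 1 - 1e-12) return(Inf)
    1 / (1 - r2)
  }, numeric(1))
  out <- data.frame(trial = seq_along(vif), vif = vif,
                    excluded = is.infinite(vif) | vif > threshold)
  class(out) <- c("trial_qc", "data.frame")
  out
}

#' Fit the single-trial GLM by ordinary least squares
#'
#' Fits `signals = X beta + error` voxel-by-voxel and extracts per-trial
#' amplitude summaries. The default summary is the canonical-regressor beta;
#' `summary_mode = "auc"` instead integrates the fitted per-trial response
#' (canonical + derivative contributions) over the run.
#'
#' Two estimation schemes are offered. `estimation = "lsa"`
#' (least-squares-all, the default) puts every trial's regressors in one
#' model; with 2 basis functions per trial at 2 scans per trial this design
#' saturates the task window and the amplitude estimates become strongly
#' variance-inflated (and scan-level indicator columns can alias exactly
#' with the trial basis, see `method`). `estimation = "lss"`
#' (least-squares-separate) fits one model per trial — that trial's
#' canonical and derivative regressors, the summed regressors of all other
#' trials, and the nuisance block — which trades a little bias for a large
#' variance reduction and is the conventional remedy for dense designs.
#'
#' @param signals Numeric vector (one voxel) or `n_scans x n_voxels` matrix.
#' @param design A `trial_design`.
#' @param summary_mode `"beta"` (default) or `"auc"`.
#' @param method `"qr"` (default) solves the full-rank normal equations and
#'   errors, naming the collinear columns, when the design is rank
#'   deficient. `"pinv"` returns the minimum-norm least-squares solution via
#'   the SVD pseudoinverse; use it for dense canonical-plus-derivative
#'   single-trial designs in which scan-level outlier indicators are exactly
#'   aliased with the trial basis (an inherent degeneracy when the basis
#'   saturates the task scans), and rely on the VIF rule to exclude the
#'   affected trials afterwards.
#' @param estimation `"lsa"` (default, one joint model) or `"lss"` (one
#'   model per trial with the other trials aggregated).
#' @return List of class `trial_glm_fit` with `amplitudes` (trials x voxels),
#'   `betas` (all coefficients x voxels; NULL for `"lss"`), `sigma2`
#'   (residual variance per voxel, df-corrected; averaged over per-trial
#'   models for `"lss"`), `summary_mode`, `estimation`.
#' @export
fit_single_trial_glm <- function(signals, design, summary_mode = c("beta", "auc"),
                                 method = c("qr", "pinv"),
                                 estimation = c("lsa", "lss")) {
  summary_mode <- match.arg(summary_mode)
  method <- match.arg(method)
  estimation <- match.arg(estimation)
  stopifnot(inherits(design, "trial_design"))
  Y <- as.matrix(signals)
  X <- design$X
  if (nrow(Y) != nrow(X)) stop("signals and design have different scan counts")
  if (estimation == "lss") return(.fit_lss(Y, design, summary_mode))
  if (method == "qr") {
    # identically-zero columns (e.g. an absent motion recording) carry no
    # information: fit without them, report beta 0
    cn <- sqrt(colSums(X^2))
    nz <- cn > 0
    Xf <- X[, nz, drop = FALSE]
    # rank check on unit-norm columns so regressor scale cannot mask or fake
    # a deficiency
    qrn <- qr(sweep(Xf, 2, cn[nz], "/"))
    if (qrn$rank < ncol(Xf)) {
      dropped <- colnames(Xf)[qrn$pivot[(qrn$rank + 1):ncol(Xf)]]
      stop("design matrix is rank deficient; collinear columns: ",
           paste(dropped, collapse = ", "))
    }
    betas <- matrix(0, ncol(X), ncol(Y),
                    dimnames = list(colnames(X), colnames(Y)))
    betas[nz, ] <- qr.coef(qr(Xf), Y)
    eff_rank <- ncol(Xf)
  } else {
    sv <- svd(X)
    tol <- max(dim(X)) * .Machine$double.eps * sv$d[1]
    pos <- sv$d > tol
    betas <- sv$v[, pos, drop = FALSE] %*%
      ((t(sv$u[, pos, drop = FALSE]) %*% Y) / sv$d[pos])
    rownames(betas) <- colnames(X)
    eff_rank <- sum(pos)
  }
  resid <- Y - X %*% betas
  df <- nrow(X) - eff_rank
  sigma2 <- colSums(resid^2) / max(df, 1)
  can_idx <- design$blocks$trial_canonical
  if (summary_mode == "beta") {
    amps <- betas[can_idx, , drop = FALSE]
  } else {
    der_idx <- design$blocks$trial_derivative
    amps <- matrix(0, length(can_idx), ncol(Y))
    for (i in seq_along(can_idx)) {
      fitted_i <- outer(X[, can_idx[i]], betas[can_idx[i], ])
      if (length(der_idx))
        fitted_i <- fitted_i + outer(X[, der_idx[i]], betas[der_idx[i], ])
      amps[i, ] <- colSums(fitted_i) * design$TR
    }
  }
  rownames(amps) <- paste0("trial_", seq_along(can_idx))
  structure(list(amplitudes = amps, betas = betas, sigma2 = sigma2,
                 summary_mode = summary_mode, estimation = "lsa"),
            class = "trial_glm_fit")
}

# least-squares-separate: one model per trial, other trials aggregated
.fit_lss <- function(Y, design, summary_mode) {
  X <- design$X
  can <- design$blocks$trial_canonical
  der <- design$blocks$trial_derivative
  use_deriv <- length(der) > 0
  nuis <- c(design$blocks$motion, design$blocks$outlier,
            design$blocks$drift, design$blocks$intercept)
  n_trials <- length(can)
  nv <- ncol(Y)
  amps <- matrix(NA_real_, n_trials, nv)
  sig <- matrix(NA_real_, n_trials, nv)
  can_sum <- rowSums(X[, can, drop = FALSE])
  der_sum <- if (use_deriv) rowSums(X[, der, drop = FALSE]) else NULL
  for (i in seq_len(n_trials)) {
    Xi <- cbind(X[, can[i]],
                if (use_deriv) X[, der[i]],
                can_sum - X[, can[i]],
                if (use_deriv) der_sum - X[, der[i]],
                X[, nuis, drop = FALSE])
    qri <- qr(Xi)
    if (qri$rank < ncol(Xi))
      stop("rank-deficient per-trial model at trial ", i)
    cf <- qr.coef(qri, Y)
    if (summary_mode == "beta") {
      amps[i, ] <- cf[1, ]
    } else {
      fitted_i <- outer(Xi[, 1], cf[1, ])
      if (use_deriv) fitted_i <- fitted_i + outer(Xi[, 2], cf[2, ])
      amps[i, ] <- colSums(fitted_i) * design$TR
    }
    res <- Y - Xi %*% cf
    sig[i, ] <- colSums(res^2) / max(nrow(Y) - ncol(Xi), 1)
  }
  rownames(amps) <- paste0("trial_", seq_len(n_trials))
  structure(list(amplitudes = amps, betas = NULL, sigma2 = colMeans(sig),
                 summary_mode = summary_mode, estimation = "lss"),
            class = "trial_glm_fit")
}

#' PCA-based noise diagnostics
#'
#' Extracts principal components of the scan-by-voxel data matrix and
#' evaluates, for each component time series, how task-related versus
#' nuisance-related it is: the component is regressed on the task design and
#' on the nuisance design, and the component is retained when its
#' task R^2 exceeds `task_r2_min` and the nuisance-to-task R^2 ratio stays
#' below `ratio_max`.
#'
#' @param data `n_scans x n_voxels` matrix.
#' @param task_design Matrix of task regressors (no intercept needed).
#' @param nuisance_design Matrix of nuisance regressors.
#' @param n_components Number of components to diagnose, default 10.
#' @param task_r2_min,ratio_max Retention rule constants (defaults 0.1 and 2).
#' @return Data frame of class `component_qc` with columns `component`,
#'   `task_r2`, `nuisance_r2`, `ratio`, `retain`.
#' @export
pca_noise_check <- function(data, task_design, nuisance_design,
                            n_components = 10, task_r2_min = 0.1,
                            ratio_max = 2) {
  data <- as.matrix(data)
  if (n_components > nrow(data))
    stop("n_components cannot exceed the number of scans")
  if (all(apply(data, 2, stats::sd) == 0))
    stop("data is constant; PCA is degenerate")
  pc <- stats::prcomp(data, center = TRUE, scale. = FALSE)
  k <- min(n_components, ncol(pc$x))
  scores <- pc$x[, seq_len(k), drop = FALSE]
  task_r2 <- apply(scores, 2, .rsq, Z = as.matrix(task_design))
  nuis_r2 <- apply(scores, 2, .rsq, Z = as.matrix(nuisance_design))
  ratio <- nuis_r2 / task_r2
  out <- data.frame(component = seq_len(k), task_r2 = task_r2,
                    nuisance_r2 = nuis_r2, ratio = ratio,
                    retain = task_r2 > task_r2_min & ratio < ratio_max)
  rownames(out) <- NULL
  class(out) <- c("component_qc", "data.frame")
  out
}
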