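test_that("framewise displacement flags injected motion jumps", {
  # constant motion: zero FD everywhere, nothing flagged
  mp <- matrix(0.3, 50, 6)
  mq <- detect_outlier_scans(mp)
  expect_equal(mq$fd, rep(0, 50))
  expect_length(mq$outliers, 0)
  # one 5 mm translation step among near-zero motion: exactly that scan
  mp2 <- matrix(0, 50, 6)
  mp2[20:50, 1] <- 5
  mq2 <- detect_outlier_scans(mp2, threshold_sd = 3)
  expect_identical(mq2$outliers, 20L)
  # hand-computed FD on a 4-scan series with a rotation term
  mp3 <- rbind(c(0, 0, 0, 0, 0, 0),
               c(0.1, 0, 0, 0, 0, 0),
               c(0.1, -0.2, 0, 0.002, 0, 0),
               c(0.1, -0.2, 0.05, 0.002, 0, 0))
  fd3 <- detect_outlier_scans(mp3)$fd
  expect_equal(fd3, c(0, 0.1, 0.2 + 0.002 * 50, 0.05))
  expect_error(detect_outlier_scans(matrix(0, 10, 5)), "6 columns")
})

test_that("design matrix column bookkeeping follows the block structure", {
  cfg <- generator_config(seed = 2)
  tt <- generate_trial_table(cfg, 1)
  for (n_out in c(0L, 2L, 5L)) {
    d <- build_single_trial_design(tt, cfg$n_scans, cfg$TR,
                                   outlier_indices = seq_len(n_out) * 30L)
    expect_equal(ncol(d$X), 2 * 75 + 12 + n_out + 1)
    expect_equal(length(d$blocks$trial_canonical), 75)
    expect_equal(length(d$blocks$motion), 12)
    expect_equal(length(d$blocks$outlier), n_out)
    expect_equal(d$X[, d$blocks$intercept], rep(1, cfg$n_scans))
    if (n_out > 0) {
      oh <- d$X[, d$blocks$outlier, drop = FALSE]
      expect_equal(unname(colSums(oh)), rep(1, n_out))
    }
  }
  # determinism
  d1 <- build_single_trial_design(tt, cfg$n_scans, cfg$TR)
  d2 <- build_single_trial_design(tt, cfg$n_scans, cfg$TR)
  expect_identical(d1, d2)
})

test_that("single-trial regressor equals the direct convolution oracle", {
  TR <- 2.5
  spec <- hrf_spec(sampling_dt = TR / 16)
  h <- canonical_hrf(spec)
  tt <- data.frame(onset = 12.5, duration = 1.25, valence = 1L)
  d <- build_single_trial_design(tt, 40, TR, spec = spec)
  oracle <- conv_oracle(12.5, 1.25, h$hrf, spec$sampling_dt, 40, TR)
  expect_equal(as.numeric(d$X[, d$blocks$trial_canonical]), oracle,
               tolerance = 1e-8)
})

test_that("degenerate trials are rejected", {
  tt_bad <- data.frame(onset = 500, duration = 100)
  expect_error(build_single_trial_design(tt_bad, 225, 2.5), "past the last scan")
  tt_zero <- data.frame(onset = 10, duration = 0)
  expect_error(build_single_trial_design(tt_zero, 225, 2.5), "positive")
})

test_that("trial VIFs detect nuisance collinearity and ignore rescaling", {
  cfg <- generator_config(seed = 6)
  tt <- generate_trial_table(cfg, 1)
  set.seed(1)
  mp <- matrix(rnorm(cfg$n_scans * 6, 0, 0.05), cfg$n_scans, 6)
  d <- build_single_trial_design(tt, cfg$n_scans, cfg$TR, motion_params = mp)
  qc <- trial_vifs(d)
  expect_true(all(qc$vif >= 1, na.rm = TRUE))
  expect_true(all(qc$vif[is.finite(qc$vif)] < 2))
  expect_false(any(qc$excluded))
  # duplicating a trial regressor as a motion column gives infinite VIF
  d_dup <- d
  d_dup$X[, d$blocks$motion[1]] <- d$X[, d$blocks$trial_canonical[3]]
  qc_dup <- trial_vifs(d_dup)
  expect_true(is.infinite(qc_dup$vif[3]))
  expect_true(qc_dup$excluded[3])
  # VIF invariant to rescaling of nuisance columns
  d_scaled <- d
  d_scaled$X[, d$blocks$motion] <- d$X[, d$blocks$motion] * 1000
  expect_equal(trial_vifs(d_scaled)$vif, qc$vif, tolerance = 1e-8)
})

test_that("OLS recovers planted betas exactly on noiseless data", {
  cfg <- generator_config(seed = 13)
  tt <- generate_trial_table(cfg, 1)
  set.seed(3)
  mp <- matrix(rnorm(cfg$n_scans * 6, 0, 0.05), cfg$n_scans, 6)
  d <- build_single_trial_design(tt, cfg$n_scans, cfg$TR, motion_params = mp)
  beta_true <- rnorm(ncol(d$X))
  y <- d$X %*% beta_true
  fit <- fit_single_trial_glm(y, d)
  expect_lt(max(abs(fit$betas - beta_true)) / max(abs(beta_true)), 1e-8)
  expect_equal(as.numeric(fit$amplitudes),
               beta_true[d$blocks$trial_canonical], tolerance = 1e-8)
})

test_that("betas match the brute-force normal-equation oracle on a toy design", {
  tt <- data.frame(onset = c(5, 25, 45), duration = c(1, 1.5, 2))
  set.seed(8)
  mp <- matrix(rnorm(240, 0, 0.1), 40, 6)
  d <- build_single_trial_design(tt, 40, 2.5, motion_params = mp)
  y <- rnorm(40)
  fit <- fit_single_trial_glm(y, d)
  oracle <- solve(crossprod(d$X), crossprod(d$X, y))[, 1]
  expect_equal(as.numeric(fit$betas), as.numeric(oracle), tolerance = 1e-8)
})

test_that("pure-noise signals give near-zero mean amplitudes", {
  tt <- data.frame(onset = seq(5, 195, by = 10), duration = 1)
  d <- build_single_trial_design(tt, 100, 2.5)
  set.seed(21)
  y <- rnorm(100)
  fit <- fit_single_trial_glm(y, d)
  expect_lt(abs(mean(fit$amplitudes)), 1.5 * sd(fit$amplitudes) /
              sqrt(nrow(fit$amplitudes)) * 3)
})

test_that("rank deficiency raises an error naming the collinear columns", {
  # two trials at the identical onset and duration produce duplicate columns
  tt <- data.frame(onset = c(10, 10, 50), duration = c(1, 1, 1))
  d <- build_single_trial_design(tt, 40, 2.5)
  expect_error(fit_single_trial_glm(rnorm(40), d), "rank deficient")
  expect_error(fit_single_trial_glm(rnorm(40), d), "trial_2")
})

test_that("LS-S estimation recovers amplitudes from a saturated design", {
  cfg <- generator_config(seed = 11, n_voxels = 4, mediator_voxels = 1)
  sub <- generate_subject_dataset(cfg, 1, regime = "consistent_pos",
                                  output = "timeseries")
  mq <- detect_outlier_scans(sub$motion_params)
  d <- build_single_trial_design(sub$trial_table, cfg$n_scans, cfg$TR,
                                 motion_params = sub$motion_params,
                                 outlier_indices = mq$outliers,
                                 drift_cutoff = 128)
  fit <- fit_single_trial_glm(sub$signals, d, estimation = "lss")
  expect_gt(cor(fit$amplitudes[, 1], sub$truth$mediator), 0.5)
  # noise voxel amplitudes do not correlate with the latent mediator
  expect_lt(abs(cor(fit$amplitudes[, 3], sub$truth$mediator)), 0.3)
})

test_that("PCA diagnostics separate task-driven from motion-driven data", {
  cfg <- generator_config(seed = 4)
  tt <- generate_trial_table(cfg, 1)
  d <- build_single_trial_design(tt, cfg$n_scans, cfg$TR)
  task <- d$X[, d$blocks$trial_canonical]
  set.seed(10)
  mp <- matrix(rnorm(cfg$n_scans * 6, 0, 0.5), cfg$n_scans, 6)
  nuis <- cbind(mp, mp^2)
  # task-driven data: first component is task-related and retained
  w <- rnorm(ncol(task))
  data_task <- outer(as.numeric(task %*% w), rnorm(12)) +
    matrix(rnorm(cfg$n_scans * 12, 0, 1e-3), cfg$n_scans, 12)
  qc1 <- pca_noise_check(data_task, task, nuis, n_components = 3)
  expect_gt(qc1$task_r2[1], 0.95)
  expect_true(qc1$retain[1])
  # motion-driven data: dominant component fails the retention rule
  data_mot <- outer(as.numeric(nuis %*% rnorm(12)), rnorm(12)) +
    matrix(rnorm(cfg$n_scans * 12, 0, 1e-3), cfg$n_scans, 12)
  qc2 <- pca_noise_check(data_mot, task, nuis, n_components = 3)
  expect_gt(qc2$nuisance_r2[1], 0.95)
  expect_false(qc2$retain[1])
  expect_error(pca_noise_check(matrix(1, 50, 4), task[1:50, ], nuis[1:50, ]),
               "constant")
})
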