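test_that("path coefficients satisfy c = c' + a*b and match the OLS oracle", {
  # closed-form 6-point example against brute-force normal equations
  X <- c(-1, -1, 0, 0, 1, 1)
  M <- c(-2, -1, 0, 1, 1, 3)
  Y <- c(-1, -1, -1, 1, 1, 1)
  fit <- fit_paths(X, M, Y)
  a_or <- ols_oracle(cbind(X), M)[2]
  cy_or <- ols_oracle(cbind(X), Y)[2]
  bm <- ols_oracle(cbind(X, M), Y)
  expect_equal(unname(coef(fit)["a"]), unname(a_or), tolerance = 1e-12)
  expect_equal(unname(coef(fit)["c"]), unname(cy_or), tolerance = 1e-12)
  expect_equal(unname(coef(fit)["c_prime"]), unname(bm[2]), tolerance = 1e-12)
  expect_equal(unname(coef(fit)["b"]), unname(bm[3]), tolerance = 1e-12)
  # identity on random data
  set.seed(14)
  for (i in 1:25) {
    n <- sample(5:60, 1)
    Xi <- sample(c(-1, 0, 1), n, replace = TRUE)
    if (sd(Xi) == 0) Xi[1] <- Xi[1] + 1
    Mi <- rnorm(n); Yi <- sample(c(-1, 1), n, replace = TRUE)
    if (sd(Yi) == 0) Yi[1] <- -Yi[1]
    cf <- coef(fit_paths(Xi, Mi, Yi))
    expect_lt(abs(cf["c"] - cf["c_prime"] - cf["ab"]), 1e-10)
  }
})

test_that("a planted null b-path yields b near zero and c near c'", {
  set.seed(77)
  n <- 5000
  X <- sample(c(-1, 0, 1), n, replace = TRUE)
  M <- 0.8 * X + rnorm(n)
  Y <- ifelse(runif(n) < plogis(0.6 * X), 1, -1)  # Y independent of M given X
  cf <- coef(fit_paths(X, M, Y))
  expect_lt(abs(cf["b"]), 0.03)
  expect_lt(abs(cf["c"] - cf["c_prime"]), 0.03)
})

test_that("degenerate path inputs raise explicit errors", {
  expect_error(fit_paths(rep(1, 10), rnorm(10), rnorm(10)), "constant")
  expect_error(fit_paths(rnorm(10), rep(0, 10), rnorm(10)), "constant")
  expect_error(fit_paths(c(-1, 1), c(0, 1), c(1, 1)), "at least 4")
  X <- c(-1, 0, 1, -1, 0, 1)
  expect_error(fit_paths(X, 2 * X, rnorm(6)), "collinear")
})

test_that("BCa bootstrap handles degenerate and reduction cases", {
  # identical rows: interval collapses onto the point estimate
  const <- matrix(rep(2.5, 20), ncol = 1)
  res <- bca_bootstrap(function(d) mean(d[, 1]), const, n_boot = 200, seed = 1)
  expect_true(res$degenerate)
  expect_equal(res$ci, c(2.5, 2.5))
  # forcing z0 = 0 and accel = 0 recovers the plain percentile interval
  set.seed(3)
  x <- matrix(rexp(30), ncol = 1)
  res2 <- bca_bootstrap(function(d) mean(d[, 1]), x, n_boot = 2000, seed = 7,
                        force_z0 = 0, force_accel = 0)
  perc <- unname(quantile(res2$replicates, c(0.025, 0.975), type = 7))
  expect_equal(res2$ci, perc, tolerance = 1e-10)
})

test_that("BCa interval matches an independent reference implementation", {
  skip_if_not_installed("boot")
  set.seed(12)
  x <- c(0.1, 0.2, 0.3, 0.5, 0.7, 1.1, 1.8, 3.0, 5.5, 9.2)  # skewed sample
  n_boot <- 20000
  ours <- bca_bootstrap(function(d) mean(d[, 1]), matrix(x, ncol = 1),
                        n_boot = n_boot, alpha = 0.05, seed = 101)
  bt <- boot::boot(x, function(d, i) mean(d[i]), R = n_boot)
  ref <- boot::boot.ci(bt, type = "bca", conf = 0.95)$bca[4:5]
  # agreement within Monte-Carlo error of the percentile estimates
  expect_equal(ours$ci[1], ref[1], tolerance = 0.08)
  expect_equal(ours$ci[2], ref[2], tolerance = 0.08)
})

test_that("bootstrap inference is deterministic in the seed", {
  set.seed(5)
  x <- matrix(rnorm(25), ncol = 1)
  r1 <- bca_bootstrap(function(d) mean(d[, 1]), x, n_boot = 500, seed = 11)
  r2 <- bca_bootstrap(function(d) mean(d[, 1]), x, n_boot = 500, seed = 11)
  expect_identical(r1$ci, r2$ci)
  expect_identical(r1$p, r2$p)
  betas <- matrix(rnorm(75 * 3), 75, 3)
  X <- rep(c(-1, 0, 1), 25); Y <- sample(c(-1, 1), 75, replace = TRUE)
  v1 <- voxelwise_mediation(betas, X, Y, n_boot = 300, seed = 9)
  v2 <- voxelwise_mediation(betas, X, Y, n_boot = 300, seed = 9)
  expect_identical(v1$paths, v2$paths)
})

test_that("voxel-wise weighted-moment bootstrap agrees with the generic path", {
  # same resamples, two code paths: closed-form weighted moments vs direct
  # refitting on resampled rows
  set.seed(42)
  n <- 40
  X <- sample(c(-1, 0, 1), n, replace = TRUE)
  M <- 0.5 * X + rnorm(n)
  Y <- ifelse(runif(n) < plogis(0.8 * M), 1, -1)
  vm <- voxelwise_mediation(matrix(M, ncol = 1), X, Y, n_boot = 4000, seed = 33)
  gen <- bca_bootstrap(function(d) coef(fit_paths(d[, 1], d[, 2], d[, 3]))["ab"],
                       cbind(X, M, Y), n_boot = 4000, seed = 33)
  expect_equal(vm$paths$ab[1], unname(gen$estimate), tolerance = 1e-12)
  expect_equal(vm$paths$p_ab[1], gen$p, tolerance = 0.02)
  expect_equal(vm$paths$ab_lo[1], gen$ci[1], tolerance = 0.05)
  expect_equal(vm$paths$ab_hi[1], gen$ci[2], tolerance = 0.05)
})

test_that("planted mediation direction is recovered with the study coding", {
  # valence -1/0/+1, response -1/+1; positive a and b give positive paths
  cfg <- generator_config(seed = 19, n_voxels = 2, mediator_voxels = 1)
  a_hats <- b_hats <- numeric(20)
  for (s in 1:20) {
    sub <- generate_subject_dataset(cfg, s, regime = "consistent_pos",
                                    a_s = 0.8, b_s = 1.2)
    cf <- coef(fit_paths(sub$trial_table$valence, sub$betas[, 1],
                         sub$trial_table$response))
    a_hats[s] <- cf["a"]; b_hats[s] <- cf["b"]
  }
  expect_gt(mean(a_hats > 0), 0.9)
  expect_gt(mean(b_hats > 0), 0.9)
  expect_equal(mean(a_hats), 0.8, tolerance = 0.15)
})

test_that("zero-variance voxels are skipped and flagged", {
  betas <- cbind(rnorm(75), rep(1, 75))
  X <- rep(c(-1, 0, 1), 25); Y <- rep(c(-1, 1), length.out = 75)
  vm <- voxelwise_mediation(betas, X, Y, n_boot = 200, seed = 2)
  expect_false(vm$paths$skipped[1])
  expect_true(vm$paths$skipped[2])
  expect_false(vm$paths$mediator[2])
})
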