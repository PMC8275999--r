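# Synthetic trial-wise datasets with known mediation ground truth.
#
# The generator emulates a self-appraisal trait-adjective judgment run:
# 75 trials (25 per valence level, randomized order) spaced 5 s apart with a
# truncated-exponential onset jitter, an HRF-convolved single-trial response
# whose amplitude depends on valence through a subject-specific a path, and a
# binary endorse/reject choice generated from the mediator and valence
# through a subject-specific b path and a direct effect.

# derive a per-subject RNG seed from the master seed (kept < 2^31)
.subject_seed <- function(seed, subject_index, salt = 0L) {
  (as.integer(seed) %% 1000003L) * 1009L + subject_index * 7L + salt
}

#' Configuration for the synthetic cohort generator
#'
#' Defaults reproduce the task geometry of the emulated study: 25 trials per
#' valence level, 5 s trial spacing, onset jitter between 0.1 and 2.35 s,
#' TR = 2.5 s. Subject-level mediation regimes control how the a (valence to
#' mediator) and b (mediator to choice) paths are drawn:
#' `consistent_pos`/`consistent_neg` draw both paths with same-sign means,
#' `covariance_driven` draws them jointly with zero means and correlation
#' `cov_corr`, and `null` sets both to zero. The default regime mix matches
#' the 17/14/16-of-47 subgroup split observed in the emulated cohort.
#'
#' @param n_subjects Cohort size (default 47).
#' @param n_per_valence Trials per valence level (default 25).
#' @param trial_spacing Seconds between trial onsets (default 5).
#' @param jitter_range Two-element range (s) of the onset jitter,
#'   default `c(0.1, 2.35)`; sampled from a truncated exponential
#'   (rate 1 / s) so short jitters are more common.
#' @param TR Repetition time (s), default 2.5.
#' @param n_scans Scans per run (default 225: the 75 x 5 s task plus
#'   pre/post padding, leaving the single-trial design overdetermined).
#' @param n_voxels Voxels simulated per subject (default 20).
#' @param mediator_voxels Indices of the contiguous voxel block carrying the
#'   mediation signal (default: the first `min(5, n_voxels)` voxels);
#'   remaining voxels are pure noise.
#' @param regime_fractions Named proportions over
#'   `consistent_pos`, `consistent_neg`, `covariance_driven`, `null`;
#'   must sum to 1.
#' @param a_mean,a_sd Mediator-path effect size (signal units per valence
#'   unit) for consistent regimes.
#' @param b_mean,b_sd Response-path effect size (log-odds per signal unit).
#' @param cov_corr Correlation of (a, b) in the covariance-driven regime
#'   (default 0.7, zero means, SDs `a_mean` and `b_mean`).
#' @param direct_effect Direct valence-to-choice effect c' (log-odds per
#'   valence unit), default 0.5.
#' @param noise_sd SD of the latent mediator noise (signal units).
#' @param scan_noise_sd SD of the white scanner noise added to voxel time
#'   series (signal units, on the scale of a unit-peak trial response);
#'   default 0.2, at which first-level amplitude uncertainty is comparable
#'   to the latent trial-to-trial variability.
#' @param response_intercept Intercept of the choice model (log-odds).
#' @param drift_amplitude Amplitude of the low-order cosine drift added to
#'   voxel time series (signal units).
#' @param motion_sd SD (mm) of the random-walk motion increments.
#' @param outlier_rate Proportion of scans injected as motion/signal
#'   outliers.
#' @param rt_meanlog,rt_sdlog Log-normal reaction-time parameters
#'   (median 1 s, sigma 0.3).
#' @param seed Master integer seed; identical configs and seeds give
#'   identical cohorts.
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(n_subjects = 47,
                             n_per_valence = 25,
                             trial_spacing = 5,
                             jitter_range = c(0.1, 2.35),
                             TR = 2.5,
                             n_scans = 225,
                             n_voxels = 20,
                             mediator_voxels = NULL,
                             regime_fractions = c(consistent_pos = 17 / 47,
                                                  consistent_neg = 14 / 47,
                                                  covariance_driven = 0,
                                                  null = 16 / 47),
                             a_mean = 0.8, a_sd = 0.25,
                             b_mean = 1.2, b_sd = 0.4,
                             cov_corr = 0.7,
                             direct_effect = 0.5,
                             noise_sd = 1,
                             scan_noise_sd = 0.2,
                             response_intercept = 0,
                             drift_amplitude = 0.5,
                             motion_sd = 0.02,
                             outlier_rate = 0.02,
                             rt_meanlog = 0, rt_sdlog = 0.3,
                             seed = 1L) {
  regimes <- c("consistent_pos", "consistent_neg", "covariance_driven", "null")
  rf <- rep(0, 4); names(rf) <- regimes
  if (is.null(names(regime_fractions)) ||
      !all(names(regime_fractions) %in% regimes))
    stop("regime_fractions must be named with a subset of: ",
         paste(regimes, collapse = ", "))
  rf[names(regime_fractions)] <- regime_fractions
  if (abs(sum(rf) - 1) > 1e-8) stop("regime_fractions must sum to 1")
  if (n_subjects < 1 || n_per_valence < 1) stop("counts must be positive")
  stopifnot(length(jitter_range) == 2, jitter_range[1] >= 0,
            jitter_range[2] >= jitter_range[1],
            a_sd >= 0, b_sd >= 0, noise_sd >= 0, motion_sd >= 0,
            outlier_rate >= 0, outlier_rate < 1,
            trial_spacing > 0, TR > 0)
  n_trials <- 3 * n_per_valence
  if (n_scans * TR < n_trials * trial_spacing + 20)
    stop("n_scans too small to contain all trials plus the HRF tail")
  if (is.null(mediator_voxels)) mediator_voxels <- seq_len(min(5, n_voxels))
  if (length(mediator_voxels) &&
      (min(mediator_voxels) < 1 || max(mediator_voxels) > n_voxels))
    stop("mediator_voxels must be indices within 1:n_voxels")
  structure(list(n_subjects = as.integer(n_subjects),
                 n_per_valence = as.integer(n_per_valence),
                 trial_spacing = trial_spacing, jitter_range = jitter_range,
                 TR = TR, n_scans = as.integer(n_scans),
                 n_voxels = as.integer(n_voxels),
                 mediator_voxels = as.integer(mediator_voxels),
                 regime_fractions = rf,
                 a_mean = a_mean, a_sd = a_sd, b_mean = b_mean, b_sd = b_sd,
                 cov_corr = cov_corr, direct_effect = direct_effect,
                 noise_sd = noise_sd, scan_noise_sd = scan_noise_sd,
                 response_intercept = response_intercept,
                 drift_amplitude = drift_amplitude, motion_sd = motion_sd,
                 outlier_rate = outlier_rate,
                 rt_meanlog = rt_meanlog, rt_sdlog = rt_sdlog,
                 seed = as.integer(seed)),
            class = "generator_config")
}

# truncated exponential sample on [lo, hi], rate 1
.rjitter <- function(n, lo, hi) {
  if (hi <= lo) return(rep(lo, n))
  u <- stats::runif(n)
  lo + (-log(1 - u * (1 - exp(-(hi - lo)))))
}

#' Generate one subject's trial table
#'
#' Produces a balanced, randomized trial sequence: `3 * n_per_valence` rows
#' with valence codes -1/0/+1 (25 each by default), onsets at
#' `trial_spacing * (i - 1)` plus a per-trial jitter inside `jitter_range`,
#' and log-normal reaction times (truncated to the trial window) that define
#' the boxcar durations. Responses are NA until filled by
#' [generate_subject_dataset()].
#'
#' @param config A [generator_config()].
#' @param subject_index Subject number (1-based); determines the subject's
#'   RNG stream.
#' @return Data frame of class `trial_table` with columns `onset`,
#'   `duration`, `trial_type`, `valence`, `response`, `response_time`.
#' @export
generate_trial_table <- function(config, subject_index = 1L) {
  stopifnot(inherits(config, "generator_config"), subject_index >= 1)
  set.seed(.subject_seed(config$seed, subject_index, salt = 1L))
  n <- 3L * config$n_per_valence
  valence <- sample(rep(c(-1L, 0L, 1L), config$n_per_valence))
  jit <- .rjitter(n, config$jitter_range[1], config$jitter_range[2])
  onset <- (seq_len(n) - 1) * config$trial_spacing + jit
  rt <- stats::rlnorm(n, config$rt_meanlog, config$rt_sdlog)
  rt <- pmin(rt, config$trial_spacing - 0.05)
  out <- data.frame(onset = onset,
                    duration = rt,
                    trial_type = c("negative", "neutral", "positive")[valence + 2L],
                    valence = valence,
                    response = NA_integer_,
                    response_time = rt)
  class(out) <- c("trial_table", "data.frame")
  out
}

# draw (a_s, b_s) for one subject given its regime
.draw_paths <- function(config, regime) {
  switch(regime,
    consistent_pos = c(a = stats::rnorm(1, config$a_mean, config$a_sd),
                       b = stats::rnorm(1, config$b_mean, config$b_sd)),
    consistent_neg = c(a = stats::rnorm(1, -config$a_mean, config$a_sd),
                       b = stats::rnorm(1, -config$b_mean, config$b_sd)),
    covariance_driven = {
      z1 <- stats::rnorm(1); z2 <- stats::rnorm(1)
      r <- config$cov_corr
      c(a = config$a_mean * z1,
        b = config$b_mean * (r * z1 + sqrt(1 - r^2) * z2))
    },
    null = c(a = 0, b = 0),
    stop("unknown regime: ", regime))
}

#' Generate one subject's dataset with ground truth
#'
#' The latent mediator amplitude of trial i is `M_i = a_s * X_i + e_i` with
#' `e_i ~ N(0, noise_sd)`. The binary choice is drawn with
#' `P(Y = +1) = plogis(response_intercept + b_s * M_i + direct_effect * X_i)`.
#' In `"timeseries"` mode, mediator voxels carry the single-trial canonical
#' design weighted by the latent amplitudes plus cosine drift and white
#' noise; other voxels are drift plus noise. Random-walk motion parameters
#' are produced, and a proportion `outlier_rate` of scans receive large
#' motion jumps and signal spikes. In `"betas"` mode the trial-by-voxel beta
#' matrix is emitted directly (mediator voxels = latent amplitude plus small
#' measurement noise), bypassing time-series synthesis.
#'
#' @param config A [generator_config()].
#' @param subject_index Subject number (determines the RNG stream).
#' @param regime Mediation regime; if NULL, drawn from
#'   `config$regime_fractions`.
#' @param a_s,b_s Optional fixed path coefficients (override the regime
#'   draw).
#' @param output `"betas"` (default; fast) or `"timeseries"`.
#' @return List of class `subject_data`: `trial_table` (responses filled),
#'   `betas` (trials x voxels) or `signals` (scans x voxels) plus
#'   `motion_params` and `outlier_scans`, and `truth` (list with `a_s`,
#'   `b_s`, `regime`, `mediator` = latent per-trial amplitudes).
#' @export
generate_subject_dataset <- function(config, subject_index = 1L,
                                     regime = NULL, a_s = NULL, b_s = NULL,
                                     output = c("betas", "timeseries")) {
  output <- match.arg(output)
  stopifnot(inherits(config, "generator_config"))
  trials <- generate_trial_table(config, subject_index)
  n <- nrow(trials)
  set.seed(.subject_seed(config$seed, subject_index, salt = 2L))
  if (is.null(regime))
    regime <- sample(names(config$regime_fractions), 1,
                     prob = config$regime_fractions)
  ab <- .draw_paths(config, regime)
  if (is.null(a_s)) a_s <- unname(ab["a"])
  if (is.null(b_s)) b_s <- unname(ab["b"])

  X <- trials$valence
  M <- a_s * X + stats::rnorm(n, 0, config$noise_sd)
  eta <- config$response_intercept + b_s * M + config$direct_effect * X
  Y <- ifelse(stats::runif(n) < stats::plogis(eta), 1L, -1L)
  trials$response <- Y

  out <- list(trial_table = trials,
              truth = list(a_s = a_s, b_s = b_s, regime = regime,
                           mediator = M))
  nv <- config$n_voxels
  med <- config$mediator_voxels
  if (output == "betas") {
    B <- matrix(stats::rnorm(n * nv, 0, config$noise_sd), n, nv)
    for (v in med) B[, v] <- M + stats::rnorm(n, 0, 0.2 * config$noise_sd)
    colnames(B) <- paste0("v", seq_len(nv))
    out$betas <- B
  } else {
    ns <- config$n_scans
    motion <- apply(matrix(stats::rnorm(ns * 6, 0, config$motion_sd), ns, 6),
                    2, cumsum)
    n_out <- stats::rbinom(1, ns, config$outlier_rate)
    outlier_scans <- sort(sample(seq_len(ns), n_out))
    if (n_out > 0)
      motion[outlier_scans, 1:3] <- motion[outlier_scans, 1:3] +
        matrix(stats::rnorm(n_out * 3, 0, 2), n_out, 3)
    design <- build_single_trial_design(trials, ns, config$TR,
                                        spec = hrf_spec())
    canon <- design$X[, design$blocks$trial_canonical, drop = FALSE]
    drift_t <- seq_len(ns) / ns
    signals <- matrix(stats::rnorm(ns * nv, 0, config$scan_noise_sd), ns, nv)
    for (v in seq_len(nv)) {
      phase <- stats::runif(1, 0, 2 * pi)
      dr <- config$drift_amplitude * cos(2 * pi * drift_t + phase)
      signals[, v] <- signals[, v] + dr
      if (v %in% med) signals[, v] <- signals[, v] + as.numeric(canon %*% M)
    }
    if (n_out > 0)
      signals[outlier_scans, ] <- signals[outlier_scans, ] +
        matrix(stats::rnorm(n_out * nv, 0, 10 * config$scan_noise_sd), n_out, nv)
    colnames(signals) <- paste0("v", seq_len(nv))
    out$signals <- signals
    out$motion_params <- motion
    out$outlier_scans <- outlier_scans
  }
  class(out) <- "subject_data"
  out
}

#' Generate a cohort with regime assignment
#'
#' Subjects are assigned to mediation regimes with counts proportional to
#' `regime_fractions` (largest-remainder rounding, order shuffled by the
#' master seed), then each subject's dataset is generated on its own RNG
#' stream.
#'
#' @param config A [generator_config()].
#' @param output Passed to [generate_subject_dataset()].
#' @return List of class `cohort`: `subjects` (list of `subject_data`) and
#'   `truth` (data.frame with per-subject `a_s`, `b_s`, `regime`).
#' @export
generate_cohort <- function(config, output = c("betas", "timeseries")) {
  output <- match.arg(output)
  stopifnot(inherits(config, "generator_config"))
  ns <- config$n_subjects
  rf <- config$regime_fractions
  raw <- rf * ns
  counts <- floor(raw)
  rem <- ns - sum(counts)
  if (rem > 0) {
    ord <- order(raw - counts, decreasing = TRUE)
    counts[ord[seq_len(rem)]] <- counts[ord[seq_len(rem)]] + 1
  }
  set.seed(.subject_seed(config$seed, 0L, salt = 3L))
  regimes <- sample(rep(names(rf), counts))
  subjects <- lapply(seq_len(ns), function(s)
    generate_subject_dataset(config, s, regime = regimes[s], output = output))
  truth <- data.frame(subject = seq_len(ns),
                      a_s = vapply(subjects, function(s) s$truth$a_s, 0),
                      b_s = vapply(subjects, function(s) s$truth$b_s, 0),
                      regime = regimes)
  structure(list(subjects = subjects, truth = truth, config = config),
            class = "cohort")
}

#' Generate a synthetic effective-connectivity parameter table
#'
#' Fixture generator for the node-strength summaries: a full directed edge
#' set over `nodes` including self-connections, with parameter estimates
#' drawn from `N(pe_mean, pe_sd)` and posterior probabilities uniform on
#' [0, 1]. Nodes in `sink_nodes` receive but do not send edges (and have no
#' self-connection row), mirroring output-only regions.
#'
#' @param nodes Character vector of node names.
#' @param sink_nodes Subset of `nodes` with no outgoing edges.
#' @param pe_mean,pe_sd Normal parameters for the PEs.
#' @param contrast Contrast label stored on every row.
#' @param seed Integer seed.
#' @return A `connectivity_table` data frame (see
#'   [parse_connectivity_table()]).
#' @export
generate_peb_table <- function(nodes, sink_nodes = character(0),
                               pe_mean = 0, pe_sd = 0.3,
                               contrast = "synthetic", seed = 1L) {
  if (!length(nodes)) stop("node list must be non-empty")
  stopifnot(all(sink_nodes %in% nodes))
  set.seed(as.integer(seed))
  src <- setdiff(nodes, sink_nodes)
  grid <- expand.grid(source = src, target = nodes,
                      stringsAsFactors = FALSE)
  grid <- grid[order(match(grid$source, nodes), match(grid$target, nodes)), ]
  grid$pe <- stats::rnorm(nrow(grid), pe_mean, pe_sd)
  grid$pp <- stats::runif(nrow(grid))
  grid$contrast <- contrast
  rownames(grid) <- NULL
  parse_connectivity_table(grid, nodes = nodes, canonicalize = FALSE)
}
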