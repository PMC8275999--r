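---
title: "Multilevel mediation effect parametric mapping: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multilevel mediation effect parametric mapping: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mepm)
```

## The scientific problem

In a trait-adjective judgment experiment, a participant sees a stream of
adjectives of varying emotional valence and decides, trial by trial, whether
each trait applies to themselves. The strength of the association between
stimulus valence and the endorse/reject choice is a behavioral index of
positive self-bias. The question `mepm` addresses is *how the brain mediates
that association*: which regions' trial-wise activity transmits the effect of
valence X on choice Y.

The core statistical object is the Baron–Kenny path model fitted across
trials within a subject, independently at every voxel (mediation effect
parametric mapping, MEPM):

* path **a**: OLS slope of the mediator M (trial-wise voxel amplitude) on the
  valence code X ∈ {−1, 0, +1};
* paths **b**, **c′**: OLS of the choice code Y ∈ {−1, +1} on X and M jointly —
  b is the mediator effect controlling for X, c′ the direct effect;
* path **c**: total effect, OLS of Y on X;
* the indirect (mediated) effect is the product **a·b**, and on any common
  sample the identity **c = c′ + a·b** holds exactly.

Y is binary but is modelled linearly: that is the MEPM convention, which keeps
the product decomposition exact. The linear b is then a monotone, attenuated
transform of the underlying logistic slope — signs and ordering are preserved,
absolute magnitudes are not interpreted.

A voxel counts as a first-level mediator when a, b, and a·b are all
significant and the direct effect strictly decreases (|c′| < |c|; ties do not
count, since a strict decrease is the defining requirement).

## Bootstrap inference

Significance of the within-subject paths uses the bias-corrected accelerated
(BCa) bootstrap over trials. For each replicate, trials are resampled with
replacement and all paths are recomputed; the bias correction z₀ comes from
the fraction of replicates below the point estimate, the acceleration from
the jackknife skewness, and the two-sided p-value is the smallest α at which
the BCa interval excludes zero, located on a grid of 400 α levels (so
p-values have resolution 1/400 = 0.0025 — adequate for thresholds down to
0.001-level maps at the default 10,000 replicates).

Two implementation choices matter:

* **Shared resamples across voxels.** `voxelwise_mediation()` draws one set
  of trial resamples per subject and applies it to every voxel, rather than
  giving each voxel its own stream. This is how whole-map bootstrapping is
  conventionally done (the resampling unit is the trial, not the voxel), it
  makes maps coherent across voxels, and it allows the replicate statistics
  to be computed through closed-form weighted moments: each resample is a
  weight vector of counts, and all five paths have closed forms in the
  weighted first and second moments of (X, M, Y). A whole 200-voxel map at
  500 replicates bootstraps in well under a second this way. Results remain
  deterministic in the seed.
* **Degenerate statistics.** If every replicate equals the point estimate
  (e.g. all subjects' effects exactly zero at the second level), the interval
  collapses to the point; p is reported as 1 when the point is 0 and as NA
  (undefined) otherwise.

The same machinery runs at the second level, resampling *subjects* for the
group mean of a, b, and a·b.

## Consistency versus covariance at the group level

The group-average indirect effect decomposes exactly as

mean(a·b) = mean(a)·mean(b) + cov(a, b)

with the population covariance (divisor n). A group effect can therefore be
**consistent** — same-sign paths in essentially all subjects, detected by
one-sample t-tests of a and b — or **covariance-driven** — a and b centred
near zero but correlated across subjects, detected by the Pearson correlation
r(a, b). The latter pattern means different individuals use the same region
in opposite directions: some respond to positive items with activation that
predicts endorsement, others to negative items with activation that predicts
rejection.

Subjects are subgrouped by the signs of their path estimates: POS (both
strictly positive), NEG (both strictly negative), NONE otherwise; exact zeros
land in NONE because the defining inequalities are strict. No per-subject
significance is required for the labels — they describe direction, not
evidence.

## Map thresholding

Three standard pieces of multiple-comparison control are provided:
Benjamini–Hochberg FDR (`fdr_bh`, step-up at q = 0.05 by default, returning
the adaptive threshold), a three-map conjunction (a voxel passes when the a,
b, and a·b maps are all below the conjunction threshold, default p < 0.002),
and Monte-Carlo cluster-extent calibration (`monte_carlo_cluster_threshold`):
white Gaussian volumes are smoothed to the requested FWHM (smooth-then-
threshold, with variance renormalised inside the mask after smoothing),
thresholded two-tailed on |z| at the primary p (two-tailed because mediation
effects are signed), and the extent k is the ceiling of the 1 − α quantile of
the maximal cluster sizes. Connectivity defaults to the 26-neighbour
convention; component labelling uses vectorised min-label propagation and is
independent of voxel visiting order.

## The synthetic-data generator

No subject-level recordings are distributed with the package, so every
statistical claim is exercised on synthetic cohorts with known ground truth.
The generator reproduces the task geometry: 75 trials (25 per valence,
randomised order), 5 s spacing with a truncated-exponential onset jitter on
[0.1 s, 2.35 s], TR = 2.5 s, 225 scans. Reaction times are log-normal
(median 1 s, σ = 0.3), truncated to the trial window, and double as boxcar
durations. Per subject, the latent mediator amplitude is M = a·X + ε with
ε ~ N(0, noise_sd), and the choice is drawn from
P(Y = +1) = logistic(intercept + b·M + c′·X), with a direct effect c′
defaulting to 0.5 log-odds per valence unit so total and indirect effects
are distinguishable.

Between-subject regimes fix the mediation structure: `consistent_pos` /
`consistent_neg` draw (a, b) with same-sign means (defaults 0.8 signal units
per valence unit and 1.2 log-odds per signal unit, SDs 0.25 and 0.4);
`covariance_driven` draws them bivariate normal with zero means, SDs equal to
the consistent-regime means, and correlation 0.7 — calibrated so that a
31-subject cohort shows the covariance signature (quiet t-tests, significant
positive r) in the large majority of replicates; `null` sets both exactly to
zero. The default regime mix (≈ 0.36 / 0.30 / 0.34 consistent-positive /
consistent-negative / null over 47 subjects) mirrors the subgroup split such
studies report.

Two output modes exist. `"betas"` emits the trial-by-voxel amplitude matrix
directly (mediator voxels carry M plus small measurement noise, the rest pure
noise) — this is the mode used for all quantitative power and calibration
experiments, and corresponds to the "precomputed beta matrix" input form.
`"timeseries"` additionally synthesises voxel time series (single-trial
canonical design × amplitudes, plus cosine drift and white scanner noise at
`scan_noise_sd`, default 0.2 on the unit-peak response scale), random-walk
motion parameters, and injected outlier scans, to exercise the GLM and QC
machinery end to end.

What the generator does **not** emulate: spatial autocorrelation of real
BOLD noise (voxels are independent), physiological noise structure,
between-region connectivity dynamics, and any text/semantic properties of
the stimuli. Passing tests therefore certify the statistical machinery under
idealised noise, not performance on real scanner data.

One calibration point deserves a note. The published behavioral summaries of
this task family include an aggregate self-bias score *below* the
chance level of 1/3 alongside a clearly positive mean input–output
correlation. For a balanced forced-choice design these are mutually
exclusive: writing p₊ for the endorsement rate of positive items and p₋ for
that of negative items, the score is (p₊ + (1 − p₋))/3 > 1/3 exactly when
p₊ > p₋, which is also exactly when the valence–response correlation is
positive. The generator therefore targets the positive-bias pattern (mean
Fisher-z IOC around 0.35–0.40, score around 0.45–0.50); the score–IOC
correlation across a default cohort comes out near 0.99 either way.

## Single-trial GLM: basis, quality control, and a design degeneracy

Each trial is modelled by a boxcar from stimulus onset to the button press,
convolved at microtime resolution (16 bins per TR, sampled at the mid-TR
reference) with the canonical double-gamma HRF (peak delay 6 s, undershoot
delay 16 s, unit dispersions, peak:undershoot 6, 32 s support — all
overridable) and its temporal derivative. The kernel is normalised to unit
peak and convolution is a Riemann sum, so regressor height is invariant to
the oversampling factor and betas live on the signal scale of the data. The
nuisance block holds the 6 motion parameters and their squares, one-hot
indicators for outlier scans, optional discrete-cosine drift regressors
(128 s cutoff) and an intercept.

Quality control follows three rules. Scans whose framewise displacement
(Power-style: sum of absolute backward differences, rotations mapped to arc
length on a 50 mm sphere) exceeds the series mean + 3 SD are flagged as
outliers. Trials whose canonical regressor has a variance inflation factor
above 2 against the nuisance block are excluded (VIF = 1/(1 − R²); the
derivative column is not assessed because only the canonical beta feeds the
mediation). And PCA component diagnostics retain a component when its task
R² exceeds 0.1 and the nuisance-to-task R² ratio stays below 2.

Implementing this surfaced a genuine degeneracy of the dense design: with
two basis functions per trial and two scans per trial (TR 2.5 s, 5 s
spacing), the trial basis *saturates* the task window. Numerically, one-hot
outlier columns inside the task window become exactly linearly dependent on
the trial regressors (smallest singular value at machine zero — a property
of this TR/spacing combination, not of the oversampling), and even the
full-rank all-trials model carries per-trial variance inflation factors in
the hundreds against *other trials'* regressors. Consequences in `mepm`:

* `fit_single_trial_glm()` defaults to strict OLS (`method = "qr"`) and
  errors, naming the collinear columns, on any exact deficiency;
  `method = "pinv"` provides the SVD minimum-norm solution that toolbox
  implementations silently fall back on.
* `estimation = "lss"` fits the least-squares-separate model — one model per
  trial, with the remaining trials' regressors summed into two aggregate
  columns — which is the standard remedy for dense event designs and
  recovers latent amplitudes at r ≈ 0.8 under the generator's default noise,
  where the joint model recovers essentially nothing.
* All quantitative mediation experiments operate on beta matrices, where the
  question does not arise.

## Behavioral scoring and subgroup prediction

The self-bias score is the proportion of *all* trials on which a positive
item was endorsed or a negative one rejected; neutral trials stay in the
denominator, bounding the score at 50/75 = 2/3 for the balanced design. The
input–output correlation (IOC) is the Fisher-z-transformed Pearson
correlation of trial-wise valence with the signed response.

Subgroup membership (e.g. POS vs everyone else) is predicted from
psychometric features by binary logistic regression. The selection method is
forward stepwise with likelihood-ratio entry at p < 0.05 — chosen because the
reported outcome shape (one or two surviving predictors from ~20 candidates
plus a percent-correctly-classified at the 0.5 cut) is what stepwise
selection produces; full-model and fixed-predictor modes are provided for
sensitivity analysis. Odds ratios are exp(B) by construction. Complete
separation is detected (divergent coefficients or saturated fitted
probabilities) and reported as non-converged rather than silently returned.

## Connectivity summaries

Group-level effective-connectivity results arrive as a directed edge list
with a parameter estimate (PE; Hz-scaled modulation for between-region edges,
log-scaled for self-connections) and a posterior probability (PP) per edge,
per contrast. `node_strengths()` computes signed directed strengths: the
out-strength of a node is the sum of its outgoing between-region PEs, the
in-strength the sum of incoming ones. Self-connections are excluded from
both sums and *all* edges enter regardless of PP — both conventions are
validated by the bundled seven-node self-appraisal table, whose printed
strength values recompute exactly under them (and only under them). Because
every between-region edge contributes once to an out-sum and once to an
in-sum, total out-strength equals total in-strength on any table — a useful
conservation check. PP filtering (presets 0.75 "positive evidence", 0.95
"strong evidence") is for reporting which edges carry evidence and never
changes strengths. One bundled value is knowingly discrepant: the group-mean
rTPJ out-strength sums to 1.044 from the printed (rounded) PEs while the
published figure is 1.054, evidently computed on unrounded estimates; the
package reports what the table supports.

## Numerical choices and test scales

* Bootstrap quantiles use R's default type-7 interpolation; the reference
  BCa implementation in `boot` interpolates on the normal-quantile scale, so
  cross-checks agree to Monte-Carlo error, not exactly.
* The z₀ proportion is clamped to [1/(2B), 1 − 1/(2B)] to keep the normal
  quantile finite when all replicates fall on one side.
* Zero-variance voxels are skipped (flagged, not errored) in map fitting;
  zero-variance path vectors make the consistency t-test degenerate
  (t = ±Inf, p = NA, flagged).
* Identically-zero design columns (e.g. absent motion) are dropped from the
  OLS fit and reported with beta 0; genuine collinearity among non-zero
  columns is an error.
* Test and calibration scales are chosen to keep the full suite around a
  minute: null calibration at 50 subjects × 200 voxels × 500 bootstrap
  replicates, power checks at 50 subjects × 1,000 replicates, cohort
  signature checks at 50 replicate cohorts of 31 subjects, Monte-Carlo
  extent calibration at 200 iterations on 12³ volumes. Production analyses
  should use the 10,000-replicate default.

## Known limitations

* Voxels are treated independently at the first level; no spatial model
  beyond cluster-extent control is implied.
* The linear-Y path model is the field convention, not a likelihood model
  for binary choices; a logistic b-path variant is deliberately out of the
  default path to preserve the exact product decomposition.
* The BCa p-value inherits the 1/400 grid resolution; p-values below 0.0025
  are reported as 0.0025.
* The generator's independence assumptions (white noise, independent voxels)
  make its power estimates optimistic relative to real data.
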