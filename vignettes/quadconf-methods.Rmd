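---
title: "Models and methods behind quadconf"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind quadconf}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(quadconf)
```

`quadconf` implements, end to end, the generative model and analysis chain of
a three-task perceptual confidence experiment: an orientation discrimination
task with equal-variance evidence, a yes/no detection task, and a
tilt-recognition task (vertical vs. tilted) engineered so that one response
class has higher evidence variance, mimicking detection. This vignette
documents the models, the tunable parameters and their defaults, the
numerical conventions, and what the synthetic data do and do not emulate.

## The evidence model

Each trial yields a scalar evidence sample from one of two Gaussians,
`x ~ N(mu_low, sigma_low)` or `x ~ N(mu_high, sigma_high)`, where "high"
denotes the higher-variance response class (signal present; tilted). Eleven
strictly increasing criteria partition the axis into 12 bins: response "low"
with confidence 6..1, then response "high" with confidence 1..6; the 6th
criterion is the decision criterion. Default criteria are quantiles of the
stimulus mixture at probabilities k/12, which populates all 12 bins in
expectation and attaches confidence symmetrically around the decision bound.

Key identities the estimators rely on:

* the log-likelihood ratio is linear in `x` iff `sigma_low = sigma_high`,
  quadratic otherwise (and even in `x` when the means coincide);
* the type-1 zROC is a line with slope `sigma_low / sigma_high` for Gaussian
  classes, so the slope estimates the sd ratio;
* an ideal observer responding by posterior comparison responds "low" more
  often than "high" under equal priors whenever `sigma_high > sigma_low`
  (`predicted_low_response_rate()` computes this exactly from the quadratic
  LLR roots; a Monte-Carlo oracle cross-checks it in the tests).

`zroc_slope()` builds cumulative rating proportions over the 11 criteria,
applies the log-linear zero-cell correction (0.5 added to every cumulative
cell, 1 to every total), z-transforms, and returns the geometric mean
of the two regression-direction slopes, which equals `sd(z_hit) / sd(z_fa)`.
Group summaries operate on log slopes, so a mean of log-slopes is a geometric
mean across observers as well — "geometric mean" is implemented across both
regression directions and subjects.

Default observers (`default_observers()`) fix the sd ratios at 1 (discrimination),
0.74 (detection) and 0.55 (tilt recognition), with mean separations chosen so
decisions at the default criteria give 76%, 78% and 77% accuracy — the regime
the package's behavioural layer emulates. Note that with mixture-quantile
criteria the median criterion balances the two responses, so the simulated
observers do not show the ideal observer's "low"-response bias; that bias is
available analytically via `predicted_low_response_rate()`.

## Synthetic sessions and stimuli

`simulate_session()` produces 5–6 runs, each holding one 26-trial block per
task in random order. Timing: uniform inter-trial jitter 0.5–4 s (the
protocol states jitter without the law; uniform is assumed), 0.5 s fixation,
0.5 s stimulus, 1 s decision window, 2.5 s rating window, 4 s instruction
screens; onsets are relative to a nominal 600 s run. Lapses are independent
Bernoulli events per trial (default rate 0.03, a typical scanner miss rate;
missed trials carry no response or confidence). Difficulty scales the class
mean separation only, leaving the variance structure intact: block accuracy
at or below 52.5% divides the difficulty parameter by 0.95, at or above 85%
multiplies it by 0.95 (the between-block rule); an optional
pre-session calibration phase applies the within-block rule (adjust every 10
trials when accuracy leaves the 60–80% band), reusing the same 0.95 step
factor for both scopes.

Stimuli are 10-frame dynamic gratings in noise: each frame starts as 142x142
uniform [0,1] luminances; frame i's pixels are replaced by a 24-pixel-period
sinusoidal grating with probability `p_i = v * exp(-|i - 5|/2)` (zero
throughout for target-absent trials). `seed_from_protocol()` reproduces the
pre-RNG seeding scheme: SHA256 over the protocol bytes, first 8 digest bytes
big-endian, reduced modulo `2^31 - 1` because R seeds are 32-bit.

## Exclusion rules

Blocks are flagged when >20% of trials are missed (evaluated on the full
26), accuracy <60%, one response covers >80% of usable trials, or one
confidence level covers >90% of a response's trials; the last rule is only
assessed for responses with at least 5 trials (a minimum-trials guard,
added to avoid flagging two-trial
responses). The first trial of every block is dropped from all analyses (25
usable trials); subjects need 3 included blocks per task.

## Confidence GLMs

`build_qc_dm()` codes, per response, a 4 s boxcar (stimulus onset through the
rating phase), a linear modulator (confidence mean-centred *per response over
included trials* — per-response centring matches
the response-specific modulators) and a quadratic modulator (squared centred
confidence, mean-centred, then serially orthogonalized against the linear
modulator — the serial main-linear-quadratic convention). Orthogonalization
happens at the modulator-value level; because trial boxcars do not overlap,
the pre-convolution columns are then orthogonal too. Nuisance regressors:
missed / first / excluded-block trials, instruction screens, three
button-press stick regressors, run constants, and any user-supplied matrix
(motion, physiological). Event regressors are convolved with the canonical
double-gamma HRF (gamma shapes 6 and 16, rate 1, undershoot ratio 6, 32 s
support, peak-normalised) on a 0.1 s grid, run by run so nothing bleeds
across run boundaries, then sampled at the TR (default 2 s).

The categorical design (`build_categorical_dm()`) has one base boxcar for the
task's included trials and 12 raw 0/1 dummy modulators (response x confidence
level); other tasks' trials stay in the baseline, the point of fitting
one matrix per task. When every level occurs the base column equals the sum
of the dummies, so the matrix is deliberately rank-deficient; `fit_glm()`
fits it with the minimum-norm pseudoinverse (`method = "pinv"`). The null
space shifts all 12 dummy betas by one common constant, which the second step
absorbs into its intercept — the linear and quadratic estimates are
unaffected. The default `method = "qr"` instead refuses rank-deficient
designs and names the collinear columns.

`two_step_polyfit()` regresses each response's six level-wise betas on
`{1, conf, conf^2}` without orthogonalization, all levels weighted equally —
estimates are therefore indifferent to the confidence distribution. Estimates
are reported in this raw-confidence polynomial basis; `modulation_from_qc()`
maps QC-DM betas into the same basis using the stored centring constant,
squared-modulator mean and orthogonalization coefficient, so the two routes
are directly comparable. The generator (`simulate_roi_timeseries()`) builds
amplitudes as `mean + g1 * cc + g2 * cc^2` with per-response centred
confidence `cc`, mirroring the QC-DM coding; `expected_modulation()` expands
the generating gains into the raw basis for recovery checks. One caveat is
inherent to the categorical route: signal from the unmodelled other tasks
leaks slightly into its estimates (well under 1% of the gains in the
noise-free tests), which is the price of the "other tasks as baseline"
design.

## RSA conventions

The 12 conditions are 3 tasks x 2 responses x high/low confidence, ordered
task-major with the high-variance response and high confidence first.
`confidence_split()` assigns trials by the per-response median (ratings at or
below the median are "low"; ties go to the low side); a response-invariant
fixed-cutoff mode is available as a flag.

Empirical RDMs use Euclidean distances exclusively *across* runs (mean over
ordered run pairs), so run-specific noise cannot masquerade as similarity;
the diagonal (cross-run self-distance) is retained and used by the
reliability diagnostic (off-diagonal ranks should exceed diagonal ranks).
The noise-ceiling lower bound is the mean leave-one-out Spearman correlation
with the average ranked RDM of the remaining subjects.

The package fixes the following conventions for the eight theoretical
RDMs (`theoretical_rdms()`):

* Decision models C (detection) and D (detection + tilt) are defined only
  within their task blocks (no-prediction mask elsewhere): 1 iff the response
  differs.
* Confidence models G (detection) and H (detection + tilt) are likewise
  block-masked; within a block they code 1 iff the *same* response carries
  different confidence, 0 on cross-response pairs. Under this convention
  `G = 1 - C` on the detection off-diagonal, reproducing the perfect negative
  Spearman correlation between the decision and confidence models; H adds
  confidence-crossed = 1 / aligned = 0 entries between the two
  unequal-variance tasks.
* The task-invariant confidence model E codes the confidence contrast within
  each task x response cell and between cells of different tasks
  (crossed = 1, aligned = 0) and masks within-task cross-response pairs; its
  unmasked support is then spanned exactly, with disjoint supports, by the 18
  sub-RDMs (6 within-cell + 12 between-cell across-task pairs — the only
  enumeration of that description yielding 18). E and the single-task
  confidence models therefore treat within-task cross-response pairs
  differently (masked vs. 0); both choices are defensible and the asymmetry
  is confined to these entries.
* Model F grades E's contrast by the variance structure: weight 1 within and
  between the unequal-variance tasks, 0.5 within discrimination, pairwise
  averages elsewhere (the grading values are exposed as
  a parameter).

Model correlations are Spearman over mutually unmasked off-diagonal entries
with average-rank ties. The sub-RDM regression fits the 18 predictors plus an
intercept over E's 54-entry support; the two reported combinations average
the response-specific detection-tilt betas ('yes'-'tilted' with
'no'-'vertical') and all four tilt-discrimination betas, with equal weights
within each combination.

`simulate_patterns()` embeds a generating RDM by classical MDS with the
Cailliez additive constant — a strictly monotone transform, so off-diagonal
rank order is preserved exactly, which is all the rank-based RSA uses —
rotates the configuration into voxel space with a random orthonormal map, and
adds independent Gaussian run noise. Masked entries of a theoretical
generating RDM are filled with the mean of its defined off-diagonal entries
before embedding. The default `signal_scale = 3` with unit pattern noise over
80 voxels puts the leave-one-out noise ceiling around 0.7 — a reliably
structured ROI in which the generating model wins the model comparison in a
majority of replicates; smaller scales emulate noisier regions.

## Group statistics

`ttest_with_d()` reports the two-sided one-sample t with `d = t / sqrt(n)`.
`rm_anova()` is the one-way repeated-measures F with df `(k-1, (k-1)(n-1))`
via `stats::aov`; if the condition sum of squares is numerically zero the F
is pinned to 0 rather than returning 0/0 rounding noise. `jzs_bf01()`
computes the default Bayes factor for the null with a Cauchy(0, scale) prior
on the standardized effect size by adaptive quadrature over the prior's
inverse-gamma mixing variance; the integrand is normalised by the null
likelihood for numerical stability, and the default scale is
`sqrt(2)/2 = 0.707`. Tests cross-check it against an independent fine-grid
Riemann sum and its monotonicity in `|t|`.

## What the generator does and does not emulate

Emulated: the three-task blockwise structure and timing, 6-level ratings from
an explicit unequal-variance observer, staircase-coupled difficulty, lapses,
HRF-convolved ROI signals with linear and quadratic confidence modulations,
and cross-run multivoxel patterns with controllable representational
geometry. Not emulated: realistic fMRI noise spectra (drift, physiological
rhythms — noise is white, with nuisance-column hooks for real recordings),
head motion, response-time structure, inter-subject parameter variability
beyond what sampling noise induces, and criterion drift. Passing tests
therefore certify the estimators and their couplings under the stated
generative assumptions, not robustness to violations of them.

## Problem sizes and numerical choices

The test suite simulates sessions of 3–6 runs, cohorts of 5–20 subjects with
10–20 replicates for the power-style properties, 20-seed recovery checks for
the GLM (both routes) and sub-RDM regression, and 200 simulations for the
type-I-error calibration of zero-gain modulators; recovery of the reference
sd ratios uses 35 observers x 2000 trials averaged over replicate seeds.
Where several confidence intervals are checked simultaneously, 99.5%
intervals are used so the joint level stays near 95%. Microtime resolution is
0.1 s; design rank is assessed by QR with R's default tolerance and the
pseudoinverse uses an SVD cutoff of `max(dim) * max(d) * eps`. Degenerate
inputs (zero-variance t-tests with a nonzero mean difference, all-one-bin
rating tables, fewer than 3 confidence levels, fewer than 2 runs or 3 usable
RDM entries) raise informative errors rather than returning numbers.
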