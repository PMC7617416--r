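---
title: "Methods: disparity pRF estimation, adaptive psychophysics, and their linkage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: disparity pRF estimation, adaptive psychophysics, and their linkage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(disparityprf)
```

This vignette documents the models implemented in `disparityprf`, the
assumptions behind them, the tunable parameters, and the design choices
made where the methodology was genuinely open.

## 1. Stimulus model

The disparity stimulus is represented at the regressor level: a signed
disparity value per visual-field quadrant per TR. Disparity levels are
geometrically (log) spaced — `log_disparity_levels()` builds
`n_steps/2 = 10` magnitudes between `d_min_mag` and `d_max_mag = 0.3`
degrees, mirrored about zero, giving 20 signed levels. Log spacing
concentrates samples at small disparities, where tuning curves are
narrowest and most informative. Zero disparity is never presented: a
geometric ladder cannot contain it, and the level count is even.

`d_min_mag` defaults to 0.01 degrees. The choice matters little above
~0.005 degrees: it sets the finest sampled disparity but not the fitted
parameter ranges.

Within a cycle (20 TRs at the default one frame per step) the magnitude
ramps small → large → small, a full disparity oscillation. On every frame
two quadrants carry positive (far) and two negative (near) disparity of
identical magnitude, so the sum over quadrants is exactly zero — the
stimulus exerts no net vergence drive. The two-positive assignment is drawn
pseudorandomly per cycle and negated on the down-ramp; consequently each
quadrant visits all 20 signed levels exactly once per cycle, while the four
quadrant regressors decorrelate across cycles. A run is 13 cycles (260
stimulation frames) plus 8 trailing rest frames (disparity `NA`, zero
neural drive), matching a 268-volume acquisition at TR = 1.355 s.

The correlated/anticorrelated stereogram distinction is metadata only: both
conditions share the identical disparity regressor, and the fitting
pipeline treats them as independent datasets distinguished by a label.

## 2. BOLD forward model and two-stage fit

The neural drive of a vertex is the Gaussian tuning response
`exp(-(d - mu)^2 / (2 sigma^2))` to its quadrant's disparity time course
(zero during rest frames). The drive is convolved with a double-gamma HRF
sampled at the TR (unit peak, peak delay 6 s, undershoot delay 16 s,
undershoot ratio 1/6 by default; `estimate_hrf()` fits the delay and ratio
parameters to a block-design run when one is available, falling back to the
canonical kernel with a `converged = FALSE` flag on failure). Convolution
assumes a steady-state pre-run history (the drive held at its first value),
so a constant drive maps to a constant response without an onset transient.
Predictions are mean-centered; amplitude `beta` and an additive baseline
are profiled out by ordinary least squares at every evaluation. The
baseline accompanies `beta` so the fit remains well-posed on unfiltered
synthetic signals; on band-passed (mean-zero) data it is ≈ 0.

**Stage 1 (grid).** `prf_grid()` crosses 100 `mu` values uniform on
[−0.3, +0.3] degrees with 100 `sigma` values geometric on [0.025, 1.5]
degrees — 10,000 candidates. The `mu` range equals the stimulus range; the
`sigma` range spans tuning widths from below the 0.1-degree physiological
floor to well above the widest widths observed in practice (≈ 2.2 degrees,
i.e. sigma ≈ 0.55), padded. For each vertex the candidate maximizing the
Pearson correlation between prediction and signal is the seed. Ties break
toward smaller `sigma`, then smaller `|mu|` (candidates are pre-sorted in
that order and the first maximum wins), making the output deterministic.
The implementation evaluates tuning responses once per (candidate, level)
— there are only 20 distinct levels — and performs the convolution as one
banded matrix product, but it is tested for exact agreement with an
independently coded per-candidate exhaustive search. An optional
vertex-neighbor-graph averaging (default off) stands in for surface-based
spatial smoothing during stage 1 only; no surface geometry is modeled.

**Stage 2 (refinement).** Nelder-Mead simplex over `(mu, sigma)` from the
seed, minimizing the residual sum of squares with the amplitude profiled
out; bounds (`mu` in [−0.6, 0.6], `sigma` in [0.01, 3] degrees) are
enforced by clamping inside the objective, relative tolerance 1e−10, at
most 500 iterations. A guard returns the seed fit whenever the optimizer
fails to improve on it, so refinement never degrades the grid solution.
`r2 = 1 − RSS/TSS` is computed against the original, unsmoothed signal and
may be negative for pathological input; thresholding handles that
naturally. Constant signals have undefined correlation and are flagged
unfit (`r2 = −Inf`).

Refinement operates on the same signals as the grid stage — band-passed
when filtering is requested, never the smoothed stage-1 signals.
Band-pass filtering (0.02–0.2 Hz) is implemented as an exactly zero-phase
FFT-domain filter with DC removal; on 268-sample runs this avoids the edge
transients of IIR alternatives. It is an explicit, optional step
(`filter` argument of `fit_prf()`; default off for synthetic data, whose
noise is white).

**Inclusion thresholds.** `apply_thresholds()` keeps vertices with
r² strictly > 0.1 and width (= 4σ, exactly) strictly > 0.1 degrees, and
records counts at each stage. Widths at or below 0.1 degrees are treated as
non-physiological fitting artifacts.

## 3. Population analyses

`compare_models()` fits tuning width against |preferred disparity| with
(a) a straight line and (b) a second-order polynomial constrained to have
its minimum at x = 0, i.e. `width = c + a x^2` with `a ≥ 0` — no linear
term, hence two parameters, the same count as the line. When the
unconstrained quadratic coefficient is negative the constraint binds and
the fit degenerates to the mean. Because the polynomial depends on x only
through x², fitting signed or absolute disparities is equivalent; the
package standardizes on |mu|. AICc is computed in its least-squares form
`n ln(RSS/n) + 2k + 2k(k+1)/(n−k−1)` with constants dropped; for equal k
the difference is `n ln(RSS_1/RSS_2)`. The probability that the quadratic
is the better model is the two-model Akaike weight
`1/(1 + exp(−ΔAICc/2))`; ΔAICc = 30 gives > 99.99%. Vertices are pooled
across participants by default (stratify externally for a per-participant
variant).

Supporting summaries: `preferred_disparity_histogram()` (50 equal-width
bins on [−0.3, +0.3] degrees, right-open except the last — a fixed,
deterministic convention), `proportion_significant()` (percentage of
vertices with r² > 0.1 per condition, relative to the count of vertices
with r² ≥ 0 under correlated stimulation), and
`qc_preferred_disparity_clustering()`, which flags a participant when more
than 85% of fitted preferred disparities fall within ±0.02 degrees of a
single symmetric mode pair (the signature of vergence drift at the
stimulus extremes, e.g. pileups at ±0.23 degrees).

## 4. Psychophysics simulation

The observer is a Weibull psychometric function in log10 relative disparity:
`p(correct) = gamma + (1 − gamma − delta)(1 − exp(−10^{beta (x − T)}))`
with chance rate gamma = 0.5 (2AFC near/far judgment), slope beta = 3.5,
lapse delta = 0.02, and true threshold T. Fixation breaks are an
independent Bernoulli process (default rate 13.8%) that rejects a trial
regardless of the stimulus; rejected trials are logged, discarded, and
replaced.

**Stage 1 — convergence.** A two-down one-up transformed staircase starts
at 0.1 degrees, stepping 0.5 log decades until three reversals, then 0.1
log decades until three more; the level at the sixth reversal initializes
stage 2. Levels are clamped to [1e−4, 1] degrees with a warning. This
staircase converges toward the ~70.7%-correct point (a constant-p observer
drifts down iff p² > 1/2), which the tests verify by simulation.

**Stage 2 — dual QUEST.** A discretized Bayesian posterior over log10
threshold (Gaussian prior, SD 1.0 log10; grain 0.002; support ±2.5 log10
around the stage-1 result) is updated multiplicatively by the Weibull
likelihood of each response. Half the trials (exact 25/25 split, randomly
permuted) are placed at the "30%" and half at the "70%" point of the
assumed Weibull evaluated at the current posterior mean. A raw 30% correct
is unreachable in 2AFC, so these sampling points are interpreted as
performance targets `gamma + q (1 − gamma − delta)` (64.4% and 83.6%
correct), inverted in closed form:
`x = T + log10(−ln(1 − q)) / beta`. The threshold estimate is the
posterior mean — the posterior functional is not otherwise pinned down, and
the mean is the standard QUEST recommendation. A full session
(`run_full_session()`) interleaves 12 staircases — 4 quadrants × 3 pedestal
disparities (near −0.4, fixation 0, far +0.4 degrees; negative = near) — in
one randomized trial order, 50 successful trials each, 600 in total.

## 5. Brain–behavior linkage

Thresholded correlated-condition vertices are binned by preferred
disparity: below −0.1 degrees → "near", above +0.1 → "far", the closed
interval [−0.1, +0.1] → "fixation". The boundary assignment is a
deterministic convention; boundary values go to the fixation bin. Within
each (participant × area × hemifield cell × pedestal bin) cell, the
*disparity resolution limit* is the 10% quantile of tuning widths — linear
interpolation between order statistics with plotting positions
`(k − 1)/(n − 1)` (R type 7), a convention fixed here for determinism —
with the median computed alongside as a robustness variant. Empty cells are
dropped before pairing. Hemifield cells default to the four quadrants,
giving 12 points per participant (3 pedestals × 4 cells). The resolution
limit is correlated with the matched stereoacuity thresholds by Spearman
rank correlation (average ranks for ties, two-sided p, normal
approximation), Bonferroni-corrected for nine visual areas
(`p_bonf = min(1, 9 p)`); fewer than three matched pairs yields a missing
result. In synthetic mode the visual-field-to-cortex match is a plain label
join; the contralateral/inverted retinotopic mapping only concerns
real-data adapters, which are out of scope.

`synthetic_linkage_check()` validates this stage end to end: cohorts are
generated with a monotone map from the linked area's resolution limit to
the log threshold (plus log-normal noise) and no link elsewhere; detection
is scored as the linked area attaining the largest rho.

## 6. Synthetic data: what it does and does not emulate

`make_vertex_population()` draws preferred disparities uniformly on the
stimulus range (optionally mixed with symmetric Gaussian modes at ±0.15
degrees, where empirical distributions peak in higher visual areas) and
widths from the quadratic relationship `width = c + a mu^2 + scatter`
(defaults c = 0.3 degrees, a = 4 per degree, scatter SD 0.05 degrees),
floored at 0.1 degrees. `make_session()` synthesizes
`beta · (drive ∗ HRF) + baseline + N(0, noise_sd)` on the 268-frame TR
grid; SNR is reported as SD(clean)/noise_sd. Noise is white Gaussian by
default: band-pass filtering is itself part of the pipeline under test,
and white noise keeps recovery tolerances interpretable.
`make_observer_set()` draws log-normal per-condition thresholds with a
configurable far-pedestal elevation (default means 0.03/0.03/0.06 degrees
for near/fixation/far), reproducing the direction of the empirical
pedestal effect by construction.

The generator deliberately omits: temporal autocorrelation and
physiological noise structure of real BOLD data, cortical surface geometry
and spatial noise correlations, vergence eye movements, the attenuated and
sparser responses to anticorrelated stereograms (an empirical finding, not
an assumption — only an optional amplitude-scaling knob is exposed), and
any dependence of tuning width on eccentricity. Passing recovery tests
therefore demonstrate the estimator's correctness under the stated noise
model, not its performance on real scanner data.

## 7. Numerical choices and problem sizes

Key numerical decisions, fixed once: grid tie-breaks (smaller sigma, then
smaller |mu|); simplex relative tolerance 1e−10 with a seed-fit fallback;
QUEST grain 0.002 log10; histogram and pedestal-bin boundary conventions
as above; quantile type 7. Degenerate inputs are handled explicitly:
constant signals are unfit, empty width cells are missing, fewer than three
correlation pairs is a missing result, concave width data bind the a ≥ 0
constraint.

The test suite and the acceptance script size their simulations to run in
minutes on one core while keeping estimates stable: 50 vertices for
noiseless recovery (errors < 1e−3 degrees), 200 vertices at noise
SD = 0.5 × signal SD (median errors bounded by tolerances frozen after a
single calibration run: 0.013 degrees for mu, 0.018 for sigma), 200
replicates of n = 500 for model-family selection, 100 replicates for QUEST
recovery (median error < 0.15 log10), and 100 synthetic cohorts of 9
participants for linkage detection. Exhaustive-search oracle equivalence is
asserted on reduced grids (120 candidates) for speed; the default
10,000-candidate grid is exercised directly by the recovery runs.

## 8. Known limitations

Real-data adapters (surface formats, retinotopic ROI delineation, scanner
preprocessing) are out of scope; inputs arrive as plain TSV matrices and
tables. The HRF estimator fits delays and undershoot ratio but not the
dispersion parameters, which are weakly identified from a single block
average. The paper-scale empirical quantities that depend on private
participant data (e.g. per-area vertex counts or the observed V1
correlation strength) are not reproducible here and are not targeted; the
package instead verifies every analytic constant and the recoverability of
every generative parameter it defines.
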