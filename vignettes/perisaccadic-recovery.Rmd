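---
title: "Peri-saccadic detection performance: models, estimators, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Peri-saccadic detection performance: models, estimators, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

When an observer tracks an attended target across a visually guided saccade,
detection performance collapses around the movement — attention is partly
diverted to saccade planning, and visual sensitivity is suppressed during the
saccade itself — and then returns to baseline. The quantity of interest is
*how quickly* performance is back at baseline after the eye lands: the
recovery time. Estimating it requires a chain of decisions — how saccades are
detected, which trials count, how a two-frame stimulus change is timestamped,
how performance is binned, and what "indistinguishable from baseline" means
statistically. `perisacc` implements that chain as a reusable, testable
pipeline, together with a synthetic-data generator that produces datasets
with known ground truth, so every stage can be validated end to end.

## The analysis chain

1. **Saccade detection** (`compute_velocity()`, `detect_saccades()`). Eye
   speed is the Euclidean norm of the smoothed central-difference derivative
   of the 1000 Hz horizontal/vertical gaze trace (moving-average half-width
   2 ms by default; one-sided differences at the endpoints). A saccade is a
   maximal run of samples strictly above an individualized threshold —
   40–70 deg/s in practice, 50 deg/s by default — lasting at least 8 ms.
   Onset is the first supra-threshold sample; offset is the first sample
   back below threshold. This "early" offset definition deliberately excludes
   post-saccadic glissades; it biases the recovery estimate upward (longer),
   never downward, which is the conservative direction here.
2. **Trial classification** (`classify_response()`). A press within 600 ms
   after the target change is a hit (the window is half-open on the left and
   closed on the right, so a press at exactly +600 ms counts); a press at or
   before the change that falls within 800 ms of a distractor change is a
   response to the distractor; other premature presses are early responses.
   A press that lands in the hit window *and* within 800 ms of a distractor
   is a hit: the distractor-attribution rule is stated for early responses,
   and a response after the target change is most plausibly a response to it.
3. **Inclusion** (`select_trials()`). A trial is analyzed only if there is
   exactly one detected saccade of at least 1 degree (sub-degree events are
   corrective movements or noise, not the target-directed saccade), its
   latency lies in [−50, +450] ms around the fixation-point jump, it lands
   within 2 degrees of the saccade target, both fixation epochs pass the
   fixation rule, and the outcome is hit or miss. Two fixation rules are
   available: a fixed 2-degree window around the fixated point, and a
   stricter 0.5-degree per-axis deviation from the epoch median (the median
   version compensates for slow calibration drifts across trials).
4. **Alignment and binning** (`align_to_saccade()`, `bin_performance()`).
   Change times use the *second* frame of the two-frame change (23.5 ms at
   85 Hz) — the conservative timestamp when the question is how early
   performance has recovered. Bins are left-closed/right-open, tile the span
   from its left edge, and carry 95% Wilson score intervals.
5. **Recovery estimation** (`estimate_recovery()`). The baseline is a single
   pooled proportion over 100–500 ms after saccade offset (one k/n, not an
   average of per-bin rates). Each successive 10 ms bin in 0–100 ms is
   compared against it with a one-sided Boschloo exact test (bin lower than
   baseline); the start of the first bin with p > 0.1 is the recovery time.
   A p-value exactly equal to the cutoff still counts as significant — the
   stopping rule requires strict exceedance. A confirmation pass at 5 ms
   bins is reported alongside, with a warning if it disagrees by more than
   one coarse bin; the coarse result is authoritative. Bins with no trials
   cannot be tested and do not stop the scan. Both the one-sided direction
   and the lenient 0.1 cutoff are conservative for this question: they can
   only delay, never hasten, the declared recovery.
6. **Supplementary estimators.** `recovery_interp80()` reports the time at
   which the piecewise-linear interpolation of bin-center rates first
   reaches 80% of baseline (if the first post-saccadic bin is already above
   the criterion, its bin center is returned — there is no earlier data to
   interpolate from). `latency_split_curves()` repeats the binning within
   predictive (0–75 ms), express (75–125 ms) and regular (125–250 ms)
   saccade-latency groups, and `false_positive_analysis()` compares
   distractor-response rates per distractor location in the 0–150 ms
   post-saccadic window against the control location (one-sided Boschloo,
   raised-rate direction).

## Exact statistics

`wilson_interval()` is the closed-form score interval without continuity
correction: center `(p̂ + z²/2n)/(1 + z²/n)`, exact 0/1 endpoints at k = 0
and k = n.

`boschloo_one_sided()` uses the one-sided Fisher p-value (hypergeometric
tail, ties included with tolerance 1e-12) as its test statistic and
maximizes, over the common nuisance success probability π, the probability
under two independent binomials of observing a table at least as extreme:

    p = max_π  P( fisher(X1, X2) ≤ fisher(k1, k2) ),   Xi ~ Bin(ni, π).

The implementation exploits that, conditional on the total S = X1 + X2, the
distribution of X1 is hypergeometric and free of π; the inner probability is
therefore `Σ_s P(S = s) H(s)` with `H(s)` computed once, which keeps the test
practical for baseline sizes in the tens of thousands. The maximization
scans 1001 equally spaced grid points and refines around the argmax by
golden-section search; tests pin the grid-refinement drift below 1e-4. No
continuity corrections, no mid-p variants, no two-sided version.
`boschloo_power()` builds the exact rejection region by full table
enumeration for small groups (used to verify size control: estimated size
never exceeds α on a dense grid of nuisance values) and falls back to
Monte Carlo with a reported standard error otherwise.

## What the generator emulates

`build_scenario()` encodes four scenarios. All times are ms on the trial
clock (0 = fixation-point onset).

| parameter | E1 | E2easy / E2hard | E3 |
|---|---|---|---|
| random-dot patterns appear | 647 | 412 | 647 |
| fixation point jumps | 1235 | 1235 | 1235 |
| target change (after pattern onset) | 118–1882 | 235–1647 | 412–2176 |
| distractor change window | 118–1882 | 118–1224 | 470–941 |
| trials with a distractor change | 39% | 27% | 60% |
| catch trials | 10% | 7% | 6% |
| distractor locations | below, right | below, right | right, left, below |
| baseline detection probability | 0.98 | 0.90 / 0.70 | 0.95 |

Changes are snapped to the 85 Hz frame grid and stored with the second-frame
convention; a distractor change always precedes the target change by at
least 400 ms (the target-change draw is restricted accordingly on distractor
trials). The saccade is 7 degrees horizontal with a raised-cosine velocity
profile, `v(τ) = (2A/D) sin²(πτ/D)` — smooth, symmetric, and with
analytically computable threshold crossings — over a default 40 ms. Saccade
latencies come from a three-component Gaussian mixture (means 50/100/170 ms,
weights 0.10/0.30/0.60, truncated to [−50, 450] ms) so that all three
latency classes are populated; the class proportions are a modeling choice,
configurable per scenario. Fixation noise is white Gaussian at 0.02 degrees
per axis — small enough that baseline speed stays far below the detection
threshold. A glissade (probability 0.3, 0.5 degrees over 20 ms, same profile
shape) follows the main saccade; its 50 deg/s peak sits exactly at the
default threshold, so it is excluded by default detection but captured when
the threshold is lowered, reproducing the threshold-sensitivity of the
offset definition. Reaction times are a shifted log-normal with median
324 ms clamped at the 600 ms deadline; each distractor change triggers an
independent false alarm with probability 0.056 (E1/E2; 0.023 in E3) within
800 ms of the change, and the earliest scheduled press terminates the trial.

The detection probability follows a piecewise time-course
(`performance_curve()`): flat baseline; a shallow linear dip (default depth
0.08) from the fixation-point jump, reflecting pre-saccadic diversion of
attention; a steep drop beginning 30 ms before saccade onset into a
suppression floor (default 0.05); and a step back to baseline 30 ms after
saccade offset (a linear-ramp recovery is available as an alternative
shape). With ~500 trials per 10 ms bin the sequential estimator resolves
this 30 ms step exactly, and the 0.05 cutoff variant can only shorten the
estimate — both behaviors are asserted in the test suite.

**Which saccade landmarks anchor the curve.** The generator keeps two sets
of ground-truth landmarks per trial: the velocity profile's support
endpoints (`onset_true`/`offset_true`, exactly the configured duration
apart) and the *operational* landmarks (`onset_ref`/`offset_ref`) where the
noise-free speed crosses the scenario's detection threshold. The behavioral
curve is keyed to the operational landmarks. This is a deliberate design
choice: "recovery 30 ms after saccade offset" is only meaningful relative to
an offset *definition*, and the study's definition is the threshold
crossing. Keying the generative step to the support endpoint while
measuring at the threshold crossing would displace the estimate by the
crossing lag — about 5 ms at 50 deg/s for a 7-degree, 40 ms saccade — purely
as a bookkeeping artifact, which per-bin samples in the hundreds would
faithfully (and misleadingly) resolve into the neighboring bin. The support
endpoints remain the reference for kinematic tests (detector recall within
2 samples at low thresholds and low noise).

What the generator does **not** emulate: dot-level random-dot kinematics or
any photometric detail; oculomotor drift, microsaccades, tracker noise
autocorrelation, or blinks; learning, fatigue, or between-subject
variability (one synthetic subject per dataset); response-key identity. A
passing suite therefore validates the *analysis chain* — detection,
selection, alignment, binning, exact inference — under a behaviorally
plausible generative model; it does not certify kinematic realism of the
traces.

## Numerical and procedural choices

- Bin origin fixed at 0 (= the saccade landmark) for the recovery scan;
  plotting spans are configurable and also anchored at their left edge.
- Pooling across trials is trial-weighted (all trials concatenated), not
  per-subject equal weighting; an analysis that wants per-subject weighting
  can run the pipeline per subject and combine.
- Latency-group intervals and all bins are half-open `[lo, hi)`; a latency
  of exactly 75 ms is an express saccade.
- Event merging in `detect_saccades()` is off by default (`min_gap = 0`,
  the literal maximal-run definition); a positive `min_gap` merges events
  separated by shorter sub-threshold gaps, which is how the glissade's
  effect on the offset (and hence on the recovery estimate) is studied.
- The latency window bounds, the 1-degree minimum saccade amplitude, and the
  8 ms minimum event duration are arbitrary but uncritical; all are exposed
  as arguments.
- First key press governs classification; in faithful data later presses
  cannot occur because the trial ends at the first press.
- RNG: one stream per dataset, seeded from the scenario config; identical
  configs give bit-identical datasets, and the CSV writers reproduce values
  to better than 1e-9 on round-trip.

## Problem sizes used in the shipped checks

The test suite simulates 8000–30000 trials for estimator-level properties
(schedule-level fast path, which bypasses trace synthesis and uses the
operational landmarks directly), 25000 trials through the full trace
pipeline for the end-to-end recovery check, and 200 replicates of 10000
trials (≈50 included change trials per 10 ms bin) for the calibration study:
the modal recovery estimate equals the generating 30 ms bin start and the
mean absolute error stays within one bin width. The acceptance script uses
110000 trials so that every 10 ms test bin holds at least ~500 included
change trials. One caveat worth stating: with the stopping rule at p > 0.1,
the first genuinely recovered bin is declared significant with probability
up to the test's size, so single-dataset estimates occasionally land one bin
late regardless of sample size; that tail is part of the estimator's
sampling distribution (hence the calibration study's modal formulation),
not a defect of any particular run.

## Limitations

- The exact-test machinery targets 2×2 comparisons; there is no hierarchical
  or curve-fitting model of the recovery time-course (by design — the
  procedure is purposely assumption-light).
- `boschloo_power()`'s enumeration is quadratic in the group sizes; for the
  baseline sizes the pipeline produces, use the Monte-Carlo method.
- The false-positive comparison needs a control location with data in the
  analysis window; scenarios without one report rates with undefined
  p-values.
- Per-subject velocity thresholds are accepted as a named vector, but the
  package provides no automatic threshold-calibration procedure: thresholds
  are a judgment call made against each subject's velocity noise floor.
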