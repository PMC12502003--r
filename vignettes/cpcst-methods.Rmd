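---
title: "Models and methods behind cpcst"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind cpcst}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(cpcst)
```

This vignette is the package's own account of its science: the closed-loop
task model and its discretization, the synthetic participant, and the
statistical machinery — what each piece assumes, which knobs matter, and
where a genuinely open design choice was settled.

## The closed-loop plant

The task stimulus obeys a first-order unstable plant,
`dx/dt = λ (x + u)`, discretized by forward Euler at the native 30 Hz task
rate: `x[n+1] = x[n] + dt·λ·(x[n] + u[n])`, `dt = 1/30 s`. Euler at the
recording rate is the right discretization here because the real task *is*
a 30 Hz discrete system — stimulus updates and position recording share the
grid — so the simulator reproduces the recorded dynamics' structure rather
than approximating a continuum. Positions are normalized (screen edges at
±1); a crash is `|x| ≥ 0.8`, treated **boundary-inclusive** because only an
inclusive threshold is deterministic and testable at the boundary. Degrees
visual angle are a reporting-only linear conversion, 27.85 DVA per unit,
chosen so the 0.8 boundary maps to the task's printed ±22.28 DVA; the
screen geometry itself does not pin this constant down unambiguously, so it
is declared rather than derived.

The sign convention is configurable (`control_sign`): the default plant is
`λ(x + u)` with `u` the already-mirrored control signal; `λ(x − u)` is the
same system with `u` negated, and the bundled controllers adapt, so both
conventions generate identical stimulus paths (a tested equivalence).
Motor noise belongs to the participant's physical output and is therefore
mirrored together with the deterministic part of the signal.

Two small, deliberate departures from an idealized textbook loop:

- **Start/reset offset** (`x_start_offset`, default 0.01 units ≈ one pixel
  ≈ 0.28 DVA). An exactly centered stimulus is a fixed point of the plant:
  with a noiseless controller nothing would ever move and calibration could
  never crash. The task's "center" is therefore taken at pixel resolution —
  a sub-pixel nudge at the start of the task and after every reset gives
  the unstable dynamics state to act on while remaining visually centered.
- **Clamping** to ±1: the stimulus cannot leave the screen. All analysis
  happens inside the 0.8 boundary, so clamping only shapes the brief
  post-crash instants.

## The synthetic participant

The controller is the minimal generative model producing the three
phenomena the task measures — latency, an instability threshold, and
attentional drift:

```
u[n] = −gain · x[n − d] + ε_motor,   d = round(delay × 30 Hz)
```

with Gaussian motor noise, a Poisson lapse process (rate `lapse_rate_hz`)
whose exponentially distributed lapses freeze `u` at its last value, and a
re-centering pause (`u = 0` for one delay period) after task start and
after every crash reset — a participant has no percept of the freshly reset
stimulus inside their own feedback delay, and without this pause the delay
line still holds pre-crash positions and slams the stimulus straight back
into the boundary, which is an artifact, not behavior. This is explicitly
*not* a claim about human motor control; it is the data engine that makes
every downstream stage testable with known ground truth.

Two properties of the loop informed the defaults:

- At `gain = 1` exactly, a constant offset is invisible to the controller
  (`x − x[n−d]` vanishes for constant histories), so constants are neither
  corrected nor amplified. Human-like mean reversion needs `gain > 1`;
  the default is 1.1 and the cohort sampler draws 1.05–1.30.
- The stability limit of the delayed loop falls roughly as `1/delay`, so
  the calibration's measured MST decreases strictly with feedback delay —
  the package's central ground-truth ordering, verified both noise-free
  (deterministically) and in sampled cohorts.

`disturbance_sd` (default 0.005 units/step) is plant-side jitter — the
accelerometer device, not the participant. It excites the loop without
entering the recorded user series, which is what makes the *pure-delay
participant* possible: with motor noise and lapses off, the recorded user
series is an exactly delayed, scaled mirror of the stimulus, and the iRT
pipeline must recover `d/30` s. Scale is irrelevant after z-scoring, so any
positive gain serves.

One master seed draws independent per-participant seeds, so cohorts are
bit-reproducible and participants could be simulated in any order.

## Calibration and the asymptote criterion

λ ramps linearly at `lambda_ramp_rate` (default 0.2 s⁻² from 0.1 s⁻¹).
The ramp rate is not dictated by the task description; the default was
chosen once so that mid-range synthetic controllers complete their 10
crashes in roughly 2–5 simulated minutes, matching the time scale on which
the task's calibration operates, and it is fully configurable. On each
crash the reached λ is recorded, λ is halved (`reset_fraction`), and the
ramp resumes; the MST is the mean of the last three crash λs.

"Time to asymptote" has no stated formula in the task description, so the
package uses a transparent, monotone stand-in: the time of the earliest
crash from which **every** subsequent crash λ stays within ±10%
(`asymptote_tolerance`) of the MST, with "only the final crash qualifies"
counted as not reached. Noise-free mid-range controllers reach this
asymptote well within 90 s; noisy default cohorts reach it less often
(the band is deliberately strict), and the cumulative-count curve
(`cumulative_asymptote_curve`) reports whatever the cohort produces. The
2-minute practice round is a no-op for analysis and is not simulated.

## Preprocessing

Crash episodes in the continuous phase are maximal runs of
boundary-exceeding samples, extended to absorb the instantaneous reset jump
(adjacent samples reached through a position step larger than 0.5 units —
half the screen in one thirtieth of a second is kinematically impossible
for behavior). The removed samples of **both** series are refilled by
monotone piecewise-cubic Hermite (PCHIP) interpolation over time, via
`pracma::pchip`: interpolating only the stimulus would manufacture
artificial stimulus–user lags precisely where the alignment is most
fragile. PCHIP's shape preservation guarantees no new extrema beyond the
flanking anchors, hence cleaned traces never re-enter the crash region;
the interpolant passes through all retained samples exactly, and linear
gaps are reconstructed to machine precision. A gap touching the first or
last sample has no anchor on one side and is refused rather than
extrapolated. Exclusion (two or more crash events) is applied per
participant *before* any iRT computation, mirroring the analysis order of
the task's pipeline.

## The iRT metric

Both series are z-scored with their own mean and SD, the user series
mirrored first. Alignment is exact dynamic time warping: cumulative
pointwise cost `|a_i − b_j|` (L1 on z-scored series; squared cost is a
config option), steps `{(1,1), (1,0), (0,1)}`, anchored at both ends. Ties
prefer the diagonal, then the step advancing the stimulus index, making the
reported path deterministic. The warp path's horizontal offsets are
latencies: for stimulus index `i`, `latency[i]` is the mean (optionally
median) of `(j − i)/30` over its matched user indices — positive when the
user lags, negative for anticipation. Converting index offsets to seconds
by dividing by the sampling rate is the dimensionally consistent reading of
"multiplying x-coordinate distances by the sampling rate".

Unbanded DTW on a full 10-minute trace is an 18,000² dynamic program —
exact is the reference behavior and remains the default of `dtw_align`; a
Sakoe–Chiba band (|i−j| ≤ band) is exposed for speed, and the pipeline
defaults to a 90-sample (3 s) band, far wider than any plausible human lag.
Boundary anchoring forces the path to (1,1) and (N,M) regardless of the
true lag, so the first and last ~`d` samples are distorted; `trim_edges_s`
(default 0, i.e. the full series) excludes the edges from the mean when
asked. Known-lag recovery holds within one sample for delays of 3–20
samples with and without the band, and small i.i.d. noise moves the mean by
less than two samples.

`discrete_sampling_residual` quantifies what a discrete-RT paradigm would
miss: the 30 Hz series minus its zero-order-hold resampling at a probe
interval, with the fraction of samples whose residual exceeds two SDs of
the full-rate series.

## Reliability, stability, Steiger's Z

The cpCST has no discrete trials, so the split-half **trial unit** is a
non-overlapping 1-second bin of the latency series (30 samples per bin, 600
units in a 10-minute run; `bin_s` configurable). One second balances unit
count against the serial dependence of neighboring samples. Each split
permutes a participant's units, halves them (first half takes the odd
unit), correlates half-means across participants, and applies
Spearman–Brown `2r/(1+r)`.

The bootstrap resamples participants with replacement; the permutation
estimate is nested *inside* each draw. The headline 1,000 permutations are
kept for the standalone estimator (`split_half_reliability`), but inside
1,000 bootstrap draws that nesting is quadratic, so draws default to 100
permutations (`n_perm`), configurable — the point estimate is unbiased
either way and the CI widens only negligibly. On the analytic true-score
model (between-SD σb, within-SD σw, k units) the corrected split-half
converges to `σb²/(σb² + σw²/k)`, and the 95% bootstrap CI covers that
value at its nominal rate — the package's calibration check for the whole
chain. For difference scores (flanker I−C) each condition is permuted and
halved separately and half-differences are correlated, preserving the
within-condition structure of the score.

Stability curves correlate first-`n`-minute participant means with
full-duration means; the curve equals 1 at the full duration by
construction. Curves are compared minute-by-minute with **Steiger's (1980)
Z for dependent correlations sharing one variable** (the full-task measure),
in the pooled-correlation form
`Z = (z_jk − z_jh)·sqrt((n−3)/(2(1−r_kh)h))`; the equivalent Dunn–Clark
covariance form serves as an independent oracle in the tests, and the
statistic holds its nominal type-I error (0.035–0.065 at α = 0.05) under a
trivariate-normal null. `steiger_z` refuses |r| = 1 (the Fisher transform
overflows); since stability curves *do* hit exactly 1,
`compare_stability_curves` clamps inputs to ±(1 − 10⁻¹²) — at n in the
hundreds this yields astronomically large Z, which is the correct verdict
when one curve is pinned at unity.

## Flanker metrics

The generator draws ex-Gaussian RTs per condition (defaults: congruent
430, neutral 450, incongruent 490 ms Gaussian means, σ = 40 ms, τ = 80 ms,
a 60 ms congruency effect) with a Gaussian participant shift on all means
and Bernoulli accuracy per condition. Condition order is first-order
counterbalanced exactly — an Eulerian circuit on the 3-condition
multigraph with equal transition multiplicities — giving exactly 120
trials per condition and every ordered transition within one of every
other.

Trimming follows the stated order: accuracy gate (< 80% overall flags the
participant), drop incorrect trials, drop RTs < 200 ms, then drop RTs more
than 2.5 SD above the participant's mean. The mean and SD are **pooled**
over the remaining correct trials of all conditions (a per-condition option
exists): "the participant's mean" reads most naturally as one mean per
participant. Two honest properties of this single-pass rule are worth
stating: re-applying it to already-trimmed heavy-tailed data recomputes a
smaller cutoff and can remove a few more trials (the rule is single-pass by
definition, and the tests pin down exactly this behavior); and the pooled
cutoff clips the slower incongruent tail slightly harder than the congruent
one, so the recovered I−C sits a few ms below the generating 60 ms. Both
are properties of the rule, not of its implementation.

## Validity models

Ability/achievement/fitness instruments are out of scope as instruments;
their scores enter as opaque numeric columns. The simulator generates them
as declared linear-plus-noise functions of *latent* traits (lapse rate,
age) rather than of measured iRT, so a positive iRT–outcome association
arises through the shared latent trait — the honest version of the
validity claim. Models are OLS (`stats::lm`) of outcome on mean iRT,
optionally with age, listwise deletion with the analyzed n reported, and
unadjusted p values (a multiplicity note is written into every report).

## Numerical choices and degenerate inputs

- Crash boundary inclusive; post-reset λ is exactly
  `reset_fraction × crash λ` (the ramp increment is skipped on the reset
  step so the invariant holds at machine precision).
- Delay quantized to whole samples; rates are per-second and converted by
  `dt` internally.
- All randomness — R and C++ alike — flows through R's RNG, so a single
  `set.seed` reproduces every trajectory bit-for-bit; noise-free settings
  consume no random numbers and are deterministic.
- Zero-variance series refuse z-scoring; an all-frozen controller is a
  degenerate-series error, not a silent NaN.
- A controller too good to crash raises a calibration timeout
  (`calibration_cap_s`, default 30 simulated minutes).
- The DTW band must satisfy `band ≥ |N − M|` or the endpoints cannot be
  joined; smaller bands are refused.
- Spearman–Brown is undefined at r = −1 and errors there; inside the
  bootstrap core a draw with undefined correlation (zero variance) is
  dropped from that draw's permutation average.

## What the tests do and do not show

The simulated cohorts exercise every analysis path with known ground
truth: latency recovery, threshold ordering, reliability calibration,
type-I control, trimming equivalence, regression coverage. Test and
script problem sizes are the package's own choices — 1–2-minute traces and
cohorts of 8–30 for the properties, a 20-participant cohort at the full
10-minute duration for the end-to-end run — large enough for each
property's statistics while keeping the suite quick. What passing does
*not* show: the controller family omits learning and practice effects,
anticipatory/predictive control, 1/f-structured motor noise, fatigue
drifts, and any age–parameter coupling; real cohort values (reliability in
the high .99s, specific stability-curve shapes, regression coefficients)
depend on the human population and cannot be certified by simulation.
Test–retest reliability is explicitly out of scope.
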