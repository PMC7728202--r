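---
title: "Detecting obstructive breathing events in murine box-flow recordings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting obstructive breathing events in murine box-flow recordings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wbpleth)
```

## The problem

Whole-body plethysmography records a continuous box-flow signal from an
unrestrained mouse. In models of obstructive sleep apnea, partial upper-airway
collapse shows up as *inspiratory flow limitation* (IFL) — breaths with a
flattened inspiratory profile, reduced peak inspiratory flow (PIF), prolonged
inspiration, and reduced tidal volume (TV) — while complete collapse shows up
as apneas, cessations of flow lasting a second or more. `wbpleth` turns a raw
box-flow trace into per-breath features, per-breath IFL flags, aggregate and
apnea calls, per-animal frequency summaries, and group-level statistics, and
ships a seeded synthetic-recording generator with ground-truth event logs so
every detector can be validated against known truth.

## Breath segmentation

The flow signal (inspiration positive, the package convention; recordings
with the opposite polarity are inverted on read) is segmented by signed zero
crossings with hysteresis. Inspiration is armed when flow exceeds `+h` and
anchored back at the preceding zero crossing; it ends at the fall through
`-h`, again anchored at the preceding crossing; expiration runs until flow
next returns to non-negative values. Samples during which no breath is in
progress — apneic gaps — belong to *no* breath and are left to the raw-signal
apnea scan.

The hysteresis level is relative: `h = 0.05 ×` a running median of `|flow|`.
The running median uses a 60 s window evaluated on a ~50 Hz decimated copy of
the rectified signal. Two properties motivated this choice: the window is
long enough that a several-second apneic gap cannot drag the threshold to
zero (which would let sensor noise masquerade as breaths inside the gap), and
a relative threshold makes segmentation — and everything downstream —
invariant under rescaling the signal, which matters because uncalibrated
box-flow units are common. With uncalibrated input, TV is in arbitrary volume
units; the Ti/TV ratio criterion below is scale-covariant, so detection is
unaffected.

Candidate breaths shorter than 0.05 s (well below any real murine breath at
2–5 Hz) or with non-positive TV are absorbed into the preceding expiration.
TV is the trapezoidal integral of inspiratory flow; on a half-sine lobe of
amplitude $A$ and duration $d$ it recovers the closed form
$TV = 2Ad/\pi$ to well under 1% at 1 kHz:

```{r halfsine}
fs <- 1000; A <- 2; d <- 0.2
f <- c(rep(0, 100), A * sin(pi * seq(0, d, by = 1/fs) / d),
       -0.5 * sin(pi * seq(0, 0.4, by = 1/fs) / 0.4), rep(0, 100))
segment_breaths(flow_trace(f, fs))[, c("ti_s", "tv_ml", "pif_ml_s")]
2 * A * d / pi
```

## The dual IFL criterion

For each breath $i$ the detector computes the mean and sample SD (denominator
$n-1$) of the Ti/TV ratio and of PIF over the 100 breaths preceding $i$
(breath $i$ excluded — including it would dilute its own deviation; prior
breaths are *not* excluded for being flagged themselves). Breath $i$ is
flow limited iff

$$\mathrm{ratio}_i \ge \bar r + 2.576\, s_r
\quad\text{and}\quad
\mathrm{PIF}_i \le \bar p - 2.576\, s_p,$$

where 2.576 is the two-sided standard-normal 99% critical value
(`qnorm(0.995)`). The ratio criterion catches prolonged inspiration and/or
reduced tidal volume; the PIF conjunction suppresses false positives from
ratio outliers with normal inspiratory drive. The first 100 breaths have no
full baseline and are never flagged; a zero-SD (constant) window degenerates
the corresponding criterion to a strict inequality against the mean.
*Aggregates* are maximal runs of ≥ 3 consecutive flagged breaths. Comparisons
use ≥/≤ at the thresholds; the abnormality classification below uses a strict
greater-than.

**Known bias — baseline contamination.** Because flagged breaths stay in
subsequent baselines, a long burst of flow-limited breaths inflates its own
running SD: by burst position $j$ the window holds $j-1$ prior outliers and
the effective z of a 5-SD event decays roughly as
$5(1-0.05(j-1))/\sqrt{1+0.24(j-1)}$, crossing the 2.576 threshold near
position 6. Detection of bursts much longer than ~6 breaths therefore
degrades from the seventh breath on. This is a property of the
no-exclusion running-baseline design, kept deliberately because the baseline
definition is "the last 100 breaths", with no robustification; the
validation suite consequently measures breath-level sensitivity on bursts of
controlled length 3 (the aggregate-qualifying minimum) at 5-SD effects,
where sensitivity is ≥ 95%, and separately reports the lower sensitivity
under the geometric burst-length default.

## Apnea detection

An apnea is a maximal interval during which $|flow|$ stays continuously below
a cessation threshold for at least 1 s. The acquisition systems that score
apneas commercially do not document their internal criterion, so the package
declares its own, parameterized and echoed in every output: 5% of the running
median PIF over the preceding 100 breaths (global median PIF as fallback
before the first full window). The threshold is relative, preserving scale
invariance. Detection runs on the raw trace, independent of segmentation, so
the detector order is segment → IFL flags, raw scan → apneas, with no
interaction. Event intervals are half-open `[start, end)` in seconds;
sample indices are 0-based in the breath tables.

## Frequencies and the abnormality cut-off

Absolute frequencies normalize to the total observation period (including
apneic time): apneas/h, IFLs/h, aggregates/h. The proportional IFL frequency
(%) normalizes to the total breath count. Summaries can be restricted to
sleep or wake epochs; an event counts toward the epoch containing its start,
and the observation period is then the summed epoch duration. An animal's
apnea frequency is *abnormal* when strictly above the control group's
mean + 2 sample SDs. With control statistics of 6.27 apneas/h, SEM 0.80 and
N = 28 (so SD = $0.80\sqrt{28}$), the rule reproduces the reference cut-off
of 14.75 apneas/h to within rounding of the SEM:

```{r cutoff}
x <- seq_len(28); x <- (x - mean(x)) / sd(x) * (0.80 * sqrt(28)) + 6.27
abnormal_cutoff(x, k = 2)
```

## The synthetic-recording generator

No raw recordings ship with studies of this kind, so the generator is the
validation substrate. It emulates murine breathing as a sequence of
template breaths: half-sine inspiratory lobe (duration Ti, amplitude PIF)
and a half-sine expiratory lobe scaled so each cycle integrates to zero,
giving the analytic oracle $TV = 2\,\mathrm{PIF}\,Ti/\pi$. Per-breath period
and amplitude are log-normal. Defaults, chosen once as physiologically
plausible study conditions and not revisited: 3 Hz breathing (murine range
2–5 Hz) with CV 0.10, PIF 1 ml/s with CV 0.10, inspiratory fraction 0.40,
apneas at 6/h of sleep (the control-mouse rate) lasting U(1, 3) s,
obstructive bursts at 15/h of sleep with geometric lengths of mean 4 (so
≥ 3-breath aggregates arise), 5-SD effect sizes, and additive Gaussian noise
of SD 0.005 ml/s (an instrument noise floor, 0.5% of PIF). Two schedule
presets cover the standard designs: an 8 h day-time sleep recording and a
22 h observation with a 9 h night-time wake block, events being injected in
sleep epochs only.

Obstructive breaths get a plateau-clipped inspiratory lobe: PIF is lowered
to (population mean − `ifl_pif_drop_sd` × baseline SD) and Ti lengthened to
(population mean + `ifl_ti_gain_sd` × baseline SD), producing exactly the
conjunction the detector requires at exactly the configured effect size.
Apneas replace whole consecutive breath cycles with zero flow plus noise —
never splitting a lobe — so segmentation stays well-posed and every injected
gap is at least the drawn ≥ 1 s duration. Overlapping placements are
resolved by rejection-resampling with a bounded attempt budget; infeasible
densities raise an error. A single seeded stream is consumed in a fixed,
documented order (event counts → morphologies → placements → noise), so the
event counts can be replayed independently of the generator — the test suite
uses this for an oracle-replay check — and identical configurations are
reproduced bit for bit.

What the generator does *not* emulate: chamber physics (humidity and
temperature compensation, true barometric TV calibration), gradual arousal
transitions, sniffing/grooming artifacts, sigh breaths, or drift in
breathing amplitude beyond the log-normal variation. Passing the validation
suite therefore shows that the detectors implement their definitions
correctly and recover known events under realistic murine rhythms; it does
not show robustness to every artifact of real chamber data.

## Statistics layer

Two-group endpoints use a Shapiro-Wilk-gated choice: both groups at p ≥ 0.05
→ pooled-variance Student's t (the classical test; Welch is available via
`var_equal = FALSE`), otherwise Mann-Whitney (exact for small tie-free
samples, normal approximation with tie correction otherwise). The gate level
and the both-groups rule are the conventional reading; zero-variance samples,
where Shapiro-Wilk is undefined, route to Mann-Whitney with a warning, and
fully degenerate inputs (every value identical in both groups) report p = 1.
Categorical 2×2 tables use the *uncorrected* Pearson chi-square: on the
abnormal-proportion table (8/25 vs 2/28) the uncorrected statistic is 5.33
(p = 0.021, printed as 0.02) while the Yates-corrected form gives ~0.05, so
the uncorrected dialect is the one that reproduces the reference analysis.
Regression is ordinary least squares with R² equal to the squared Pearson
correlation and a t-based two-sided slope p-value. Multi-group machinery
(ANOVA/Kruskal-Wallis with post-hoc corrections, mixed-effects models) is
deliberately out of scope: those designs are recorded and handed to the
standard implementations, as no bespoke computation is involved. No
multiple-testing correction is applied across the endpoint panel, matching
the reference analysis.

## Numerical choices and degenerate inputs

* Running window statistics use centered cumulative sums (values are first
  centered on the global mean), keeping the windowed mean/SD within 1e-9
  relative of a from-scratch recomputation while staying O(n).
* Tiny negative variances from float dust are clamped to zero so constant
  windows report an exact zero SD and take the strict-inequality branch.
* Breaths are half-open in time; an expiration may not run past the next
  onset sample, so summed breath durations never exceed the trace duration.
* An all-zero trace segments to zero breaths (not an error); apnea detection
  without any segmented breath warns and returns nothing, since the
  cessation threshold cannot be calibrated.
* Traces must be uniformly sampled; timestamps deviating more than 1 ppm of
  the recording span from the ideal grid are rejected as discontinuities
  rather than zero-padded.
* The Ct triplicate average is the arithmetic mean of finite values;
  replicate spreads over one cycle warn. `dct` is target minus housekeeper —
  the direction under which a target rarer than the housekeeper yields
  < 100% — and `2^(-dct) × 100` maps `dct = 0` to exactly 100% with exact
  halving per added cycle.

## Problem sizes used in validation

The shipped validation suite simulates 10-minute recordings at 1 kHz
(~1800 breaths, ~17 full baseline windows each): 20 recordings for the
oracle-equivalence suite, 10 each for the sensitivity and specificity
suites, and 20 replications of a 16-animal null study at 200 Hz for the
type-I-error check. These sizes give stable proportions (tens of thousands
of judged breaths) while keeping the whole suite re-runnable in minutes;
they are the package's own validation design, and all of them regenerate
from seeds at run time.

## Known limitations

* Breath parsing in commercial acquisition software is proprietary; the
  zero-crossing-with-hysteresis segmentation here is declared as the
  reference implementation, not recovered from any vendor.
* The relative flow-cessation threshold (5% of running median PIF) is a
  declared operationalization of "cessation of breathing"; other plausible
  criteria (breath-interval or volume based) would call slightly different
  boundaries for marginal events.
* Long obstructive bursts self-contaminate the running baseline (see above).
* TV from uncalibrated box flow is in arbitrary units; absolute volumes
  require chamber calibration, which is out of scope.
* Sleep/wake epochs come from the schedule (or the simulator); no EEG-based
  sleep staging is attempted.
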