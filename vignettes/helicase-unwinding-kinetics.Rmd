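---
title: "Quantifying helicase unwinding at strand-specific protein barriers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying helicase unwinding at strand-specific protein barriers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(unwindr)
```

## The problem

Replicative helicases such as CMG unwind duplex DNA by steric exclusion:
the motor encircles the leading-strand template and excludes the lagging
strand. A protein block covalently attached to the *leading* strand
arrests the helicase permanently, while a block on the *lagging* strand is
either bypassed without consequence (a clicked streptavidin) or induces a
transient pause when the protein stabilizes the duplex ahead of the fork
(a trapped methyltransferase, "MH"). Two kinds of measurement quantify
this behaviour:

* **ensemble fluorescence unwinding curves** — a quencher/fluorophore pair
  reports the fraction of substrate unwound versus time in a
  single-turnover reaction;
* **single-molecule intensity traces** — fluorescent RPA accumulates on
  unwound ssDNA of a surface-tethered 2.7-kb substrate imaged by TIRF at
  10-s intervals; full unwinding releases the untethered strand and the
  signal drops abruptly.

`unwindr` implements both analysis paths and a simulator that generates
data with the statistical structure the analyses assume, so that every
estimator can be validated by parameter recovery.

## The ensemble model

Single-turnover unwinding curves are described by an m-step sequential
model: completion requires `m` consecutive exponential waiting steps with
common observed rate `k_obs`, so the unwound fraction is the Erlang CDF

$$f_{ss}(t) = 1 - \sum_{r=1}^{m} \frac{(k_{obs}t)^{r-1}}{(r-1)!}\,
e^{-k_{obs}t}.$$

`fss_model()` evaluates this sum directly. `m` is a model choice fixed by
the user (default `m = 2`, which reproduces the lag phase of measured
curves); it is never fitted, because selecting an integer step count from
a single noisy curve is ill-posed, and residuals of fits with different
`m` are not comparable (an information criterion would be needed, and the
data rarely support it). `fit_kobs()` fits amplitude, baseline and
`k_obs` by ordinary nonlinear least squares (no error model is available
for plate-reader noise, so no weighting), and `normalize_curve()` returns
`(signal - B)/A` — model-based normalization avoids the bias of min–max
scaling under noise.

**Delay estimation.** The slowing imposed by a duplex-stabilizing
lagging-strand block is summarized as the difference of interpolated
half-unwinding times (t50) between a blocked and a reference curve. The
t50 difference is model-light and recovers an injected pure time shift
exactly. The normalization used inside `estimate_delay()` includes a free
onset term `t0` (`B + A f_{ss}(\max(t - t_0, 0))`): without it, fitting a
time-shifted curve with an un-shifted model distorts the fitted amplitude
and baseline and corrupts t50 by several times the interpolation error.
Confidence intervals come from residual resampling (1000 replicates,
seed-controlled), recentred on the observed delay because the fitted
m-step form is only an approximation for pause-mixture ensembles. An
alternative delay definition — difference of fitted `m/k_obs` means — is
deliberately not the default: it inherits model misfit where the t50
shift does not.

## The simulator

`simulate_trace()` draws a per-molecule rate from a Normal population
with mean 8.2 and SD 4.2 bp/s, the distribution measured on fully unwound
single molecules without a barrier. The draw is truncated to
`[0.5, 2*rate_mean - 0.5]` bp/s: the floor removes unphysical
non-translocating molecules, and making the truncation symmetric keeps
the population mean exactly at `rate_mean` (one-sided truncation would
inflate it by ~4%, which would propagate into every rate-recovery check).
The truncation narrows the realized SD to ~3.9 bp/s; matching the mean
was judged more important than the second moment, since every downstream
quantity is calibrated against the mean.

Unwound bp advances deterministically at the drawn rate between frames.
At 10-s framing and ~8 bp/s, single-base-pair stochasticity is
unresolvable (~80 bp advance per frame against ~50 bp of intensity
noise), so a continuous-advance model is used rather than 1-bp Gillespie
stepping.

Barrier encounters follow the mechanism of the block, drawn per molecule
with the barrier's `occupancy` (protein conjugation is never complete):

* `pause` (lagging-strand duplex stabilizer): with probability
  `pause_probability` the molecule halts at the barrier for an
  Exponential(`pause_mean_s`) duration — default mean 4.63 min, the
  single-exponential fit to measured pause durations — then resumes at
  its pre-pause rate (measured post-bypass rates are indistinguishable
  from unadducted ones, so no rate change is modelled);
* `arrest` (leading-strand block): the molecule halts permanently;
* `transparent` (clicked streptavidin on the lagging strand): no effect —
  under a common seed the trace is bit-identical to a no-barrier trace,
  which the test suite asserts.

Intensity is proportional to unwound bp (RPA binds both unwound strands)
with additive Gaussian noise, default SD 2% of full scale — a choice, as
the source data carry no noise figure. On completion the signal drops to
`drop_factor` (default 0.5) of full scale: the released strand carries
away its complement of bound RPA; the depth of this drop is not
quantified anywhere, so it is a free parameter. All times are seconds
internally; minutes appear only in reported kinetic quantities.

**Calibrating the pausing probability.** The reported pausing fraction —
26% of molecules with a discernible (>30 s) pause — is an *observed*
fraction. With exponential durations of mean 4.63 min, a fraction
`exp(-0.5/4.63) = 0.898` of pauses exceed 30 s, so the generator's
underlying probability is `0.26/0.898 = 0.290`
(`underlying_pause_probability()`). Whether the observed 26% reflects
incomplete crosslinking or sub-threshold pauses is not resolvable from
the published numbers; the simulator therefore exposes `occupancy` and
`pause_probability` separately, defaults the former to 1 for the
lagging-strand block, and puts the whole calibration in the latter.

`simulate_ensemble()` draws completion times from the Erlang model plus
barrier terms and returns the completed fraction per frame; as
`n` grows (no barrier) the curve converges to `fss_model()`, which the
suite verifies against Dvoretzky–Kiefer–Wolfowitz bounds at n = 10,000.

## The trace pipeline

`detect_completion()` finds the earliest frame where the median-filtered
intensity falls by ≥30% of the running pre-drop rise and stays below for
three frames; single-frame dips are never completions. Absence of a drop
is censoring, a value rather than an error.

`calibrate_trace()` anchors the pre-drop plateau to the substrate length.
For completed traces the full-scale intensity is estimated by
extrapolating the last pre-drop frames to the drop time (midpoint
convention); reading the pre-drop maximum instead systematically
undershoots by about one frame of advance and inflates recovered rates by
~5%. The irreducible calibration uncertainty is half a frame of advance
(~41 bp at 8.2 bp/s). Censored traces are calibrated against the median
plateau of completed traces in the same batch — an arrested molecule's own
maximum would misread its stall point as full unwinding. A lone censored
trace falls back to its own maximum with a warning.

`detect_pauses()` segments the calibrated trajectory: 3-frame median
filter; candidate frames seeded where the 5-frame local least-squares
slope (or two consecutive 3-frame slopes, for short pauses) falls below
the 1 bp/s rate floor; runs extended outward while the trajectory stays
within a noise-scaled band of the pause level; fragments at the same
level unioned. The rate floor is ~12% of the mean rate — the 30-s
criterion alone does not separate pauses from slow molecules given the
8.2 ± 4.2 bp/s spread. Candidates are then validated:

1. duration ≥ 30 s (the discernibility threshold);
2. the interior is genuinely flat — slope below twice the floor *and*
   within-interval variance consistent with noise (a noise-mimicked
   "pause" on an advancing molecule hides a linear drift);
3. the pause is resolvable: the advance the molecule would have made,
   judged from its flanking rate, exceeds 4× the frame noise, and the
   flanking rate itself exceeds twice the floor;
4. ≥100 bp of further advance follows — terminal plateaus of stalled or
   completed molecules are never pauses.

**Detection limit.** A pause's entire signature is `v × duration` of lost
advance measured against frame noise (~54 bp at the 2% default). Events
below ~300 bp of implied advance are statistically indistinguishable from
noise excursions, in both directions: short pauses on slow molecules are
not callable, and a few percent of traces yield spurious sub-frontier
calls. The suite therefore asserts that spurious calls are rare and
*never* exceed the resolvability frontier, rather than a literal zero.
Pause recall and precision against the simulator's truth channel are both
above 0.9 at the default noise for pauses of at least 60 s.

Pauses within ±150 bp of the barrier are flagged `near_barrier` — the
window reflects a couple of pixels of typical mapping noise; the source
analysis says only "near" the block. Classification:
`stalled` requires a censored completion *and* a terminal plateau (last
120 s slower than the floor) inside the barrier window; a plateau
elsewhere, or a trace still rising at acquisition end, is `ambiguous` and
is counted, never dropped. Fork rates are least-squares slopes with pause
intervals excised and their elapsed time compressed out (post-bypass
rates match unadducted rates, so excision is the default; a flag
includes them).

`fit_pause_durations()` fits the single-exponential pause-duration
distribution by maximum likelihood with left truncation at the detection
threshold: for a truncated exponential the MLE of the mean is the sample
mean minus the threshold, reducing to the plain MLE as the threshold goes
to zero. SE is `mean/sqrt(n)`.

## Densitometry

Gel quantification starts from band-intensity tables (image linearization
and ROI extraction are upstream, out of scope): `band_fraction()` computes
`100 * sum(numerator - bg)/sum(denominator - bg)` with either a per-band
background column or a scalar per lane (the background protocol of the
source gels is not described; scalar-per-lane is the default and is
recorded in the output). The result is scale-invariant and complementary
fractions partition to 100%. `percent_unwound_series()` maps a band
scheme across lanes into a tidy table for replicate aggregation.

## Problem sizes and reproducibility

The package's recovery checks use: 200–500 traces per batch for rate and
pausing-fraction recovery (at 4.2 bp/s population SD, a few hundred
molecules put the sample mean comfortably inside a 5% band), 420 traces
for the pausing fraction (matching the reported cohort), 109 pause
durations (the published n), 100 traces for stall-fraction and
pause-position recovery, and n = 10,000 Monte-Carlo draws for the
closed-form/empirical CDF comparison. All randomness flows from a single
seed; identical seed and configuration give bit-identical output.
`scripts/acceptance.R` re-runs the whole recovery surface from one seed.

## What passing tests do and do not show

The simulator reproduces the statistical structure the analyses assume:
population rate spread, exponential pauses, occupancy-thinned barrier
encounters, completion-triggered signal drop, additive Gaussian noise.
Real traces additionally contain photobleaching and drift, uneven RPA
loading, focus fluctuations, and correlated noise, none of which are
modelled; parameter recovery here validates the estimators, not the
microscope. Known limitations: threshold-based segmentation rather than
HMM/CUSUM change-point inference (noted as future work); no modelling of
helicase loading kinetics or RPA binding kinetics; duplex-stabilization
thermodynamics are represented only phenomenologically as a pause-time
distribution; stall-position calibration requires completed molecules in
the batch.
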