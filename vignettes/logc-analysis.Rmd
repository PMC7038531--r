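---
title: "Estimating loss of ground contact in race walking from a trunk-mounted inertial sensor"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating loss of ground contact in race walking from a trunk-mounted inertial sensor}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(logcwalk)
```

## The problem

Race walking rules require that no loss of ground contact (LOGC) visible to
the human eye occurs. Flight phases in elite race walking last a few tens of
milliseconds, near or below the ~40 ms limit of human vision (LHE), so
judging by eye is unreliable exactly where it matters. `logcwalk` estimates
per-step flight time from a single inertial sensor worn at the base of the
spine (L5--S1), classifies steps and 30-step judging sequences, and
summarizes infringement and performance in five normalized indices drawn on
a radar chart.

## The timing model

The sensor provides the vertical (`a_vert`) and anteroposterior (`a_ap`)
acceleration of the centre of mass at `f = 200` Hz. After zero-phase
low-pass filtering (fourth-order Butterworth, one forward and one backward
pass; 20 Hz cut-off vertically, 30 Hz anteroposteriorly), two landmarks are
detected per step:

* **MAPA** -- the maximum of the anteroposterior acceleration, a proxy for
  the heel strike that starts the next step;
* **NPVA** -- the minimum of the vertical acceleration, which precedes the
  toe-off of the current step.

The flight-time estimate for step $i$ is

$$\mathrm{LOGC}_{T,i} = t_{\max,i+1} - t_{\min,i} - E(SC_i),$$

where $E$ is a cadence-dependent threshold: the part of the
NPVA-to-heel-strike interval that is still ground contact. $E$ follows a
no-intercept quadratic in step cadence $SC$ (steps/s),

$$E(SC) = \frac{SC^2}{a} + \frac{SC}{b}, \qquad a = -40.921,\; b = 11.242,$$

valid on $SC \in [2.8, 4.0]$; it decreases with cadence, crosses zero at
$SC = -a/b \approx 3.64$ steps/s and is clamped below at zero (a threshold
is a duration). A non-positive $\mathrm{LOGC}_T$ means double support: no
flight occurred. `fit_threshold_model()` re-estimates $(a, b)$ from
optimal-threshold data by least squares on the linear basis $(SC^2, SC)$,
with the three exclusion rules (cadence out of range, negative optimal
threshold, outside the 99% prediction bounds, the last applied iteratively
to a fixed point) and a least-absolute-residual fit reported alongside.

Each detected event carries one sample of uncertainty, so the timing is
bracketed by $\mathrm{LOGC}_T \mp 2/f$ (a 20 ms wide interval at 200 Hz).

## Classification

Judges consider a sequence of `NS = 30` steps (the number of steps crossing
a judge's field of view), so per-step values are averaged over consecutive
non-overlapping 30-step windows. Three classifiers are provided, for steps
and for sequences:

* **binary** (`classify_binary`): legal iff the timing is at or below
  LHE = 40 ms -- equality resolves in the athlete's favour;
* **three-level** (`classify_three_level`): uses the timing interval; legal
  if it lies wholly at or below LHE, illegal if wholly above, *doubt* (the
  judge's yellow paddle) if it straddles the limit;
* **fuzzy** (`fuzzy_membership`): a membership $\eta \in [0,1]$ in the
  illegal class, 0 at or below $LHE - 2/f$ (30 ms at 200 Hz), 1 at or above
  $LHE + 2/f$ (50 ms), linear in between. The equations only pin the two
  plateaus; the linear ramp is this package's reading of the published
  membership sketch.

The infringement fraction $\mathrm{LOGC}_{C,S}$ of a sequence is the share
of illegal *binary* step labels among its 30 steps.

## Performance parameters

Per step: cadence $SC_i = 1/(t_{\max,i+1} - t_{\max,i})$; step-length ratio
$SLR_i = 100\, v / (SC_i\, h)$ (percent of stature $h$, with $v$ the
externally measured mean speed); and smoothness

$$S_i = T^5 \left(\frac{SC_i}{v}\right)^2 \int_{t_{\max,i}}^{t_{\max,i+1}} j^2(t)\,dt,$$

the dimensionless jerk cost of the anteroposterior acceleration over the
step ($T$ the step duration, $j$ the jerk by central differences,
trapezoid integration). The $(SC/v)^2$ factor -- division by step length
squared -- is the only grouping of the published expression that is
dimensionless and lands in the stated 1 (ideal) to 10 (worst) band; it is
adopted here and verified numerically by a unit-rescaling invariance test.

## Normalized indices and the radar score

Five indices run from 0 (best) to 1 (worst):

| index | parameter | anchors |
|---|---|---|
| $\delta$ | sequence timing | 0 at $LHE-2/f$, 0.4 at $LHE$, 1 at $LHE+3/f$ (collinear, slope $f/5$) |
| $\alpha$ | infringement fraction | identity |
| $\gamma$ | sequence cadence | 0.4 at 3.130 steps/s, 0 at 3.380 steps/s |
| $\rho$ | step-length ratio | 0.4 at 62.8, 0 at 71.4 |
| $\mu$ | smoothness | 0 at $S=1$, 1 at $S=10$ |

The cadence and SLR anchors come from elite-competition correlations
($SC = 0.259 v + 2.253$ with $v$ in m/s; $SLR = 2.47 v + 32.73$ with $v$ in
km/h) evaluated at the 50 km qualifying-standard speed (12.20 km/h, mapped
to 0.4, "sufficient") and the 20 km world-record speed (mapped to 0,
"optimal"). The unit convention per correlation is the one that reproduces
the published anchors 3.130 and 62.8 -- with the conventions swapped,
neither is reproduced. Note one published inconsistency: the record speed
as printed (4.38 m/s) yields a cadence anchor of 3.387, slightly above the
printed 3.380; `calibration_constants()` therefore defaults to the printed
anchors, while `calibrate_boundaries()` derives anchors from any pair of
reference speeds.

For the radar chart each index is drawn with radius $1 - \text{index}$ on
its own axis (wider polygon = better gesture), axes 72° apart in the fixed
order $(\alpha, \delta, \mu, \rho, \gamma)$ -- infringement right,
performance left. The synthesis score is $\epsilon = A / A_{\max}$ with $A$
the shoelace polygon area and $A_{\max} = \tfrac52 \sin 72°$ the unit
pentagon. Because the area depends on the axis order, the order is recorded
with every score. `best_admissible()` maximizes $\epsilon$ subject to
$\delta \le 0.4$ and $\alpha \le 0.4$ -- the best speed at which the
technique is still admissible.

## Camera benchmark and agreement

A 240 fps camera brackets each flight between
$\mathrm{LOGC}_{B,\min} = (FNC - FNB)/FR$ and
$\mathrm{LOGC}_{B,\max} = (FND - FNA)/FR$ (four annotated frame numbers
around toe-off and heel strike; the bracket is exactly $2/FR$ wide, clamped
at zero for sub-frame flights). The central estimate is the bracket
midpoint. Agreement statistics treat the camera as truth with **legal as
the positive class**: the false-alarm rate is $1 - TPR$ (legal steps
flagged), the miss-alarm rate equals $FPR$ (illegal steps passed). The
three-level comparison feeds per-class (recall, precision) points, plus the
anchor $(0, 1)$, into a trapezoidal precision--recall AUC. The fuzzy
comparison scores $\sigma = \eta - \lambda$ per item; $|\sigma| < 0.5$ is
acceptable and $\tau$ is the acceptable fraction ($|\sigma| = 0.5$ counts
as wrong, as published). Hedges' g (pooled SD, small-sample correction
$J = 1 - 3/(4N - 9)$) between the slowest and fastest speed groups gives
per-index weights $\kappa_i = |g_i| / \sum |g_i|$.

## The synthetic generator

No field recordings are distributed, so `generate_trial()` fabricates
trials with known ground truth: raised-cosine pulses (8 m/s² / 25 ms
half-width) in the anteroposterior channel at each heel strike, and dips
(gravity minus a 12 m/s² / 30 ms pulse) in the vertical channel placed at
$\mathrm{TOE} - E(SC)$, plus seeded Gaussian noise. Placing the dip at
$\mathrm{TOE} - E$ makes the timing model exactly invertible: a perfect
detector recovers the true flight time exactly, so recovery error isolates
detection and quantization effects. `generate_video_annotations()`
frame-quantizes the true events at 240 fps the way an annotator would
(last frame at or before toe-off; first frame strictly after heel strike),
which provably brackets the true flight time.

The generator emulates waveform landmarks, sampling, quantization and
sensor noise. It does **not** emulate soft-tissue artefacts, sensor
misplacement, asymmetric gait, cadence drift within a step, or bent-knee
infringements -- passing recovery tests on synthetic data therefore
demonstrates the correctness of the pipeline's arithmetic and detection
logic, not field accuracy on real athletes.

## Numerical choices

* *Filtering.* "Filtered twice" is implemented as one forward and one
  backward pass of the 4th-order Butterworth filter (zero net phase,
  squared magnitude). Edges are handled by odd-reflection padding sized
  from the filter's largest pole magnitude so the zero-state startup
  transient decays below $10^{-13}$ (about 100 samples at 20 Hz / 200 Hz);
  a fixed short pad leaves visible DC transients.
* *Peak gate.* Heel-strike candidates must clear
  `median + 5 * IQR` of the post-warm-up anteroposterior signal and be at
  least 0.25 s apart. The 5-IQR gate rejects noise-only maxima (Gaussian
  extremes reach ~2.7 IQR) while heel-strike pulses sit far above it; both
  knobs are configurable since peak detection is not prescribed by the
  published method.
* *Ties.* Flat minima/maxima resolve to the earliest sample.
* *Cadence gating* excludes individual steps outside [2.8, 4.0] steps/s
  (reported, with reasons) and never aborts a trial.
* *Warm-up.* The first 10 s of a trial (athlete still accelerating) are
  excluded before event detection.
* *Problem sizes.* Tests use 25--70 s synthetic trials (about 70--215
  steps) and 10 noise seeds, enough for the detection-rate and timing
  statistics to stabilize well below their asserted bounds.

## A worked example

```{r example, eval = FALSE}
library(logcwalk)

trial <- generate_trial(sim_spec(duration = 60, cadence = 3.2,
                                 flight_time = 0.045, noise_sd = 0.3))
res <- analyze_trial(trial$trace, trial$meta)
res
res$sequences[, c("sequence", "logct_seq_s", "logcc_seq", "label_threelevel")]

ann <- generate_video_annotations(trial$truth)
plot_radar(res$profiles[1, ])
```

## Known limitations

* The threshold model is calibrated on elite athletes; outside the valid
  cadence band the threshold is clamped, not extrapolated.
* Speed is an external input; errors in it propagate into SLR and
  smoothness (but not into timing or classification).
* Bent-knee infringements, left/right attribution and stance sub-phases
  are out of scope.
* The index normalization uses one set of anchors; per-event (20 km vs
  50 km, men vs women) calibrations would need different constants, which
  `calibration_constants()` accepts but does not provide.
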