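---
title: "Methods: markerless exergame kinematics and the Normalized Efficiency Index"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: markerless exergame kinematics and the Normalized Efficiency Index}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(exerkin)
```

## What the package computes

`exerkin` implements an analysis pipeline for exergame-based motor
monitoring in Parkinson's disease with markerless pose tracking. A webcam
front end estimates 33 skeletal landmarks per frame (MediaPipe Pose
topology) at a nominal 30 fps; each exergame trial is stored as one JSON
file holding the 3D world-coordinate trajectory of those landmarks plus
the game's event log. From these recordings the package derives:

1. **Motor functional parameters (MFPs)** — joint angles, ranges of
   motion, angular velocities, and bilateral Symmetry Indices — after a
   standardized signal-conditioning chain;
2. **Game-based metrics (GBMs)** — points, errors, pauses, completion
   times, key-press cadence, movement-validity share, peaks per minute —
   from the event log;
3. **Progression metrics** — per-subject maximum difficulty levels, the
   Percentage of Completion, and the Normalized Efficiency Index (NEI);
4. **Clinical validity statistics** — Spearman rank correlations of NEI
   against MDS-UPDRS Part III scores, independent t-tests, and a
   questionnaire domain analysis.

A synthetic-data generator produces trials and whole cohorts with known
ground truth so that every stage is testable without any recording.

## Signal conditioning

Each of the three coordinate components of each landmark is processed
independently, in this order:

1. **Median filter, window 8 samples.** Removes impulsive tracking
   outliers while preserving edges. The window is even, so a convention
   is required: the window at sample $i$ spans $[i-4,\,i+3]$ (left-heavy
   center) and the median of an even count is the mean of the two middle
   order statistics. Edges use nearest-value (replicate) padding, which
   never invents data beyond the recording. A short even window slightly
   flattens the extrema of smooth oscillations — about
   $A\,(1-\cos(2\pi f\,\delta))$ for a sinusoid of amplitude $A$ and
   frequency $f$, with $\delta \approx 2/30$ s — which is why recovery
   tolerances below are stated in absolute degrees.
2. **Cubic-spline resampling to 50 Hz.** An interpolating cubic spline
   (Forsythe–Malcolm–Moler end conditions, exact on polynomials up to
   degree 3) is evaluated on a uniform grid spanning exactly the first to
   the last timestamp; the grid size is chosen so the effective rate is
   as close as possible to 50 Hz while preserving both endpoints. Frames
   flagged as non-finite (tracking drop-outs) are retained on loading,
   excluded from spline construction, and re-created by the interpolant —
   loading never silently drops frames.
3. **Third-order low-pass Butterworth, 10 Hz cutoff.** Designed by
   bilinear transform with prewarping at the cutoff. Applied
   forward–backward by default (zero phase, no lag, effectively squared
   magnitude), because the analysis is offline and event alignment must
   not be shifted; a single causal pass is available
   (`zero_phase = FALSE`). Edge transients are controlled by
   odd-symmetric extension plus offset removal, so a constant series
   passes through bit-exactly (unity DC gain including the edges). The
   analytic gain of this digital filter at frequency $f$ is
   $\bigl(1 + (\tan(\pi f/f_s)/\tan(\pi f_c/f_s))^{2n}\bigr)^{-1/2}$
   (squared when zero-phase); `butterworth_gain()` exposes it and the
   test suite uses it as the oracle. At 15 Hz and $f_s = 50$ Hz this is
   0.146 per pass — noticeably stronger than the continuous-time value
   0.284, because the bilinear transform warps frequencies toward
   Nyquist. The 10 Hz cutoff retains the voluntary-movement band
   (≤ 2 Hz in all waveforms here) and, together with the median filter,
   suppresses the high-frequency interference band (> 7.5 Hz) by more
   than 95 % in power.

## Motor functional parameters

Angles are computed framewise from two body-segment vectors $v_1, v_2$ as
$\theta = \arccos\!\bigl(v_1 \cdot v_2 / \lVert v_1\rVert\lVert
v_2\rVert\bigr)$, clamped into $[-1, 1]$ before the arccos; results lie
in $[0^\circ, 180^\circ]$ and are invariant to positive scaling of either
segment. The default joint table (`default_joint_table()`) is a
provisional engineering choice, fully overridable per exergame profile:
arm elevation against the trunk's longitudinal axis, elbow angle between
upper arm and forearm, leg angle against the world vertical, knee angle
between thigh and shank, trunk angle between the pelvis–shoulder axis and
the world vertical (the world frame is right-handed, y-up, meters).

For every bilateral parameter $P$ the **Symmetry Index** is
$\mathrm{SI} = \lvert P_R/P_L - 1\rvert$: 0 means perfect bilateral
symmetry. The denominator is the left side by definition, so SI is not
invariant under swapping sides (SI(3,2) = 0.5 but SI(2,3) ≈ 0.33); it is
invariant under common positive rescaling.

Trial-level summaries reduce each angle series to one number. The
reductions are not uniquely determined by the reported tables, so the
package fixes and documents them: bilateral angles are the mean over
sides of per-repetition maxima; trunk angle is the series mean (mean
deviation from vertical); ROM is the mean over sides of per-repetition
max−min; velocity is the mean over sides of per-repetition peak absolute
angular speed (central differences on the 50 Hz grid). Angular rather
than linear velocity is reported (`ARM_VEL`, deg/s); the profile
configuration is the place to change that if linear end-point speed is
wanted instead.

**Repetition segmentation** finds local maxima of the game's driving
angle with a minimum topographic prominence (default 10°, so sub-degree
jitter never splits repetitions) and minimum separation (default 0.4 s,
i.e. repetition rates up to 2.5 Hz); when two candidates are too close
the higher peak wins. With fewer than two peaks, summaries fall back to
the whole series.

Per-game MFP sets: AIRPLANE `ARM_ANG, ELB_ANG, ARM_SI, ELB_SI, T_ANG`;
SKI `LEG_ANG, KNEE_ANG, LEG_SI, KNEE_SI, T_ANG`; PIANO `ARM_ANG, T_ANG`;
GYM `ROM_ANG, ARM_VEL, ANG_SI, VEL_SI`.

## Game-based metrics

`TIME` is the wall-clock trial duration (last event or frame minus first
frame) with pauses *included*; whether the study's completion times
exclude paused intervals is not documented, so the pause-adjusted value
is exposed separately as `TIME_ACTIVE` rather than silently substituted.
`KEY_TIME` is the mean interval between consecutive key presses (PIANO);
`MOV_OK` the percentage of valid movements among movement events,
reported missing when no movement events exist; `PPM` the repetition-peak
count scaled to a per-minute rate (GYM). `POINT` is a generic count of
point events — the game-specific meaning (targets hit, gates passed)
lives with the event producer. Per-level summary tables report MFPs as
mean ± sample SD and SIs/GBMs as means only, with `n_trials` conserved.

## Progression and the Normalized Efficiency Index

For each subject and game, the progression record is the maximum level
over completed trials and the earliest session achieving it. The
**Percentage of Completion** normalizes across games with different level
counts: $C = 100\,\cdot\,\text{max level} / \text{theoretical max}$. The
per-game **NEI** is

$$\mathrm{NEI} = \frac{C_{MAX}^2}{100 \cdot S_{TARGET}} \in [0, 100],$$

where $S_{TARGET} \in \{1..10\}$ is the session of first achievement.
The quadratic numerator prioritizes full mastery over rapid partial
progression: reaching 50 % in session 1 scores the same (25) as full
mastery in session 4. `NEI_TOT` is the sum over the four games
($[0, 400]$), asserted additive on every result.

Choices the published material leaves open, fixed here:

* **Theoretical maxima** default to the study protocol's observed level
  ranges — Airplane 8, Ski 11, Piano 2, Gym 3 — and are overridable
  everywhere, since the platform is parametric. Levels bypassed by the
  clinical team still count toward the maximum; only the highest
  achieved level enters $C_{MAX}$.
* **Gym direction combination.** The two Gym directions report one
  combined game: the per-session combined level is the minimum over the
  directions recorded in that session (a level only counts once both
  directions reach it), and max/first-session extraction runs on that
  combined series.
* A subject stuck at level 0 gets $C_{MAX} = 0$, hence NEI = 0 with
  $S_{TARGET} = 1$.
* A game with no trials is an error by default; `missing_as_zero = TRUE`
  scores it 0 for incomplete cohorts.

## Statistics

Spearman correlations are computed as the Pearson correlation of
average-rank transforms — the definition itself, kept explicit so tie
handling is pinned down — with a two-sided p-value from the
t-approximation $t = \rho\sqrt{(n-2)/(1-\rho^2)}$; an exact permutation
p-value is available for $n \le 8$ (exhaustive enumeration; beyond that
the t-approximation is the appropriate tool at the cohort sizes
involved). Pearson level-vs-score correlations use per-level means, which
is how the summary tables print them. Independent t-tests default to
Welch's unequal-variance form (robust to the unequal cell sizes of the
per-level tables); the pooled form is a flag. Outlier handling is an
explicit exclusion list recorded in every result — the re-analysis
without an incongruent subject is the same operation with a different
list, and an empty list changes nothing. Raw p-values are reported
without multiple-testing correction, matching the reporting style of the
target analyses; `stats::p.adjust` can be applied downstream if wanted.

Questionnaire analysis reports per-item cohort means ± SD, session-trend
means over a positional tertile partition of each subject's attended
sessions (initial/intermediate/final; the middle bucket absorbs the
remainder, so 10 sessions split 3/4/3 and every session lands in exactly
one bucket), and Spearman correlations of per-subject mean item scores
against NEI_TOT.

## The synthetic-data generator

The generator is first-class, tested code: it defines the conditions
under which the pipeline's recovery properties are demonstrated.

**Trials.** A fixed 33-landmark articulated stick model with
anthropometric segment lengths performs one kinematic archetype per game:
sinusoidal trunk sway with a static T-pose (AIRPLANE), seated antiphase
knee flexion (SKI), rhythmic arm elevation with key presses at the peaks
(PIANO), and bilateral arm raises in the sagittal or frontal plane (GYM;
ALT antiphase, SING/SIM in phase). Only landmarks used by the joint
table move with full fidelity; face, hands, and feet ride rigidly on
their parent segments. The noise-free joint-angle series are returned as
a ground-truth channel and are recoverable by the kinematics module to
better than $10^{-6}$ degrees; the right/left amplitude ratio $r$
surfaces as an amplitude-type SI of exactly $\lvert r-1\rvert$. Default
waveform frequencies (0.2–0.4 Hz) and amplitudes sit in the ranges the
per-level tables report for the corresponding parameters. Noise defaults
(3 mm jitter, 0.2 spikes/s of 15 cm, 4 mm band at 12 Hz) are engineering
choices; the interference band is placed above the 10 Hz cutoff because
that is the band the conditioning chain is designed to remove, and the
suppression property is asserted against it.

**Cohorts.** Each of `n_subjects` gets an impairment score $u \in
[0, 1]$ (uniform by default — deliberately wider than a typical
mild-to-moderate clinic cohort so recovery is demonstrated across the
whole range). Attendance follows the study pattern (≈70 % attend all 10
sessions, the rest 7 or 5). The progression link is monotone by
construction: expected first-mastery session
$s^\* = 1 + \lfloor u \,(\text{max sessions} - 1)\rfloor$ plus rounded
Gaussian noise, and the level schedule in session $s$ is
$\lfloor M \min(s/s^\*, 1)\rfloor$. A subject whose $s^\*$ exceeds their
attendance simply never reaches the maximum — the schedule is truncated,
not accelerated, which keeps the link monotone across subjects with
different attendance. Simulated MDS-UPDRS sub-items rise with $u$
through staggered per-item difficulties (offset so cohort totals sit in
a clinically plausible range); questionnaire answers are positively
(well-being, satisfaction, usability) or negatively (fatigue) linked to
$1-u$; lateral Gym raises are executed with 85 % of the frontal
excursion, planting the direction effect the t-test layer is meant to
detect. All randomness flows from one master seed; every trial records
its derived seed so any single trajectory can be re-materialized.

**What the generator does not emulate** — and hence what passing tests
do *not* show about real data: real pose-estimation error is neither
white nor stationary (it correlates across landmarks, worsens with
self-occlusion and clothing, and depends on pose); soft-tissue and
perspective effects are absent; movement waveforms are exactly periodic;
medication on/off cycles are not modeled, so the wearing-off
incongruence pattern can only be reproduced by construction, not
emergent; and the impairment→UPDRS link is far cleaner than clinical
reality. The tests demonstrate correctness of the computations under
controlled conditions, not clinical validity.

## Numerical choices and problem sizes

Recovery tolerances: ROM within 1° at amplitude 50° (dominated by the
even-window median flattening described above, which is why low waveform
frequencies are the default), amplitude-SI within 0.02 at $r = 1.2$
(ratios are insensitive to the common flattening factor), tremor-band
power suppression ≥ 95 %, filter gains within 2 % of the analytic
response. The planted-signal recovery check uses a noiseless link at
$n = 200$ subjects, where the NEI_TOT-vs-UPDRS Spearman correlation is
required to reach $-0.95$ or stronger; the residual distance from $-1$
comes from rank ties in both coarsely discretized scores. Analysis
scripts materialize trajectories for a six-subject subset with 8-second
trials, and the suite's simulated trials are 4–20 s — sizes chosen so
the full analysis re-runs in minutes on a laptop while every property is
still exercised; none of the estimators depends on these sizes.

## Known limitations

The default joint table approximates the deployed games' segment choices
and should be re-derived from the game configuration before ingesting
real recordings; the JSON schema is this package's own (a mapping layer
is expected for externally produced files). SI is undefined when the
left-side parameter is zero and is reported as an error rather than a
number. The per-level Pearson correlations operate on level means, so
their p-values reflect the number of levels, not the number of trials.
The NEI treats session indices as the only time base; calendar spacing
between sessions is ignored.
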