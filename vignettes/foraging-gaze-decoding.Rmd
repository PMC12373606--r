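---
title: "Decoding search conditions from eye and head movements: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding search conditions from eye and head movements: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gazeforage)
```

# The analysis problem

In head-mounted-display (HMD) foraging search, a standing observer scans a
frontal 180-degree scene containing 12–18 camouflaged targets and 12
distractors, shooting targets under one of four conditions crossing target
discriminability (Easy/Hard) with time pressure (45 s Low / 18 s High
limits). The HMD records the eye-in-head direction as a unit vector at
120 Hz (with pupil diameter as a validity signal) and the head orientation
as yaw/pitch/roll at about 90 Hz. `gazeforage` turns those raw streams into
trial-level evidence about the task the observer is performing: it detects
saccades, fixations, head movements and head fixations, computes a
76-feature movement battery and behavioural performance measures, and asks
how well a classifier can decode the condition of a single trial from its
features.

Because no public recording of this task exists, the package ships a
synthetic session generator with exact ground truth. The generator is a
first-class, tested component: it defines the study conditions under which
every claim made by the test suite holds.

# Pipeline

## Validity and gap repair

A sample is *valid* iff its pupil diameter is strictly positive. Maximal
invalid runs strictly shorter than 50 ms are filled by linear interpolation
of the eye direction between the flanking valid samples (renormalized to
unit length) and marked usable; runs of 50 ms or longer are masked together
with 2 samples on each side. Runs touching a trial boundary have no flank
and are always masked — the pipeline never extrapolates. Gap durations are
counted as samples divided by the sampling rate, so at 120 Hz a 5-sample
(41.7 ms) run is repaired and a 6-sample (50 ms) run is masked.

## Timebase alignment

Eye (120 Hz) and head (~90 Hz) streams are resampled onto one uniform clock
(default 120 Hz) spanning their overlap: eye directions by spherical linear
interpolation, head angles linearly. A resampled point is usable only if
both flanking source samples are usable. Internally everything lives in a
single right-handed frame (+X right, +Y up, +Z forward); the recorded eye
stream's +X-left axis is negated on ingest and recorded head pitch
(positive down) becomes elevation (positive up), so per-axis features share
sign conventions across effectors. Axis naming for features follows the
usual rotational convention: X = pitch, Y = yaw, Z = roll.

## Derivatives

Velocities are finite differences — central where possible, one-sided at
usable-span edges — without smoothing. We considered a pre-threshold
moving-average window (common in velocity-threshold detector lineages) and
decided against it: the synthetic trajectories are minimum-jerk smooth, so
smoothing would only bias peak velocities downward, and on real data the
choice should be the caller's preprocessing step, not a hidden default.
Acceleration and jerk are repeated first differences, with the usable mask
eroded once per order so no derivative ever straddles a masked span.

Per-axis *eye* velocities are the time-derivatives of the three components
of the eye-direction unit vector, scaled by 180/π; the norm of that vector
is exactly the total angular speed in deg/s, and all three components carry
signal (an angle parameterization would leave a torsion axis identically
zero). Per-axis *head* velocities are derivatives of the pitch/yaw/roll
angles, and total head speed is the rotation angle between consecutive
orientations (via quaternions) times the sampling rate.

## Event detection

**Saccades.** Each participant gets an adaptive elliptical velocity
threshold: the mean and standard deviation of each velocity component over
all of that participant's usable samples, with radii at six standard
deviations; a sample is supra-threshold iff
$\sum_i ((v_i-\mu_i)/(6\sigma_i))^2 > 1$. For isotropic Gaussian noise the
exceedance probability is the $\chi^2_3$ tail beyond 36, below $10^{-7}$ —
the threshold only fires on genuine dynamics. Degenerate axes are floored
at $\sigma = 0.1$ deg/s with a warning. Maximal supra-threshold runs of at
least 12 ms become candidates; amplitude is the great-circle angle between
the eye directions at onset and offset (not path length), and peak velocity
the maximum total angular speed inside the run. Candidates longer than
120 ms, with peak velocity below 25 or above 1000 deg/s, or with amplitude
of 1 degree or less are removed as biologically implausible, each removal
logged with its reason. The threshold is computed per participant, not per
trial: trial-level estimates would be noisy and would let trial content
shift the detection criterion.

**Fixations** are maximal fully-usable inter-saccade intervals of at least
75 ms. Detection runs on the eye-in-head signal; object labeling uses gaze
(eye plus head) through the per-sample gazed-object column, with each
fixation labeled target/distractor/none by the modal label over its samples
and ties resolving to none. Interpolated (short-gap) samples count as
usable and may lie inside events.

**Head movements** use a sliding-window rule on total head speed with a
fixed 6 deg/s threshold: onset requires a 100 ms window with at least 72%
of samples supra-threshold and no 3 consecutive sub-threshold samples, and
is placed at the window's first supra-threshold sample; offset comes from
the first subsequent 22 ms window with at least 72% of samples below
threshold, at its first sub-threshold sample. Windows slide one sample at a
time and are rounded to the nearest sample count at the working rate.
Movements with amplitude of 1 degree or less are removed; **head
fixations** are the complement intervals of at least 75 ms. The head
threshold is fixed, not participant-adaptive — head speed has a hard floor
of stillness, unlike the eye's continuous noise.

## The feature battery

Each trial yields 76 named features — 45 eye and 31 head — normalized by
trial duration wherever a count or sum would otherwise scale with trial
length:

* **Fixation (13)** — frequency, average duration and duration proportion,
  overall and for target/distractor subsets; fixations per available
  target/distractor; and two target-preference ratios, one count-based
  (target fixations over other fixations, denominator floored at 1) and one
  duration-based (denominator floored at one minimum fixation duration,
  75 ms). The enumerable battery otherwise yields 44 eye features; the
  duration-based ratio is the 45th, and `ratio_mode` switches the
  denominator to distractor-only fixations if preferred.
* **Saccade (5)** — frequency, average size, summed size per second, and
  average size of saccades landing on targets and on distractors. A saccade
  inherits the object label of the immediately following fixation ("size of
  a saccade *to* a target" presupposes a destination).
* **Eye-head coordination (3)** — mean eye-in-head eccentricity; global eye
  movement per second (total angular path length over usable sample pairs,
  independent of event classification); and the mean eye contribution to
  the gaze angle, `eye/(eye+head)` with both angles measured from the
  forward reference and samples where both are under 0.5 degrees skipped.
* **Kinematics (24 per effector)** — mean and SD of absolute velocity,
  acceleration and jerk, overall and per axis. Absolute values are used
  because signed per-axis means vanish by symmetry and would carry no
  information; the ambiguity is noted, and a signed variant would be a
  one-line change in `kinematic_features()`.

Averages over empty subsets (e.g. no distractor fixations in a trial)
default to 0 so the matrix stays dense for the classifier; `empty = NA`
leaves them missing instead, for workflows that prefer explicit
missingness.

## Behavioural measures

Completion time is scene onset to button press or time limit, whichever is
first. Inter-target time is the mean interval between successive target
hits (undefined below two hits, excluded downstream). Sensitivity is
$d' = \Phi^{-1}(H) - \Phi^{-1}(FA)$ with the log-linear correction (0.5
added to each cell, 1 to each denominator) so extreme rates stay finite; a
half-count rule is available. Shots at the background count toward neither
hits nor false alarms — false alarms are distractor hits only.

## Classification suite

Seven models: a 4-way condition model (Easy-Low/Easy-High/Hard-Low/
Hard-High) for each feature set (eye+head, eye-only, head-only), and 2-way
discriminability and pressure models for eye-only and head-only.

Each model first runs **shadow selection**: 50 random-forest iterations, in
each of which every feature is paired with a shuffled copy and scores a hit
when its impurity importance beats the maximum shadow importance; features
whose hit counts beat a Binomial(50, ½) null one-sided at α = 0.05 with a
Bonferroni adjustment across the feature set are selected, and undecided
features are dropped. The adjustment follows the canonical shadow-selection
implementations; without it, in-sample chance associations of a fixed
dataset accumulate hits across iterations (the shadows are re-shuffled
every iteration, a lucky real feature is not) and the null selection rate
inflates. Even adjusted, a dataset whose labels happen to correlate with
some feature at in-sample p ≈ 0.005 will — correctly, from the selector's
viewpoint — yield a selection; on shuffled-label fixtures with 25 features
this happens in roughly one shuffle in ten. The selected features go into
a pipeline of standard scaling and an RBF-kernel SVM (cost 1, kernel width
1/(d·Var) of the scaled training data — the no-tuning defaults, since
nothing suggests a hyperparameter search) under stratified 10-fold
cross-validation, with scaling fit on training folds only. Folds are
stratified over pooled trials rather than grouped by participant — the
suite estimates a generalized, cross-participant decoder; a group-aware
split is a caller-level change of `stratified_folds()` and would carry its
own caveats about participant identity leakage, which are worth stating:
pooled folds let the model exploit participant idiosyncrasies shared
between folds.

Accuracies are compared to chance (0.25 or 0.5) by a two-sided one-sample
Wilcoxon signed-rank test, exact at n = 10 folds when fold accuracies are
distinct (ties force the standard normal approximation; all ten folds on
one side of chance give exactly p = 2/1024 ≈ 0.002). Effect sizes are
Hedges' g — the bias-corrected standardized mean difference, with the exact
gamma-function correction factor (0.9228 at n = 10). Model pairs are
compared by paired Wilcoxon tests on fold accuracies with Holm's step-down
correction within each family (the three 4-way models; the four 2-way
models); all models of a label scheme share one fold-partition seed so the
pairing is meaningful. Feature rankings use a Monte-Carlo permutation
Shapley approximation evaluated on a stratified 20% subset: features are
revealed in random order against a shuffled-background copy, and the change
in the model's decision-value score for each sample's predicted class is
credited to the revealed feature; ranking is by mean absolute attribution.
Exact Shapley values would need $2^d$ coalitions; with shared random
orderings the estimator is deterministic given its seed and splits credit
between duplicated features, which the test suite checks.

# The synthetic generator

## What it emulates

Scenes draw 12–18 targets (uniform) and 12 distractors uniformly within
the frontal 180 degrees at 10–100 m. A trial is a scanpath of alternating
fixations and gaze shifts: onset-to-onset intervals are lognormal with mean
1/`saccade_rate` (so the configured rate is honored even though head
recruitment stretches individual movements), gaze-shift amplitudes are
gamma-distributed (right-skewed, like empirical amplitude histograms), and
movement trajectories are minimum-jerk ramps so velocity, acceleration and
jerk are all finite, smooth and non-degenerate. Saccadic peak velocity
follows a saturating main sequence
$V_p = V_{max}(1 - e^{-A/A_0})$ (defaults 600 deg/s and 14 deg), with the
minimum-jerk identity $D = 1.875\,A/V_p$ fixing the duration; durations are
capped at 118 ms so every injected event passes the plausibility filters.

When a gaze shift would push the eye beyond the head-recruitment
eccentricity (condition knob, ~12–18 deg), the head carries the remainder:
the eye saccades to a "parked" eccentricity of 4–12 deg and a concurrent,
slower head movement (its own main sequence, defaults 260–300 deg/s and
25 deg) completes the shift, keeping eye-in-head within roughly ±15 deg. If
the eye's share would be tiny (below `min_saccade_deg`) the shift becomes
head-only with the eye stable in the head. Engagement is probabilistic:
fixated unshot targets are shot with `hit_p`, distractors with `fa_p`;
when no fresh target is reachable at the drawn amplitude the scanpath
pursues the nearest remaining one, so easy low-pressure trials genuinely
finish by button press (about 97% of Low trials end by button; a
substantial share of High trials time out). Scanning continues through the
post-completion decision delay. Dropouts set the pupil to zero over random
intervals. Participants get lognormal tendency multipliers (drawn once per
participant) on rate, amplitude, head recruitment and head speed — the
"head-mover" axis of individual variation.

Ground truth records every injected saccade and head movement with exact
times. For head movements it also records when the injected speed profile
crosses 6 deg/s (closed form for a minimum-jerk profile), because for
threshold-based head classifiers that crossing *is* the onset definition;
recovery is measured against it.

## Condition defaults

The four cells shift parameters in the directions established for foraging
under discrimination difficulty and time pressure: Hard slows the scan
(rate 2.2→1.9 Hz within Low), shrinks amplitudes, multiplies distractor
refixations (0.15→0.45), and lowers hit while raising false-alarm
probability; High pressure speeds the scan (up to 2.9 Hz), enlarges
amplitudes, recruits the head earlier and moves it faster, and trades
accuracy for speed. Head-parameter separations are kept milder than the
eye ones so that — as in real data — eye features carry more decodable
information than head features, while head features still add some. These
defaults were fixed once, from these qualitative constraints, before the
acceptance suite existed, and are not tuned to any test.

A **null configuration** gives all four cells identical parameters (18 s
limits everywhere), making every feature's distribution label-independent
by construction — the chance-calibration fixture. That fixture is generated
with the per-participant tendency multipliers switched off, so its trials
are exchangeable: it isolates the *classifier's* calibration. With
participant clustering left on, pooled stratified folds sit measurably
below chance on null data, because each participant's per-fold label
composition anti-correlates with their training composition — the
cluster-level analogue of the classic cross-validation imbalance pessimism
(see Limitations). A **clean configuration**
(zero jitter, no dropouts, sparse 0.5 Hz scanning, amplitudes 10–28 deg,
fast dynamics: 900 deg/s, $A_0 = 10$) exists for detector validation: on
noise-free data the 6σ threshold's variance comes entirely from the
saccade samples themselves, so the threshold scales with the *rms* injected
velocity, and only a sparse, high-velocity, narrow-amplitude regime keeps
every injected event comfortably supra-threshold with crossing delays under
one sample. That is a validation fixture, not a realistic session; the
study conditions use realistic rates and accept that small saccades fall
below the adaptive threshold, exactly as they do in practice.

## What it does not emulate

No 3-D rendering, occlusion, lighting or camouflage imagery — the
gazed-object label is generated directly (nearest object within a 2-degree
acceptance cone of gaze), standing in for an engine ray-cast, and is part
of the input contract. No torso, no ambulation, no vestibulo-ocular
counter-rotation (during head-only shifts gaze rides the head; eye-in-head
stays constant rather than counter-rolling), no smooth pursuit, no
microsaccades or fixational drift beyond white angular jitter, and constant
3 mm pupil outside dropouts. Passing tests therefore certify the pipeline's
arithmetic and detector logic under the stated kinematic model — they do
not certify detector performance against real HMD noise, slippage or
blink dynamics.

# Numerical choices and degenerate inputs

* "Under 50 ms" is read strictly: a 50 ms gap is masked.
* Event durations count samples over rate, so a 2-sample run at 120 Hz is
  16.7 ms and survives the 12 ms floor while a 1-sample run does not.
* σ floor 0.1 deg/s on the threshold ellipse; warned, never silent.
* Empty event sets yield empty tables, not errors; a trial with no saccades
  produces one trial-long fixation and zeroed saccade features.
* The interpolation of eye directions is linear with renormalization;
  spherical interpolation is used only at resampling, where neighbouring
  samples are close enough that the two agree to first order.
* All randomness flows through explicit integer seeds; every generator,
  selection, fold-partition and ranking function is bit-reproducible given
  its seed and restores the caller's RNG state.

# Problem sizes used by the test suite

The shipped tests run the pipeline at the scale the claims require:
detector recovery on 30 clean trials (~650 saccades, ~370 head movements),
chance calibration on a 2000-trial null dataset (25 participants × 20
trials per cell at 18 s limits) with ten fold-partition seeds, and effect
recovery on a 2400-trial study (30 participants × 20 trials per cell)
through the full seven-model suite. The acceptance script reproduces the
suite on a 384-trial study (12 participants × 8 per cell), which keeps the
whole script within a few minutes while leaving all seven models clearly
above chance.

# Known limitations

* The generator's condition effects are larger and cleaner than human
  effects; decoding accuracies on synthetic studies should not be compared
  numerically with accuracies on real recordings.
* Pooled-trial folds measure a generalized decoder, not subject-held-out
  generalization. On *null* data with participant clustering they are also
  slightly anticonservative below chance (about two accuracy points in our
  2000-trial null runs): a participant's trials of a given label that land
  in the test fold are exactly the ones missing from that participant's
  training trials, so a cluster-memorizing model anti-predicts the held-out
  labels. Group-aware splits remove both issues at once.
* The head-only gaze-shift mode replaces vestibulo-ocular dynamics; on real
  data, compensatory eye-in-head rotation during head movements can be
  misclassified as saccades by any velocity-threshold detector, and this
  failure mode is deliberately absent from the synthetic fixtures.
* The Shapley approximation ranks features; its absolute attribution values
  depend on the background distribution and the decision-value scale and
  should not be interpreted as calibrated contributions.
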