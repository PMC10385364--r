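---
title: "Assessing fall risk from a waist-worn inertial sensor: models, parameters and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing fall risk from a waist-worn inertial sensor}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`tugfall` turns a six-axis inertial recording of an instrumented, modified
Timed Up and Go (TUG) test — 30 s of quiet standing, an audio cue, a 3 m
walk, a pause, a turn merged with sitting down, a pause, standing up, and
the walk back — into ten balance, gait and functional features, assesses
their test-retest reliability, and classifies fall-risk severity into two
(faller / nonfaller) or six ordinal levels, either from the features or
directly from the raw signals with a two-branch convolutional + LSTM
network. Because no public recording of this protocol exists, the package
ships a scripted trial simulator with exact ground truth; every processing
stage is validated by parameter recovery against that truth.

## The signal chain and its assumptions

The device is worn at the waist, close to the body's centre of mass (CoM),
with (by default) x = medial-lateral (ML), y = vertical (V),
z = anterior-posterior (AP); the axis map is configurable because handsets
differ. The chain is:

1. **Uniform resampling** (linear interpolation to 100 Hz). Linear
   interpolation is exact for locally affine signals and robust to the
   modest timestamp jitter phones produce.
2. **Zero-lag low-pass filtering**, 4th-order Butterworth at 20 Hz. The
   filter is realised spectrally: the analytic forward-backward cascade
   magnitude $|H(f)|^2 = 1/(1+(f/20)^8)$ is applied to the FFT of the
   odd-reflection-padded signal. This has exactly zero phase and matches
   the analytic response at every frequency, including near Nyquist where
   recursive bilinear designs deviate from the analog prototype.
3. **Orientation estimation** by a quaternion complementary filter: the
   gyroscope is integrated sample by sample and the inclination is nudged
   toward the measured gravity direction. Two choices matter:
   - the correction gain is 0.002 per step (a ~5 s time constant at
     100 Hz). A fast gain (e.g. 0.02, τ ≈ 0.5 s) *cancels genuine sway*: an
     oscillating horizontal acceleration looks like an oscillating tilt,
     and the filter tracks $1/(1+j\omega\tau)$ of it, removing
     $|1 - 1/(1+j\omega\tau)| \approx 18\%$ of the sway band. At τ = 5 s
     the in-band loss is below 1%, while the initial inclination still
     comes instantly from aligning the first accelerometer sample with
     gravity.
   - the correction is *gated*: it is applied only where the accelerometer
     norm has stayed within 0.15 m/s² of g for 0.3 s. During walking and
     transitions the specific force is dominated by linear acceleration;
     correcting there tilts the estimate and leaks gravity into the
     horizontal channels for seconds afterwards.
   Yaw is unobservable from the accelerometer and follows the integrated
   gyroscope alone; all yaw-based logic uses yaw *rate*, which is immune
   to slow drift.
4. **World-frame projection**: device acceleration rotated by the
   estimated quaternion, gravity subtracted, horizontal axes re-anchored
   to the mean heading of the first standing second.
5. **Frequency-domain double integration** to displacement: the spectrum
   is divided by $(i 2\pi f)^2$ and all bins below a cut-off are zeroed,
   which removes the free constants of integration and the cumulative
   drift a time-domain integrator accrues. Integration is done *per phase
   window* (with a short cosine taper on the window edges) rather than
   over the whole trial, so that spectral leakage from large events — the
   3 m walking translation above all — cannot bleed into other phases.

### High-pass cut-offs per band

The drift-removal cut-off is a genuine tuning parameter and is set per
feature band:

| band | window | cut-off | why |
|---|---|---|---|
| balance (APDisp, MLDisp) | 30 s standing | 0.3 Hz | sway is designed/observed at ≥ 0.45 Hz; a 30 s window resolves 0.3 Hz cleanly |
| gait (VRange, MLRange) | bout ± 0.5 s (≈ 4.5–7 s) | DC bin only | the ML stride sway sits at 0.7–1.1 Hz, within an octave of a 0.5 Hz cut; removing resolvable low bins strips real envelope sidebands that the $1/\omega^2$ weighting amplifies and inflates the excursion by 5–11%. A window this short cannot resolve sub-0.2 Hz drift in any case, so only the DC (mean) bin is removed. |
| transitions (PTurnSit, PStand) | t2 → t7 (≈ 8–12 s) | 0.02 Hz | a sit or stand is a *low-frequency step* in vertical position; cut-offs of 0.3–0.5 Hz destroy 35–90% of its max–min excursion, while 0.02 Hz removes only DC/drift and recovers the designed excursion exactly |

The trade-off of the low cut-offs is noise: very-low-frequency
accelerometer noise is amplified by $1/\omega^2$, which adds a few percent
of scatter to the affected features at realistic noise levels (0.02–0.05
m/s²). That scatter is part of the measurement error the reliability
statistics quantify.

## Segmentation

The nine protocol instants t0…t8 are found from three signal families:
the AP acceleration envelope (gait onset t1, bout boundaries t2, t7, t8),
the yaw-rate pulse (turn start t3, taken as the *start* of the yaw ramp,
located by walking outward from the peak |yaw rate|), and the two vertical
acceleration transients between the bouts (sit completion t4, stand
interval t5–t6). Two envelopes are used per channel: a moving maximum of a
4 Hz re-filtered copy for *detection* (robust to broadband noise; movement
content lives below ~2.5 Hz), and a moving maximum of the raw signal for
*edge refinement*, whose only edge effect is a deterministic half-window
shift that is subtracted out. Detection thresholds are `mean + 4·SD` of
the pre-cue standing baseline (`k_sd = 4`, hold 0.1 s, both configurable);
edge floors are the larger of 2% of the region's peak and 1.8× the quiet
floor of the envelope (its 25th percentile over the searched span). The
ordering invariant t0 < cue ≤ t1 < t2 ≤ t3 < t4 < t5 < t6 ≤ t7 < t8 is
enforced after every segmentation; violations are structured errors naming
the offending pair.

## The ten features

With phases in hand (all intervals half-open, seconds from trial start):

* **APDisp, MLDisp** (mm): 90th percentile of |CoM displacement| per
  horizontal axis over quiet standing, from windowed double integration
  scaled by the inverted-pendulum ratio CoM-height/sensor-height
  (defaults 0.55/0.53 of stature: quiet standing approximated as rotation
  about the ankles). The percentile is computed on the window interior
  (1st to 29th second) to keep taper edges out of the statistic.
* **VRange, MLRange** (mm): max–min of the vertical / ML displacement per
  walking bout, averaged over the outbound and return bouts.
* **PTurnSit, PStand** (W): $m \, g \, |\Delta h| / \Delta t$ with
  $\Delta h$ the vertical CoM excursion inside the transition interval and
  $\Delta t$ its duration.
* **APJerkSit, APJerkStand** (m/s³): max–min of the central-difference
  jerk of the AP acceleration inside each transition.
* **Reaction_Time** (s): t1 − cue time.
* **Total_Time** (s): (t2−t1) + (t8−t7) + (t4−t3) + (t6−t5); pauses are
  excluded by construction.

## The trial simulator

The simulator scripts the protocol from closed-form smooth primitives:
sway as two sinusoids per horizontal axis (primary frequency ~0.45 Hz plus
a 15% second harmonic) fading out shortly before the cue (anticipatory
stiffening, which also gives the reaction-time detector a quiet
background); walking bouts as windowed sinusoids (vertical and AP at step
frequency, ML at stride = half step frequency with ~1 s build-up) plus a
3 m quintic-smoothstep translation; sit/stand as quintic vertical steps
with Hann-windowed AP bursts; the turn as a 180° quintic yaw ramp at the
start of the sit. All tracks are C²-continuous, differentiated to
acceleration, rotated into the device frame by the scripted yaw, with
gravity on the device vertical and white noise on top. Ground truth
(phase times and the feature values implied by the designed tracks) is
computed at simulation time from the same definitions the extractor uses.

Six canonical risk-level profiles interpolate from "very low" to "very
high" risk, with trends in the physiologically expected direction (higher
risk: more sway, slower and flatter gait, longer walks, weaker and slower
transitions, smoother transitions, longer latencies). A cohort draws each
participant's profile around their level's mean with a ~5% multiplicative
random effect shared across repetitions, plus ~3% repetition-to-repetition
variation, so repetitions correlate and ICCs land in a realistic high
band. These numbers are design choices, not estimates: the study this
emulates reports no distributional description of its signals, so cohort
means are only loosely comparable and are not treated as recoverable
targets.

What the simulator deliberately does not model: soft-tissue artefact,
gyroscope bias and scale error, multi-segment kinematics (the trunk stays
upright except for yaw), irregular stepping, fall events, or
device-dependent axis misalignment. Passing the recovery suite therefore
shows the *pipeline* is correct and well-calibrated on signals whose
generative structure matches its assumptions — not that the features are
accurate on arbitrary real-world recordings.

## Statistics

Test-retest reliability uses the two-way random-effects, absolute
agreement intraclass correlation. The single-measure form is

$$ICC(2,1) = \frac{MS_R - MS_E}{MS_R + (k-1) MS_E + \tfrac{k}{n}(MS_C - MS_E)}$$

from the subject × repetition ANOVA mean squares, with the Shrout–Fleiss
F-based 95% interval. Because the average-of-repetitions reading of the
coefficient is also defensible for this design, the average-measure form
ICC(2,k) is computed alongside and both are reported; the single-measure
form is primary. Group differences use the pooled-variance Student t-test
on per-participant averages, preceded by Shapiro–Wilk normality and
(mean-centred) Levene homoscedasticity checks at α = 0.05; no
multiple-testing correction is applied, matching the analysis this
pipeline mirrors.

## Classification

The feature route standardises the ten features (mean 0, SD 1 on the
training split), prunes them by recursive feature elimination to at most
six (one feature removed per step, ranked by the model's own importances
where available — coefficients, Gini, gain — and by a multinomial-logistic
surrogate otherwise), and fits one of fifteen families: logistic
regression, ridge, lasso, k-nearest neighbours, naive Bayes, LDA, decision
tree, perceptron, multilayer perceptron, a linear hinge-loss SGD
classifier, gradient-boosted trees (two configurations, shallow/slow and
deep/fast), an RBF support vector machine, random forest, and multiclass
AdaBoost (SAMME over depth-1 stumps). Evaluation: stratified 80/20 split
(optionally group-aware, keeping a participant's repetitions on one side —
measurement-level splitting risks repetition leakage and both modes are
provided), repeated stratified 10-fold CV with 10 repeats (exactly 100
fold evaluations) inside the training split, and test-set accuracy,
G-mean (geometric mean of per-class recalls) and F1 (binary F1 on the
faller class; macro-averaged for six classes).

The raw-signal route feeds two branches: 64-sample windows of the six
filtered device channels (stride 32 by default), and the log-magnitude
STFT of the 384-sample channel concatenation (frame 20, step 2, yielding a
183 × 11 image; rectangular frames by default, Hann optional; ε = 10⁻⁶
inside the logarithm). Branch 1 stacks four 1D convolutions
(64/128/512/1024 filters, kernel 3, ReLU, dropout), two LSTM stages
(128/64 units) and three dense stages (256/128/64); branch 2 stacks three
3 × 3 2D convolutions (32/64/64 filters, dropout, 2 × 2 max pooling); the
concatenated features pass through 128- and 64-unit dense layers to a
softmax over 2 or 6 classes. Training is Adam on categorical
cross-entropy, batch 32, 100 epochs. The engine (convolutions, LSTM,
pooling, dropout, Adam, backpropagation) is implemented in the package in
plain R and is verified against numerical differentiation to ~10⁻¹⁰; a
reduced-width profile (`nn_config_reduced()`: 12/16/24/32 filters, 24/12
LSTM units, dropout 0.05, learning rate 3e-3, 30 epochs, ~20k
parameters) exists so that training-based checks complete in minutes on
one CPU. Windows inherit their trial's
label; trial-level prediction averages the per-window softmax and breaks
ties toward the lower risk level. Widths, dropout (0.3), kernel sizes and
pooling are configuration, since only the filter counts, the LSTM/dense
stage counts, the head widths and the softmax output are fixed by the
published topology.

### Why the learning benchmark uses a frequency-contrast cohort

The learning-sanity comparison trains the network and the feature bank on
a cohort whose two classes share amplitudes, excursions, durations and
latencies but differ in sway and step *frequency*. The ten features are
range-, quantile- and duration-based, so they are nearly blind to this
contrast, while raw acceleration scales with frequency squared and
separates cleanly. This isolates exactly the qualitative claim under
test — that a classifier reading the raw signals can exceed any classifier
limited to the extracted features — rather than re-testing feature
separability, which the risk-level cohort already covers. The transition
bursts also differ in frequency, with amplitude scaled inversely so the
jerk feature stays class-blind. Training uses only *active* windows
(mean within-window accelerometer SD at least 0.12 m/s²): rest pauses
carry the trial label but no class signal and would cap window-level
accuracy. Problem sizes for the shipped checks: 48 participants (24 per
class, 12 s standing), a stratified 80/20 split, at most 480 training
windows, the reduced network profile with early stopping at 99.5%
running training accuracy; the reported training accuracy is measured on
the training windows with dropout disabled.

## Numerical choices and degenerate inputs

Quantiles use R's default (type 7) definition. Envelope windows: 0.45 s
(AP; above half the slowest stride period so the envelope bridges
oscillation zero crossings) and 0.15 s (vertical). Ties in trial-level
argmax go to the lower risk level. Zero-norm accelerometer samples skip
the orientation correction (counted and messaged). Constant ICC tables,
single-member classes, degenerate transition intervals, too-short signals
and non-monotone timestamps are structured errors. The whole chain is
deterministic given input and configuration; every stochastic step
(simulation, splits, folds, initialisation, dropout, shuffling) takes an
explicit seed and restores the caller's RNG state.

## Known limitations

* The simulator's scripted, single-segment kinematics make segmentation
  easier than on real recordings; the noise-robustness property (≥ 90% of
  events within ±0.2 s at accelerometer noise up to ~0.1 m/s²) degrades at
  extreme noise (0.2 m/s²), where bout-edge refinement occasionally slides
  along noise ridges.
* Yaw drift is bounded only by gyroscope bias, which the simulator does
  not inject; with real gyros the turn detector's baseline threshold term
  absorbs slow drift but large bias would shift t3.
* The full-width network (~10⁷ parameters) is buildable and differentiable
  but not practical to train in plain R; all shipped training runs use the
  reduced profile.
* Published cohort statistics (feature means, ICC values, model
  accuracies) from the study this package re-implements are not
  reproduction targets: the underlying recordings are not public, and the
  synthetic cohort is matched to the protocol, not to that sample.
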