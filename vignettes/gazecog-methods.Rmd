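---
title: "Screening cognitive decline from eye-tracking and facial blend shapes: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening cognitive decline from eye-tracking and facial blend shapes: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(gazecog)
```

## The screening problem

`gazecog` implements a complete analysis chain for screening cognitive
decline (CD, pooling mild cognitive impairment and mild Alzheimer's
disease) against healthy controls (HC) from short multimodal behavioral
recordings. A subject completes five gamified tasks while a head-mounted
display records, at a nominal 120 Hz, eleven oculomotor channels (the 3-D
origins of both eyes, the merged 3-D gaze point, and both pupil diameters
in mm), two eye-openness channels in [0, 1], and six facial blend-shape
(FBS) intensities in [0, 1] natively sampled at 60 Hz and upsampled to
120 Hz by nearest-neighbor interpolation. The five paradigms are:

* **VSST** — visual short-term memory and search: 3 s memorization, 8 s
  search among five objects, one trial;
* **MCT** — memory calculation: 3 s memorization, 10 s dynamic search,
  5 s numeric option selection, two trials;
* **PRT** — pupillary light reflex: 5 s fixation whose final second
  carries a light stimulus, two trials;
* **ST** — saccades: 2 s central + 2 s peripheral target, six pro-saccade
  (PS) then six anti-saccade (AS) trials;
* **FET** — facial emotion expression: 5 s of voluntarily expressed
  happiness, then 5 s of sadness.

Two classifier families are built on these recordings: 27 formula-defined
behavioral features feeding classical tabular models, and a deep
multi-task multi-stream parallel convolutional network (MT-MSPCNN)
consuming the preprocessed raw sequences.

## Preprocessing

The pipeline order is fixed: blink repair, pupil filtering, facial
smoothing.

* **Blinks.** A sample is a blink when *either* eye's openness falls below
  `tau = 0.9`. The openness signal is described per eye; we flag the
  per-sample minimum because a blink corrupts gaze and pupil channels of
  both eyes simultaneously. The blink mask is applied jointly to pupil,
  gaze-point and eye-origin channels, and masked spans are repaired by
  linear interpolation (edge gaps hold the nearest valid value).
* **Pupil filtering.** Both pupil series pass through a causal 2nd-order
  low-pass Butterworth recursion with cutoff `fs/8`, implemented in its
  time-domain recursive form
  $\hat x_n = \tfrac{1}{\Omega}\sum_{i=0}^{p} h_i x_{n-i} - \sum_{j=1}^{q} g_j \hat x_{n-j}$
  with coefficients from the standard bilinear-transform design
  (`signal::butter`). Filtering is causal, not zero-phase, so every
  latency feature inherits the same small group delay in both groups.
  The recursion starts from the steady state of the first sample (a
  constant startup pad) rather than a zero state, which would otherwise
  inject a multi-second artifact at the start of the recording. Only the
  pupil channels are filtered; gaze positions are left unfiltered because
  saccade velocity profiles are the signal of interest there.
* **Facial smoothing.** The six FBS channels are convolved with a
  normalized Gaussian kernel (sigma = 2 samples, truncated at 4 sigma,
  reflect padding), which preserves constants exactly.

Gaze is merged binocularly: the cyclopean origin is the per-sample
midpoint of the two eye origins and the line of sight runs to the
recorded gaze point. Angular velocity is the angle subtended at the
cyclopean origin between the directions one sample before and after,
divided by the elapsed time (central difference; one-sided at the
boundaries). An angular (rather than Euclidean) velocity was chosen
because all event-segmentation thresholds are expressed in degrees.

## Oculomotor events (I-VDT)

Fixations and saccades are segmented with the velocity- and
dispersion-threshold algorithm: velocity threshold 30 deg/s (strict
inequality; ties are fixation), temporal window 130 ms, dispersion
threshold 2 deg, minimum saccade duration 0.04 s. Supra-threshold runs
shorter than the minimum duration are folded back into the surrounding
samples. The remaining samples are grouped by the classical
dispersion-window test; dispersion is measured as the diagonal of the
azimuth/elevation bounding box seen from the cyclopean origin — an
incremental surrogate for the maximum pairwise angle that can be updated
in O(1) per sample and coincides with it when the extreme points sit at
the box corners. Low-velocity drift that never passes the dispersion test
(the smooth-pursuit class of the original algorithm) is absorbed into the
neighboring fixation, because all paradigms here use stationary targets;
consequently events exactly tile each segment. Saccade latencies are
measured from stimulus onset, and saccades with latency below 100 ms are
excluded as anticipatory before any feature is computed.

## The 27 behavioral features

Per task: VSST — ROI fixation percentage, time to first ROI fixation
(capped at the 8-s phase when the ROI is never reached, mirroring the
expression-latency fallback), total ROI dwell (fixations plus intra-ROI
saccades), median saccade amplitude in degrees, and median ROI fixation
duration. MCT — attention allocation `Aa = Tc/Tall` (we use the realized
search-phase duration for `Tall`, with a configuration override, since
the nominal phase is 10 s while the feature definition mentions 5 s) and
calculation latency. PRT — per eye and per trial: maximum constriction
acceleration and velocity, diameter range, response latency (first sample
more than 3 pre-stimulus standard deviations below the running-mean
baseline $\mu_{T_b}$, computed with the recursion
$\mu \leftarrow \tfrac{k}{k+1}\mu + \tfrac{1}{k+1}\hat x$ which equals
the arithmetic mean), time to peak velocity and time to maximum
constriction, both measured from constriction onset; eyes averaged, then
trials averaged. ST — latency, mean velocity, peak velocity and amplitude
of the first admissible saccade per trial, aggregated separately over PS
and AS trials; the peak velocity feature is the single maximum across a
condition's effective saccades. FET — per emotion, on the mean of the
left/right cheek channels after smoothing: mean intensity, supra-threshold
duration (`theta = 0.1`) and onset latency with a 5-s fallback.

ROI membership is a sphere test (default radius 0.15 m) on 3-D gaze
endpoints, standing in for engine-level ray-collision hits. Features of a
missing task are flagged and median-imputed within the training split for
the tabular models only; the deep model never consumes features.

The 27 features join age, sex, education and the ten granular MoCA-B item
scores into a 40-column design table for the baselines: L2 logistic
regression (inverse strength 1.0, via a `glmnet` ridge fit with
`lambda = 1/(nC)`), Gaussian naive Bayes, and an RBF SVM with the
`"scale"` kernel-width rule and C selected on the validation split from
{0.1, 0.4, 0.7, 1}. Group contrasts are tested feature-wise with
two-sided Mann-Whitney U tests (normal approximation with tie correction,
appropriate at n = 20 per group), with CD as the positive class and no
multiplicity correction (raw p-values are reported).

## MT-MSPCNN

Each task's preprocessed 17-channel sequence (11 oculomotor + 6 facial;
the four eye-tracking tasks carry zero-filled facial channels, so one
encoder shape serves all tasks) is cut into overlapping subspace windows
of `W = 150` samples with stride `S = 50`; the tail shorter than a window
is discarded, giving `N = floor((L - W)/S) + 1` instances per bag.

**Input standardization.** Model inputs are z-scored, and the open design
question is whether the statistics come from each subject or from the
training set. We center each channel per subject and scale by the
training-set standard deviation (`standardize = "center_subject"`). The
rationale: static between-subject offsets — resting pupil diameter,
anisocoria, idiosyncratic head geometry — are clinically uninformative
nuisance that a small-cohort network otherwise memorizes, while the
*amplitude* of dynamic responses (e.g., light-reflex constriction depth)
is informative and must not be rescaled away, which full per-subject
z-scoring would do. Both alternatives remain available as options.

**Encoder.** Four parallel streams with kernel sizes 3/5/7/9, each
convolution -> ReLU -> max pooling (kernel = stride) -> convolution ->
ReLU -> global average pooling, with symmetric zero padding preserving
length (stream channel plans 16/32, 32/64, 8/16, 16/32); the concatenated
embedding has D = 144. The architecture leaves the activation function
open; ReLU is the conventional choice. The
primitives are implemented in C++ (im2col + BLAS matrix products) with
analytically derived gradients, verified against numerical
differentiation.

**Phase 1** assigns each subject's label to all of their windows and
trains encoder + a 64-unit MLP instance head by soft-weighted
cross-entropy (Adam, lr 0.001, batch 32): instance weights
`w_i = exp(-gamma * loss_i)` with `gamma = 1`, recomputed each epoch from
the previous epoch's per-instance losses (all weights are 1 in the first
epoch), and a restricted epoch budget — both mechanisms limit the damage
of the label noise that uninformative windows inject.

**Phase 2** freezes the encoder, embeds each bag once, and trains only
the gated-attention pooling
$e_n = w^\top\big(\tanh(W_V z_n) \odot \sigma(W_U z_n)\big)$,
$a = \mathrm{softmax}(e)$, $Z_{bag} = \sum_n a_n z_n$ (K = 64) and the
linear bag classifier by cross-entropy, one bag per step. When a
validation split is available the epoch with the best validation bag
accuracy is kept.

**Fusion.** One model per task; a subject's diagnosis is the majority of
the five binary votes. Five voters cannot tie; if abstentions (missing
tasks) produce a tie, the CD class is returned with a flag — for a
screening instrument the conservative error is the false positive.

**Evaluation protocol.** Per repeat: 5 + 5 subjects held out as a test
set; 15 + 15 drawn from the remainder and split 7:3 stratified (11
training, 4 validation per class — the ceiling of 0.7 x 15); all splits
re-drawn each repeat; subject-level accuracy, precision, recall
(sensitivity) and F1 reported as mean and standard deviation over
repeats.

## The synthetic cohort generator

Clinical recordings of this kind are not publicly available, so
`generate_cohort()` synthesizes raw sessions with the statistical
structure the analysis assumes: 20 HC and
20 CD subjects by default, all five paradigms at their nominal timings,
facial channels natively at 60 Hz, blinks injected as openness dips with
pupil dropout at about 10 per minute (suppressed around the light
stimulus and right after saccade-target onsets, emulating task-linked
blink inhibition), and Gaussian sensor noise. Gaze trajectories are
fixation/saccade schedules with minimum-jerk transitions (smooth,
realistic, and analytically integrable, so amplitude, peak velocity
`1.875 A/T` and peak acceleration `(10/sqrt(3)) A/T^2` are known in
closed form); the pupillary reflex, after latency `T1`, is a fast
minimum-jerk constriction to 85% of the amplitude `Rd` over `Dc`
followed by a slow creep to the full amplitude (so the maximum
constriction sits at a well-defined time whose group shift survives the
threshold-based onset detection) and a brisk exponential redilation that
leaves the next trial's baseline clean; expressions are delayed smooth
ramps on the cheek channels.
Pupil noise is modeled as slow hippus-like fluctuation plus a small
quantization-scale white component — pupillometry noise is not white, and
a white model at realistic amplitude would dominate the double-difference
acceleration feature.

Latent per-subject parameters are drawn per group from the effect table
(`effect_table()`): the directions follow the reported group contrasts
(reduced search efficiency and ROI dwell, delayed first fixations, lower
attention allocation and longer calculation latency, delayed and
attenuated pupillary constriction, longer saccade latencies with lower
peak velocity and reduced anti-saccade amplitude, and blunted, delayed
facial expression). Because the CD label pools MCI and mild AD, decline
severity is heterogeneous: one latent severity factor per CD subject
(truncated normal around 1) scales *all* of that subject's shifts, so
mildly affected subjects sit near the group boundary on every task at
once — which is what makes decision fusion outperform single tasks, and
what a pooled MCI+AD cohort actually looks like. Beyond the
feature-level shifts, decline expresses four further documented
oculomotor/autonomic signs that give the sequence model window-level
signal: saccadic vigor (the peak-velocity trait drives the transitions
of *all* gaze tasks, not just the saccade task), anti-saccade
hypometria (an undershooting primary saccade followed by a corrective
step), increased fixational instability (slow gaze wander whose
amplitude grows with decline; `wander_scale = 0` disables it for
boundary-exact tests), and an attenuated task-evoked pupillary response
(cognitive-load dilation during the search and calculation phases,
released before the light-reflex task so its baseline stays clean).
Magnitudes are calibration choices of this generator — group means for
these behavioral features are not publicly available for the clinical
setting it emulates — chosen so that the known-direction contrasts reach
Mann-Whitney p < 0.05 at n = 20/20 and every single-task model is
accurate but imperfect with decision fusion above it, the operating
regime the method is designed for. Under minimum-jerk kinematics mean
and peak saccade velocity are proportional, so the generator cannot keep
mean velocity group-neutral while shifting peak velocity; mean velocity
is therefore excluded from the known-contrast checks. This is a known,
accepted limitation.

`null_cohort()` zeroes every shift for type-I-error and chance-level
checks, and `sample_cohort_truth()` draws only the latent parameter table
(no signals) for calibration experiments over many seeds.

**What passing tests show — and what they do not.** The generator
emulates channel structure, task timing, event kinematics and effect
directions; it does not emulate head-motion artifacts, calibration drift,
pursuit of moving objects in the MCT (targets are rendered static),
severity substructure within CD, or correlated missingness. Results on
synthetic cohorts validate the implementation and the method's operating
characteristics under its assumptions, not clinical performance.

## Numerical choices and degenerate inputs

Ties at the velocity threshold classify as fixation; a segment shorter
than the 130-ms window yields no events; a fully masked series cannot be
interpolated and errors; channels with zero variance are centered, not
scaled; a condition with no admissible saccade yields missing features; a
constant pupil window reports zero velocities and the window length as
latency, flagged; empty bags warn and abstain at prediction time.
Problem sizes used by the shipped checks: ten protocol repeats with a
phase-1 budget of 8 epochs under a 280-step optimization floor (tasks
with few windows train extra epochs so every task model gets a
comparable number of Adam steps; the phase-1 default cap of 30 epochs
applies when training a final model rather than running repeated
evaluations) and a phase-2 budget of 50 epochs; three repeats for
null-cohort chance checks; and 200 draws for type-I calibration at the
latent-parameter level — full-signal synthesis over hundreds of cohorts
adds nothing to that calibration because the test statistics act on the
per-subject feature values.

## Known limitations

The I-VDT merge rules for sub-minimum saccade runs follow one defensible
reading of the original algorithm (fold into flanking events). Phase
boundaries inside a task are inferred from nominal durations, not logged
markers. The MCT `Tall` ambiguity (5 s vs the 10-s phase) is resolved in
favor of the realized phase duration with an override. Latency-type
features carry a small positive detection bias (threshold crossing on a
smooth onset plus the causal filter's group delay) that is shared by
both groups, and the fixation-onset estimate sits a few samples inside
the sub-velocity-threshold tail of slow, large saccades. Group signals
that live purely in fine temporal statistics of gaze (e.g., a 60-ms
latency shift inside a 1.25-s window) are at the edge of what the
global-average-pooled encoder resolves at this cohort size; the
generator's amplitude-like signs (pupil dynamics, expression intensity,
fixational wander, task-evoked dilation) are what give each task model
its discriminative power.
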