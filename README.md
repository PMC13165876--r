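# gazecog

Screening cognitive decline from multimodal behavioral recordings.

Healthy aging and early cognitive decline (CD — mild cognitive impairment
pooled with mild Alzheimer's disease) separate measurably in how people
look, react and emote. `gazecog` implements a complete digital-biomarker
analysis chain for short five-task assessment sessions recorded by a
head-mounted display: eleven oculomotor channels at 120 Hz (both 3-D eye
origins, the merged 3-D gaze point, both pupil diameters), two eye-openness
channels, and six facial blend-shape intensities natively at 60 Hz. The
five paradigms are visual short-term-memory search (VSST), memory
calculation (MCT), the pupillary light reflex (PRT), pro-/anti-saccades
(ST), and voluntary facial emotion expression (FET).

The package provides:

* **Preprocessing** — blink detection on eye openness (threshold
  τ = 0.9), joint linear gap repair, a causal 2nd-order Butterworth
  recursion (cutoff fs/8) for the pupil,
  x̂ₙ = (1/Ω) Σᵢ hᵢ xₙ₋ᵢ − Σⱼ gⱼ x̂ₙ₋ⱼ, and Gaussian smoothing (σ = 2)
  of the facial channels.
* **Oculomotor events** — I-VDT segmentation into fixations and saccades
  (velocity 30°/s, window 130 ms, dispersion 2°, minimum saccade 0.04 s)
  with exclusion of anticipatory saccades (latency < 100 ms).
* **27 behavioral features** across the five tasks (ROI dwell statistics,
  attention allocation Aa = Tc/Tall, calculation latency, six pupillary
  reflex descriptors from the running-mean baseline
  μ ← k/(k+1)·μ + 1/(k+1)·x̂, saccade latency/velocity/amplitude per
  condition, and expression intensity I = (1/N)ΣVal, duration
  T = Δt·Σ1(Val > θ), latency L = min(tᵢ − t₀ | Val > θ) with a 5-s
  fallback), plus the 40-column baseline table (27 features + age, sex,
  education, 10 MoCA-B item scores).
* **MT-MSPCNN** — the deep classifier: overlapping subspace windows
  (W = 150, S = 50), four parallel convolutional streams (kernels
  3/5/7/9, concatenated embedding D = 144) implemented with compiled
  conv/pool kernels, two-phase training (soft-weighted instance
  pretraining with wᵢ = exp(−γ·lossᵢ), then gated-attention
  multiple-instance pooling eₙ = wᵀ(tanh(W_V zₙ) ⊙ σ(W_U zₙ)) with a
  frozen encoder), and majority-vote fusion of the five task models.
* **Baselines & statistics** — L2 logistic regression, Gaussian naive
  Bayes, RBF SVM with a C grid, subject-level accuracy/precision/
  recall/F1, and feature-wise Mann-Whitney U group tests.
* **A synthetic cohort generator** — clinical recordings of this kind
  are not publicly available, so
  `generate_cohort()` synthesizes complete raw sessions (default 20 HC +
  20 CD) with the documented effect directions, a latent CD severity
  factor, blinks, sensor noise and ground-truth records, making every
  stage testable end to end.

## Worked example

```r
library(gazecog)

co <- generate_cohort(cohort_config(n_hc = 20, n_cd = 20), seed = 7)
f  <- extract_features(co$sessions[["S01"]], co$truth[["S01"]]$rois)
round(f[1:13], 3)
#> vsst_fix_roi  vsst_tf_roi   vsst_t_roi      vsst_sl  vsst_tm_roi       mct_aa
#>       50.512        1.692        3.292       21.921        0.475       49.667
#>       mct_lc   prt_ac_max   prt_vc_max       prt_rd       prt_t1       prt_t2
#>        0.875       55.352        3.232        0.938        0.371        0.117
#>       prt_t3
#>        0.500
```

Subject S01 (a healthy control) fixated the search target 50.5% of total
fixation time, first reached it 1.69 s after search onset, and showed a
0.94 mm pupillary constriction peaking at 3.2 mm/s — all in the healthy
range. Feature-wise group statistics:

```r
feats <- extract_cohort_features(co)
head(mannwhitney_all(feats)[c("feature", "U", "p", "median_hc", "median_cd")], 5)
#>        feature   U        p median_hc median_cd
#> 11      prt_t1 400 6.72e-08     0.344     0.502
#> 24 fet_t_happy   0 6.77e-08     4.379     2.921
#> 26 fet_l_happy 400 6.77e-08     0.621     2.079
#> 8   prt_ac_max   0 6.80e-08    91.365    18.118
#> 14    st_ls_ps 400 6.80e-08     0.213     0.322
```

The declined group's pupillary response starts later (0.50 vs 0.34 s)
and accelerates far less, its pro-saccades launch 110 ms later, and its
expressions are shorter and markedly delayed — each U statistic at or
near its extreme at n = 20/20.

The full evaluation protocol (per repeat: 5+5 held-out test subjects,
15+15 train/validation at 7:3, all five task models trained and fused by
majority vote) is one call:

```r
ev <- evaluate_protocol(co, seed = 1, repeats = 10,
                        cfg1 = soft_weight_config(epochs = 8, min_steps = 280),
                        epochs2 = 50)
ev$summary
```

which reports subject-level mean ± sd accuracy, precision, recall and F1
for each single-task model and the fused classifier. A thin command-line
front end (`inst/cli/gazecog.R`) exposes `simulate`, `extract`,
`evaluate`, `train` and `predict` subcommands.

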