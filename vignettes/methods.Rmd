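---
title: "Decoding persistent psychological lenses from fNIRS: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding persistent psychological lenses from fNIRS: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(neurolens)
```

## The problem

People carry persistent subjective filters — "psychological lenses" such
as feeling overwhelmed at work — that sit between momentary mental
states and stable traits. These lenses shape how a person experiences
shared content, and they often stay hidden from self-report. The premise
of this package is the *neural reference groups* idea: if two groups of
people (say, overwhelmed vs. not) process a shared naturalistic stimulus
differently, a new individual can be classified by which group's
stimulus-locked brain response their own response resembles.

`neurolens` implements that pipeline for functional near-infrared
spectroscopy (fNIRS): cortical hemoglobin signals recorded while
participants watch a common video, regions of interest in the default
mode network (TPJ, dmPFC, amPFC), 1–7 Likert outcome measures
dichotomized into reference groups, and a multitimepoint pattern
analysis (MTPA) that selects the seconds of the stimulus carrying
group-discriminative information.

## Preprocessing model

Raw data are dual-wavelength (760/850 nm) optical-density series at
3.906 Hz. The cleaning chain, in order:

1. **Channel quality control.** A sliding quartile coefficient of
   dispersion, `QCD = (Q3 - Q1) / |Q3 + Q1|`, computed on a centred
   4-s window at every sample. A channel is removed when its QCD
   exceeds `Cthresh = 0.6 - 0.03 * fs` continuously for 2 s or more
   (`compute_cthresh(3.906)` = 0.48282). The window is twice the
   persistence criterion deliberately: quartiles only react once a
   disturbance occupies at least half the window, so a sub-2-s burst
   cannot trip a rule that is meant to catch sustained saturation. The
   absolute-value denominator keeps the index defined for signals that
   fluctuate around zero.
2. **Motion-spike removal.** A sample is a spike when it differs by
   more than 5 global standard deviations from some sample less than
   1 s away on *each* side — a transient that departs and returns
   (series edges use the available side). Flagged samples are linearly
   interpolated rather than deleted so the timeseries keeps its
   stimulus alignment. The SD is computed on the whole channel.
3. **Bandpass 0.008–0.2 Hz.** An order-2 Butterworth prototype applied
   forward–backward (zero phase, effective order 4). The series is
   extended by even-mirror reflection before filtering: odd reflection
   injects a DC step equal to twice the endpoint value, which leaks
   through the very low high-pass corner as a long transient (we
   measured residual 1-Hz leakage an order of magnitude larger with odd
   reflection). The measured response of the chosen filter attenuates
   1-Hz (cardiac) and 0.001-Hz (drift) tones by more than 10x and
   passes 0.05-Hz content at better than 99%.
4. **Modified Beer–Lambert inversion.** Per timepoint, the 2x2 system
   relating optical-density change to HbO/HbR concentration change is
   solved with standard tabulated extinction coefficients, 3-cm
   source–detector separation and a differential pathlength factor of
   6.0 at both wavelengths (the conventional adult default; DPF is
   config-exposed since acquisition-specific values are preferable when
   known). Only HbO continues downstream.
5. **Autocorrelation-change QC.** Channels whose lag-1 autocorrelation
   changes by strictly more than 0.1 between the series before and
   after spike correction are excluded — a large change means motion
   correction restructured the signal rather than repairing isolated
   samples.
6. **ROI averaging and z-scoring.** Unweighted mean over the retained
   channels of each ROI, then z-scored per participant and ROI
   (mean 0, SD 1 before resampling).
7. **Resampling to 1 Hz.** Mean over consecutive 1-s bins — averaging
   rather than decimation, acting as the anti-alias smoother. A
   10-min-53-s stimulus yields exactly 653 features.

Two notes on stage order. Spike interpolation must precede the bandpass
(the filter would smear a spike below its own detection threshold); the
test suite pins this by showing the swapped order changes the output.
The bandpass and the Beer–Lambert solve, by contrast, are both linear
operators and commute to machine precision, so their relative order is
a convention, not a testable property.

Participants who lose every channel of an ROI are dropped from that
ROI's analyses only, not from the study.

## Outcome dichotomization

Each 1–7 Likert measure is split into high/low reference groups at the
threshold making the classes most even. Candidates are half-integers
(1.5…6.5, nobody omitted) and integers (2…6, respondents at the
threshold omitted). Ties between equally balanced thresholds prefer
half-integer splits, then fewer omissions, then the scale centre, then
the lower threshold — the tie-breaking is a documented convention since
only the outcomes of such a search are ever reported in practice. A
measure is dropped as degenerate when its best split lands at the scale
extremes (<=2 or >=6), when the minority class falls below 35%, or when
more than 15% of respondents would be omitted; all three cutoffs are
config-exposed.

Class balance inside a training fold is restored by upsampling the
minority class with randomized repetition. The function receives
training labels only, so the held-out subject can never be replicated
into training, and the repeated cases are redrawn in every fold of
every repeat.

## MTPA: selection, refit, cross-validation

For each (ROI, measure) pair, subjects-by-timepoints matrix `X` and
binary labels `y`:

- **Temporal searchlight.** An elastic-net-penalized logistic path
  (mixing `alpha = 0.9`, close to lasso for sparsity while tolerating
  the strong collinearity of neighbouring seconds) is fit on the
  balanced training fold; the regularization strength lambda is chosen
  by internal stratified 10-fold cross-validation minimizing total
  held-out binomial deviance. Timepoints with nonzero coefficients are
  the selected features; the set may be empty. Fold assignment is
  stratified and seed-deterministic; we code the small CV loop in the
  package (the path fits themselves are glmnet's) so the same machinery
  scales down reproducibly inside permutations.
- **Selection-then-refit.** Shrunken coefficients blur interpretation,
  so classification uses a fresh logistic fit on the selected columns:
  iteratively reweighted least squares with a tiny ridge (1e-6) on the
  non-intercept terms, which keeps perfectly separated folds usable
  instead of fatal. With zero selected features the model falls back to
  an intercept-only majority-class predictor; on balanced training data
  that is an explicit seeded coin flip, which is why a pair whose
  selection collapses hovers at chance accuracy with ~1 retained
  feature.
- **LOOCV with repeats.** Each subject is held out in turn; balancing,
  lambda selection, feature selection and the refit all see only the
  remaining subjects. The full cycle is repeated 50 times by default
  (per-repeat seed = master seed + repeat index) and averaged, because
  the upsampling makes single runs stochastic. Reported per pair:
  accuracy, per-timepoint selection frequency across folds x repeats,
  and mean retained-feature count.
- **Leakage guards.** Tests embed the held-out label in a
  training-constant canary column (the fold's prediction must not
  move) and verify fold-for-fold agreement with an independently coded
  nested-loop oracle under shared seeds. Training rows are
  canonicalized to subject-identifier order inside each fold, so
  results are invariant to subject arrival order when per-subject seeds
  are used.

The ablation baseline (`ridge_baseline()`) runs the identical LOOCV
and balancing protocol with a ridge-penalized logistic model on all
timepoints — isolating what temporal selection itself contributes.

## Inference

**Family-wise test.** The nine (ROI, measure) accuracies are dependent —
same brains, correlated outcomes — so the package uses a
maximal-statistic permutation test: per permutation, labels are
shuffled once per measure (reused across that measure's ROIs,
preserving the dependence the correction must respect), the full
MTPA-LOOCV accuracy is recomputed for every pair, and the maximum
across pairs is recorded. A pair's corrected p-value is the share of
null maxima at or above its observed accuracy (`count/n` convention,
matching a reported minimum of 1/n at n permutations; a
`(count+1)/(n+1)` variant is config-exposed). Because the null maximum
is a maximum over several chance-level statistics its mean sits well
above 50% — elevated null means are a property of the correction, not a
bias. Within permutations the 50-repeat average is reduced to one
repeat by default (`perm_repeats`): nesting the full average inside
1,000 permutations is computationally disproportionate and only narrows
the null's jitter.

**Stimulus mapping.** The 25 most frequently selected timepoints (ties
at the cutoff resolved to the earliest second) are compared against the
never-selected timepoints. Both sets are shifted 3 s backward to
stimulus time to account for hemodynamic delay. For each per-second
binary theme track, a 2x2 table (theme present/absent x top/never)
gives an odds ratio, with a Haldane–Anscombe +0.5 on all cells when any
cell is zero. Significance comes from circle-shift permutation: the top
indicator is rotated by a uniform random offset in [1 s, duration−1 s] —
preserving its autocorrelation while breaking stimulus alignment — and
the odds ratio recomputed against the never set stripped of any overlap
with the rotated top set; the one-sided p is the share of null odds
ratios at or above the observed. Themes are tested independently
without multiplicity correction, mirroring exploratory practice. The
lag is applied before partitioning; both choices are config-exposed.

## The synthetic cohort generator

The generator defines the study conditions everything is tested under:
a two-group cohort at 3.906 Hz watching a 653-s stimulus, three ROIs
with four channels each. Latent per-participant HbO is the sum of a
shared stimulus-driven component (SD 0.3 uM), idiosyncratic smooth
subject noise (SD 0.6 uM — intersubject correlation around 0.2, typical
of naturalistic-viewing cohorts), and, in the planted ROI, a group
effect: a double-gamma kernel re-centred so its peak falls *on* each
planted second, scaled so the group mean difference there equals
`effect_size` between-subject SDs on the 1-Hz ROI scale. Because
per-participant z-scoring divides signal and noise alike, that
standardized effect is preserved through the pipeline. HbR is generated
as anticorrelated (-0.5) with its own noise, and channel optical
density is produced by the *forward* Beer–Lambert model — so the
package's inversion is exercised end to end, not round-tripped against
itself. Channels add white noise, cardiac (~1 Hz) and respiratory
(~0.3 Hz) oscillations with per-participant frequency jitter, slow
drift, participant-level motion spikes (Poisson, 6–9 SD, under 1 s,
hitting a random channel subset), and saturated channels (probability
0.05): near-constant traces with 2.5–6-s high-dispersion bursts, giving
the QCD rejector true positives with sub-criterion structure around
them. Likert outcomes are rounded Gaussians at group modes 2 and 6
(dispersion 1), bimodal as such scales look in practice; theme tracks
are random interval unions at 10–20% coverage, except one "signal"
theme placed at the planted seconds shifted 3 s earlier in stimulus
time.

What the generator does *not* emulate: scalp optics and partial volume
effects, anatomical variability in channel placement, systemic
physiology shared across groups, non-stationary artifact regimes, and
heterogeneity of the planted response across participants (every
group member diverges with the same amplitude and latency). Passing
recovery tests therefore demonstrates that the machinery is correct
and calibrated under its assumed signal model — not that any
particular real-world cohort is decodable.

One consequence of that coherence deserves emphasis. Because the
planted group difference is a single fixed time course in smooth
band-limited noise, a deviance-tuned dense ridge classifier is close
to optimal for the generator's data, and the test suite finds it
matches or exceeds selection-then-refit across effect sizes and cohort
sizes. The selection advantage reported for real field cohorts — where
dense classifiers hover near chance — evidently rests on data
properties (per-subject response heterogeneity, artifact-laden
non-Gaussian noise) this signal model deliberately omits. The
directional ablation comparison is still computed by the suite at a
field-scale instantiation, and its outcome documents this boundary of
the synthetic model rather than a property of the estimator.

## Numerical and scaling choices

- Seeds: one master integer drives everything through a Lehmer-style
  `derive_seed(seed, salt)`; repeats use `seed + r`; every stochastic
  routine restores the caller's RNG state.
- Fold CV deviance is summed (not averaged per fold), a documented
  minor variant; the lambda grid is glmnet's default log-spaced path.
- `mtpa_config(lambda = )` fixes lambda and skips the internal CV.
  The family-wise calibration study in the test suite uses it (50 null
  studies x 9 pairs x 101 LOOCV runs is ~270k penalized fits on one
  CPU); observed and permuted data get the identical reduced
  configuration, which leaves the calibration property untouched.
- Simulation scales in the test suite: signal recovery at n = 60
  participants, effect 1.2 at 20 planted seconds, 10 repeats;
  classifier null calibration over 20 cohorts of n = 16; family-wise
  calibration over 50 studies of n = 6 with 100 permutations;
  circle-shift uniformity over 200 runs of 1,200 shifts. These are the
  package's chosen desk-scale study conditions and are asserted at the
  tolerances the underlying binomial/KS sampling distributions imply.
- Degenerate inputs: constant label vectors, empty classes, singular
  extinction matrices, zero-variance series and out-of-range intervals
  are errors; empty selection sets, all-zero selection frequencies and
  all-ones theme tracks degrade gracefully (fallback classifier,
  warning + reduced top set, p = 1).

## Known limitations

- The QCD windowing ("modified" dispersion), the spike-SD scope
  (global), the DPF value, and the CV-fold stratification are
  documented conventions where acquisition practice varies; all are
  config-exposed rather than hard-coded.
- Headline accuracies from any particular human cohort are not
  reproducible from synthetic data and are not asserted anywhere; the
  test suite checks properties (recovery, calibration, ablation
  direction, oracle equivalence) instead.
- SNIRF interchange is not provided; cohort I/O is CSV + JSON sidecar.
- v1 offers no alternative classifiers and no FDR-style inference.
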