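---
title: "Methods: masked pre-training and transfer for wearable motor-impairment grading"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: masked pre-training and transfer for wearable motor-impairment grading}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its models and the design
choices behind them: what each stage assumes, which parameters matter and
why their defaults are what they are, what the synthetic cohorts do and do
not emulate, and where the numerically delicate spots are.

## 1. The task and the data model

The pipeline grades bradykinesia — slowness and amplitude decay of
repetitive voluntary movement — from two tri-axial accelerometers worn
during MDS-UPDRS-style tasks (finger tapping FT, hand movements HM,
pronation–supination PS, toe tapping TT, leg agility LA), sampled at 80 Hz.
Clinical scores 0–4 are collapsed to a binary label: 0/1 = low, 3/4 = high;
score-2 recordings are excluded from every dataset, since the middle grade
is both clinically ambiguous and rare enough to starve a binary decision
boundary.

A *recording* is one participant-session-task series from both sensors; it
is also the unit of grouping for splits (every 5-s window cut from it
carries the recording's `group_id`), which is what makes the
cross-validation leakage-free.

## 2. The synthetic cohort generator

The generator exists so the entire pipeline is testable without clinical
data. Each recording is built as

```
movement(t) = A exp(-d t) cos(2 pi f t + jitter(t)) * gate(t)
tremor(t)   = T env(t) sin(2 pi f_tr t),   f_tr ~ U(4, 6) Hz
core(t)     = movement(t) + tremor(t)
sensor_s(t) = gain_s * core(t) * axis_s + N(0, sigma_n^2) per axis
```

with `gate(t)` a product of cosine-tapered dips to zero (hesitations,
Poisson arrivals, 0.3–1.0 s each), `jitter(t)` a Brownian phase walk, and
`env(t)` a slow (0.2–0.5 Hz) waxing-waning envelope on the tremor. Both
sensors share the movement phase; they differ by gain, axis direction and
independent noise, which is exactly the redundancy the two-channel model
input assumes.

Severity maps linearly between a severity-0 and a severity-4 anchor, with
multiplicative log-normal participant heterogeneity (sd 0.15 on the log
scale) that is drawn once per recording and applied at every severity, so
the maps are monotone under a shared RNG state:

| parameter | severity 0 | severity 4 | units |
|---|---|---|---|
| movement amplitude | 1.0 | 0.30 | g |
| amplitude decrement | 0 | 0.08 | 1/s |
| tremor amplitude | 0 | 0.35 | g |
| hesitation rate | 0 | 0.50 | events/s |
| phase jitter | 0.02 | 0.50 | rad |
| movement-rate scale | 1.0 | 0.70 | — |

Severity 0 anchors tremor and hesitations at exactly zero, so controls are
clean quasi-periodic movers. The anchors were chosen to express severity in
the *shape* of the signal, not only its scale: per-segment standardization
(Section 3) erases amplitude level, so whatever the classifier learns must
survive in envelope morphology — hesitation dips, the exponential
sequence-effect decay, phase irregularity, and the slow waxing-waning of
tremor power. These are also the clinically described signatures of
bradykinesia and rest tremor, which is why we consider the emulation fair
rather than convenient. With these defaults, raw-signal amplitude separates
severity {0,1} from {3,4} at well over one pooled SD, and high-severity
recordings carry a 4–6 Hz spectral peak absent in controls (both asserted
in the test suite).

Task movement rates are FT 3.2, HM 1.9, PS 1.6, TT 1.8, LA 1.7 Hz. The
values keep the fastest task fastest, and deliberately avoid the bands
[1, 1.5] and [2, 3] Hz: the resultant magnitude rectifies a sinusoid, so
its spectrum lives at even harmonics 2f, 4f, and those bands would alias a
*movement* harmonic into the 4–6 Hz *tremor* band, making the tremor
diagnostic ill-posed.

The default population is 20 PD + 8 HOA participants with retest
probability 19/28, matching the reference cohort's 28 participants of whom
19 returned. A single retest fraction cannot reproduce the study's exact
32 PD / 16 HOA session split (that would need cohort-specific fractions of
0.6 and 1.0); we match the total expected session count (47 ≈ 48) and
document the discrepancy rather than invent per-cohort fields. Severities
are drawn per recording from a configurable distribution (default roughly
balanced with severity 2 deliberately under-weighted). One severity label
is emitted per recording; whether clinical scoring was side- or
task-resolved is not recoverable from the study description, so the
single-label reading is an explicit assumption.

What the generator does *not* emulate: biomechanics (no limb model, no
gravity component), medication state, disease progression, sensor drift,
or artefacts. Passing tests on synthetic cohorts therefore demonstrate
that the pipeline's machinery is correct and that it can recover a known
severity signal — not that it reaches any particular accuracy on clinical
data.

## 3. Preprocessing

The chain is: resultant magnitude per sensor → jerk (first difference ×
sampling rate) → sliding 1-s RMS → overlapping 400-sample segments →
per-channel standardization → binary label. Choices worth recording:

* **Channel set.** The model consumes the per-sensor RMS-of-jerk (an N×2
  matrix). This is the minimal reading of the stated operation order with
  two sensors; the raw resultant is not appended as an extra channel.
* **Jerk scaling.** The forward difference is multiplied by the sampling
  rate so the channel has physical units (g/s). Standardization later
  removes the scale; the factor is kept purely for interpretability.
* **RMS window.** Sliding (stride 1) rather than block-wise, so 400 samples
  still span 5 s and the 400-step segment convention stays exact.
  Block-wise RMS (stride = window) is available via `rms_window(stride=)`
  but would downsample 80-fold.
* **Segment stride.** Default 80 samples (1 s, 80 % overlap): several votes
  per recording for max-vote inference without exploding the dataset. The
  overlap is configurable.
* **Standardization** is per channel within each segment, guarding
  degenerate channels with an epsilon (1e-8): a constant channel becomes
  zeros, never NaN. Per-channel (rather than pooled) scaling stops one
  sensor's gain from dominating both channels.
* Recordings shorter than one segment are skipped with a warning, not an
  error, so one truncated file cannot abort a cohort run.

## 4. Splits

Stratified K-fold over PD groups deals each label class round-robin after
shuffling, which guarantees fold sizes within one group of each other and
per-fold class counts within one group of n_class/K. The 70–30
train/validation split of the non-test folds is random over groups and
*not* re-stratified, mirroring the study's wording that reserves
stratification for the folds. Split sizes round half-up with remainders
going to the training side (small cohorts need training data more than
validation precision). A segment-level leakage tripwire runs at
construction; grouping is by recording, not participant, so a participant's
test and retest sessions can land in different folds — the stricter
participant-level grouping is deliberately not the default because the
study groups by recording.

## 5. The network

Each XceptionTime-style module concatenates four branches (each `f`
channels): three depthwise-separable convolutions at kernels {k, k/2, k/4}
(odd-rounded; default k = 39, i.e. about half a second at 80 Hz) fed by a
shared pointwise bottleneck, plus a max-pool(3)→pointwise branch. The
concatenation is batch-normalized; after every second module a residual
path (pointwise conv + batch norm from the input of the previous module)
is added before the ReLU. Branch width doubles per module. The
reconstruction head is a single pointwise convolution back to the input
channels (length-preserving); the classification head is global average
pooling over time followed by a two-layer pointwise stack to one logit
with a sigmoid, matching the binary cross-entropy objective. Backbone
parameter shapes depend only on the config — never on the head — which is
what makes weight transfer between the reconstruction and classification
models exact.

The engine is the package's own: activations are (channels, time, batch)
arrays, pointwise convolutions are BLAS matrix products, depthwise
convolutions and max-pooling run in C++, and a small reverse-mode tape
accumulates gradients. Analytic gradients are checked against central
finite differences in the test suite (relative error below 1e-3 at machine
step 1e-5, the expected finite-difference noise floor). Two engine details
matter for reproducibility: batch-norm running statistics are updated via
the tape (models are plain R lists, so in-place mutation is not available),
and the head-only phase of FTL runs batch norm in inference mode so that a
frozen backbone is frozen *including* its running statistics.

## 6. Masked pre-training

Masks alternate masked/unmasked runs with geometric lengths on support
{1, 2, …}: masked mean lm = 3 samples, unmasked mean lu = lm(1−r)/r = 17,
giving masked fraction r = 0.15. The geometric is parameterized with
success probability 1/mean so run lengths are always at least 1. Masks are
drawn independently per channel (a shared-across-channels mode exists) and
resampled every epoch — fresh corruption maximizes coverage of each
segment; a freeze flag reproduces the fixed-mask alternative. The loss is
MSE averaged over masked positions only, which makes it scale-free in r;
an all-unmasked draw (vanishing probability at these lengths) would leave
the loss undefined, so that batch is skipped and the masks resampled at
the next epoch. Training uses Adam under a one-cycle schedule (cosine
warm-up over the first quarter of steps from peak/25 to the peak rate,
then cosine annealing to peak/1e4) — the "maximum learning rate" phrasing
of the protocol is the one-cycle convention of its toolchain. The
checkpoint with the best validation masked-MSE is retained; validation
masks are drawn once so checkpoint selection is not noisy.

Per fold i, two weight sets are produced: `W_PD(i)` (PD training groups
only) and `W_PD_HOA(i)` (PD plus HOA training groups), validated on the
corresponding validation sets.

## 7. Supervised variants

Per fold, the ten-variant cross of Table-1 structure: training set {TrnPD,
TrnPD∪TrnHOA} × initialization {RandInit, W_PD, W_PD,HOA} × scheme {FTL,
FTA}, where RandInit has no transfer scheme. FTL fine-tunes the head alone
for 10 epochs, then everything for 50; FTA fine-tunes everything for 50;
RandInit trains everything for 50. All use binary cross-entropy (with a
1e-7 probability clamp), batch size 64 (unspecified in the protocol;
exposed in the config), one-cycle at peak 1e-3, and best-validation-loss
checkpointing — best-epoch rather than last-epoch selection guards the
small-data regime against late overfitting, and no early stopping is
applied beyond it. Class imbalance is left unweighted; the stratified
folds bound the skew. Test sets never contain HOA groups.

## 8. Inference, metrics, noise

Segmented inference thresholds the per-window probability at 0.5, with
p = 0.5 mapping to "high" (a documented boundary convention). Max-vote
labels a recording with the mode of its windows' labels; ties — possible
with even window counts — break by the mean window probability against
0.5. F1 uses "high" as the positive class and reports 0 in the degenerate
no-positives case. The robustness probe adds N(0, 0.05²) noise to the
*standardized* test segments, so sigma is a fraction of unit variance; a
pre-standardization interpretation would be confounded by the per-segment
rescaling that immediately follows. No monotone degradation is asserted
anywhere: noise occasionally helps some tasks, and the reports simply
record both columns. Attribute aggregation pools all matching model × fold
rows (rather than averaging fold means), and the report labels it as such.

## 9. CKA

Linear CKA is computed in feature space, `||Y'X||_F^2 /
(||X'X||_F ||Y'Y||_F)` after column centering — algebraically identical to
the centered-Gram HSIC form (verified against it in the tests) and cheaper
when dimensions are far fewer than probe rows. The numerator averages both
evaluation orders so the index is bit-exactly symmetric despite float
summation order. Representations are module outputs averaged over time
(pooling, not flattening, keeps the dimension independent of input length).
The probe set for fold i is that fold's PD test segments, so no compared
model saw the probe rows during training; FTL models are excluded, leaving
one model per training-set × initialization cell; and pairing is
cross-group within the same fold only (models from different folds saw
different data and are not comparable). The pairing/averaging scheme behind
the study's published tables is not described there; the within-fold
cross-pair average is this package's documented choice.

## 10. Orchestration, seeds, problem sizes

`run_stage()` writes per-stage artifacts (CSV recordings and manifests,
segment stores, split manifests with the seed in a header line, weight and
model checkpoints, evaluation and CKA tables) under one output directory,
with a JSON manifest recording the config hash and per-stage seeds. One
global seed fans out to stage seeds by fixed offsets so any stage can be
rerun independently and reproducibly; reruns overwrite deterministically.
`epochs_scale` multiplies every epoch count uniformly for desk-scale runs.

The test suite runs everything at reduced scale as the package's own
standing choice of problem sizes: mechanics on 2-module, 2–6-filter
networks; masking statistics on 10,000 masks of length 4,000; split
integrity on a 200-group cohort; pre-training efficacy on an 8-participant
cohort for 5 epochs; and end-to-end severity recovery on a 40-PD-recording
cohort with severities {0,1,3,4}, K = 2 and 10 supervised epochs, where
the transfer-initialized classifier reaches max-vote accuracy well above
0.85. Study-scale settings (K = 5, 200/50-epoch schedules, 4-module
backbone) remain the constructor defaults.

## 11. Known limitations

* Synthetic cohorts are phenomenological, not biomechanical; accuracy on
  them bounds nothing about clinical data.
* The engine is CPU-only and sized for desk-scale experiments; study-scale
  epoch counts on large cohorts are possible but slow.
* Only the binary low/high task is implemented; 5-level ordinal grading,
  rigidity assessment and non-80-Hz resampling are out of scope.
* The reconstruction head used by the original protocol is not described
  there; any length-preserving head is compatible since only backbone
  weights transfer, and the pointwise head is the simplest such choice.
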