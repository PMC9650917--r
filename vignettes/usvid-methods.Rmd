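---
title: "Methods: attention-pooled classification of breast ultrasound video"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: attention-pooled classification of breast ultrasound video}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the model

Breast ultrasound is acquired as a cine sequence, but most computer-aided
diagnosis systems classify a single hand-picked key frame, discarding the
rest of the video and with it much of the diagnostic evidence. `usvid`
implements a video-level classifier that encodes every frame and aggregates
the per-frame evidence into one decision.

The pipeline has three learned stages.

**Frame encoder** $\Theta(\cdot)$. A ResNet-18-style convolutional backbone
adapted to this modality: one grayscale input channel; *group normalization*
in the stem and in every residual block in place of batch normalization
(video batches hold few distinct clips whose frames are highly correlated,
so batch statistics are degenerate — per-sample group statistics are not);
and one *non-local block* appended to each of stages 3 and 4. A non-local
block computes, for every spatial position, a softmax-weighted sum of
(bottlenecked, $C/2$-dimensional) features over *all* positions — embedded-
Gaussian self-attention — added residually. Its output projection is
initialized to zero, so each block starts as the identity and learns
long-range spatial interactions only insofar as they reduce the loss.
Global average pooling yields an $m$-vector per frame, $f_t = \Theta(v_t)$,
with $m = 8 \times \mathrm{base\_width}$ (512 at full width, 128 for the
tiny preset).

**Contrastive pretraining.** Before supervised training, the encoder can be
pretrained on unlabeled clips in the SimCLR style: sample $N$ clips and $M$
frames from each, produce two independently augmented views per frame
(flip, crop-then-resize, zoom, elastic deformation, brightness, contrast),
project the encoder features through a two-layer MLP head, L2-normalize, and
minimize the NT-Xent loss

$$\ell = \frac{1}{2NM}\sum_i -\log
  \frac{\exp(\mathrm{sim}(z_i, z_{p(i)})/\tau)}
       {\sum_{k \ne i} \exp(\mathrm{sim}(z_i, z_k)/\tau)},$$

with $\mathrm{sim}$ the cosine similarity, $\tau$ the temperature and
$p(\cdot)$ the positive-pair involution. The rationale is clinical:
ultrasound lesions show large within-class appearance variation across
probe positions, and instance-discrimination pretraining teaches the
encoder which appearance changes are nuisance (the augmentation family is
designed to mimic probe handling) before any labels are used.

**Temporal attention pooling and classification.** Frame features
$F^t \in \mathbb{R}^m$ are aggregated by a per-dimension attention: a
cascade of shared linear+Tanh layers $E^t_l = \sigma(W_l E^t_{l-1} + b_l)$
(with $E^t_0 = F^t$) produces logits $e^t \in (-1,1)^m$; a softmax *across
frames, separately for every feature dimension* gives a column-stochastic
attention matrix $A$; and the video-level feature is the per-dimension
convex combination $\bar F_i = \sum_t A^t_i F^t_i$. A single linear layer
$m \to 2$ with softmax and cross-entropy closes the model.

Two degeneracies are built into this aggregator and are used as test
oracles: uniform attention (zeroed cascade) makes $\bar F$ exactly the
frame mean (average pooling), and a per-dimension one-hot logit pattern
drives it toward the frame-wise maximum (max pooling). The aggregation is
invariant to frame order and accepts any sequence length, so inference uses
the full clip while training subsamples a fixed $T$.

## Positive-pair definition (an open design point)

The pretext formulation applies the augmentation per frame, which makes two
augmentations of the *same frame* the positive pair and everything else —
including other frames of the same video — negatives. The clinical
motivation (recognizing different cross-sections of one lesion) suggests an
alternative where two different frames of the same clip are positives. Both
are implemented (`positive_mode = "augmented_frame"` / `"same_video"`); the
strict per-frame reading is the default because it is the literal
formulation, and same-video frames in one batch then act as hard negatives.

Whether to freeze or fine-tune the encoder after pretraining is likewise
open; the package fine-tunes end to end (the pipeline is one network), and
`linear_probe()` provides the frozen-encoder protocol separately.

## Tunable parameters

| Parameter | Default (published schedule) | Tiny preset | Notes |
|---|---|---|---|
| supervised epochs / lr / momentum / weight decay | 320 / 1e-4 / 0.9 / 5e-4 | 12 / 0.01 / 0.9 / 5e-4 | SGD, cosine-annealed lr |
| sample length $T$ (frames) | 16 | 8 | training subsample; inference uses all frames |
| batch size (clips) | 8 | 8 | |
| pretext epochs / lr / weight decay | 8192 / 9e-3 / 1e-6 | 12 / 0.05 / 1e-6 | view batch 64 (paper) vs 48 (tiny) |
| pretext optimizer | LARS | SGD | see below |
| NT-Xent temperature $\tau$ | 0.5 | 0.5 | unpublished; SimCLR convention |
| projection head | $m \to m \to 128$ | same | ReLU between layers, L2-normalized output |
| attention cascade depth $L$ | 2 | 2 | depth unpublished; minimal nonlinear cascade |
| group-norm groups | 32 | gcd(32, C) | reduced when channels < 32 |
| encoder width | 64 (m = 512) | 16 (m = 128) | |

The LARS optimizer (layer-wise trust-ratio scaling over momentum SGD, with
biases and normalization affines excluded from adaptation and decay) is the
published pretext optimizer and the `paper_default` choice. Its trust ratio
is calibrated for large-batch regimes; at the 48-view micro-batches of the
tiny preset it scales steps down so far that the loss barely moves, so the
tiny preset uses the plain momentum-SGD fallback. Both are available via
`pretrain_config(optimizer = )`.

The tiny supervised preset also enables light augmentation of the sampled
training frames (crop 0.7–1.0, flip, small brightness/contrast, mild
elastic). With only 120 training clips the encoder otherwise memorizes the
speckle texture of individual clips (train loss → 0 with test accuracy near
chance); per-epoch augmentation plus jittered frame sampling closes that
generalization gap. The published schedule leaves this off.

## The synthetic data generator

No clinical recordings ship with the package; `generate_clip()` /
`generate_dataset()` emulate the relevant statistics of breast ultrasound
video so every stage is exercisable:

- **Speckle.** Each frame is `clean * (1 + s·Z)` with a standard-normal
  field `Z` and dispersion `s` (default 0.35), Gaussian-smoothed at
  σ = 1 px to reproduce the spatial correlation of speckle, then clipped to
  [0, 1]. A mild vertical intensity gradient mimics depth attenuation.
- **Lesion morphology by class**, following the standard sonographic cues:
  benign lesions are smooth ellipses, circumscribed (≈1.5 px margin ramp),
  at 0.4× background intensity; malignant lesions are star-convex polygons
  with per-vertex radial spiculation (amplitude `irregularity`, default
  0.45 of the radius), ill-defined margins (≈3.5 px ramp), markedly
  hypoechoic cores, and posterior acoustic shadowing (15–30 % attenuation
  below the mass). Population-level separation of the boundary-irregularity
  statistic (perimeter²/4π·area of an independently segmented mask) is a
  tested invariant.
- **Probe motion.** A bounded random-walk translation (default ≤1 px/frame),
  slow zoom within [0.97, 1.03], and a per-frame brightness offset relate
  consecutive frames, mimicking an operator adjusting the probe, scale and
  gain.
- **Format.** 8-bit grayscale PNGs `frame_0000.png …` per clip directory,
  `index.csv` (video_id, label, n_frames, relative_path) and `splits.json`;
  a write→read round trip is exact up to the 8-bit quantization.

The split is stratified by class at the requested test fraction (default
0.4, mirroring a roughly 40 % random test split on a cohort of 152
malignant / 116 benign sequences; stratification keeps small synthetic runs
balanced). Frame rate, acquisition resolution and other probe-level details
are not modeled; defaults (64×64, 8–16 frames) are free parameters chosen
for CPU-scale experiments.

**What passing tests do and do not show.** The generator produces lesions
whose class cues are stronger and cleaner than clinical reality: real
malignant/benign appearance overlaps heavily, and real speckle is
anisotropic and probe-dependent. Success of the scaled-down pipeline on
synthetic data demonstrates that the implementation can learn the intended
cues end to end — not that the method attains any particular clinical
accuracy.

## Numerical choices

- All softmaxes (attention, non-local, classifier, NT-Xent) subtract the
  per-row/column maximum before exponentiation.
- Group norm uses an ε of 1e-5 inside the square root; the variance is
  floored at 0.
- The projection head guards the zero-vector case with an ε = 1e-12
  denominator instead of erroring.
- Attention logits are Tanh-bounded in (−1, 1) by the literal cascade, so
  per-pair weight ratios cannot exceed e²; the exact max-pooling limit is
  mathematically unreachable under that bound. `attention_config(
  final_activation = "none")` removes the final Tanh where the unbounded
  regime is wanted; the Tanh default preserves the published formulation.
- AUC uses the Mann–Whitney rank statistic with ties counted ½; the ROC
  staircase keeps only the last point of each tied-score group, which makes
  its trapezoidal area equal the rank AUC to machine precision. AP is the
  step-interpolated area under the precision–recall curve. Malignant is the
  positive class and the decision threshold is 0.5 (both conventions, not
  published choices).
- Weight init: He-normal for convolutions and linear layers scaled by fan-in;
  non-local output projections zero; classifier init at sd 0.01.
- Every stochastic step (clip synthesis, splits, shuffling, frame sampling,
  augmentation, batch composition) derives its stream from an integer seed
  through a fixed multiplicative hash kept below 2³¹, so fixed-seed
  single-threaded reruns are bit-identical.

## Problem sizes used by the tests

The test suite and `scripts/acceptance.R` run everything at CPU scale,
chosen as the smallest sizes at which the scientific claims are visible:
unit oracles at tensor sizes of a few thousand elements; smoke training on
6–12 clips of 32×32; and the end-to-end study at the tiny preset — 100
clips per class of 8 frames at 64×64 (120 train / 80 test after the
stratified 40 % split), 12 supervised epochs, and 12 pretext epochs of 8
× 48-view batches for the transfer comparison, 3 seeds each. The published
schedule (320 supervised epochs at width 64; 8192 pretext epochs) is
encoded in `resolve_run_config("paper_default")` and is never exercised by
tests.

## Known limitations

- The backbone, autodiff and optimizers are purpose-built for this
  architecture; there is no GPU path, and double precision throughout makes
  large-scale training impractical — the package targets method study and
  reproduction at desk scale.
- DICOM/cine-loop ingestion, BI-RADS interpretation, and the comparison
  video architectures (R3D, TSM, LSTM aggregation, external attention
  variants) are out of scope; only the average/max-pooling degenerate
  baselines of the aggregator ship.
- `linear_probe()` uses a ridge-logistic fit (`glmnet`); with very few
  labeled videos its variance across seeds is substantial, which is why the
  transfer comparison is majority-over-seeds rather than a single run.
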