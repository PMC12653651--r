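---
title: "Diffusion-filtered contrastive pretraining for pest imagery: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Diffusion-filtered contrastive pretraining for pest imagery: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`cropclr` implements a three-stage label-efficient recognition pipeline for
field pest imagery: (1) self-supervised contrastive pretraining with a
momentum encoder and a queue of negatives, (2) a feature-space diffusion
filter that discards augmented view pairs whose reconstructed second-order
structure disagrees, and (3) few-shot fine-tuning through class-token
attention aggregation. This vignette explains each model, its assumptions,
the tunable parameters, and the numerical choices made where the design was
genuinely open. Everything runs on a single CPU; there is no deep-learning
framework underneath — the convolutional backbone, transformer blocks and
their backward passes are implemented directly on R matrices, which keeps
runs bit-reproducible under a fixed seed in single-threaded BLAS mode.

## 1. Augmentation and positive-pair construction

Images are standardized to a square target (default 512 px; 64 px in the
desk-scale profile): non-square inputs are center-cropped to the shorter
side and bilinearly resized; only when the aspect ratio exceeds 2 — where a
square crop would discard more than half of one dimension — is the image
scaled to fit and zero-padded. Color normalization applies histogram
equalization to the luminance channel of a YCbCr decomposition (chroma
untouched; the inverse transform is the exact matrix inverse, so the
decomposition round-trips to machine precision) followed by gray-world
white balance, whose per-channel gains equalize the pre-clip channel means
exactly.

A positive pair is two independent augmentation draws from one source
image. Each draw samples

* rotation θ ~ U(−30°, 30°), bilinear resampling, reflective border;
* horizontal flip with probability 0.5;
* zoom s ~ U(0.8, 1.2), applied after rotation (the order is a fixed
  convention for determinism);
* 3×3 Gaussian blur with σ ~ U(0.5, 1.5);
* 1–3 cutout rectangles, each covering a uniform fraction U(0.05, 0.20) of
  the image area, filled with mid-gray (128) or zeros. Integer rounding of
  the rectangle sides is nudged back into the admissible area band so every
  realized rectangle respects the bounds exactly.

Disabling every perturbation reduces a view to the standardized image
bit-for-bit; this identity property is what makes the pipeline's unit tests
exact. Color normalization is applied identically at pretraining and at
inference (a single flag controls both paths).

## 2. Viewpoint-invariant contrastive encoding

A residual convolutional backbone `f` and a two-layer projection head `g`
(512 → 128 → 128, rectifier in between; a single affine adapter bridges the
backbone width to 512 when they differ) map each view to a unit-norm
embedding `z`. View one goes through the primary encoder, view two through
a momentum encoder of identical shape updated by an exponential moving
average θ′ ← m·θ′ + (1 − m)·θ with m = 0.999. Momentum embeddings are
pushed into a FIFO queue of capacity K that serves as the negative set of
the InfoNCE loss

L = −log [ exp(sim(z_i, z_j)/τ) / (exp(sim(z_i, z_j)/τ) + Σ_k exp(sim(z_i, z_k)/τ)) ]

with temperature τ = 0.2 and cosine similarity. The loss is one-directional
(no symmetrized pass with the views swapped). The queue starts pre-filled
with seeded random unit vectors so the loss is defined from the first step;
the placeholders are evicted FIFO within a few batches. K defaults to 4096
(256 in the desk-scale profile) — the canonical much larger queues add
nothing at these dataset sizes.

## 3. The diffusion consistency filter

Aggressive augmentation can destroy the diagnostic content of a view —
a cutout that happens to cover the lesion produces a *pseudo-positive*
pair whose views are not semantically equivalent. The filter works in
feature space: the backbone's last spatial stage is passed through a 1×1
channel adapter and interpolated to an H×W×C grid (16×16×128 by default,
8×8×32 in the desk-scale profile). The forward process draws

e_t ~ N(α_t · e_0, (1 − α_t) · I)

elementwise. This mean coefficient α_t (rather than √ of a cumulative
product) is deliberately implemented as stated; the standard
denoising-diffusion parameterization is available through
`schedule_convention = "sqrt_cumulative"`. The reverse model is a small
transformer (4 layers, 8 heads, feed-forward width 512 by default; 2/2/64
in the desk-scale profile) with learned positional and timestep embeddings
and two heads: a mean branch μ(e_t, t) and a softplus-positive scale branch
η(e_t, t). The mean branch is parameterized residually, μ = e_t + W·h with
a small-scale output weight, so an untrained network is close to the
identity — reconstruction then degrades gracefully rather than collapsing
all inputs to a common output, which keeps the filter informative from the
first training step. The network trains with the trajectory reconstruction
objective Σ_t ‖e_{t−1} − μ(e_t, t)‖²; η does not appear in that objective
and is an output-only branch by default. During pretraining the sum over
timesteps is estimated by uniformly subsampling 2 of the T timesteps and
rescaling (an unbiased estimator; the exported loss operation always
evaluates the full sum).

After reconstructing both views' maps from their terminal noisy states, the
filter compares second-order structure:

D(ẽ₁, ẽ₂) = 1 − Tr(Σ₁ Σ₂) / (‖Σ₁‖_F · ‖Σ₂‖_F)

where Σ is the spatial covariance of the map. For positive semi-definite
inputs D lies in [0, 1] (Cauchy–Schwarz for the trace inner product), is
symmetric, and is zero exactly when the covariances coincide up to scale.
A pair is retained when D falls below δ; by default δ is the 0.8 batch
quantile of the current distances (retain ~80%), with a fixed-δ mode
available. Discarded pairs are excluded from the InfoNCE term of that step
but their momentum embeddings still enter the queue — they remain perfectly
valid negatives for other images. The joint objective is
L_contrast + λ·L_diff with λ = 0.5, and the diffusion gradient reaches the
encoder through e₀ (a stop-gradient flag can sever it).

**Schedule choice.** The per-step coefficients are linear from 0.95 down to
0.8 over T = 10 steps. The terminal signal level matters on small grids: at
a terminal α of 0.5 the covariance of the noisy map is 0.25·Σ + 0.5·I and,
with only 64 spatial observations, the Wishart sampling noise of the
covariance estimate dominates the structural signal, leaving the filter
unable to separate destroyed views from ordinary ones. At α_T = 0.8 enough
second-order structure survives the round trip for corrupted pairs to score
systematically higher — the test-suite checks exactly this stochastic
ordering, and the filter-ablation test checks that gating by it does not
hurt downstream accuracy. A deeper terminal noising is entirely reasonable
for the 16×16×128 grid at full scale and remains one configuration flag
away.

## 4. Few-shot fine-tuning by class-token attention

After pretraining the backbone is frozen — its parameter checksum is
asserted unchanged — and only a light attention head trains on k labeled
images per class. N learnable class tokens (one per label; optional
register tokens can be appended) attend over the projected patch features
of the frozen grid through

Attention(Q, K, V) = softmax(QKᵀ/√d_k) V,  Q = T_c W_Q, K = P W_K, V = P W_V

inside 3 pre-norm transformer layers (8 heads, feed-forward 128 → 256 →
128, residual connections). Patch tokens are ordered row-major, so patch k
sits at grid cell (k div W, k mod W). The N class-token outputs are
concatenated into one vector and mapped by a single affine layer with a
logistic squashing to per-class probabilities; training minimizes
multi-label binary cross-entropy against one-hot targets, and evaluation
decodes single labels by argmax — this satisfies both the multi-label loss
formulation and the single-label evaluation protocol. The optimizer is
momentum gradient descent (lr 10⁻³, momentum 0.9, weight decay 5×10⁻⁴) with
optional early stopping on a validation fold. Training is stage-wise: the
joint pretraining objective in stage one, the classification loss alone in
stage two; the fully-joint three-term objective is available as
`total_loss()` for experiments that co-train.

Head pruning ranks heads by the mean (over a calibration batch) of the
maximum attention mass any class token places on a single patch — heads
that focus sharply on discriminative patches score high — and keeps the
top-k with ties broken toward the lower head index; pruning to the full
head count is an exact no-op. Thresholding a class token's attention row at
a quantile yields a binary pseudo-mask over the patch grid for
localization.

## 5. The synthetic data generator

The generator emulates what matters to this pipeline: classes that differ
by *texture motif* (spots, stripes, blotches, rings — echoing necrotic
spots, feeding streaks, bronzing patches and ring lesions) drawn over a
leaf-like background (green base, vein bands, smooth mottle), with nuisance
variation in illumination gain (U(0.75, 1.25)), small viewpoint rotation
(±10°) and defocus blur (σ up to 0.8). Every image is a pure function of
(spec, class, seed). A trivial pixel-statistics classifier already exceeds
chance on these classes — the suite checks this, which guarantees that
downstream learning tests are not vacuous. What the generator does *not*
emulate: photorealistic pests, occlusion by other plants, scale variation
across fields, class imbalance, and label noise. Passing the desk-scale
tests therefore demonstrates that the machinery trains, filters and
transfers as specified — not that field-scale accuracy figures transfer.

## 6. Desk-scale study configuration

The `"test"` profile used by the test-suite and the acceptance study: 64 px
inputs, a 3-stage backbone (8/16/32 channels, stride 2 each), an 8×8×32
feature grid, a 2-layer/2-head/64-wide reconstruction net, queue capacity
256, batch 32, Adam at lr 10⁻⁴. The end-to-end study generates 100 images
per class for 3 classes, pretrains 10 epochs, fine-tunes 10-shot with early
stopping on the validation fold, and evaluates on the 15% test split; the
robustness protocol perturbs test images with rotations of 10–50°, a
central 15% occlusion and ±20% brightness shifts, reporting the fraction of
unchanged argmax labels and the mean absolute change of the top
probability. A composite of those two numbers — consistency × (1 −
confidence variation) — is available behind a flag and is labeled
non-canonical: no standard formula exists for such a summary, and the two
components are more informative separately.

## 7. Numerical choices and degenerate inputs

* Pixel values are doubles in [0, 255] end to end; every augmentation clips
  back into range. PNG fixtures quantize to 8 bits; tests that require
  bit-exactness quantize first.
* The luminance histogram uses 256 integer bins; a single-bin (constant)
  luminance maps to itself rather than dividing by zero.
* Gray-world balance refuses zero-mean channels; the structural distance
  refuses zero covariance matrices; InfoNCE refuses an empty queue and
  non-positive temperatures — degenerate inputs fail loudly, never
  silently.
* Cutout rectangles are nudged after integer rounding so the realized area
  honours the configured band exactly.
* Quantile thresholds (filter δ, pseudo-masks) use the default continuous
  quantile definition (type 7); filter comparisons are strict (`D < δ`).
* All stochastic draws go through isolated seeded streams that never touch
  the global RNG; derived seeds stay below 2³¹.
* Per-class split quotas use largest-remainder apportionment with a
  rotating tie-break so aggregate totals track the requested ratios.

## 8. Known limitations

The backbone's "paper" profile is a residual network of the ResNet-50
family, not a layer-exact replica, and pretrained initialization is
optional and unused in tests. Momentum-encoder benefits are muted at
desk scale: with m = 0.999 and a few hundred optimizer steps the momentum
encoder stays close to its initialization, so the contrastive target is
nearly fixed; this is the faithful behaviour of the update rule at small
step counts, not a defect of it. The diffusion filter's selectivity depends
on the signal-to-noise ratio of the terminal state relative to the spatial
grid size (Section 3); at full scale the default would plausibly move back
toward deeper noising. Fine-tuning quality at k-shot scale varies by a few
points across seeds — the acceptance study reports single-seed numbers and
the suite checks a three-seed mean only where a direction, not a level, is
asserted.
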