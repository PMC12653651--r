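# cropclr

Label-efficient pest-image classification in R: self-supervised contrastive
pretraining with a momentum encoder, a feature-space **diffusion consistency
filter** that removes misleading augmented pairs, and few-shot fine-tuning
through **class-token attention aggregation**.

Field imagery of crop pests is expensive to label: symptoms vary by species
and growth stage, and experts are scarce. The pipeline here learns general
representations from *unlabeled* images and then adapts them to pest
classes from as few as 5–10 labeled images per class. It is aimed at
researchers in agricultural image analysis who want a fully inspectable,
CPU-reproducible implementation of this training recipe — every layer and
backward pass is plain R matrix algebra, with no deep-learning framework
underneath.

## The method

**Stage 1 — viewpoint-invariant contrastive encoding.** Two augmented views
`x_i = t_i(x)`, `x_j = t_j(x)` of each image (rotation U(−30°, 30°), flip,
scale U(0.8, 1.2), 3×3 Gaussian blur with σ ~ U(0.5, 1.5), cutout covering
5–20% of the area, after luminance equalization and gray-world balance) are
embedded by a primary encoder and a momentum encoder
(θ′ ← m·θ′ + (1 − m)·θ, m = 0.999). With a FIFO queue of momentum-encoded
negatives z_k⁻, training minimizes InfoNCE:

    L_contrast = −log exp(sim(z_i, z_j)/τ) /
                 (exp(sim(z_i, z_j)/τ) + Σ_k exp(sim(z_i, z_k⁻)/τ)),  τ = 0.2

**Stage 1b — diffusion filtering of pseudo-positives.** An augmentation can
destroy the diagnostic texture it was supposed to preserve. Each view's
spatial feature map e₀ is progressively noised, e_t ~ N(α_t e₀, (1 − α_t)I),
reconstructed by a small transformer decoder trained with
Σ_t ‖e_{t−1} − μ_θ(e_t, t)‖², and the pair is kept only when the structural
distance between the reconstructions' covariance matrices,

    D_struct = 1 − Tr(Σ₁Σ₂) / (‖Σ₁‖_F ‖Σ₂‖_F),

falls below a threshold (by default the 0.8 batch quantile). The joint
objective is `L_contrast + 0.5 · L_diff`.

**Stage 2 — few-shot fine-tuning.** The backbone is frozen; N learnable
class tokens attend over the frozen patch features,
`softmax(QKᵀ/√d_k)V` with `Q = W_Q T_c`, `K = W_K P`, `V = W_V P`, inside a
3-layer/8-head transformer head trained with multi-label binary
cross-entropy on k images per class. Attention heads can be pruned by
importance, and thresholded attention rows yield localization pseudo-masks.

## Worked example

```r
library(cropclr)

# 3 pest classes, 100 synthetic images each, 70/15/15 split
spec <- synthetic_dataset_spec(n_classes = 3, per_class_count = 100,
                               image_size = 64, seed = 20)
manifest <- generate_dataset(spec, "pest_data")
manifest <- split_dataset(manifest, c(0.70, 0.15, 0.15), seed = 1)

# stage 1: contrastive + diffusion pretraining (desk-scale profile)
config <- run_config("test", epochs = 10, batch_size = 32, seed = 1)
ck <- pretrain(config, manifest, verbose = TRUE)
#> epoch 1: contrast 4.0784 diff 6008.8487 joint 3008.5027 keep 0.78
#> epoch 2: contrast 5.5025 diff 5153.3300 joint 2582.1675 keep 0.78
#> ...
#> epoch 10: contrast 5.5223 diff 3626.0357 joint 1818.5401 keep 0.78

# stage 2: 10-shot fine-tuning, early stopping on the val fold
model <- finetune_pipeline(ck, manifest, k = 10, n_classes = 3,
                           seed = 1, epochs = 200, use_val = TRUE)
evaluate_model(model, manifest, "test")$accuracy
#> [1] 0.8
```

`keep` is the filter's retention rate (≈0.8 by construction of the batch
quantile); `contrast` rises early while the queue fills with real momentum
embeddings and then plateaus; the reconstruction loss (`diff`) falls as the
decoder learns to denoise. The final number is test-split accuracy against
a 1/3 chance level. A robustness report
(`prediction_consistency(model, samples)`) gives the fraction of test
images whose predicted label survives rotations of 10–50°, occlusion and
brightness shifts, plus the mean absolute change in top probability.

The command-line front end wraps the same functions:

```sh
Rscript inst/cli/cropclr.R generate-data --classes 3 --per-class 100 --size 64 --seed 1 --out pest_data
Rscript inst/cli/cropclr.R pretrain --manifest pest_data/manifest.csv --seed 1 --out ck.rds
Rscript inst/cli/cropclr.R finetune --checkpoint ck.rds --manifest pest_data/manifest.csv --kshot 10 --classes 3 --out model.rds
Rscript inst/cli/cropclr.R evaluate --model model.rds --manifest pest_data/manifest.csv
```

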