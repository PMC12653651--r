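Package: cropclr
Title: Contrastive Pretraining with Diffusion-Consistency Pair Filtering for Pest Image Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Self-supervised contrastive representation learning for field pest
    imagery with a momentum encoder and negative queue (InfoNCE), viewpoint
    augmentations (rotation, flip, scale, Gaussian blur, cutout, histogram
    equalization, gray-world balance), a feature-space diffusion filter that
    discards augmented view pairs whose reconstructed second-order structure
    disagrees (covariance structural distance), and few-shot fine-tuning via
    class-token attention aggregation with head pruning and pseudo-masks.
    Includes a deterministic synthetic pest-image generator, dataset
    manifests and stratified splitting, classification and segmentation
    metrics, and a prediction-consistency robustness protocol, all runnable
    on a single CPU at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    png,
    jpeg,
    stats,
    utils,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    EBImage,
    jsonlite,
    optparse
Config/testthat/edition: 3
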