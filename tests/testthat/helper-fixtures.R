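# Shared fixtures: everything generated in code, cached per test session.

tiny_spec <- function(n_classes = 3, per_class = 6, size = 64, seed = 7) {
  synthetic_dataset_spec(n_classes = n_classes, per_class_count = per_class,
                         image_size = size, seed = seed)
}

# one cached sample per call signature
fixture_image <- local({
  cache <- new.env(parent = emptyenv())
  function(class_id = 0, seed = 1, size = 64) {
    key <- paste(class_id, seed, size)
    if (is.null(cache[[key]])) {
      cache[[key]] <- generate_synthetic_image(class_id, tiny_spec(size = size), seed)
    }
    cache[[key]]
  }
})

# flat mid-gray test image of a given size
gray_image <- function(size = 64, value = 128) {
  image_sample(array(value, c(size, size, 3)), source_id = "gray")
}

# a small on-disk dataset + stratified split, cached for the session
fixture_dataset <- local({
  cache <- new.env(parent = emptyenv())
  function(per_class = 8, seed = 7) {
    key <- paste(per_class, seed)
    if (is.null(cache[[key]])) {
      dir <- file.path(tempdir(), paste0("cropclr_ds_", per_class, "_", seed))
      man <- generate_dataset(tiny_spec(per_class = per_class, seed = seed), dir)
      cache[[key]] <- split_dataset(man, c(0.6, 0.2, 0.2), seed = 1)
    }
    cache[[key]]
  }
})

tiny_encoder <- local({
  cache <- new.env(parent = emptyenv())
  function(seed = 1) {
    key <- as.character(seed)
    if (is.null(cache[[key]])) {
      cache[[key]] <- encoder_init(encoder_config("test"), new_rng(seed))
    }
    cache[[key]]
  }
})

# independent connected-component count (EBImage oracle)
blob_count <- function(mask) {
  lab <- EBImage::bwlabel(mask)
  max(lab)
}

random_unit <- function(rng, d) {
  v <- rng_norm(rng, d)
  v / sqrt(sum(v^2))
}

random_psd <- function(rng, d) {
  A <- matrix(rng_norm(rng, d * d), d, d)
  crossprod(A) / d
}
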