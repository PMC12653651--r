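# Synthetic pest-image fixtures, dataset manifests, folder I/O and
# stratified splitting.  Images are procedural: per-class texture motifs
# (spots, stripes, blotches, rings) drawn over a leaf-like background with
# nuisance variation in illumination, blur and slight viewpoint rotation.
# Everything is a pure function of (spec, seed).

#' Construct an image sample
#'
#' The unit of all image I/O in the package: an RGB raster with values in
#' `[0, 255]`, an optional integer class label and a unique source id.
#'
#' @param pixels numeric `H x W x 3` array with finite values in `[0, 255]`.
#' @param label optional class index in `0..n_classes-1`.
#' @param source_id unique string identifying the originating capture; views
#'   derived from the same capture share it.
#' @return an object of class `image_sample`.
#' @export
image_sample <- function(pixels, label = NULL, source_id = "img") {
  d <- dim(pixels)
  if (is.null(d) || length(d) != 3L || d[3] != 3L) {
    stop("pixels must be an H x W x 3 array", call. = FALSE)
  }
  if (d[1] < 32L || d[2] < 32L) stop("image sides must be >= 32 pixels", call. = FALSE)
  if (!all(is.finite(pixels))) stop("pixels must be finite", call. = FALSE)
  structure(list(pixels = pixels, label = label, source_id = source_id),
            class = "image_sample")
}

#' @export
print.image_sample <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<image_sample %dx%dx3 id=%s label=%s>\n", d[1], d[2],
              x$source_id, if (is.null(x$label)) "NA" else x$label))
  invisible(x)
}

#' Describe a synthetic dataset
#'
#' @param n_classes number of pest classes (>= 2).
#' @param per_class_count images generated per class (>= 1).
#' @param image_size square image side in pixels (>= 32).
#' @param motif_params optional list (one entry per class) with fields
#'   `kind` (one of `"spots"`, `"stripes"`, `"blotches"`, `"rings"`),
#'   `density`, `scale` and `color` (RGB in 0-255). When `NULL` a default
#'   palette of visually distinct motifs is assigned.
#' @param nuisance_params list with `brightness` range (multiplicative) and
#'   `blur` sigma range; defaults emulate mild field illumination and focus
#'   variation.
#' @param seed integer; the master seed all generation derives from.
#' @return an object of class `synthetic_dataset_spec`.
#' @export
synthetic_dataset_spec <- function(n_classes = 3, per_class_count = 10,
                                   image_size = 64, motif_params = NULL,
                                   nuisance_params = list(brightness = c(0.75, 1.25),
                                                          blur = c(0, 0.8)),
                                   seed = 1L) {
  stopifnot(n_classes >= 2, per_class_count >= 1, image_size >= 32)
  if (is.null(motif_params)) motif_params <- default_motifs(n_classes)
  stopifnot(length(motif_params) == n_classes)
  structure(list(n_classes = as.integer(n_classes),
                 per_class_count = as.integer(per_class_count),
                 image_size = as.integer(image_size),
                 motif_params = motif_params,
                 nuisance_params = nuisance_params,
                 seed = as.integer(seed)),
            class = "synthetic_dataset_spec")
}

# distinct motif kind + color per class; hues chosen to mimic pest damage
# (necrotic browns, chlorotic yellows, mite bronzing, rust pustules)
default_motifs <- function(n_classes) {
  kinds <- c("spots", "stripes", "blotches", "rings")
  colors <- list(c(105, 60, 30), c(200, 180, 60), c(150, 120, 40),
                 c(180, 80, 40), c(90, 40, 70), c(220, 140, 90))
  lapply(seq_len(n_classes), function(i) {
    list(kind = kinds[(i - 1L) %% length(kinds) + 1L],
         density = 14 + 4 * ((i - 1L) %/% length(kinds)),
         scale = 3 + ((i - 1L) %% 3),
         color = colors[[(i - 1L) %% length(colors) + 1L]])
  })
}

# smooth random field: coarse gaussian grid bilinearly upsampled
smooth_field <- function(size, coarse, rng, sd = 1) {
  g <- matrix(rng_norm(rng, coarse * coarse, 0, sd), coarse, coarse)
  M <- resize_matrix(coarse, coarse, size, size)
  matrix(M %*% as.vector(g), size, size)
}

#' Generate one synthetic pest image
#'
#' Deterministic for fixed `(class_id, spec, seed)`: the drawing stream is
#' derived from `spec$seed`, the class and the per-image seed, and never
#' touches the global RNG.
#'
#' @param class_id class index in `0..spec$n_classes-1`.
#' @param spec a [synthetic_dataset_spec()].
#' @param seed per-image seed (e.g. the image index).
#' @return an [image_sample()] with `label = class_id`.
#' @export
generate_synthetic_image <- function(class_id, spec, seed) {
  stopifnot(inherits(spec, "synthetic_dataset_spec"))
  if (class_id < 0 || class_id >= spec$n_classes) {
    stop("class_id out of range [0, n_classes)", call. = FALSE)
  }
  S <- spec$image_size
  rng <- new_rng((spec$seed * 100003 + class_id * 8191 + seed * 131) %% 2147483647)

  # leaf-like background: green base with vein-ish gradient and mottle
  base <- c(70, 120, 55) + rng_norm(rng, 3, 0, 8)
  yy <- matrix(seq(0, 1, length.out = S), S, S)
  xx <- t(yy)
  mottle <- smooth_field(S, 6, rng, sd = 10)
  veins <- 6 * sin(xx * (8 + rng_unif(rng, 1, -2, 2)) * pi + yy * 2)
  px <- array(0, c(S, S, 3))
  for (ch in 1:3) px[, , ch] <- base[ch] + mottle + veins * (ch == 2)

  mp <- spec$motif_params[[class_id + 1L]]
  mask <- motif_mask(S, mp, rng)
  alpha <- 0.85 * mask
  for (ch in 1:3) px[, , ch] <- (1 - alpha) * px[, , ch] + alpha * mp$color[ch]

  # nuisance: illumination gain, slight viewpoint rotation, defocus blur
  np <- spec$nuisance_params
  gain <- rng_unif(rng, 1, np$brightness[1], np$brightness[2])
  px <- px * gain
  theta <- rng_unif(rng, 1, -10, 10)
  px <- warp_rotate_scale(px, theta, 1)
  sig <- rng_unif(rng, 1, np$blur[1], np$blur[2])
  if (sig > 0.05) px <- blur3(px, sig)
  px <- pmin(pmax(px, 0), 255)
  image_sample(px, label = as.integer(class_id),
               source_id = sprintf("c%d_s%d", class_id, seed))
}

# binary-ish (0..1) motif mask on an S x S grid
motif_mask <- function(S, mp, rng) {
  yy <- matrix(seq_len(S), S, S)
  xx <- t(yy)
  m <- matrix(0, S, S)
  kind <- mp$kind
  dens <- mp$density
  sc <- mp$scale * S / 64        # scale in 64-px units
  if (kind == "spots") {
    for (i in seq_len(dens)) {
      cx <- rng_unif(rng, 1, 1, S); cy <- rng_unif(rng, 1, 1, S)
      r <- sc * rng_unif(rng, 1, 0.6, 1.4)
      m <- pmax(m, (sqrt((xx - cx)^2 + (yy - cy)^2) < r) * 1)
    }
  } else if (kind == "stripes") {
    phi <- rng_unif(rng, 1, -0.3, 0.3) + pi / 5
    period <- sc * 2.5
    phase <- rng_unif(rng, 1, 0, 2 * pi)
    wav <- sin(2 * pi * (xx * cos(phi) + yy * sin(phi)) / period + phase)
    m <- (wav > 0.35) * 1
  } else if (kind == "blotches") {
    for (i in seq_len(max(2, dens %/% 4))) {
      cx <- rng_unif(rng, 1, 1, S); cy <- rng_unif(rng, 1, 1, S)
      for (j in 1:5) {
        ox <- rng_norm(rng, 1, 0, sc); oy <- rng_norm(rng, 1, 0, sc)
        r <- sc * rng_unif(rng, 1, 0.8, 1.8)
        m <- pmax(m, (sqrt((xx - cx - ox)^2 + (yy - cy - oy)^2) < r) * 1)
      }
    }
  } else if (kind == "rings") {
    for (i in seq_len(dens)) {
      cx <- rng_unif(rng, 1, 1, S); cy <- rng_unif(rng, 1, 1, S)
      r <- sc * rng_unif(rng, 1, 1.2, 2.2)
      d <- sqrt((xx - cx)^2 + (yy - cy)^2)
      m <- pmax(m, (abs(d - r) < sc * 0.35) * 1)
    }
  } else {
    stop("unknown motif kind: ", kind, call. = FALSE)
  }
  m
}

#' Generate a dataset of synthetic images on disk
#'
#' Writes `n_classes * per_class_count` PNG files plus a `manifest.csv`
#' (columns `path,source_id,label,split`) into `out_dir`.
#'
#' @param spec a [synthetic_dataset_spec()].
#' @param out_dir output directory (created if missing).
#' @return the manifest `data.frame`, invisibly written to
#'   `file.path(out_dir, "manifest.csv")`.
#' @export
generate_dataset <- function(spec, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir, call. = FALSE)
  recs <- list()
  for (cls in seq_len(spec$n_classes) - 1L) {
    for (i in seq_len(spec$per_class_count)) {
      img <- generate_synthetic_image(cls, spec, i)
      path <- file.path(out_dir, sprintf("class%d_%03d.png", cls, i))
      png::writePNG(img$pixels / 255, path)
      recs[[length(recs) + 1L]] <- data.frame(
        path = path, source_id = img$source_id,
        label = cls, split = NA_character_, stringsAsFactors = FALSE)
    }
  }
  manifest <- do.call(rbind, recs)
  write_manifest(manifest, file.path(out_dir, "manifest.csv"))
  manifest
}

#' Write / read a dataset manifest
#'
#' @param manifest data.frame with columns `path`, `source_id`, `label`, `split`.
#' @param path CSV file path.
#' @export
write_manifest <- function(manifest, path) {
  utils::write.csv(manifest, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path, call. = FALSE)
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("path", "source_id", "label", "split")
  if (!all(need %in% names(m))) {
    stop("manifest must have columns path,source_id,label,split", call. = FALSE)
  }
  validate_manifest(m)
  m
}

validate_manifest <- function(m) {
  if (anyDuplicated(m$source_id)) stop("source_ids must be unique", call. = FALSE)
  ok <- is.na(m$split) | m$split %in% c("train", "val", "test")
  if (!all(ok)) stop("split labels must be train/val/test or NA", call. = FALSE)
  invisible(m)
}

#' Assign train/val/test splits, stratified by label
#'
#' Each source id lands in exactly one split; counts follow the requested
#' ratios by largest-remainder apportionment within each label (a rotating
#' tie-break keeps the aggregate totals on target). Deterministic under
#' `seed`.
#'
#' @param manifest a manifest data.frame.
#' @param ratios length-3 positive fractions (train, val, test), summing to ~1.
#' @param seed integer seed for the shuffle.
#' @return the manifest with its `split` column filled.
#' @export
split_dataset <- function(manifest, ratios = c(0.70, 0.15, 0.15), seed = 1L) {
  stopifnot(length(ratios) == 3, all(ratios >= 0), abs(sum(ratios) - 1) < 1e-6)
  validate_manifest(manifest)
  rng <- new_rng(seed)
  splits <- c("train", "val", "test")
  n_active <- sum(ratios > 0)
  out <- manifest
  rotation <- 0L
  for (lab in sort(unique(manifest$label))) {
    idx <- which(manifest$label == lab)
    if (length(idx) < n_active) {
      stop("label ", lab, " has fewer images than active splits", call. = FALSE)
    }
    idx <- idx[rng_sample(rng, seq_along(idx))]
    quota <- length(idx) * ratios
    counts <- floor(quota)
    rem <- length(idx) - sum(counts)
    if (rem > 0) {
      frac <- quota - counts
      # rotate the preference order across labels so ties don't pile up
      pref <- ((seq_along(splits) - 1 + rotation) %% 3) + 1
      ord <- order(-frac, pref)
      counts[ord[seq_len(rem)]] <- counts[ord[seq_len(rem)]] + 1
      rotation <- rotation + 1L
    }
    assign_vec <- rep(splits, times = counts)
    out$split[idx] <- assign_vec
  }
  out
}

#' Read an image folder via its manifest
#'
#' @param manifest_path path to a manifest CSV.
#' @return list with `samples` (list of [image_sample()]) and `manifest`.
#' @export
read_image_folder <- function(manifest_path) {
  manifest <- read_manifest(manifest_path)
  samples <- lapply(seq_len(nrow(manifest)), function(i) {
    p <- manifest$path[i]
    if (!file.exists(p)) stop("missing image file: ", p, call. = FALSE)
    px <- read_image_file(p)
    image_sample(px, label = if (is.na(manifest$label[i])) NULL else manifest$label[i],
                 source_id = manifest$source_id[i])
  })
  list(samples = samples, manifest = manifest)
}

read_image_file <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    png = png::readPNG(path),
    jpg = ,
    jpeg = jpeg::readJPEG(path),
    stop("unsupported image format: ", ext, call. = FALSE))
  if (length(dim(raw)) == 2L) raw <- array(rep(raw, 3), c(dim(raw), 3))
  if (dim(raw)[3] > 3L) raw <- raw[, , 1:3, drop = FALSE]
  raw * 255
}

#' Write image samples and a manifest to a folder
#'
#' @param samples list of [image_sample()].
#' @param out_dir output directory.
#' @param format `"png"` (lossless, default) or `"jpeg"`.
#' @return manifest data.frame (also written as `manifest.csv`).
#' @export
write_image_folder <- function(samples, out_dir, format = c("png", "jpeg")) {
  format <- match.arg(format)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  recs <- lapply(seq_along(samples), function(i) {
    s <- samples[[i]]
    path <- file.path(out_dir, sprintf("%s.%s", s$source_id, format))
    if (format == "png") {
      png::writePNG(s$pixels / 255, path)
    } else {
      jpeg::writeJPEG(s$pixels / 255, path, quality = 0.95)
    }
    data.frame(path = path, source_id = s$source_id,
               label = if (is.null(s$label)) NA_integer_ else s$label,
               split = NA_character_, stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, recs)
  write_manifest(manifest, file.path(out_dir, "manifest.csv"))
  manifest
}
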