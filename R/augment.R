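# Preprocessing and viewpoint augmentation: standardization to a square
# target, luminance equalization, gray-world white balance, random
# rotation/flip/scale, 3x3 Gaussian blur, cutout occlusion, and positive
# view-pair construction for contrastive learning.

#' Augmentation parameters
#'
#' Defaults follow the preprocessing protocol the models are trained with:
#' 512 px square target, rotation U(-30, 30) degrees, horizontal flip with
#' probability 0.5, scale U(0.8, 1.2), 3x3 Gaussian blur with sigma
#' U(0.5, 1.5), and 1-3 cutout rectangles each covering U(0.05, 0.20) of
#' the image area, filled with mid-gray (128) or zeros.
#'
#' @param target_size square output side in pixels.
#' @param rotation_range degrees, `c(lo, hi)`.
#' @param flip_prob horizontal flip probability.
#' @param scale_range zoom factor range.
#' @param blur_kernel blur kernel side (fixed 3).
#' @param sigma_range blur standard-deviation range; a zero draw disables blur.
#' @param cutout_fraction_range per-rectangle area as a fraction of image area.
#' @param cutout_fill `"gray"` (value 128) or `"zero"`.
#' @param n_cutouts_range integer range for the number of rectangles;
#'   `c(0, 0)` disables cutout.
#' @param color_normalize apply luminance equalization + gray-world balance
#'   after standardization (the same flag is honoured at inference).
#' @param identity when `TRUE`, return a parameter set with every
#'   perturbation disabled, so the pipeline reduces to standardization.
#' @return an object of class `augmentation_params`.
#' @export
augmentation_params <- function(target_size = 512,
                                rotation_range = c(-30, 30),
                                flip_prob = 0.5,
                                scale_range = c(0.8, 1.2),
                                blur_kernel = 3,
                                sigma_range = c(0.5, 1.5),
                                cutout_fraction_range = c(0.05, 0.20),
                                cutout_fill = c("gray", "zero"),
                                n_cutouts_range = c(1, 3),
                                color_normalize = TRUE,
                                identity = FALSE) {
  cutout_fill <- match.arg(cutout_fill)
  if (identity) {
    rotation_range <- c(0, 0); flip_prob <- 0; scale_range <- c(1, 1)
    sigma_range <- c(0, 0); n_cutouts_range <- c(0, 0); color_normalize <- FALSE
  }
  stopifnot(target_size >= 32, blur_kernel == 3,
            rotation_range[1] <= rotation_range[2],
            scale_range[1] <= scale_range[2], scale_range[1] > 0,
            sigma_range[1] <= sigma_range[2], sigma_range[1] >= 0,
            flip_prob >= 0, flip_prob <= 1,
            cutout_fraction_range[1] <= cutout_fraction_range[2],
            cutout_fraction_range[1] > 0, cutout_fraction_range[2] < 1,
            n_cutouts_range[1] <= n_cutouts_range[2], n_cutouts_range[1] >= 0)
  structure(list(target_size = as.integer(target_size),
                 rotation_range = rotation_range, flip_prob = flip_prob,
                 scale_range = scale_range, blur_kernel = 3L,
                 sigma_range = sigma_range,
                 cutout_fraction_range = cutout_fraction_range,
                 cutout_fill = cutout_fill,
                 n_cutouts_range = as.integer(n_cutouts_range),
                 color_normalize = color_normalize),
            class = "augmentation_params")
}

#' Standardize an image to a square target
#'
#' Non-square inputs are center-cropped to the shorter side and bilinearly
#' resized; inputs with aspect ratio above 2 (where cropping would discard
#' more than half of one dimension) are instead scaled to fit and
#' zero-padded to square.
#'
#' @param img an [image_sample()].
#' @param target_size output side in pixels (default 512).
#' @return an [image_sample()] of shape `target_size x target_size x 3`.
#' @export
standardize_image <- function(img, target_size = 512) {
  px <- img$pixels
  h <- dim(px)[1]; w <- dim(px)[2]
  if (h == 0 || w == 0) stop("empty image", call. = FALSE)
  aspect <- max(h, w) / min(h, w)
  if (aspect <= 2) {
    side <- min(h, w)
    r0 <- floor((h - side) / 2)
    c0 <- floor((w - side) / 2)
    px <- px[r0 + seq_len(side), c0 + seq_len(side), , drop = FALSE]
    out <- resize_bilinear(px, target_size, target_size)
  } else {
    s <- target_size / max(h, w)
    nh <- max(1L, round(h * s)); nw <- max(1L, round(w * s))
    small <- resize_bilinear(px, nh, nw)
    out <- array(0, c(target_size, target_size, 3))
    r0 <- floor((target_size - nh) / 2); c0 <- floor((target_size - nw) / 2)
    out[r0 + seq_len(nh), c0 + seq_len(nw), ] <- small
  }
  image_sample(out, label = img$label, source_id = img$source_id)
}

# bilinear resize with pixel-center alignment; exact identity when the
# output grid equals the input grid
resize_bilinear <- function(px, out_h, out_w) {
  d <- dim(px)
  if (d[1] == out_h && d[2] == out_w) return(px)
  ys <- (seq_len(out_h) - 0.5) * d[1] / out_h - 0.5
  xs <- (seq_len(out_w) - 0.5) * d[2] / out_w - 0.5
  y0 <- floor(ys); wy <- ys - y0
  x0 <- floor(xs); wx <- xs - x0
  y0 <- pmin(pmax(y0, 0), d[1] - 1); y1 <- pmin(y0 + 1, d[1] - 1)
  x0 <- pmin(pmax(x0, 0), d[2] - 1); x1 <- pmin(x0 + 1, d[2] - 1)
  W00 <- outer(1 - wy, 1 - wx); W10 <- outer(wy, 1 - wx)
  W01 <- outer(1 - wy, wx); W11 <- outer(wy, wx)
  out <- array(0, c(out_h, out_w, d[3]))
  for (ch in seq_len(d[3])) {
    p <- px[, , ch]
    out[, , ch] <- p[y0 + 1, x0 + 1] * W00 + p[y1 + 1, x0 + 1] * W10 +
      p[y0 + 1, x1 + 1] * W01 + p[y1 + 1, x1 + 1] * W11
  }
  out
}

# BT.601 full-range YCbCr; the inverse is the exact matrix inverse so the
# decomposition round-trips to machine precision
.ycc_fwd <- rbind(c(0.299, 0.587, 0.114),
                  c(-0.168736, -0.331264, 0.5),
                  c(0.5, -0.418688, -0.081312))
.ycc_inv <- solve(.ycc_fwd)

rgb_to_ycbcr <- function(px) {
  R <- px[, , 1]; G <- px[, , 2]; B <- px[, , 3]
  M <- .ycc_fwd
  list(Y = M[1, 1] * R + M[1, 2] * G + M[1, 3] * B,
       Cb = 128 + M[2, 1] * R + M[2, 2] * G + M[2, 3] * B,
       Cr = 128 + M[3, 1] * R + M[3, 2] * G + M[3, 3] * B)
}

ycbcr_to_rgb <- function(Y, Cb, Cr) {
  M <- .ycc_inv
  cb <- Cb - 128; cr <- Cr - 128
  out <- array(0, c(dim(Y), 3))
  out[, , 1] <- M[1, 1] * Y + M[1, 2] * cb + M[1, 3] * cr
  out[, , 2] <- M[2, 1] * Y + M[2, 2] * cb + M[2, 3] * cr
  out[, , 3] <- M[3, 1] * Y + M[3, 2] * cb + M[3, 3] * cr
  out
}

#' Equalize the luminance channel
#'
#' Histogram equalization of the YCbCr luma channel; chroma is untouched.
#' A single-bin (constant) luminance is returned unchanged.
#'
#' @param img an [image_sample()].
#' @return an [image_sample()] with equalized luminance.
#' @export
equalize_luminance <- function(img) {
  ycc <- rgb_to_ycbcr(img$pixels)
  bins <- pmin(pmax(floor(ycc$Y), 0), 255)
  counts <- tabulate(bins + 1L, nbins = 256L)
  cdf <- cumsum(counts) / length(bins)
  cdf_min <- cdf[which(counts > 0)[1]]
  if (cdf_min >= 1) {
    ynew <- ycc$Y  # constant luminance: single-bin histogram, identity map
  } else {
    lut <- 255 * (cdf - cdf_min) / (1 - cdf_min)
    ynew <- matrix(lut[bins + 1L], nrow(bins), ncol(bins))
  }
  out <- pmin(pmax(ycbcr_to_rgb(ynew, ycc$Cb, ycc$Cr), 0), 255)
  image_sample(out, label = img$label, source_id = img$source_id)
}

#' Gray-world white balance
#'
#' Each channel is scaled by `mean(channel means) / channel mean`, which
#' makes the (pre-clip) channel means exactly equal.
#'
#' @param img an [image_sample()].
#' @param clip clip the result to `[0, 255]` (default). Disable to inspect
#'   the pre-clip balance.
#' @return an [image_sample()].
#' @export
gray_world_balance <- function(img, clip = TRUE) {
  px <- img$pixels
  mu <- c(mean(px[, , 1]), mean(px[, , 2]), mean(px[, , 3]))
  if (any(mu <= 1e-12)) stop("zero-mean channel: gray-world gain undefined", call. = FALSE)
  gains <- mean(mu) / mu
  out <- px
  for (ch in 1:3) out[, , ch] <- px[, , ch] * gains[ch]
  if (clip) out <- pmin(pmax(out, 0), 255)
  res <- image_sample(out, label = img$label, source_id = img$source_id)
  attr(res, "gains") <- gains
  res
}

#' Draw the spatial augmentation parameters
#'
#' @param params an [augmentation_params()].
#' @param rng a [new_rng()] stream.
#' @return list with `theta` (degrees), `flip` (logical), `s` (scale factor);
#'   uniform marginals over the configured ranges.
#' @export
sample_spatial_params <- function(params, rng) {
  theta <- rng_unif(rng, 1, params$rotation_range[1], params$rotation_range[2])
  flip <- rng_unif(rng, 1) < params$flip_prob
  s <- rng_unif(rng, 1, params$scale_range[1], params$scale_range[2])
  list(theta = theta, flip = flip, s = s)
}

gaussian_kernel3 <- function(sigma) {
  if (sigma <= 0) stop("sigma must be positive", call. = FALSE)
  d <- c(-1, 0, 1)
  k <- outer(d, d, function(a, b) exp(-(a^2 + b^2) / (2 * sigma^2)))
  k / sum(k)
}

# mirror-pad by one pixel (edge replication) and convolve 3x3
blur3 <- function(px, sigma) {
  k <- gaussian_kernel3(sigma)
  d <- dim(px)
  ri <- c(1, seq_len(d[1]), d[1])
  ci <- c(1, seq_len(d[2]), d[2])
  out <- array(0, d)
  for (ch in seq_len(d[3])) {
    p <- px[ri, ci, ch]
    acc <- matrix(0, d[1], d[2])
    for (dr in 0:2) for (dc in 0:2) {
      acc <- acc + k[dr + 1, dc + 1] * p[dr + seq_len(d[1]), dc + seq_len(d[2])]
    }
    out[, , ch] <- acc
  }
  out
}

#' Apply a 3x3 Gaussian blur
#'
#' @param img an [image_sample()].
#' @param sigma kernel standard deviation (> 0).
#' @return blurred [image_sample()]; reflective border handling.
#' @export
apply_gaussian_blur <- function(img, sigma) {
  out <- blur3(img$pixels, sigma)
  image_sample(out, label = img$label, source_id = img$source_id)
}

#' Apply cutout occlusion
#'
#' Inserts `n` axis-aligned rectangles (n drawn from `n_cutouts_range`),
#' each with area a uniform fraction of the image area in
#' `cutout_fraction_range`, fully inside the image, filled with mid-gray
#' or zeros.
#'
#' @param img an [image_sample()].
#' @param params an [augmentation_params()].
#' @param rng a [new_rng()] stream.
#' @return list with `image` and `rects` (data.frame `row0,col0,h,w`
#'   of 0-based offsets).
#' @export
apply_cutout <- function(img, params, rng) {
  px <- img$pixels
  H <- dim(px)[1]; W <- dim(px)[2]
  A <- H * W
  lo <- params$cutout_fraction_range[1] * A
  hi <- params$cutout_fraction_range[2] * A
  n <- rng_int(rng, 1, params$n_cutouts_range[1], params$n_cutouts_range[2])
  fill <- if (params$cutout_fill == "gray") 128 else 0
  rects <- list()
  if (n >= 1) for (i in seq_len(n)) {
    S <- rng_unif(rng, 1, lo, hi)
    r <- rng_unif(rng, 1, 0.5, 2)              # aspect ratio w/h
    w <- max(1L, min(W, round(sqrt(S * r))))
    h <- max(1L, min(H, round(S / w)))
    # nudge the integer sides back inside the admissible area band
    guard <- 0L
    while ((w * h > hi || w * h < lo) && guard < 4 * (H + W)) {
      if (w * h > hi) { if (w >= h && w > 1) w <- w - 1L else h <- h - 1L }
      else { if (w <= h && w < W) w <- w + 1L else h <- h + 1L }
      guard <- guard + 1L
    }
    r0 <- rng_int(rng, 1, 0, H - h)
    c0 <- rng_int(rng, 1, 0, W - w)
    px[r0 + seq_len(h), c0 + seq_len(w), ] <- fill
    rects[[i]] <- data.frame(row0 = r0, col0 = c0, h = h, w = w)
  }
  list(image = image_sample(px, label = img$label, source_id = img$source_id),
       rects = if (length(rects)) do.call(rbind, rects) else
         data.frame(row0 = integer(), col0 = integer(), h = integer(), w = integer()))
}

# inverse-mapped affine warp about the image center: rotation by theta
# degrees followed by zoom s, bilinear sampling, reflective border.
# Exact identity for theta = 0, s = 1.
warp_rotate_scale <- function(px, theta_deg, s = 1) {
  d <- dim(px)
  H <- d[1]; W <- d[2]
  th <- theta_deg * pi / 180
  ct <- cos(th); st <- sin(th)
  cy <- (H + 1) / 2; cx <- (W + 1) / 2
  yo <- matrix(seq_len(H), H, W) - cy
  xo <- matrix(seq_len(W), H, W, byrow = TRUE) - cx
  # inverse map: un-zoom then un-rotate
  xs <- (ct * xo + st * yo) / s + cx
  ys <- (-st * xo + ct * yo) / s + cy
  x0 <- floor(xs); y0 <- floor(ys)
  wx <- xs - x0; wy <- ys - y0
  reflect <- function(v, n) {
    v <- (v - 1) %% (2 * n)
    v <- ifelse(v >= n, 2 * n - 1 - v, v)
    v + 1
  }
  y0r <- reflect(y0, H); y1r <- reflect(y0 + 1, H)
  x0r <- reflect(x0, W); x1r <- reflect(x0 + 1, W)
  out <- array(0, d)
  for (ch in seq_len(d[3])) {
    p <- px[, , ch]
    i00 <- p[cbind(as.vector(y0r), as.vector(x0r))]
    i10 <- p[cbind(as.vector(y1r), as.vector(x0r))]
    i01 <- p[cbind(as.vector(y0r), as.vector(x1r))]
    i11 <- p[cbind(as.vector(y1r), as.vector(x1r))]
    v <- (1 - wy) * (1 - wx) * i00 + wy * (1 - wx) * i10 +
      (1 - wy) * wx * i01 + wy * wx * i11
    out[, , ch] <- matrix(v, H, W)
  }
  out
}

#' Build a contrastive view pair
#'
#' The source image is standardized (and optionally color-normalized), then
#' two independent augmentation draws are applied: rotation, horizontal
#' flip, scale, Gaussian blur, cutout. With every perturbation disabled the
#' views equal the standardized image exactly.
#'
#' @param x an [image_sample()].
#' @param params an [augmentation_params()].
#' @param rng a [new_rng()] stream.
#' @return object of class `view_pair` with fields `x_i`, `x_j`,
#'   `source_id`, `drawn_params_i`, `drawn_params_j`.
#' @export
make_view_pair <- function(x, params, rng) {
  base <- standardize_image(x, params$target_size)
  if (params$color_normalize) {
    base <- gray_world_balance(equalize_luminance(base))
  }
  v1 <- augment_once(base, params, rng)
  v2 <- augment_once(base, params, rng)
  structure(list(x_i = v1$image, x_j = v2$image, source_id = x$source_id,
                 drawn_params_i = v1$drawn, drawn_params_j = v2$drawn),
            class = "view_pair")
}

augment_once <- function(base, params, rng) {
  sp <- sample_spatial_params(params, rng)
  px <- base$pixels
  if (sp$theta != 0) px <- warp_rotate_scale(px, sp$theta, 1)
  if (sp$flip) px <- px[, rev(seq_len(dim(px)[2])), , drop = FALSE]
  if (sp$s != 1) px <- warp_rotate_scale(px, 0, sp$s)
  sigma <- rng_unif(rng, 1, params$sigma_range[1], params$sigma_range[2])
  if (sigma > 0) px <- blur3(px, sigma)
  img <- image_sample(pmin(pmax(px, 0), 255), label = base$label,
                      source_id = base$source_id)
  rects <- NULL
  if (params$n_cutouts_range[2] > 0) {
    co <- apply_cutout(img, params, rng)
    img <- co$image
    rects <- co$rects
  }
  list(image = img,
       drawn = list(theta = sp$theta, flip = sp$flip, s = sp$s,
                    sigma = sigma, cutouts = rects))
}
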