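test_that("standardization crops, resizes and pads as specified", {
  out <- standardize_image(fixture_image(0, 1), 512)
  expect_equal(dim(out$pixels), c(512, 512, 3))

  # already-square at target size: exact identity
  sq <- gray_image(64)
  sq$pixels[] <- seq_len(length(sq$pixels)) %% 251
  expect_identical(standardize_image(sq, 64)$pixels, sq$pixels)

  # 512 x 1024: retained region is columns 256..767 (0-based), by
  # independent crop arithmetic
  wide <- image_sample(array(rep(seq_len(1024), each = 512), c(512, 1024, 3)),
                       source_id = "wide")
  std <- standardize_image(wide, 512)
  expect_identical(std$pixels, wide$pixels[, 256 + seq_len(512), , drop = FALSE])

  # extreme aspect ratio (> 2): scaled to fit and zero-padded
  tall <- image_sample(array(100, c(300, 64, 3)), source_id = "tall")
  padded <- standardize_image(tall, 64)
  expect_equal(dim(padded$pixels), c(64, 64, 3))
  expect_true(any(padded$pixels == 0))      # padding present
  expect_true(any(padded$pixels > 90))      # content present
})

test_that("luminance equalization linearizes the CDF and preserves chroma", {
  # constant image maps to a constant
  g <- gray_image(64, 77)
  expect_equal(equalize_luminance(g)$pixels, g$pixels)

  # full-range luminance ramp: post-equalization CDF within 2% of linear
  ramp <- array(rep(seq(0, 255, length.out = 64), 64), c(64, 64, 3))
  eq <- equalize_luminance(image_sample(ramp, source_id = "ramp"))
  y <- 0.299 * eq$pixels[, , 1] + 0.587 * eq$pixels[, , 2] + 0.114 * eq$pixels[, , 3]
  probe <- seq(10, 245, by = 15)
  emp_cdf <- vapply(probe, function(v) mean(y <= v), numeric(1))
  expect_lt(max(abs(emp_cdf - probe / 255)), 0.02 + 1 / 64)

  # chroma (Cb, Cr) untouched for interior pixels, by direct recomputation
  img <- fixture_image(1, 2)
  eq2 <- equalize_luminance(img)
  cb <- function(p) 128 - 0.168736 * p[, , 1] - 0.331264 * p[, , 2] + 0.5 * p[, , 3]
  cr <- function(p) 128 + 0.5 * p[, , 1] - 0.418688 * p[, , 2] - 0.081312 * p[, , 3]
  y2 <- 0.299 * eq2$pixels[, , 1] + 0.587 * eq2$pixels[, , 2] + 0.114 * eq2$pixels[, , 3]
  interior <- eq2$pixels > 1 & eq2$pixels < 254
  keep <- interior[, , 1] & interior[, , 2] & interior[, , 3]
  expect_lt(max(abs((cb(eq2$pixels) - cb(img$pixels))[keep])), 1e-6)
  expect_lt(max(abs((cr(eq2$pixels) - cr(img$pixels))[keep])), 1e-6)
})

test_that("gray-world balance equalizes pre-clip channel means", {
  g <- gray_image(64, 90)
  expect_equal(gray_world_balance(g)$pixels, g$pixels)

  # channel means (50, 100, 150) -> gains (2, 1, 2/3), by hand arithmetic
  px <- array(0, c(64, 64, 3))
  px[, , 1] <- 50; px[, , 2] <- 100; px[, , 3] <- 150
  bal <- gray_world_balance(image_sample(px, source_id = "tint"), clip = FALSE)
  expect_equal(attr(bal, "gains"), c(2, 1, 2 / 3), tolerance = 1e-12)

  img <- fixture_image(2, 3)
  bal2 <- gray_world_balance(img, clip = FALSE)
  mu <- apply(bal2$pixels, 3, mean)
  expect_lt(diff(range(mu)) / mean(mu), 1e-6)

  zero <- gray_image(64, 0)
  expect_error(gray_world_balance(zero), "zero-mean")
})

test_that("spatial parameter draws have the stated uniform ranges", {
  params <- augmentation_params(target_size = 64)
  rng <- new_rng(11)
  draws <- replicate(1e4, unlist(sample_spatial_params(params, rng)[c("theta", "s")]))
  theta <- draws[1, ]; s <- draws[2, ]
  expect_true(all(theta >= -30 & theta <= 30))
  expect_true(all(s >= 0.8 & s <= 1.2))
  # uniformity at alpha = 0.01 against the exact null (independent KS oracle)
  expect_gt(stats::ks.test(theta, "punif", -30, 30)$p.value, 0.01)
  expect_gt(stats::ks.test(s, "punif", 0.8, 1.2)$p.value, 0.01)
  # seed determinism
  r1 <- sample_spatial_params(params, new_rng(5))
  r2 <- sample_spatial_params(params, new_rng(5))
  expect_identical(r1, r2)
})

test_that("the 3x3 Gaussian blur kernel is normalized and correct", {
  for (sig in c(0.5, 1, 1.5)) {
    expect_equal(sum(cropclr:::gaussian_kernel3(sig)), 1, tolerance = 1e-9)
  }
  g <- gray_image(64, 123)
  expect_equal(apply_gaussian_blur(g, 1)$pixels, g$pixels, tolerance = 1e-9)
  # impulse response at the center equals the kernel center weight
  imp <- array(0, c(33, 33, 3)); imp[17, 17, ] <- 255
  blurred <- apply_gaussian_blur(image_sample(imp, source_id = "imp"), 0.5)
  k <- exp(-outer(c(-1, 0, 1)^2, c(-1, 0, 1)^2, "+") / (2 * 0.25))
  expect_equal(blurred$pixels[17, 17, 1], 255 * k[2, 2] / sum(k), tolerance = 1e-9)
  expect_error(apply_gaussian_blur(g, 0), "positive")
})

test_that("cutout rectangles obey the area band and are single components", {
  skip_if_not_installed("EBImage")
  params <- augmentation_params(target_size = 64, cutout_fill = "zero",
                                n_cutouts_range = c(1, 1))
  rng <- new_rng(21)
  img <- gray_image(64, 200)
  A <- 64 * 64
  fracs <- replicate(1000, {
    res <- apply_cutout(img, params, rng)
    res$rects$h * res$rects$w / A
  })
  expect_true(all(fracs >= 0.05 & fracs <= 0.20))
  # zero fill and single-rectangle connectivity via a component oracle
  res <- apply_cutout(img, params, rng)
  masked <- res$image$pixels[, , 1] == 0
  expect_equal(sum(masked), res$rects$h * res$rects$w)
  expect_equal(blob_count(masked), 1)
  # gray fill mode
  params_g <- augmentation_params(target_size = 64, n_cutouts_range = c(1, 1))
  res_g <- apply_cutout(img, params_g, rng)
  expect_true(any(res_g$image$pixels == 128))
})

test_that("view pairs reduce to standardization when perturbations are off", {
  img <- fixture_image(0, 5)
  idp <- augmentation_params(target_size = 64, identity = TRUE)
  rng <- new_rng(3)
  vp <- make_view_pair(img, idp, rng)
  std <- standardize_image(img, 64)
  expect_identical(vp$x_i$pixels, std$pixels)
  expect_identical(vp$x_j$pixels, std$pixels)
  expect_identical(vp$source_id, img$source_id)
})

test_that("generic seeded draws give distinct views within the target size", {
  img <- fixture_image(1, 6)
  params <- augmentation_params(target_size = 64)
  differs <- vapply(1:100, function(s) {
    vp <- make_view_pair(img, params, new_rng(s))
    !identical(vp$x_i$pixels, vp$x_j$pixels)
  }, logical(1))
  expect_true(all(differs))
  vp <- make_view_pair(img, params, new_rng(1))
  expect_equal(dim(vp$x_i$pixels), c(64, 64, 3))
  expect_true(all(vp$x_i$pixels >= 0 & vp$x_i$pixels <= 255))
  expect_true(all(vp$x_j$pixels >= 0 & vp$x_j$pixels <= 255))
  # reproducible from the seed
  vp2 <- make_view_pair(img, params, new_rng(1))
  expect_identical(vp$x_i$pixels, vp2$x_i$pixels)
})
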