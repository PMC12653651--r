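test_that("forward diffusion has the stated Gaussian moments", {
  # alpha_t = 1: exact identity
  sch1 <- diffusion_schedule(2, 1, 1)
  e0 <- array(2, c(4, 4, 2))
  expect_equal(forward_diffuse(e0, sch1, 1, new_rng(1)), e0)
  expect_equal(dim(forward_diffuse(e0, sch1, 2, new_rng(1))), dim(e0))
  expect_error(forward_diffuse(e0, sch1, 3, new_rng(1)), "out of range")

  # alpha_t = 0.75, e_0 = 2: mean 1.5, variance 0.25 within 3 SE over 1e4 draws
  sch <- diffusion_schedule(1, 0.75, 0.75)
  rng <- new_rng(12)
  draws <- vapply(1:10000, function(i) forward_diffuse(2, sch, 1, rng), numeric(1))
  se_mean <- 0.5 / sqrt(10000)
  expect_lt(abs(mean(draws) - 1.5), 3 * se_mean)
  se_var <- 0.25 * sqrt(2 / 9999)
  expect_lt(abs(var(draws) - 0.25), 3 * se_var)

  # the standard convention uses sqrt of the cumulative product
  schc <- diffusion_schedule(2, 0.9, 0.8, convention = "sqrt_cumulative")
  cf <- cropclr:::diffuse_coefs(schc, 2)
  expect_equal(cf$mean, sqrt(0.9 * 0.8))
  expect_equal(cf$sd, sqrt(1 - 0.9 * 0.8))
})

test_that("the reconstruction net has the contracted output behavior", {
  rng <- new_rng(3)
  net <- recon_net_init(16, 8, 4, n_layers = 2, n_heads = 2, ffn_hidden = 16,
                        rng = rng)
  e_t <- array(rng_norm(rng, 16 * 8), c(4, 4, 8))
  out <- reverse_step(e_t, 2, net)
  expect_equal(dim(out$mu), dim(e_t))
  expect_equal(dim(out$eta), dim(e_t))
  expect_true(all(is.finite(out$mu)))
  expect_true(all(out$eta > 0))
  out2 <- reverse_step(e_t, 2, net)
  expect_identical(out, out2)
  expect_error(reverse_step(e_t, 9, net), "out of range")

  # T = 1 reconstruction is a single mean step
  sch <- diffusion_schedule(1, 0.8, 0.8)
  net1 <- recon_net_init(16, 8, 1, n_layers = 1, n_heads = 2, ffn_hidden = 16,
                         rng = rng)
  expect_equal(reconstruct(e_t, sch, net1), reverse_step(e_t, 1, net1)$mu)
  sch4 <- diffusion_schedule(4, 0.9, 0.6)
  expect_equal(dim(reconstruct(e_t, sch4, net)), dim(e_t))
})

test_that("the reconstruction loss matches term-by-term recomputation", {
  rng <- new_rng(5)
  sch <- diffusion_schedule(4, 0.9, 0.6)
  net <- recon_net_init(9, 6, 4, n_layers = 1, n_heads = 2, ffn_hidden = 12,
                        rng = rng)
  traj <- forward_trajectory(array(rng_norm(rng, 54), c(3, 3, 6)), sch, rng)
  loss <- diffusion_loss(traj, net)
  expect_gte(loss, 0)
  brute <- 0
  for (t in 1:4) {
    mu <- reverse_step(traj[[t + 1]], t, net)$mu
    brute <- brute + sum((traj[[t]] - mu)^2)
  }
  expect_equal(loss, brute, tolerance = 1e-6)
  expect_error(diffusion_loss(traj[1:3], net), "length")
})

test_that("training the net on a fixed map reduces reconstruction error", {
  rng <- new_rng(10)
  sch <- diffusion_schedule(3, 0.9, 0.6)
  net <- recon_net_init(16, 8, 3, n_layers = 1, n_heads = 2, ffn_hidden = 16,
                        rng = rng)
  target <- array(rng_norm(rng, 16 * 8), c(4, 4, 8))
  err <- function(nn, seed) {
    rr <- new_rng(seed)
    mean(vapply(1:5, function(i) {
      eT <- forward_diffuse(target, sch, 3, rr)
      sum((reconstruct(eT, sch, nn) - target)^2)
    }, numeric(1)))
  }
  before <- err(net, 42)
  opt <- adam_init(net$params)
  trained <- net
  for (i in 1:200) {
    dl <- cropclr:::diffusion_loss_grad(list(target), sch, trained, rng,
                                        stop_gradient = TRUE)
    st <- adam_step(trained$params, dl$grads, opt, lr = 1e-3)
    trained$params <- st$params
    opt <- st$state
  }
  expect_lt(err(trained, 42), before)
})

test_that("feature covariance is the spatial second-moment matrix", {
  expect_equal(feature_covariance(array(3, c(4, 4, 5))), matrix(0, 5, 5))
  two <- matrix(c(1, -1, 0, 0), 2, 2)   # positions (1,0) and (-1,0)
  expect_equal(feature_covariance(two), diag(c(1, 0)))
  expect_error(feature_covariance(matrix(1, 1, 4)), "at least 2")
  rng <- new_rng(6)
  for (i in 1:25) {
    e <- array(rng_norm(rng, 6 * 6 * 4), c(6, 6, 4))
    S <- feature_covariance(e)
    expect_equal(S, t(S), tolerance = 1e-6)
    expect_gt(min(eigen(S, symmetric = TRUE, only.values = TRUE)$values), -1e-8)
  }
})

test_that("structural distance behaves as a bounded symmetric dissimilarity", {
  rng <- new_rng(7)
  S <- random_psd(rng, 5)
  expect_lt(abs(structural_distance(S, S)), 1e-9)
  expect_equal(structural_distance(diag(c(1, 0)), diag(c(0, 1))), 1)
  expect_error(structural_distance(matrix(0, 2, 2), diag(2)), "zero matrix")
  # 1e3 random PSD pairs vs brute-force trace/Frobenius computation
  for (i in 1:1000) {
    A <- random_psd(rng, 4); B <- random_psd(rng, 4)
    d1 <- structural_distance(A, B)
    d2 <- structural_distance(B, A)
    brute <- 1 - sum(diag(A %*% B)) / (sqrt(sum(A^2)) * sqrt(sum(B^2)))
    expect_equal(d1, brute, tolerance = 1e-9)
    expect_equal(d1, d2, tolerance = 1e-12)
    expect_gte(d1, 0); expect_lte(d1, 1)
  }
})

test_that("pair filtering thresholds distances and is monotone in delta", {
  rng <- new_rng(8)
  e <- array(rng_norm(rng, 64), c(4, 4, 4))
  cfg <- filter_config(delta = 0.5, delta_mode = "fixed")
  same <- filter_pair(e, e, cfg)
  expect_true(same$keep)
  expect_lt(same$distance, 1e-9)
  e2 <- array(rng_norm(rng, 64), c(4, 4, 4))
  cfg0 <- filter_config(delta = 0, delta_mode = "fixed")
  expect_false(filter_pair(e, e2, cfg0)$keep)
  # constructed distances {0.1, 0.3, 0.9} at delta 0.5: first two retained,
  # checked against an explicit threshold scan
  fb <- cropclr:::filter_batch(c(0.1, 0.3, 0.9), cfg)
  expect_equal(fb$keep, c(0.1, 0.3, 0.9) < 0.5)
  expect_equal(sum(fb$keep), 2)
  # monotonicity: retained set grows with delta
  d <- rng_unif(rng, 50)
  kept_sets <- lapply(c(0.2, 0.5, 0.8), function(dl) {
    which(cropclr:::filter_batch(d, filter_config(delta = dl, delta_mode = "fixed"))$keep)
  })
  expect_true(all(kept_sets[[1]] %in% kept_sets[[2]]))
  expect_true(all(kept_sets[[2]] %in% kept_sets[[3]]))
})

test_that("corrupted views have stochastically larger structural distance", {
  enc <- tiny_encoder(3)
  params <- augmentation_params(target_size = 64)
  severe <- augmentation_params(target_size = 64,
                                cutout_fraction_range = c(0.45, 0.5),
                                n_cutouts_range = c(2, 2))
  sch <- diffusion_schedule(4, 0.95, 0.7)
  net <- recon_net_init(64, 32, 4, n_layers = 1, n_heads = 2, ffn_hidden = 32,
                        rng = new_rng(15))
  rng <- new_rng(14)
  dist_for <- function(p, seed) {
    img <- fixture_image(seed %% 3, seed)
    vp <- make_view_pair(img, p, new_rng(seed))
    rec <- cropclr:::reconstruct_batch(
      list(forward_diffuse(encode_feature_map(vp$x_i, enc), sch, 4, rng),
           forward_diffuse(encode_feature_map(vp$x_j, enc), sch, 4, rng)),
      sch, net)
    structural_distance(feature_covariance(rec[[1]]),
                        feature_covariance(rec[[2]]))
  }
  mild <- vapply(1:50, function(s) dist_for(params, s), numeric(1))
  harsh <- vapply(1:50, function(s) dist_for(severe, 1000 + s), numeric(1))
  expect_gt(mean(harsh), mean(mild))
})

test_that("the joint loss combines the two objectives linearly", {
  expect_equal(joint_pretrain_loss(2, 3, 0.5), 3.5)
  expect_equal(joint_pretrain_loss(1.7, 100, 0), 1.7)
  expect_equal(formals(joint_pretrain_loss)$lambda, 0.5)
})
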