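test_that("embeddings are unit-norm, 128-d and deterministic", {
  enc <- tiny_encoder()
  img <- standardize_image(fixture_image(0, 1), 64)
  z1 <- encode_project(img, enc)
  z2 <- encode_project(img, enc)
  expect_length(z1, 128)
  expect_equal(sqrt(sum(z1^2)), 1, tolerance = 1e-6)
  expect_identical(z1, z2)
  small <- image_sample(array(1, c(32, 32, 3)), source_id = "small")
  expect_error(encode_project(small, enc), "standardized")
})

test_that("the full-scale encoder profile wires up consistently", {
  cfg <- encoder_config("paper")
  expect_equal(cfg$input_size, 512L)
  enc <- encoder_init(cfg, new_rng(1))
  expect_length(enc$params$stages, 5)
  # last stage width equals the projection input: no adapter needed
  expect_null(enc$params$adapter)
  expect_equal(dim(enc$params$fc1$W), c(512L, 128L))
  expect_equal(dim(enc$params$fc2$W), c(128L, 128L))
  # residual stages carry two extra convolutions
  expect_true(all(c("res1", "res2") %in% names(enc$params$stages[[3]])))
  # pretrained-weight loading round-trips and validates shapes
  path <- file.path(tempdir(), "bb.rds")
  saveRDS(enc$params$stages, path)
  enc2 <- load_backbone_weights(encoder_init(cfg, new_rng(2)), path)
  expect_identical(enc2$params$stages, enc$params$stages)
  tiny <- tiny_encoder()
  expect_error(load_backbone_weights(tiny, path), "mismatch")
})

test_that("the EMA update follows m * old + (1 - m) * new", {
  mk <- function(w, m = NULL) {
    s <- list(params = list(w = w), config = NULL)
    if (!is.null(m)) s$m <- m
    s
  }
  expect_equal(ema_update(mk(0, m = 1), mk(1))$params$w, 0)       # m = 1: frozen
  expect_equal(ema_update(mk(0, m = 0), mk(1))$params$w, 1)       # m = 0: copy
  expect_equal(ema_update(mk(0, m = 0.9), mk(1))$params$w, 0.1)   # direct arithmetic
  # geometric gap decay m^n on scalars
  m <- 0.95; target <- mk(1)
  s <- mk(0, m = m)
  for (n in 1:20) s <- ema_update(s, target)
  expect_equal(abs(s$params$w - 1), m^20, tolerance = 1e-12)
})

test_that("cosine similarity is bounded and scale-invariant", {
  rng <- new_rng(2)
  expect_equal(cosine_similarity(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(cosine_similarity(c(1, 0), c(0, 1)), 0)
  for (i in 1:20) {
    a <- rng_norm(rng, 8); b <- rng_norm(rng, 8)
    expect_equal(cosine_similarity(2 * a, b), cosine_similarity(a, b))
    expect_true(abs(cosine_similarity(a, b)) <= 1 + 1e-12)
  }
  expect_error(cosine_similarity(rep(0, 3), c(1, 0, 0)), "zero vector")
})

test_that("InfoNCE matches its closed form and is monotone in negatives", {
  d <- 4
  z <- c(1, 0, 0, 0)
  q1 <- queue_push(negative_queue(8, d), matrix(c(0, 1, 0, 0), 1))
  expect_equal(info_nce_loss(z, z, q1, tau = 1), log(1 + exp(-1)),
               tolerance = 1e-9)
  q2 <- queue_push(q1, matrix(c(0, 0, 1, 0), 1))
  expect_equal(info_nce_loss(z, z, q2, tau = 0.2), log(1 + 2 * exp(-5)),
               tolerance = 1e-9)
  # replacing a negative with a more similar one never lowers the loss
  rng <- new_rng(3)
  for (i in 1:20) {
    zi <- random_unit(rng, d); zj <- random_unit(rng, d)
    far <- random_unit(rng, d)
    near <- zi + 0.1 * rng_norm(rng, d); near <- near / sqrt(sum(near^2))
    if (sum(near * zi) < sum(far * zi)) next
    lo <- info_nce_loss(zi, zj, queue_push(negative_queue(4, d), matrix(far, 1)))
    hi <- info_nce_loss(zi, zj, queue_push(negative_queue(4, d), matrix(near, 1)))
    expect_gte(hi, lo)
  }
  expect_error(info_nce_loss(z, z, negative_queue(4, d)), "empty")
  expect_error(info_nce_loss(z, z, q1, tau = 0), "positive")
  expect_gt(info_nce_loss(z, c(0, 1, 0, 0), q1), 0)
})

test_that("the negative queue has FIFO semantics and bounded length", {
  d <- 3
  K <- 5
  basis <- l2_normalize_rows(matrix(rng_norm(new_rng(6), 8 * 3, 2), 8, 3))
  q <- negative_queue(K, d)
  # FIFO simulation oracle: a plain list mirror
  mirror <- list()
  for (i in 1:8) {
    q <- queue_push(q, basis[i, ])
    mirror <- c(mirror, list(basis[i, ]))
    if (length(mirror) > K) mirror <- mirror[-1]
    expect_lte(queue_length(q), K)
  }
  expect_equal(queue_length(q), K)
  expect_equal(q$buffer, do.call(rbind, mirror))
  # push onto empty queue: length = batch size
  q0 <- queue_push(negative_queue(10, d), basis[1:4, ])
  expect_equal(queue_length(q0), 4)
  expect_error(queue_push(q0, c(3, 0, 0)), "unit-norm")
  # capacity never exceeded over many random pushes
  rng <- new_rng(8)
  qq <- negative_queue(7, d)
  for (i in 1:200) {
    n <- rng_int(rng, 1, 1, 4)
    qq <- queue_push(qq, l2_normalize_rows(matrix(rng_norm(rng, n * d), n, d)))
    expect_lte(queue_length(qq), 7)
  }
})

test_that("a contrastive step composes encoding, loss, queue and EMA", {
  enc <- tiny_encoder()
  mom <- momentum_encoder_init(enc, m = 0.9)
  cfg <- contrastive_config(K = 16, d = 128)
  rngq <- new_rng(4)
  queue <- negative_queue(16, 128, prefill_rng = rngq)
  pair <- make_view_pair(fixture_image(0, 2),
                         augmentation_params(target_size = 64), new_rng(5))
  pre_buffer <- queue$buffer
  prior_mom <- mom$params
  out <- contrastive_step(pair, enc, mom, queue, cfg)
  # loss equals a recomputation from the emitted embeddings + pre-push queue
  qpre <- negative_queue(16, 128)
  qpre$buffer <- pre_buffer
  expect_equal(out$loss, info_nce_loss(out$z_i, out$z_j, qpre, cfg$tau),
               tolerance = 1e-9)
  # queue grew FIFO by one momentum embedding
  expect_equal(queue_length(out$queue), 16)
  expect_equal(out$queue$buffer[16, ], out$z_j)
  # momentum params equal the EMA of their priors
  expected <- tree_map2(prior_mom, enc$params, function(pp, p) 0.9 * pp + 0.1 * p)
  expect_equal(out$momentum_state$params, expected)
  # feature maps for the filter are emitted at the configured shape
  expect_equal(dim(out$e_i), c(8, 8, 32))
  expect_equal(dim(out$e_j), c(8, 8, 32))
})

test_that("optimizing the contrastive loss never touches momentum parameters", {
  man <- fixture_dataset(per_class = 6)
  cfg <- run_config("test", epochs = 1, batch_size = 6, seed = 2, m = 1)
  ck <- pretrain(cfg, man)
  init <- encoder_init(cfg$encoder, new_rng(rng_spawn_seeds(new_rng(cfg$seed), 5)[1]))
  # with m = 1 the EMA is frozen: momentum params must equal initialization
  expect_equal(ck$momentum$params, init$params, tolerance = 0)
  # while the primary encoder moved
  expect_false(isTRUE(all.equal(ck$encoder$params, init$params)))
})
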