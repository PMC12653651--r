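test_that("token sequences have the documented layout and patch order", {
  rng <- new_rng(1)
  cfg <- finetune_config(n_classes = 3, width = 32, n_heads = 4,
                         ffn_hidden = 64, n_registers = 0)
  head <- head_init(cfg, rng)
  F_grid <- array(rng_norm(rng, 16 * 16 * 32), c(16, 16, 32))
  seqm <- build_token_sequence(F_grid, head)
  expect_equal(nrow(seqm), 3 + 256)
  cfg_r <- finetune_config(n_classes = 3, width = 32, n_heads = 4,
                           ffn_hidden = 64, n_registers = 4)
  head_r <- head_init(cfg_r, rng)
  expect_equal(nrow(build_token_sequence(F_grid, head_r)), 263)
  # patch token k at grid cell (k %/% W, k %% W), via an index-map oracle
  P <- cropclr:::patches_from_fm(F_grid)
  W <- 16
  for (k in c(0, 5, 17, 255)) {
    expect_equal(P[k + 1, ], F_grid[k %/% W + 1, k %% W + 1, ])
  }
})

test_that("class-token attention matches a brute-force computation", {
  rng <- new_rng(2)
  # generic case: rows sum to one
  proj <- mha_init(8, 2, rng)
  tokens <- matrix(rng_norm(rng, 2 * 8), 2, 8)
  patches <- matrix(rng_norm(rng, 5 * 8), 5, 8)
  out <- class_token_attention(tokens, patches, proj, n_heads = 2)
  expect_equal(rowSums(out$attn), c(1, 1), tolerance = 1e-6)
  expect_equal(dim(out$outputs), c(2, 8))
  # zero query projection: uniform attention over patches
  proj0 <- proj
  proj0$Wq <- proj0$Wq * 0
  proj0$bq <- proj0$bq * 0
  out0 <- class_token_attention(tokens, patches, proj0, n_heads = 2)
  expect_equal(out0$attn, matrix(1 / 5, 2, 5), tolerance = 1e-9)
  # 2-token/3-patch toy vs independent softmax-matmul, single head
  proj1 <- list(Wq = diag(2), Wk = diag(2), Wv = matrix(c(1, 0, 1, 1), 2),
                bq = rep(0, 2), bk = rep(0, 2), bv = rep(0, 2))
  tk <- matrix(c(1, 0, 0, 1), 2, byrow = TRUE)
  pt <- matrix(c(1, 0, 0, 1, 1, 1), 3, byrow = TRUE)
  res <- class_token_attention(tk, pt, proj1, n_heads = 1)
  S <- tk %*% t(pt) / sqrt(2)
  A <- exp(S) / rowSums(exp(S))
  expect_equal(res$attn, A, tolerance = 1e-6)
  expect_equal(res$outputs, A %*% (pt %*% matrix(c(1, 0, 1, 1), 2)),
               tolerance = 1e-6)
})

test_that("the head forward pass emits valid probabilities and attention", {
  rng <- new_rng(3)
  cfg <- finetune_config(n_classes = 3, width = 16, n_layers = 3, n_heads = 4,
                         ffn_hidden = 32)
  head <- head_init(cfg, rng)
  F_grid <- array(rng_norm(rng, 8 * 8 * 16), c(8, 8, 16))
  out <- finetune_forward(F_grid, head)
  expect_length(out$yhat, 3)
  expect_true(all(out$yhat > 0 & out$yhat < 1))
  expect_identical(out$yhat, finetune_forward(F_grid, head)$yhat)
  # attention maps are row-stochastic at every layer
  for (A in out$attn) {
    expect_equal(rowSums(A), rep(1, 3), tolerance = 1e-6)
    expect_true(all(A >= 0))
  }
})

test_that("multi-label BCE matches hand arithmetic", {
  expect_equal(multilabel_bce(c(1, 0, 1), rep(0.5, 3)), log(2), tolerance = 1e-9)
  expect_equal(multilabel_bce(c(0, 1, 0), rep(0.5, 3)), log(2), tolerance = 1e-9)
  expect_equal(multilabel_bce(c(1, 0, 1), c(0.9, 0.1, 0.8)),
               (-log(0.9) - log(0.9) - log(0.8)) / 3, tolerance = 1e-9)
  expect_lt(multilabel_bce(c(1, 0), c(1, 0)), 1e-6)
  expect_error(multilabel_bce(c(1, 0), c(0.5)), "length")
})

test_that("the total objective weights its three terms as configured", {
  expect_equal(total_loss(1, 2, 3, loss_weights(0.5, 1.0)), 5.0)
  expect_equal(total_loss(1.3, 99, 77, loss_weights(0, 0)), 1.3)
  w <- loss_weights()
  expect_equal(w$lambda1, 0.5)
  expect_equal(w$lambda2, 1.0)
})

test_that("head pruning keeps the top-k heads with index tie-breaks", {
  expect_equal(prune_heads(c(0.9, 0.1, 0.5, 0.5), 2), c(1, 0, 1, 0))
  expect_equal(prune_heads(runif(6), 6), rep(1, 6))
  expect_error(prune_heads(c(1, 2), 0), "out of range")
  rng <- new_rng(4)
  for (i in 1:50) {
    sc <- rng_unif(rng, 8)
    k <- rng_int(rng, 1, 1, 8)
    mask <- prune_heads(sc, k)
    # independent sort oracle
    expect_setequal(which(mask == 1), order(-sc)[seq_len(k)])
  }
})

test_that("pruning with keep = all reproduces unpruned outputs exactly", {
  rng <- new_rng(5)
  cfg <- finetune_config(n_classes = 2, width = 16, n_layers = 2, n_heads = 4,
                         ffn_hidden = 32)
  head <- head_init(cfg, rng)
  F_grid <- array(rng_norm(rng, 8 * 8 * 16), c(8, 8, 16))
  full <- finetune_forward(F_grid, head, head_mask = rep(1, 4))
  none <- finetune_forward(F_grid, head)
  expect_identical(full$yhat, none$yhat)
  # masking a head changes the output
  masked <- finetune_forward(F_grid, head, head_mask = c(1, 1, 1, 0))
  expect_false(identical(masked$yhat, none$yhat))
})

test_that("attention pseudo-masks threshold at the row quantile", {
  attn <- matrix(c(seq(0.01, 0.16, length.out = 16),
                   rep(1 / 16, 16)), 2, byrow = TRUE)
  attn <- attn / rowSums(attn)
  m <- attention_pseudo_mask(attn, 1, 0.75, hw = 4)
  expect_equal(dim(m), c(4, 4))
  # independent quantile computation
  thr <- quantile(attn[1, ], 0.75, type = 7)
  expect_equal(sum(m), sum(attn[1, ] > thr))
  # near-zero quantile: everything above the threshold except exact ties
  m0 <- attention_pseudo_mask(attn, 1, 0.001, hw = 4)
  expect_gte(sum(m0), 15)
  # uniform attention: all weights tie at the quantile, nothing exceeds it
  mu <- attention_pseudo_mask(attn, 2, 0.5, hw = 4)
  expect_equal(sum(mu), 0)
  # row-major reshape: patch k -> cell (k %/% W, k %% W)
  expect_equal(m[1, 2], as.numeric(attn[1, 2] > thr))
})

test_that("k-shot fine-tuning freezes the backbone and learns", {
  enc <- tiny_encoder(2)
  spec <- tiny_spec(per_class = 6, seed = 3)
  kshot <- unlist(lapply(0:2, function(cl) {
    lapply(1:3, function(i) generate_synthetic_image(cl, spec, i))
  }), recursive = FALSE)
  before <- cropclr:::param_checksum(enc$params)
  ft <- finetune(enc, kshot, k = 3, n_classes = 3, epochs = 40, seed = 4)
  expect_identical(cropclr:::param_checksum(enc$params), before)
  expect_identical(ft$backbone_checksum, before)
  # exactly k * n_classes samples consumed
  expect_equal(nrow(ft$history), 40)
  # smoothed loss decreases on separable synthetic features
  sm <- stats::filter(ft$history$train_loss, rep(1 / 5, 5), sides = 1)
  expect_lt(sm[40], sm[6])
  # protocol violation: a class with the wrong shot count
  expect_error(finetune(enc, kshot[1:8], k = 3, n_classes = 3),
               "protocol")
})
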