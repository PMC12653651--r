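# Few-shot fine-tuning by class-token attention aggregation: learnable
# per-class tokens attend over frozen patch features through a small
# transformer head; multi-label BCE training, head pruning, pseudo-masks.

#' Fine-tuning head configuration
#'
#' @param n_classes number of class tokens N (one per label).
#' @param width channel width C of the patch features (default 128).
#' @param n_layers transformer depth (default 3).
#' @param n_heads attention heads (default 8; must divide `width`).
#' @param ffn_hidden feed-forward hidden width (default 256; the printed
#'   head uses 128 -> 256 -> 128).
#' @param n_registers optional register tokens appended after the class
#'   tokens (default 0).
#' @export
finetune_config <- function(n_classes = 3L, width = 128L, n_layers = 3L,
                            n_heads = 8L, ffn_hidden = 256L, n_registers = 0L) {
  if (width %% n_heads != 0) stop("n_heads must divide width", call. = FALSE)
  structure(list(n_classes = as.integer(n_classes), width = as.integer(width),
                 n_layers = as.integer(n_layers), n_heads = as.integer(n_heads),
                 ffn_hidden = as.integer(ffn_hidden),
                 n_registers = as.integer(n_registers)),
            class = "finetune_config")
}

#' Initialize the attention-aggregation head
#'
#' @param config a [finetune_config()].
#' @param rng a [new_rng()] stream.
#' @return a `finetune_head`: class tokens, patch projection, transformer
#'   layers and the final linear classifier.
#' @export
head_init <- function(config, rng) {
  C <- config$width
  N <- config$n_classes
  nt <- N + config$n_registers
  layers <- lapply(seq_len(config$n_layers), function(i) {
    list(ln1 = ln_init(C), mha = mha_init(C, config$n_heads, rng),
         ln2 = ln_init(C),
         W1 = affine_init(C, config$ffn_hidden, rng),
         W2 = affine_init(config$ffn_hidden, C, rng, scale = 0.05))
  })
  params <- list(
    tokens = matrix(rng_norm(rng, nt * C, 0, 0.05), nt, C),
    patch_proj = affine_init(C, C, rng, scale = sqrt(1 / C)),
    layers = layers,
    cls = affine_init(N * C, N, rng, scale = sqrt(1 / (N * C)))
  )
  structure(list(params = params, config = config), class = "finetune_head")
}

# row-major patch matrix from an H x W x C feature grid: patch k
# (0-based) sits at grid cell (k %/% W, k %% W)
patches_from_fm <- function(e) {
  d <- dim(e)
  matrix(aperm(e, c(2, 1, 3)), d[1] * d[2], d[3])
}

#' Build the token sequence for the fine-tuning head
#'
#' `[N class tokens | register tokens | H*W patch tokens]`, with the patch
#' features linearly projected to width C and ordered row-major.
#'
#' @param F_grid `H x W x C` feature grid from the frozen backbone.
#' @param head a [head_init()] head.
#' @return matrix `(N + registers + H*W) x C`.
#' @export
build_token_sequence <- function(F_grid, head) {
  cfg <- head$config
  if (dim(F_grid)[3] != cfg$width) stop("feature width mismatch", call. = FALSE)
  P <- affine_fwd(head$params$patch_proj, patches_from_fm(F_grid))
  rbind(head$params$tokens, P)
}

#' Class-token cross-attention
#'
#' The aggregation primitive: `softmax(Q K' / sqrt(d_k)) V` with
#' `Q = T_c W_Q`, `K = P W_K`, `V = P W_V`, multi-head with `d_k = C / h`.
#'
#' @param tokens `N x C` class-token matrix.
#' @param patches `(H*W) x C` patch-feature matrix.
#' @param proj multi-head projection parameters ([mha_init()]-shaped; the
#'   output projection is not applied here).
#' @param n_heads number of heads.
#' @param head_mask optional 0/1 vector; masked heads contribute zero.
#' @return list with `outputs` (`N x C`) and `attn`, the head-averaged
#'   row-stochastic `N x (H*W)` attention map.
#' @export
class_token_attention <- function(tokens, patches, proj, n_heads, head_mask = NULL) {
  C <- ncol(tokens)
  if (C %% n_heads != 0) stop("n_heads must divide the width", call. = FALSE)
  dk <- C / n_heads
  mask <- head_mask %||% rep(1, n_heads)
  Q <- tokens %*% proj$Wq + matrix(proj$bq, nrow(tokens), C, byrow = TRUE)
  K <- patches %*% proj$Wk + matrix(proj$bk, nrow(patches), C, byrow = TRUE)
  V <- patches %*% proj$Wv + matrix(proj$bv, nrow(patches), C, byrow = TRUE)
  out <- matrix(0, nrow(tokens), C)
  attn_sum <- matrix(0, nrow(tokens), nrow(patches))
  for (h in seq_len(n_heads)) {
    cols <- ((h - 1) * dk + 1):(h * dk)
    A <- softmax_rows(Q[, cols, drop = FALSE] %*% t(K[, cols, drop = FALSE]) / sqrt(dk))
    out[, cols] <- mask[h] * (A %*% V[, cols, drop = FALSE])
    attn_sum <- attn_sum + A
  }
  list(outputs = out, attn = attn_sum / n_heads)
}

# Batched head forward: features is a list of H x W x C grids.  Per layer,
# the (class + register) tokens attend to that sample's projected patches:
# x <- x + MHA(LN(x) -> patches); x <- x + FFN(LN(x)).  Returns sigmoid
# class probabilities, per-layer head-averaged attention maps for the
# class tokens, and caches for the backward pass.
head_forward_batch <- function(features, head, head_mask = NULL, keep_cache = FALSE) {
  cfg <- head$config
  p <- head$params
  B <- length(features)
  N <- cfg$n_classes
  nt <- N + cfg$n_registers
  C <- cfg$width
  Praw <- do.call(rbind, lapply(features, patches_from_fm))
  np <- nrow(Praw) / B
  P <- affine_fwd(p$patch_proj, Praw)
  x <- p$tokens[rep(seq_len(nt), B), , drop = FALSE]
  caches <- vector("list", cfg$n_layers)
  attn <- vector("list", cfg$n_layers)
  for (li in seq_len(cfg$n_layers)) {
    lp <- p$layers[[li]]
    l1 <- ln_fwd(lp$ln1, x)
    at <- mha_fwd(lp$mha, l1$out, P, cfg$n_heads, B, nt, np, head_mask = head_mask)
    x1 <- x + at$out
    l2 <- ln_fwd(lp$ln2, x1)
    f1 <- affine_fwd(lp$W1, l2$out)
    a1 <- relu(f1)
    f2 <- affine_fwd(lp$W2, a1)
    xn <- x1 + f2
    attn[[li]] <- lapply(seq_len(B), function(b) {
      A <- Reduce(`+`, at$cache$attn[[b]]) / cfg$n_heads
      A[seq_len(N), , drop = FALSE]
    })
    caches[[li]] <- if (keep_cache) list(xin = x, l1 = l1, at = at, x1 = x1,
                                         l2 = l2, f1 = f1, a1 = a1) else
                                    list(at_attn = at$cache$attn)
    x <- xn
  }
  feat_vec <- t(vapply(seq_len(B), function(b) {
    rows <- ((b - 1) * nt + 1):((b - 1) * nt + N)
    as.vector(t(x[rows, , drop = FALSE]))
  }, numeric(N * C)))
  logits <- affine_fwd(p$cls, feat_vec)
  yhat <- sigmoid(logits)
  list(yhat = yhat, attn = attn,
       cache = if (keep_cache) list(caches = caches, x_final = x, Praw = Praw,
                                    P = P, feat_vec = feat_vec, B = B, np = np) else NULL)
}

# gradients for all head parameters given dlogits (B x N)
head_backward_batch <- function(head, cache, dlogits) {
  cfg <- head$config
  p <- head$params
  B <- cache$B
  N <- cfg$n_classes
  nt <- N + cfg$n_registers
  C <- cfg$width
  bcls <- affine_bwd(p$cls, cache$feat_vec, dlogits)
  dx <- matrix(0, nt * B, C)
  for (b in seq_len(B)) {
    rows <- ((b - 1) * nt + 1):((b - 1) * nt + N)
    dx[rows, ] <- matrix(bcls$dx[b, ], N, C, byrow = TRUE)
  }
  dP <- matrix(0, nrow(cache$P), C)
  dlayers <- vector("list", cfg$n_layers)
  for (li in rev(seq_len(cfg$n_layers))) {
    lp <- p$layers[[li]]
    ca <- cache$caches[[li]]
    da1 <- dx %*% t(lp$W2$W)
    gW2 <- list(W = crossprod(ca$a1, dx), b = colSums(dx))
    df1 <- relu_bwd(ca$f1, da1)
    gW1 <- list(W = crossprod(ca$l2$out, df1), b = colSums(df1))
    bl2 <- ln_bwd(lp$ln2, ca$l2$cache, df1 %*% t(lp$W1$W))
    dx1 <- dx + bl2$dx
    bat <- mha_bwd(lp$mha, ca$at$cache, dx1)
    dP <- dP + bat$dxkv
    bl1 <- ln_bwd(lp$ln1, ca$l1$cache, bat$dxq)
    dx <- dx1 + bl1$dx
    dlayers[[li]] <- list(ln1 = bl1$grads, mha = bat$grads, ln2 = bl2$grads,
                          W1 = gW1, W2 = gW2)
  }
  dtokens <- rowsum(dx, rep(seq_len(nt), B))
  bpp <- affine_bwd(p$patch_proj, cache$Praw, dP)
  list(tokens = dtokens, patch_proj = bpp$grads, layers = dlayers,
       cls = bcls$grads)
}

#' Forward pass of the fine-tuning head on one feature grid
#'
#' @param F_grid `H x W x C` frozen feature grid.
#' @param head a [head_init()] head.
#' @param head_mask optional 0/1 per-head mask from [prune_heads()].
#' @return list with `yhat` (sigmoid class probabilities, length N) and
#'   `attn`, per-layer head-averaged `N x (H*W)` attention maps.
#' @export
finetune_forward <- function(F_grid, head, head_mask = NULL) {
  out <- head_forward_batch(list(F_grid), head, head_mask = head_mask)
  list(yhat = as.vector(out$yhat), attn = lapply(out$attn, `[[`, 1))
}

#' Multi-label binary cross-entropy
#'
#' `-(1/N) sum_i [ y_i log yhat_i + (1 - y_i) log(1 - yhat_i) ]` with the
#' predictions clipped to `[eps, 1 - eps]`.
#'
#' @param y 0/1 target vector.
#' @param yhat predicted probabilities in `[0, 1]`, same length.
#' @param eps clipping constant (default 1e-7).
#' @export
multilabel_bce <- function(y, yhat, eps = 1e-7) {
  if (length(y) != length(yhat)) stop("length mismatch", call. = FALSE)
  q <- pmin(pmax(yhat, eps), 1 - eps)
  -mean(y * log(q) + (1 - y) * log(1 - q))
}

#' Loss weights for the staged objective
#'
#' @param lambda1 diffusion weight (default 0.5).
#' @param lambda2 classification weight (default 1.0).
#' @export
loss_weights <- function(lambda1 = 0.5, lambda2 = 1.0) {
  stopifnot(lambda1 >= 0, lambda2 >= 0)
  list(lambda1 = lambda1, lambda2 = lambda2)
}

#' Total training objective
#'
#' `L_contrast + lambda1 * L_diff + lambda2 * L_cls`.
#'
#' @param L_contrast,L_diff,L_cls finite loss values.
#' @param weights a [loss_weights()].
#' @export
total_loss <- function(L_contrast, L_diff, L_cls, weights = loss_weights()) {
  stopifnot(is.finite(L_contrast), is.finite(L_diff), is.finite(L_cls))
  L_contrast + weights$lambda1 * L_diff + weights$lambda2 * L_cls
}

#' Prune attention heads by importance
#'
#' Retains the `keep_count` heads with the highest importance scores (ties
#' broken toward the lower head index); masked heads contribute zero to
#' the layer output.
#'
#' @param head_importance numeric importance per head.
#' @param keep_count number of heads to keep (>= 1).
#' @return 0/1 mask of length `n_heads`.
#' @export
prune_heads <- function(head_importance, keep_count) {
  n <- length(head_importance)
  if (keep_count < 1 || keep_count > n) stop("keep_count out of range", call. = FALSE)
  ord <- order(-head_importance, seq_len(n))
  mask <- rep(0, n)
  mask[ord[seq_len(keep_count)]] <- 1
  mask
}

#' Per-head importance on a calibration batch
#'
#' For each head of the last layer: the maximum attention mass any class
#' token places on a single patch, averaged over the calibration samples.
#'
#' @param head a fine-tuned head.
#' @param features list of feature grids (calibration batch).
#' @return numeric vector of length `n_heads`.
#' @export
head_importance <- function(head, features) {
  cfg <- head$config
  out <- head_forward_batch(features, head, keep_cache = TRUE)
  last <- out$cache$caches[[cfg$n_layers]]$at$cache$attn
  sapply(seq_len(cfg$n_heads), function(h) {
    mean(vapply(last, function(ab) max(ab[[h]][seq_len(cfg$n_classes), ]), numeric(1)))
  })
}

#' Binary pseudo-mask from a class attention row
#'
#' Patches whose attention weight exceeds the class row's `quantile`
#' threshold are set to 1, reshaped to the `H x W` grid (row-major patch
#' order).
#'
#' @param attn `N x (H*W)` attention map.
#' @param class_index 1-based class row.
#' @param quantile threshold quantile in `(0, 1)`.
#' @param hw grid side H (= W).
#' @export
attention_pseudo_mask <- function(attn, class_index, quantile, hw) {
  row <- attn[class_index, ]
  thr <- as.numeric(stats::quantile(row, quantile, type = 7))
  mask <- as.numeric(row > thr)
  t(matrix(mask, hw, hw))
}

#' Fine-tune the attention head on a k-shot labeled set
#'
#' The backbone is frozen: only the class tokens, attention projections,
#' feed-forward layers and classifier move. Training uses multi-label BCE
#' on one-hot targets with momentum gradient descent (lr 1e-3, momentum
#' 0.9, weight decay 5e-4) and optional early stopping on a validation
#' fold.
#'
#' @param encoder_state frozen primary `encoder_state` from pretraining.
#' @param kshot_samples list of labeled [image_sample()]s, exactly `k` per
#'   class.
#' @param k shots per class.
#' @param n_classes number of classes.
#' @param epochs training epochs (default 120).
#' @param lr,momentum,weight_decay optimizer settings.
#' @param val_samples optional labeled validation samples for early stopping.
#' @param patience early-stopping patience in epochs (default 20).
#' @param seed head-initialization seed.
#' @param head_config optional [finetune_config()]; defaults to the
#'   encoder's feature width with 8 heads and 3 layers.
#' @param preprocess preprocessing applied before encoding (a function of
#'   an [image_sample()]); defaults to standardization to the encoder size.
#' @return list with the trained `head`, `history` (per-epoch losses),
#'   `backbone_checksum` (unchanged by training), and the `preprocess`
#'   function used.
#' @export
finetune <- function(encoder_state, kshot_samples, k, n_classes,
                     epochs = 120L, lr = 1e-3, momentum = 0.9,
                     weight_decay = 5e-4, val_samples = NULL, patience = 20L,
                     seed = 1L, head_config = NULL, preprocess = NULL) {
  labels <- vapply(kshot_samples, function(s) as.integer(s$label), integer(1))
  tab <- tabulate(labels + 1L, nbins = n_classes)
  if (any(tab != k)) {
    stop("k-shot protocol violated: every class needs exactly ", k, " samples",
         call. = FALSE)
  }
  cfg <- head_config %||% finetune_config(
    n_classes = n_classes, width = encoder_state$config$feat_c,
    n_heads = min(8L, encoder_state$config$feat_c), n_layers = 3L,
    ffn_hidden = 2L * encoder_state$config$feat_c)
  preprocess <- preprocess %||% function(img) {
    standardize_image(img, encoder_state$config$input_size)
  }
  checksum_before <- param_checksum(encoder_state$params)
  feats <- lapply(kshot_samples, function(s) {
    encode_feature_map(preprocess(s), encoder_state)
  })
  Y <- matrix(0, length(labels), n_classes)
  Y[cbind(seq_along(labels), labels + 1L)] <- 1
  vfeats <- NULL; vY <- NULL
  if (!is.null(val_samples)) {
    vlab <- vapply(val_samples, function(s) as.integer(s$label), integer(1))
    vfeats <- lapply(val_samples, function(s) {
      encode_feature_map(preprocess(s), encoder_state)
    })
    vY <- matrix(0, length(vlab), n_classes)
    vY[cbind(seq_along(vlab), vlab + 1L)] <- 1
  }
  rng <- new_rng(seed)
  head <- head_init(cfg, rng)
  opt <- sgdm_init(head$params)
  history <- data.frame(epoch = integer(), train_loss = numeric(),
                        val_loss = numeric())
  best <- list(loss = Inf, params = head$params, epoch = 0L)
  stale <- 0L
  for (ep in seq_len(epochs)) {
    fwd <- head_forward_batch(feats, head, keep_cache = TRUE)
    q <- pmin(pmax(fwd$yhat, 1e-7), 1 - 1e-7)
    train_loss <- -mean(rowMeans(Y * log(q) + (1 - Y) * log(1 - q)))
    # d(BCE)/dlogits for sigmoid outputs, averaged per sample and class
    dlogits <- (q - Y) / (n_classes * length(feats))
    grads <- head_backward_batch(head, fwd$cache, dlogits)
    st <- sgdm_step(head$params, grads, opt, lr = lr, momentum = momentum,
                    weight_decay = weight_decay)
    head$params <- st$params
    opt <- st$state
    val_loss <- NA_real_
    monitor <- train_loss
    if (!is.null(vfeats)) {
      vf <- head_forward_batch(vfeats, head)
      vq <- pmin(pmax(vf$yhat, 1e-7), 1 - 1e-7)
      val_loss <- -mean(rowMeans(vY * log(vq) + (1 - vY) * log(1 - vq)))
      monitor <- val_loss
    }
    history <- rbind(history, data.frame(epoch = ep, train_loss = train_loss,
                                         val_loss = val_loss))
    if (monitor < best$loss - 1e-6) {
      best <- list(loss = monitor, params = head$params, epoch = ep)
      stale <- 0L
    } else {
      stale <- stale + 1L
      if (!is.null(vfeats) && stale >= patience) break
    }
  }
  if (!is.null(vfeats)) head$params <- best$params
  stopifnot(param_checksum(encoder_state$params) == checksum_before)
  list(head = head, history = history,
       backbone_checksum = checksum_before, preprocess = preprocess,
       config = cfg)
}
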