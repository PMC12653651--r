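# Viewpoint-invariant contrastive encoding: a residual convolutional
# backbone with projection head, a momentum (EMA) encoder, a FIFO queue of
# negative embeddings, and the InfoNCE objective.

#' Contrastive configuration
#'
#' @param tau InfoNCE temperature (default 0.2).
#' @param m momentum coefficient for the EMA encoder (default 0.999).
#' @param K negative-queue capacity (default 4096).
#' @param d embedding dimension (default 128).
#' @export
contrastive_config <- function(tau = 0.2, m = 0.999, K = 4096L, d = 128L) {
  stopifnot(tau > 0, m >= 0, m <= 1, K >= 1)
  structure(list(tau = tau, m = m, K = as.integer(K), d = as.integer(d)),
            class = "contrastive_config")
}

#' Encoder configuration
#'
#' Two profiles: `"paper"`, a residual convolutional backbone in the
#' ResNet-50 family operating on 512 px inputs with a 16x16x128 feature
#' grid; and `"test"`, a small 3-stage convnet on 64 px inputs with an
#' 8x8x32 grid, sized for CPU-scale experiments. The projection head is
#' two affine layers 512 -> 128 -> 128 with an interleaved rectifier; a
#' single affine adapter bridges the backbone width to the 512-wide
#' projection input when they differ.
#'
#' @param profile `"test"` or `"paper"`.
#' @param embed_dim projection output dimension d.
#' @param feat_hw side of the spatial feature grid fed to the diffusion
#'   filter and the fine-tuning head.
#' @param feat_c channel width of that feature grid.
#' @export
encoder_config <- function(profile = c("test", "paper"), embed_dim = 128L,
                           feat_hw = NULL, feat_c = NULL) {
  profile <- match.arg(profile)
  cfg <- if (profile == "test") {
    list(input_size = 64L, widths = c(8L, 16L, 32L), strides = c(2L, 2L, 2L),
         residual = c(FALSE, FALSE, FALSE), feat_hw = 8L, feat_c = 32L)
  } else {
    list(input_size = 512L, widths = c(32L, 64L, 128L, 256L, 512L),
         strides = rep(2L, 5), residual = c(FALSE, TRUE, TRUE, TRUE, TRUE),
         feat_hw = 16L, feat_c = 128L)
  }
  cfg$profile <- profile
  cfg$proj_in <- 512L
  cfg$proj_hidden <- 128L
  cfg$embed_dim <- as.integer(embed_dim)
  if (!is.null(feat_hw)) cfg$feat_hw <- as.integer(feat_hw)
  if (!is.null(feat_c)) cfg$feat_c <- as.integer(feat_c)
  cfg$grid_hw <- cfg$input_size %/% prod(cfg$strides)
  structure(cfg, class = "encoder_config")
}

#' Initialize an encoder
#'
#' @param config an [encoder_config()].
#' @param rng a [new_rng()] stream.
#' @return an `encoder_state`: backbone + projection + feature-adapter
#'   parameters and the configuration.
#' @export
encoder_init <- function(config, rng) {
  widths <- config$widths
  c_in <- 3L
  stages <- list()
  for (i in seq_along(widths)) {
    st <- list(main = conv_init(3L, c_in, widths[i], rng))
    st$main$stride <- as.numeric(config$strides[i])
    if (config$residual[i]) {
      st$res1 <- conv_init(3L, widths[i], widths[i], rng)
      st$res2 <- conv_init(3L, widths[i], widths[i], rng, scale = 0.01)
    }
    stages[[i]] <- st
    c_in <- widths[i]
  }
  last <- widths[length(widths)]
  params <- list(stages = stages)
  params$adapter <- if (last != config$proj_in) {
    affine_init(last, config$proj_in, rng)
  } else {
    NULL
  }
  params$fc1 <- affine_init(config$proj_in, config$proj_hidden, rng)
  params$fc2 <- affine_init(config$proj_hidden, config$embed_dim, rng)
  params$feat <- conv_init(1L, last, config$feat_c, rng)
  params <- params[!vapply(params, is.null, logical(1))]
  structure(list(params = params, config = config), class = "encoder_state")
}

#' Load pretrained backbone weights into an encoder
#'
#' Optionally initializes the convolutional stages from a serialized
#' parameter bundle (an RDS file holding a list shaped like
#' `state$params$stages`). Stages whose shapes do not match are rejected.
#' Pretrained initialization is never required: all training paths work
#' from random initialization.
#'
#' @param state an `encoder_state`.
#' @param path RDS file with a `stages` parameter list.
#' @return the encoder with its backbone stages replaced.
#' @export
load_backbone_weights <- function(state, path) {
  if (!file.exists(path)) stop("weights file not found: ", path, call. = FALSE)
  stages <- readRDS(path)
  if (length(stages) != length(state$params$stages)) {
    stop("stage count mismatch", call. = FALSE)
  }
  for (i in seq_along(stages)) {
    for (nm in names(state$params$stages[[i]])) {
      old <- state$params$stages[[i]][[nm]]$W
      new <- stages[[i]][[nm]]$W
      if (is.null(new) || !identical(dim(old), dim(new))) {
        stop("shape mismatch in stage ", i, " (", nm, ")", call. = FALSE)
      }
    }
  }
  state$params$stages <- stages
  state
}

#' Create a momentum encoder from a primary encoder
#'
#' @param state an `encoder_state`.
#' @param m momentum coefficient in `[0, 1]` (default 0.999).
#' @return a `momentum_encoder_state` with a deep copy of the parameters.
#' @export
momentum_encoder_init <- function(state, m = 0.999) {
  structure(list(params = state$params, config = state$config, m = m),
            class = "momentum_encoder_state")
}

#' Exponential-moving-average update of the momentum encoder
#'
#' Every momentum parameter p' is replaced by `m * p' + (1 - m) * p`; the
#' primary encoder is untouched.
#'
#' @param momentum_state a `momentum_encoder_state`.
#' @param state the primary `encoder_state`.
#' @return the updated `momentum_encoder_state`.
#' @export
ema_update <- function(momentum_state, state) {
  m <- momentum_state$m
  momentum_state$params <- tree_map2(momentum_state$params, state$params,
                                     function(pp, p) m * pp + (1 - m) * p)
  momentum_state
}

backbone_fwd <- function(params, config, x, keep_cache = FALSE) {
  caches <- list()
  h <- x
  for (i in seq_along(params$stages)) {
    st <- params$stages[[i]]
    cm <- conv_fwd(st$main, h)
    a <- relu(cm$out)
    cache_i <- list(in_main = h, conv_main = cm, pre_main = cm$out)
    h <- a
    if (!is.null(st$res1)) {
      c1 <- conv_fwd(st$res1, h)
      a1 <- relu(c1$out)
      c2 <- conv_fwd(st$res2, a1)
      pre <- c2$out + h
      cache_i <- c(cache_i, list(res_in = h, conv1 = c1, pre1 = c1$out,
                                 a1 = a1, conv2 = c2, pre_res = pre))
      h <- relu(pre)
    }
    caches[[i]] <- if (keep_cache) cache_i else NULL
  }
  list(grid = h, caches = caches)
}

backbone_bwd <- function(params, config, caches, dgrid) {
  grads <- list(stages = vector("list", length(params$stages)))
  dh <- dgrid
  for (i in rev(seq_along(params$stages))) {
    st <- params$stages[[i]]
    ca <- caches[[i]]
    g <- list()
    if (!is.null(st$res1)) {
      dpre <- relu_bwd(ca$pre_res, dh)
      b2 <- conv_bwd(st$res2, ca$conv2$cache, dpre)
      da1 <- relu_bwd(ca$pre1, b2$dx)
      b1 <- conv_bwd(st$res1, ca$conv1$cache, da1)
      dh <- dpre + b1$dx
      g$res1 <- c(b1$grads, list(k = 0, stride = 0, pad = 0))
      g$res2 <- c(b2$grads, list(k = 0, stride = 0, pad = 0))
    }
    dmain <- relu_bwd(ca$pre_main, dh)
    bm <- conv_bwd(st$main, ca$conv_main$cache, dmain)
    g$main <- c(bm$grads, list(k = 0, stride = 0, pad = 0))
    dh <- bm$dx
    grads$stages[[i]] <- g[names(st)]
  }
  list(dx = dh, grads = grads)
}

# grid (h, w, C) -> unit-norm embedding; optionally keeps caches
project_fwd <- function(params, config, grid, keep_cache = FALSE) {
  C <- dim(grid)[3]
  gm <- matrix(grid, prod(dim(grid)[1:2]), C)
  v <- matrix(colMeans(gm), 1, C)
  a <- if (!is.null(params$adapter)) affine_fwd(params$adapter, v) else v
  h1p <- affine_fwd(params$fc1, a)
  h1 <- relu(h1p)
  z0 <- affine_fwd(params$fc2, h1)
  z <- l2_normalize_rows(z0)
  cache <- if (keep_cache) list(grid_dim = dim(grid), v = v, a = a,
                                h1p = h1p, h1 = h1, z0 = z0) else NULL
  list(z = as.vector(z), cache = cache)
}

project_bwd <- function(params, config, cache, dz) {
  dz0 <- l2_normalize_rows_bwd(cache$z0, matrix(dz, 1))
  b2 <- affine_bwd(params$fc2, cache$h1, dz0)
  dh1p <- relu_bwd(cache$h1p, b2$dx)
  b1 <- affine_bwd(params$fc1, cache$a, dh1p)
  grads <- list(fc1 = b1$grads, fc2 = b2$grads)
  da <- b1$dx
  if (!is.null(params$adapter)) {
    ba <- affine_bwd(params$adapter, cache$v, da)
    grads$adapter <- ba$grads
    dv <- ba$dx
  } else {
    dv <- da
  }
  gd <- cache$grid_dim
  dgrid <- array(rep(dv / prod(gd[1:2]), each = prod(gd[1:2])), gd)
  list(dgrid = dgrid, grads = grads)
}

# backbone grid -> diffusion/fine-tuning feature map (feat_hw x feat_hw x feat_c)
feature_map_fwd <- function(params, config, grid, keep_cache = FALSE) {
  cf <- conv_fwd(params$feat, grid)
  d <- dim(cf$out)
  M <- resize_matrix(d[1], d[2], config$feat_hw, config$feat_hw)
  fm_mat <- M %*% matrix(cf$out, d[1] * d[2], d[3])
  fmap <- array(fm_mat, c(config$feat_hw, config$feat_hw, d[3]))
  list(fmap = fmap, cache = if (keep_cache) list(conv = cf, d = d, M = M) else NULL)
}

feature_map_bwd <- function(params, config, cache, dfmap) {
  d <- cache$d
  dmat <- t(cache$M) %*% matrix(dfmap, config$feat_hw^2, d[3])
  bc <- conv_bwd(params$feat, cache$conv$cache, array(dmat, d))
  list(dgrid = bc$dx, grads = list(feat = c(bc$grads, list(k = 0, stride = 0, pad = 0))))
}

#' Encode and project an image to a unit-norm embedding
#'
#' @param x a standardized [image_sample()] matching the encoder input size.
#' @param state an `encoder_state` (or `momentum_encoder_state`).
#' @return numeric embedding of length `embed_dim`, unit L2 norm.
#' @export
encode_project <- function(x, state) {
  px <- x$pixels
  cfg <- state$config
  if (dim(px)[1] != cfg$input_size || dim(px)[2] != cfg$input_size) {
    stop("input must be standardized to ", cfg$input_size, " px", call. = FALSE)
  }
  bb <- backbone_fwd(state$params, cfg, px / 255)
  project_fwd(state$params, cfg, bb$grid)$z
}

#' Spatial feature map of an image
#'
#' The backbone's last spatial stage passed through a 1x1 channel adapter
#' and bilinearly interpolated to the configured `feat_hw` grid.
#'
#' @inheritParams encode_project
#' @return `feat_hw x feat_hw x feat_c` array.
#' @export
encode_feature_map <- function(x, state) {
  bb <- backbone_fwd(state$params, state$config, x$pixels / 255)
  feature_map_fwd(state$params, state$config, bb$grid)$fmap
}

#' Cosine similarity
#'
#' @param a,b numeric vectors (nonzero).
#' @return scalar in `[-1, 1]`; invariant to rescaling of either argument.
#' @export
cosine_similarity <- function(a, b) {
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) stop("cosine similarity undefined for zero vector", call. = FALSE)
  sum(a * b) / (na * nb)
}

#' Create a negative queue
#'
#' FIFO buffer of unit-norm momentum embeddings used as InfoNCE negatives.
#'
#' @param capacity maximum number of entries K.
#' @param d embedding dimension.
#' @param prefill_rng optional [new_rng()]; when given, the queue starts
#'   full of random unit vectors (evicted FIFO as real embeddings arrive)
#'   so the loss is defined from the first step.
#' @export
negative_queue <- function(capacity, d = 128L, prefill_rng = NULL) {
  buf <- matrix(numeric(0), 0, d)
  if (!is.null(prefill_rng)) {
    buf <- l2_normalize_rows(matrix(rng_norm(prefill_rng, capacity * d), capacity, d))
  }
  structure(list(buffer = buf, capacity = as.integer(capacity)),
            class = "negative_queue")
}

#' Push embeddings onto the negative queue
#'
#' @param queue a [negative_queue()].
#' @param batch matrix of unit-norm rows (or a single vector).
#' @return the queue with FIFO semantics: newest rows at the end, oldest
#'   evicted once capacity is exceeded.
#' @export
queue_push <- function(queue, batch) {
  if (is.null(dim(batch))) batch <- matrix(batch, 1)
  nrm <- sqrt(rowSums(batch^2))
  if (any(abs(nrm - 1) > 1e-4)) stop("queue entries must be unit-norm", call. = FALSE)
  buf <- rbind(queue$buffer, batch)
  n <- nrow(buf)
  if (n > queue$capacity) buf <- buf[(n - queue$capacity + 1):n, , drop = FALSE]
  queue$buffer <- buf
  queue
}

#' @rdname queue_push
#' @export
queue_length <- function(queue) nrow(queue$buffer)

#' InfoNCE contrastive loss for one positive pair
#'
#' `-log( exp(sim(z_i, z_j)/tau) / (exp(sim(z_i, z_j)/tau) +
#' sum_k exp(sim(z_i, z_k)/tau)) )` with the queue entries as negatives.
#'
#' @param z_i,z_j embeddings of the two views.
#' @param queue a non-empty [negative_queue()].
#' @param tau temperature (> 0).
#' @return strictly positive scalar loss.
#' @export
info_nce_loss <- function(z_i, z_j, queue, tau = 0.2) {
  if (tau <= 0) stop("temperature must be positive", call. = FALSE)
  if (queue_length(queue) == 0) stop("negative queue is empty", call. = FALSE)
  s_pos <- cosine_similarity(z_i, z_j)
  zi_u <- z_i / sqrt(sum(z_i^2))
  s_neg <- as.vector(queue$buffer %*% zi_u) /
    sqrt(rowSums(queue$buffer^2))
  m <- max(s_pos, s_neg) / tau
  -(s_pos / tau) + m + log(exp(s_pos / tau - m) + sum(exp(s_neg / tau - m)))
}

# batched InfoNCE over unit-norm rows; returns loss (weighted mean over
# pairs with weight > 0) and the gradient wrt Zi
info_nce_batch <- function(Zi, Zj, negs, tau, weights = NULL) {
  B <- nrow(Zi)
  weights <- weights %||% rep(1, B)
  s_pos <- rowSums(Zi * Zj)
  S <- Zi %*% t(negs)                     # B x K
  logits <- cbind(s_pos, S) / tau
  mx <- apply(logits, 1, max)
  P <- exp(logits - mx)
  P <- P / rowSums(P)
  losses <- -log(P[, 1])
  wsum <- sum(weights)
  if (wsum == 0) {
    return(list(loss = 0, losses = losses, dZi = Zi * 0))
  }
  dlogits <- P
  dlogits[, 1] <- dlogits[, 1] - 1
  dlogits <- dlogits * (weights / wsum) / tau
  dZi <- dlogits[, 1] * Zj + dlogits[, -1, drop = FALSE] %*% negs
  list(loss = sum(losses * weights) / wsum, losses = losses, dZi = dZi)
}

#' One contrastive step on a single view pair
#'
#' Encodes `x_i` with the primary encoder and `x_j` with the momentum
#' encoder, evaluates the InfoNCE loss against the pre-push queue, pushes
#' `z_j`, applies the EMA update, and emits the spatial feature maps needed
#' by the diffusion filter. No optimizer step is taken here.
#'
#' @param pair a `view_pair`.
#' @param state primary `encoder_state`.
#' @param momentum_state `momentum_encoder_state`.
#' @param queue non-empty [negative_queue()].
#' @param config a [contrastive_config()].
#' @return list with `loss`, updated `momentum_state` and `queue`, `z_i`,
#'   `z_j`, and feature maps `e_i`, `e_j`.
#' @export
contrastive_step <- function(pair, state, momentum_state, queue, config) {
  bb_i <- backbone_fwd(state$params, state$config, pair$x_i$pixels / 255)
  z_i <- project_fwd(state$params, state$config, bb_i$grid)$z
  e_i <- feature_map_fwd(state$params, state$config, bb_i$grid)$fmap
  bb_j <- backbone_fwd(momentum_state$params, momentum_state$config,
                       pair$x_j$pixels / 255)
  z_j <- project_fwd(momentum_state$params, momentum_state$config, bb_j$grid)$z
  e_j <- feature_map_fwd(momentum_state$params, momentum_state$config, bb_j$grid)$fmap
  loss <- info_nce_loss(z_i, z_j, queue, config$tau)
  queue <- queue_push(queue, z_j)
  momentum_state <- ema_update(momentum_state, state)
  list(loss = loss, momentum_state = momentum_state, queue = queue,
       z_i = z_i, z_j = z_j, e_i = e_i, e_j = e_j)
}
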