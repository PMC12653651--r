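# Minimal neural-network core: seeded RNG streams, parameter trees, and
# layers (dense, conv, layer norm, multi-head attention) with hand-written
# backward passes.  Everything is plain double matrices/arrays so that runs
# are bit-reproducible on a single thread.

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- RNG streams -----------------------------------------------------------
# An isolated Mersenne-Twister stream.  Draws never touch the caller's
# global RNG state, so every stochastic operation is a pure function of
# (seed, draw index).

#' Create an isolated seeded random stream
#'
#' @param seed integer seed.
#' @return an object of class `cropclr_rng` usable by the stochastic
#'   operations of the package. Draws from the stream do not disturb the
#'   global R random state.
#' @export
new_rng <- function(seed) {
  stopifnot(length(seed) == 1L, is.finite(seed))
  env <- new.env(parent = emptyenv())
  old <- get0(".Random.seed", envir = globalenv())
  set.seed(as.integer(seed %% 2147483647L))
  env$state <- get(".Random.seed", envir = globalenv())
  if (is.null(old)) {
    rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  class(env) <- "cropclr_rng"
  env
}

rng_draw <- function(rng, fn) {
  stopifnot(inherits(rng, "cropclr_rng"))
  old <- get0(".Random.seed", envir = globalenv())
  assign(".Random.seed", rng$state, envir = globalenv())
  out <- fn()
  rng$state <- get(".Random.seed", envir = globalenv())
  if (is.null(old)) {
    rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  out
}

rng_unif <- function(rng, n, min = 0, max = 1) {
  rng_draw(rng, function() stats::runif(n, min, max))
}

rng_norm <- function(rng, n, mean = 0, sd = 1) {
  rng_draw(rng, function() stats::rnorm(n, mean, sd))
}

# uniform integer in [lo, hi], inclusive
rng_int <- function(rng, n, lo, hi) {
  pmin(lo + floor(rng_unif(rng, n) * (hi - lo + 1)), hi)
}

rng_sample <- function(rng, x, size = length(x), replace = FALSE) {
  rng_draw(rng, function() sample(x, size, replace))
}

# derive k child seeds (below 2^31) so sub-modules get independent streams
rng_spawn_seeds <- function(rng, k) {
  floor(rng_unif(rng, k) * 2147483646) + 1
}

# ---- parameter trees -------------------------------------------------------

tree_map <- function(a, f) {
  if (is.list(a)) lapply(a, tree_map, f = f) else f(a)
}

tree_map2 <- function(a, b, f) {
  if (is.list(a)) {
    out <- Map(function(x, y) tree_map2(x, y, f), a, b)
    out
  } else {
    f(a, b)
  }
}

tree_zeros_like <- function(a) tree_map(a, function(x) x * 0)

tree_unlist <- function(a) unlist(a, use.names = FALSE)

tree_add <- function(a, b) tree_map2(a, b, `+`)

# checksum used to assert that frozen parameters never move
param_checksum <- function(params) {
  v <- tree_unlist(params)
  sum(v) + sum(v * seq_along(v) %% 97)
}

# ---- dense layer -----------------------------------------------------------

affine_init <- function(n_in, n_out, rng, scale = NULL) {
  scale <- scale %||% sqrt(2 / n_in)
  list(
    W = matrix(rng_norm(rng, n_in * n_out, 0, scale), n_in, n_out),
    b = numeric(n_out)
  )
}

affine_fwd <- function(p, x) {
  # x: n x n_in
  out <- x %*% p$W
  out <- out + matrix(p$b, nrow(out), ncol(out), byrow = TRUE)
  out
}

affine_bwd <- function(p, x, dout) {
  list(
    dx = dout %*% t(p$W),
    grads = list(W = crossprod(x, dout), b = colSums(dout))
  )
}

relu <- function(x) {
  x[x < 0] <- 0
  x
}

relu_bwd <- function(x, dout) {
  dout[x <= 0] <- 0
  dout
}

softplus <- function(x) ifelse(x > 30, x, log1p(exp(pmin(x, 30))))

sigmoid <- function(x) 1 / (1 + exp(-x))

softmax_rows <- function(s) {
  e <- exp(s - apply(s, 1L, max))
  e / rowSums(e)
}

# dS given A = softmax_rows(S) and dA
softmax_rows_bwd <- function(A, dA) {
  A * (dA - rowSums(A * dA))
}

# rows of x normalized to unit L2 norm
l2_normalize_rows <- function(x) {
  nrm <- sqrt(rowSums(x^2))
  x / nrm
}

l2_normalize_rows_bwd <- function(x, dout) {
  nrm <- sqrt(rowSums(x^2))
  z <- x / nrm
  (dout - z * rowSums(dout * z)) / nrm
}

# ---- layer normalization ---------------------------------------------------

ln_init <- function(width) list(g = rep(1, width), b = rep(0, width))

ln_fwd <- function(p, x, eps = 1e-5) {
  mu <- rowMeans(x)
  xc <- x - mu
  inv <- 1 / sqrt(rowMeans(xc^2) + eps)
  xhat <- xc * inv
  out <- xhat * matrix(p$g, nrow(x), ncol(x), byrow = TRUE) +
    matrix(p$b, nrow(x), ncol(x), byrow = TRUE)
  list(out = out, cache = list(xhat = xhat, inv = inv))
}

ln_bwd <- function(p, cache, dout) {
  xhat <- cache$xhat
  inv <- cache$inv
  dxhat <- dout * matrix(p$g, nrow(dout), ncol(dout), byrow = TRUE)
  dx <- inv * (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat))
  list(
    dx = dx,
    grads = list(g = colSums(dout * cache$xhat), b = colSums(dout))
  )
}

# ---- multi-head attention --------------------------------------------------
# Query tokens attend to key/value tokens; batched as stacked row blocks.
# Supports a per-head 0/1 mask (head pruning) applied to the head outputs.

mha_init <- function(width, n_heads, rng) {
  stopifnot(width %% n_heads == 0)
  s <- sqrt(1 / width)
  list(
    Wq = matrix(rng_norm(rng, width * width, 0, s), width, width),
    Wk = matrix(rng_norm(rng, width * width, 0, s), width, width),
    Wv = matrix(rng_norm(rng, width * width, 0, s), width, width),
    Wo = matrix(rng_norm(rng, width * width, 0, s), width, width),
    bq = numeric(width), bk = numeric(width),
    bv = numeric(width), bo = numeric(width)
  )
}

# xq: (B*Tq) x C, xkv: (B*Tk) x C
mha_fwd <- function(p, xq, xkv, n_heads, B, Tq, Tk, head_mask = NULL) {
  C <- ncol(xq)
  dk <- C / n_heads
  mask <- head_mask %||% rep(1, n_heads)
  Q <- xq %*% p$Wq + matrix(p$bq, nrow(xq), C, byrow = TRUE)
  K <- xkv %*% p$Wk + matrix(p$bk, nrow(xkv), C, byrow = TRUE)
  V <- xkv %*% p$Wv + matrix(p$bv, nrow(xkv), C, byrow = TRUE)
  O <- matrix(0, nrow(xq), C)
  attn <- vector("list", B)
  for (b in seq_len(B)) {
    rq <- ((b - 1) * Tq + 1):(b * Tq)
    rk <- ((b - 1) * Tk + 1):(b * Tk)
    ab <- vector("list", n_heads)
    for (h in seq_len(n_heads)) {
      cols <- ((h - 1) * dk + 1):(h * dk)
      S <- (Q[rq, cols, drop = FALSE] %*% t(K[rk, cols, drop = FALSE])) / sqrt(dk)
      A <- softmax_rows(S)
      ab[[h]] <- A
      O[rq, cols] <- mask[h] * (A %*% V[rk, cols, drop = FALSE])
    }
    attn[[b]] <- ab
  }
  out <- O %*% p$Wo + matrix(p$bo, nrow(xq), C, byrow = TRUE)
  list(out = out, cache = list(Q = Q, K = K, V = V, O = O, attn = attn,
                               xq = xq, xkv = xkv, n_heads = n_heads,
                               B = B, Tq = Tq, Tk = Tk, mask = mask))
}

mha_bwd <- function(p, cache, dout) {
  Q <- cache$Q; K <- cache$K; V <- cache$V
  n_heads <- cache$n_heads
  B <- cache$B; Tq <- cache$Tq; Tk <- cache$Tk
  mask <- cache$mask
  C <- ncol(Q)
  dk <- C / n_heads
  dWo <- crossprod(cache$O, dout)
  dbo <- colSums(dout)
  dO <- dout %*% t(p$Wo)
  dQ <- matrix(0, nrow(Q), C)
  dK <- matrix(0, nrow(K), C)
  dV <- matrix(0, nrow(V), C)
  for (b in seq_len(B)) {
    rq <- ((b - 1) * Tq + 1):(b * Tq)
    rk <- ((b - 1) * Tk + 1):(b * Tk)
    for (h in seq_len(n_heads)) {
      if (mask[h] == 0) next
      cols <- ((h - 1) * dk + 1):(h * dk)
      A <- cache$attn[[b]][[h]]
      dOh <- mask[h] * dO[rq, cols, drop = FALSE]
      dA <- dOh %*% t(V[rk, cols, drop = FALSE])
      dV[rk, cols] <- dV[rk, cols] + t(A) %*% dOh
      dS <- softmax_rows_bwd(A, dA) / sqrt(dk)
      dQ[rq, cols] <- dS %*% K[rk, cols, drop = FALSE]
      dK[rk, cols] <- dK[rk, cols] + t(dS) %*% Q[rq, cols, drop = FALSE]
    }
  }
  dxq <- dQ %*% t(p$Wq)
  dxkv <- dK %*% t(p$Wk) + dV %*% t(p$Wv)
  grads <- list(
    Wq = crossprod(cache$xq, dQ), Wk = crossprod(cache$xkv, dK),
    Wv = crossprod(cache$xkv, dV), Wo = dWo,
    bq = colSums(dQ), bk = colSums(dK), bv = colSums(dV), bo = dbo
  )
  list(dxq = dxq, dxkv = dxkv, grads = grads)
}

# ---- 2-d convolution (im2col) ----------------------------------------------

.conv_cache <- new.env(parent = emptyenv())

conv_idx <- function(H, W, C, k, stride, pad) {
  key <- paste(H, W, C, k, stride, pad, sep = "_")
  hit <- .conv_cache[[key]]
  if (!is.null(hit)) return(hit)
  Hp <- H + 2 * pad
  Wp <- W + 2 * pad
  Ho <- (Hp - k) %/% stride + 1
  Wo <- (Wp - k) %/% stride + 1
  oi <- rep(seq_len(Ho), times = Wo)
  oj <- rep(seq_len(Wo), each = Ho)
  base <- (oi - 1) * stride + ((oj - 1) * stride) * Hp
  off_i <- rep(seq_len(k), times = k * C)
  off_j <- rep(rep(seq_len(k), each = k), times = C)
  off_c <- rep(seq_len(C), each = k * k)
  off <- off_i + (off_j - 1) * Hp + (off_c - 1) * Hp * Wp
  idx <- outer(base, off, `+`)
  out <- list(idx = idx, Ho = Ho, Wo = Wo, Hp = Hp, Wp = Wp)
  .conv_cache[[key]] <- out
  out
}

conv_init <- function(k, c_in, c_out, rng, scale = NULL) {
  n_in <- k * k * c_in
  scale <- scale %||% sqrt(2 / n_in)
  list(
    W = matrix(rng_norm(rng, n_in * c_out, 0, scale), n_in, c_out),
    b = numeric(c_out),
    k = as.numeric(k), stride = 1, pad = as.numeric((k - 1L) %/% 2L)
  )
}

pad_array <- function(x, pad) {
  if (pad == 0) return(x)
  d <- dim(x)
  xp <- array(0, c(d[1] + 2 * pad, d[2] + 2 * pad, d[3]))
  xp[pad + seq_len(d[1]), pad + seq_len(d[2]), ] <- x
  xp
}

conv_fwd <- function(p, x) {
  d <- dim(x)
  ci <- conv_idx(d[1], d[2], d[3], p$k, p$stride, p$pad)
  xp <- pad_array(x, p$pad)
  cols <- matrix(xp[ci$idx], nrow(ci$idx), ncol(ci$idx))
  outm <- cols %*% p$W
  outm <- outm + matrix(p$b, nrow(outm), ncol(outm), byrow = TRUE)
  list(out = array(outm, c(ci$Ho, ci$Wo, ncol(p$W))),
       cache = list(cols = cols, dims = d, ci = ci))
}

conv_bwd <- function(p, cache, dout) {
  ci <- cache$ci
  d <- cache$dims
  doutm <- matrix(dout, nrow(ci$idx), length(dout) / nrow(ci$idx))
  dW <- crossprod(cache$cols, doutm)
  db <- colSums(doutm)
  dcols <- doutm %*% t(p$W)
  acc <- rowsum(as.vector(dcols), group = as.vector(ci$idx))
  dxp <- numeric(ci$Hp * ci$Wp * d[3])
  dxp[as.integer(rownames(acc))] <- acc
  dxp <- array(dxp, c(ci$Hp, ci$Wp, d[3]))
  dx <- if (p$pad > 0) {
    dxp[p$pad + seq_len(d[1]), p$pad + seq_len(d[2]), , drop = FALSE]
  } else {
    dxp
  }
  list(dx = dx, grads = list(W = dW, b = db))
}

# ---- bilinear interpolation matrix for feature grids -----------------------

.resize_cache <- new.env(parent = emptyenv())

# Dense (h_out*w_out) x (h_in*w_in) matrix; grids vectorized column-major.
resize_matrix <- function(h_in, w_in, h_out, w_out) {
  key <- paste(h_in, w_in, h_out, w_out, sep = "_")
  hit <- .resize_cache[[key]]
  if (!is.null(hit)) return(hit)
  M <- matrix(0, h_out * w_out, h_in * w_in)
  for (jo in seq_len(w_out)) {
    xs <- (jo - 0.5) * w_in / w_out - 0.5
    x0 <- floor(xs); wx <- xs - x0
    x0 <- min(max(x0, 0), w_in - 1); x1 <- min(x0 + 1, w_in - 1)
    for (io in seq_len(h_out)) {
      ys <- (io - 0.5) * h_in / h_out - 0.5
      y0 <- floor(ys); wy <- ys - y0
      y0 <- min(max(y0, 0), h_in - 1); y1 <- min(y0 + 1, h_in - 1)
      r <- io + (jo - 1) * h_out
      add <- function(yy, xx, w) {
        cidx <- (yy + 1) + xx * h_in
        M[r, cidx] <<- M[r, cidx] + w
      }
      add(y0, x0, (1 - wy) * (1 - wx))
      add(y1, x0, wy * (1 - wx))
      add(y0, x1, (1 - wy) * wx)
      add(y1, x1, wy * wx)
    }
  }
  .resize_cache[[key]] <- M
  M
}

# ---- optimizers ------------------------------------------------------------

adam_init <- function(params) {
  list(m = tree_zeros_like(params), v = tree_zeros_like(params), t = 0)
}

adam_step <- function(params, grads, state, lr = 1e-4,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1
  state$m <- tree_map2(state$m, grads, function(m, g) beta1 * m + (1 - beta1) * g)
  state$v <- tree_map2(state$v, grads, function(v, g) beta2 * v + (1 - beta2) * g^2)
  c1 <- 1 - beta1^state$t
  c2 <- 1 - beta2^state$t
  upd <- tree_map2(state$m, state$v, function(m, v) {
    lr * (m / c1) / (sqrt(v / c2) + eps)
  })
  params <- tree_map2(params, upd, `-`)
  list(params = params, state = state)
}

sgdm_init <- function(params) list(vel = tree_zeros_like(params))

sgdm_step <- function(params, grads, state, lr = 1e-3,
                      momentum = 0.9, weight_decay = 5e-4) {
  g <- tree_map2(grads, params, function(gr, p) gr + weight_decay * p)
  state$vel <- tree_map2(state$vel, g, function(v, gr) momentum * v + gr)
  params <- tree_map2(params, state$vel, function(p, v) p - lr * v)
  list(params = params, state = state)
}
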