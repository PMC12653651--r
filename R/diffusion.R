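# Feature-space diffusion filtering: forward Gaussian noising of feature
# maps, a transformer-based reverse reconstruction network (mean and scale
# branches), the covariance structural distance, pair filtering, and the
# joint pretraining objective.

#' Diffusion schedule
#'
#' A sequence of per-step coefficients `alpha_1..alpha_T` in `(0, 1]`,
#' non-increasing; the forward process draws
#' `e_t ~ N(alpha_t * e_0, (1 - alpha_t) I)` elementwise. The
#' `"sqrt_cumulative"` convention instead uses `sqrt(prod(alpha_1..t))` as
#' the mean coefficient and `1 - prod(alpha_1..t)` as the variance, the
#' standard denoising-diffusion parameterization.
#'
#' @param T_steps number of timesteps (default 10).
#' @param alpha_start,alpha_end endpoints of a linear schedule
#'   (defaults 0.95 down to 0.8: the terminal state keeps enough signal for
#'   the covariance comparison to stay informative on small feature grids).
#' @param convention `"as_printed"` (default) or `"sqrt_cumulative"`.
#' @export
diffusion_schedule <- function(T_steps = 10L, alpha_start = 0.95, alpha_end = 0.8,
                               convention = c("as_printed", "sqrt_cumulative")) {
  convention <- match.arg(convention)
  alpha <- seq(alpha_start, alpha_end, length.out = T_steps)
  stopifnot(all(alpha > 0), all(alpha <= 1), all(diff(alpha) <= 1e-12))
  structure(list(T_steps = as.integer(T_steps), alpha = alpha,
                 convention = convention),
            class = "diffusion_schedule")
}

diffuse_coefs <- function(schedule, t) {
  if (t < 1 || t > schedule$T_steps) stop("timestep out of range", call. = FALSE)
  if (schedule$convention == "as_printed") {
    a <- schedule$alpha[t]
    list(mean = a, sd = sqrt(1 - a))
  } else {
    ab <- prod(schedule$alpha[seq_len(t)])
    list(mean = sqrt(ab), sd = sqrt(1 - ab))
  }
}

#' Forward diffusion of a feature map
#'
#' Samples `e_t ~ N(alpha_t e_0, (1 - alpha_t) I)` elementwise; with
#' `alpha_t = 1` the output equals `e_0` exactly.
#'
#' @param e_0 feature map (array or matrix).
#' @param schedule a [diffusion_schedule()].
#' @param t timestep in `1..T`.
#' @param rng a [new_rng()] stream.
#' @export
forward_diffuse <- function(e_0, schedule, t, rng) {
  cf <- diffuse_coefs(schedule, t)
  eps <- array(rng_norm(rng, length(e_0)), dim(e_0) %||% length(e_0))
  cf$mean * e_0 + cf$sd * eps
}

# full trajectory e_0..e_T, each e_t drawn from its marginal
forward_trajectory <- function(e_0, schedule, rng) {
  traj <- vector("list", schedule$T_steps + 1L)
  traj[[1]] <- e_0
  for (t in seq_len(schedule$T_steps)) {
    traj[[t + 1L]] <- forward_diffuse(e_0, schedule, t, rng)
  }
  traj
}

#' Reconstruction network
#'
#' A conditional variational decoder over the spatial feature grid:
#' learned positional and timestep embeddings, `n_layers` pre-norm
#' transformer blocks (multi-head self-attention + feed-forward), and two
#' output branches: the mean `mu(e_t, t)`, parameterized residually around
#' the input, and a strictly positive scale `eta(e_t, t)` via softplus.
#'
#' @param n_tokens number of spatial positions H*W.
#' @param width channel width C.
#' @param T_steps number of timesteps conditioned on.
#' @param n_layers transformer depth (default 4).
#' @param n_heads attention heads (default 8).
#' @param ffn_hidden feed-forward hidden width (default 512).
#' @param rng a [new_rng()] stream.
#' @export
recon_net_init <- function(n_tokens, width, T_steps, n_layers = 4L,
                           n_heads = 8L, ffn_hidden = 512L, rng) {
  layers <- lapply(seq_len(n_layers), function(i) {
    list(ln1 = ln_init(width), mha = mha_init(width, n_heads, rng),
         ln2 = ln_init(width),
         W1 = affine_init(width, ffn_hidden, rng),
         W2 = affine_init(ffn_hidden, width, rng, scale = 0.05))
  })
  params <- list(
    pos = matrix(rng_norm(rng, n_tokens * width, 0, 0.02), n_tokens, width),
    temb = matrix(rng_norm(rng, T_steps * width, 0, 0.02), T_steps, width),
    layers = layers,
    mu = affine_init(width, width, rng, scale = 0.01),
    eta = affine_init(width, width, rng, scale = 0.01)
  )
  structure(list(params = params, n_tokens = as.integer(n_tokens),
                 width = as.integer(width), T_steps = as.integer(T_steps),
                 n_layers = as.integer(n_layers), n_heads = as.integer(n_heads),
                 ffn_hidden = as.integer(ffn_hidden)),
            class = "recon_net")
}

fm_as_tokens <- function(e) {
  if (is.matrix(e)) return(e)
  matrix(e, prod(dim(e)[1:2]), dim(e)[3])
}

tokens_as_fm <- function(m, hw) array(m, c(hw, hw, ncol(m)))

# batched forward through the transformer trunk; X: (B*n_tokens) x C
recon_trunk_fwd <- function(net, X, t, B, keep_cache = FALSE) {
  p <- net$params
  n <- net$n_tokens
  emb <- p$pos + matrix(p$temb[t, ], n, net$width, byrow = TRUE)
  x <- X + emb[rep(seq_len(n), B), , drop = FALSE]
  caches <- vector("list", net$n_layers)
  for (li in seq_len(net$n_layers)) {
    lp <- p$layers[[li]]
    l1 <- ln_fwd(lp$ln1, x)
    at <- mha_fwd(lp$mha, l1$out, l1$out, net$n_heads, B, n, n)
    x1 <- x + at$out
    l2 <- ln_fwd(lp$ln2, x1)
    f1 <- affine_fwd(lp$W1, l2$out)
    a1 <- relu(f1)
    f2 <- affine_fwd(lp$W2, a1)
    x2 <- x1 + f2
    caches[[li]] <- if (keep_cache) list(xin = x, l1 = l1, at = at, x1 = x1,
                                         l2 = l2, f1 = f1, a1 = a1) else NULL
    x <- x2
  }
  list(out = x, caches = caches)
}

recon_trunk_bwd <- function(net, caches, dout) {
  p <- net$params
  dlayers <- vector("list", net$n_layers)
  dx <- dout
  for (li in rev(seq_len(net$n_layers))) {
    lp <- p$layers[[li]]
    ca <- caches[[li]]
    # ffn branch
    da1 <- dx %*% t(lp$W2$W)
    gW2 <- list(W = crossprod(ca$a1, dx), b = colSums(dx))
    df1 <- relu_bwd(ca$f1, da1)
    gW1 <- list(W = crossprod(ca$l2$out, df1), b = colSums(df1))
    dl2out <- df1 %*% t(lp$W1$W)
    bl2 <- ln_bwd(lp$ln2, ca$l2$cache, dl2out)
    dx1 <- dx + bl2$dx
    # attention branch
    bat <- mha_bwd(lp$mha, ca$at$cache, dx1)
    dl1out <- bat$dxq + bat$dxkv
    bl1 <- ln_bwd(lp$ln1, ca$l1$cache, dl1out)
    dx <- dx1 + bl1$dx
    dlayers[[li]] <- list(ln1 = bl1$grads, mha = bat$grads, ln2 = bl2$grads,
                          W1 = gW1, W2 = gW2)
  }
  list(dX = dx, dlayers = dlayers)
}

#' One reverse (denoising) step
#'
#' @param e_t noisy feature map at timestep `t`.
#' @param t timestep.
#' @param net a [recon_net_init()] network.
#' @return list with the mean branch `mu` and strictly positive scale
#'   branch `eta`, both feature-map shaped.
#' @export
reverse_step <- function(e_t, t, net) {
  if (t < 1 || t > net$T_steps) stop("timestep out of range", call. = FALSE)
  X <- fm_as_tokens(e_t)
  if (nrow(X) != net$n_tokens || ncol(X) != net$width) {
    stop("feature map shape does not match the network", call. = FALSE)
  }
  tr <- recon_trunk_fwd(net, X, t, B = 1L)
  mu <- X + affine_fwd(net$params$mu, tr$out)
  eta <- softplus(affine_fwd(net$params$eta, tr$out)) + 1e-4
  shape <- dim(e_t)
  if (length(shape) == 3L) {
    mu <- array(mu, shape); eta <- array(eta, shape)
  }
  list(mu = mu, eta = eta)
}

#' Reverse reconstruction from the terminal noisy state
#'
#' Iterates the mean path `e_{t-1} <- mu(e_t, t)` from `t = T` down to 1.
#'
#' @param e_T terminal noisy feature map.
#' @param schedule a [diffusion_schedule()].
#' @param net a [recon_net_init()] network.
#' @return the reconstructed feature map (same shape as `e_T`).
#' @export
reconstruct <- function(e_T, schedule, net) {
  x <- e_T
  for (t in rev(seq_len(schedule$T_steps))) {
    x <- reverse_step(x, t, net)$mu
  }
  x
}

# batched reconstruction of a list of maps (inference, mean path)
reconstruct_batch <- function(fmaps, schedule, net) {
  B <- length(fmaps)
  shape <- dim(fmaps[[1]])
  X <- do.call(rbind, lapply(fmaps, fm_as_tokens))
  for (t in rev(seq_len(schedule$T_steps))) {
    tr <- recon_trunk_fwd(net, X, t, B = B)
    X <- X + affine_fwd(net$params$mu, tr$out)
  }
  lapply(seq_len(B), function(b) {
    rows <- ((b - 1) * net$n_tokens + 1):(b * net$n_tokens)
    array(X[rows, ], shape)
  })
}

#' Variational reconstruction loss along a trajectory
#'
#' `sum_t || e_{t-1} - mu(e_t, t) ||^2` (squared Frobenius norm over the
#' grid), for a trajectory `e_0..e_T` generated under one schedule.
#'
#' @param e_trajectory list of `T + 1` feature maps `e_0..e_T`.
#' @param net a [recon_net_init()] network.
#' @export
diffusion_loss <- function(e_trajectory, net) {
  T_steps <- length(e_trajectory) - 1L
  if (T_steps != net$T_steps) stop("trajectory length does not match schedule", call. = FALSE)
  loss <- 0
  for (t in seq_len(T_steps)) {
    mu <- reverse_step(e_trajectory[[t + 1L]], t, net)$mu
    loss <- loss + sum((e_trajectory[[t]] - mu)^2)
  }
  loss
}

# Training pass: batched over maps and summed over timesteps.  Returns the
# mean-per-map loss, parameter gradients, and (unless stopped) the
# gradient wrt each e_0 (reparameterized through every e_t draw).
# `n_t_sample` draws a random subset of timesteps and rescales by
# T / n_t_sample, an unbiased estimate of the full sum.
diffusion_loss_grad <- function(e0_list, schedule, net, rng,
                                stop_gradient = FALSE, n_t_sample = NULL) {
  B <- length(e0_list)
  n <- net$n_tokens
  Ts <- schedule$T_steps
  E0 <- do.call(rbind, lapply(e0_list, fm_as_tokens))     # (B*n) x C
  coefs <- lapply(seq_len(Ts), diffuse_coefs, schedule = schedule)
  t_used <- seq_len(Ts)
  w_t <- 1
  if (!is.null(n_t_sample) && n_t_sample < Ts) {
    t_used <- sort(rng_sample(rng, seq_len(Ts), n_t_sample))
    w_t <- Ts / n_t_sample
  }
  s_needed <- sort(unique(c(t_used, t_used - 1L)))
  s_needed <- s_needed[s_needed >= 1L]
  Es <- vector("list", Ts + 1L)   # token matrices for e_0..e_T
  Es[[1]] <- E0
  for (s in s_needed) {
    eps <- matrix(rng_norm(rng, length(E0)), nrow(E0), ncol(E0))
    Es[[s + 1L]] <- coefs[[s]]$mean * E0 + coefs[[s]]$sd * eps
  }
  loss <- 0
  grads <- NULL
  dEs <- vector("list", Ts + 1L)  # dL/de_s
  for (t in t_used) {
    tr <- recon_trunk_fwd(net, Es[[t + 1L]], t, B = B, keep_cache = TRUE)
    mu <- Es[[t + 1L]] + affine_fwd(net$params$mu, tr$out)
    resid <- Es[[t]] - mu
    loss <- loss + w_t * sum(resid^2)
    dmu <- -2 * w_t * resid
    gmu <- list(W = crossprod(tr$out, dmu), b = colSums(dmu))
    dtrunk <- dmu %*% t(net$params$mu$W)
    bt <- recon_trunk_bwd(net, tr$caches, dtrunk)
    # embedding gradients: sum over batch blocks of the input grad
    demb <- bt$dX
    demb_tok <- rowsum(demb, rep(seq_len(n), B))
    dtemb <- matrix(0, Ts, net$width)
    dtemb[t, ] <- colSums(demb)
    g_t <- list(pos = demb_tok, temb = dtemb, layers = bt$dlayers,
                mu = gmu,
                eta = list(W = net$params$eta$W * 0, b = net$params$eta$b * 0))
    grads <- if (is.null(grads)) g_t else tree_add(grads, g_t)
    if (!stop_gradient) {
      dEs[[t]] <- (dEs[[t]] %||% 0) + 2 * w_t * resid
      dEs[[t + 1L]] <- (dEs[[t + 1L]] %||% 0) + dmu + bt$dX
    }
  }
  dE0 <- NULL
  if (!stop_gradient) {
    dE0 <- matrix(0, nrow(E0), ncol(E0))
    for (s in seq_len(Ts + 1L)) {
      if (is.null(dEs[[s]])) next
      a <- if (s == 1L) 1 else coefs[[s - 1L]]$mean
      dE0 <- dE0 + a * dEs[[s]]
    }
  }
  list(loss = loss / B, grads = tree_map(grads, function(g) g / B),
       dE0 = if (is.null(dE0)) NULL else dE0 / B)
}

#' Covariance of a spatial feature map
#'
#' Treats the `H*W` spatial positions as observations of a C-dimensional
#' variable: `Sigma = X_c' X_c / (H*W)` after subtracting the spatial mean.
#'
#' @param e feature map (`H x W x C` array or `(H*W) x C` matrix with
#'   at least 2 rows).
#' @return symmetric positive semi-definite `C x C` matrix.
#' @export
feature_covariance <- function(e) {
  X <- fm_as_tokens(e)
  if (nrow(X) < 2) stop("feature map needs at least 2 spatial positions", call. = FALSE)
  Xc <- sweep(X, 2, colMeans(X))
  crossprod(Xc) / nrow(X)
}

#' Structural distance between covariance matrices
#'
#' `D = 1 - Tr(S1 S2) / (||S1||_F ||S2||_F)`; symmetric, zero for equal
#' symmetric matrices, and in `[0, 1]` for positive semi-definite inputs.
#'
#' @param S1,S2 nonzero symmetric matrices.
#' @export
structural_distance <- function(S1, S2) {
  n1 <- sqrt(sum(S1^2)); n2 <- sqrt(sum(S2^2))
  if (n1 == 0 || n2 == 0) stop("structural distance undefined for zero matrix", call. = FALSE)
  1 - sum(S1 * t(S2)) / (n1 * n2)
}

#' Filter configuration
#'
#' @param delta fixed retention threshold on the structural distance.
#' @param lambda joint-loss weight on the diffusion term (default 0.5).
#' @param delta_mode `"batch-quantile"` (default; `delta` is recomputed as
#'   the `delta_quantile` of the current batch's distances) or `"fixed"`.
#' @param delta_quantile retention quantile (default 0.8: retain ~80%).
#' @export
filter_config <- function(delta = 0.5, lambda = 0.5,
                          delta_mode = c("batch-quantile", "fixed"),
                          delta_quantile = 0.8) {
  delta_mode <- match.arg(delta_mode)
  stopifnot(delta >= 0, lambda >= 0, delta_quantile > 0, delta_quantile < 1)
  structure(list(delta = delta, lambda = lambda, delta_mode = delta_mode,
                 delta_quantile = delta_quantile),
            class = "filter_config")
}

#' Keep-or-discard decision for a reconstructed pair
#'
#' Computes the structural distance between the covariance matrices of the
#' two reconstructed feature maps and retains the pair when it falls below
#' the threshold.
#'
#' @param e1,e2 reconstructed feature maps of the two views.
#' @param config a [filter_config()] (fixed-threshold mode).
#' @return list with `keep` (logical) and `distance`.
#' @export
filter_pair <- function(e1, e2, config) {
  d <- structural_distance(feature_covariance(e1), feature_covariance(e2))
  list(keep = d < config$delta, distance = d)
}

# batch decision; in batch-quantile mode the threshold is the configured
# quantile of the batch's distances
filter_batch <- function(distances, config) {
  delta <- if (config$delta_mode == "batch-quantile") {
    as.numeric(stats::quantile(distances, config$delta_quantile, type = 7))
  } else {
    config$delta
  }
  list(keep = distances < delta, delta = delta)
}

#' Joint pretraining loss
#'
#' `L_contrast + lambda * L_diff`.
#'
#' @param L_contrast,L_diff finite loss values.
#' @param lambda balancing coefficient (default 0.5).
#' @export
joint_pretrain_loss <- function(L_contrast, L_diff, lambda = 0.5) {
  stopifnot(is.finite(L_contrast), is.finite(L_diff))
  L_contrast + lambda * L_diff
}
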