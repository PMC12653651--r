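# Orchestration: joint contrastive + diffusion pretraining with pair
# filtering, k-shot fine-tuning, evaluation, checkpoints and YAML configs.

#' Run configuration
#'
#' Bundles every stage's settings. The `"paper"` profile follows the
#' published training protocol (512 px inputs, ResNet-family backbone,
#' 16x16x128 feature grid, 4-layer/8-head reconstruction net, queue 4096,
#' Adam lr 1e-4, batch 32, 100 epochs). The `"test"` profile is the
#' desk-scale variant used throughout the test-suite: 64 px inputs, small
#' backbone, 8x8x32 grid, 2-layer/4-head reconstruction net, queue 256.
#'
#' @param profile `"test"` or `"paper"`.
#' @param epochs pretraining epochs.
#' @param batch_size minibatch size (default 32).
#' @param lr pretraining learning rate (default 1e-4, Adam).
#' @param seed master seed; all streams derive from it.
#' @param tau,m,K InfoNCE temperature, EMA momentum, queue capacity.
#' @param T_steps,alpha_start,alpha_end,schedule_convention diffusion schedule.
#' @param lambda joint-loss weight on the diffusion term.
#' @param delta_mode,delta,delta_quantile filter threshold settings.
#' @param stop_gradient block the diffusion gradient from reaching the
#'   encoder through `e_0` (default `FALSE`: the modules are co-trained).
#' @param corrupt_fraction fraction of pairs whose second view is
#'   deliberately destroyed (heavy occlusion + noise); used by the filter
#'   ablation protocol, 0 in normal training.
#' @param use_filter gate the InfoNCE contribution by the diffusion filter
#'   (default TRUE).
#' @param augmentation an [augmentation_params()]; defaults to the paper
#'   settings at the profile's input size.
#' @export
run_config <- function(profile = c("test", "paper"), epochs = 10L,
                       batch_size = 32L, lr = 1e-4, seed = 1L,
                       tau = 0.2, m = 0.999, K = NULL,
                       T_steps = 10L, alpha_start = 0.95, alpha_end = 0.8,
                       schedule_convention = "as_printed", lambda = 0.5,
                       delta_mode = "batch-quantile", delta = 0.5,
                       delta_quantile = 0.8, stop_gradient = FALSE,
                       corrupt_fraction = 0, use_filter = TRUE,
                       augmentation = NULL) {
  profile <- match.arg(profile)
  enc <- encoder_config(profile)
  K <- K %||% if (profile == "test") 256L else 4096L
  recon <- if (profile == "test") {
    list(n_layers = 2L, n_heads = 2L, ffn_hidden = 64L, t_subsample = 2L)
  } else {
    list(n_layers = 4L, n_heads = 8L, ffn_hidden = 512L, t_subsample = NULL)
  }
  augmentation <- augmentation %||% augmentation_params(target_size = enc$input_size)
  structure(list(
    profile = profile, encoder = enc,
    contrastive = contrastive_config(tau = tau, m = m, K = K, d = enc$embed_dim),
    schedule = diffusion_schedule(T_steps, alpha_start, alpha_end,
                                  schedule_convention),
    recon = recon,
    filter = filter_config(delta = delta, lambda = lambda,
                           delta_mode = delta_mode,
                           delta_quantile = delta_quantile),
    augmentation = augmentation,
    epochs = as.integer(epochs), batch_size = as.integer(batch_size),
    lr = lr, seed = as.integer(seed), stop_gradient = stop_gradient,
    corrupt_fraction = corrupt_fraction, use_filter = use_filter
  ), class = "run_config")
}

load_split_samples <- function(manifest, split, samples = NULL) {
  rows <- which(manifest$split == split)
  if (length(rows) == 0) stop("no samples in split '", split, "'", call. = FALSE)
  if (is.null(samples)) {
    lapply(rows, function(i) {
      px <- read_image_file(manifest$path[i])
      image_sample(px, label = manifest$label[i], source_id = manifest$source_id[i])
    })
  } else {
    idx <- match(manifest$source_id[rows], vapply(samples, `[[`, "", "source_id"))
    if (anyNA(idx)) stop("samples do not cover the manifest", call. = FALSE)
    samples[idx]
  }
}

# destroy a view: heavy occlusion over ~60% of the area plus strong noise
corrupt_view <- function(img, rng) {
  px <- img$pixels
  H <- dim(px)[1]; W <- dim(px)[2]
  h <- round(H * 0.78); w <- round(W * 0.78)
  r0 <- rng_int(rng, 1, 0, H - h)
  c0 <- rng_int(rng, 1, 0, W - w)
  noise <- array(rng_unif(rng, h * w * 3, 0, 255), c(h, w, 3))
  px[r0 + seq_len(h), c0 + seq_len(w), ] <- noise
  image_sample(px, label = img$label, source_id = img$source_id)
}

#' Self-supervised pretraining with diffusion-filtered contrastive pairs
#'
#' Per step: view pairs are built by the augmentation pipeline; the primary
#' encoder embeds view 1 and the momentum encoder view 2; both views'
#' feature maps are noised and reconstructed by the diffusion net, whose
#' covariance structural distance gates each pair's InfoNCE contribution;
#' the joint objective `L_contrast + lambda * L_diff` is optimized with
#' Adam; the momentum embeddings are queued and the EMA update applied.
#'
#' @param config a [run_config()].
#' @param manifest a split manifest with a non-empty `train` split.
#' @param samples optional pre-loaded list of [image_sample()]s matching
#'   the manifest (skips disk reads).
#' @param verbose print per-epoch losses.
#' @return a checkpoint list (encoder, momentum encoder, queue,
#'   reconstruction net, schedule, config, logs, filter log).
#' @export
pretrain <- function(config, manifest, samples = NULL, verbose = FALSE) {
  train <- load_split_samples(manifest, "train", samples)
  seeds <- rng_spawn_seeds(new_rng(config$seed), 5)
  rng_init <- new_rng(seeds[1]); rng_aug <- new_rng(seeds[2])
  rng_diff <- new_rng(seeds[3]); rng_shuf <- new_rng(seeds[4])
  rng_queue <- new_rng(seeds[5])
  enc_cfg <- config$encoder
  enc <- encoder_init(enc_cfg, rng_init)
  mom <- momentum_encoder_init(enc, m = config$contrastive$m)
  queue <- negative_queue(config$contrastive$K, enc_cfg$embed_dim,
                          prefill_rng = rng_queue)
  net <- recon_net_init(enc_cfg$feat_hw^2, enc_cfg$feat_c,
                        config$schedule$T_steps,
                        n_layers = config$recon$n_layers,
                        n_heads = config$recon$n_heads,
                        ffn_hidden = config$recon$ffn_hidden, rng = rng_init)
  opt_params <- list(enc = enc$params, net = net$params)
  opt <- adam_init(opt_params)
  step <- 0L
  epoch_log <- data.frame(epoch = integer(), loss_contrast = numeric(),
                          loss_diff = numeric(), loss_joint = numeric(),
                          retention = numeric())
  filter_log <- list()
  n <- length(train)
  for (ep in seq_len(config$epochs)) {
    ord <- rng_sample(rng_shuf, seq_len(n))
    sums <- c(lc = 0, ld = 0, lj = 0, ret = 0, nb = 0)
    for (b0 in seq(1, n, by = config$batch_size)) {
      idx <- ord[b0:min(b0 + config$batch_size - 1, n)]
      if (length(idx) < 2) next
      B <- length(idx)
      pairs <- lapply(train[idx], make_view_pair, params = config$augmentation,
                      rng = rng_aug)
      corrupted <- rep(FALSE, B)
      if (config$corrupt_fraction > 0) {
        corrupted <- rng_unif(rng_aug, B) < config$corrupt_fraction
        for (i in which(corrupted)) {
          pairs[[i]]$x_j <- corrupt_view(pairs[[i]]$x_j, rng_aug)
        }
      }
      # primary branch with caches; momentum branch inference-only
      fwd <- lapply(pairs, function(pr) {
        bb <- backbone_fwd(enc$params, enc_cfg, pr$x_i$pixels / 255,
                           keep_cache = TRUE)
        pj <- project_fwd(enc$params, enc_cfg, bb$grid, keep_cache = TRUE)
        fm <- feature_map_fwd(enc$params, enc_cfg, bb$grid, keep_cache = TRUE)
        list(bb = bb, pj = pj, fm = fm)
      })
      Zi <- do.call(rbind, lapply(fwd, function(f) f$pj$z))
      mom_out <- lapply(pairs, function(pr) {
        bb <- backbone_fwd(mom$params, enc_cfg, pr$x_j$pixels / 255)
        list(z = project_fwd(mom$params, enc_cfg, bb$grid)$z,
             fm = feature_map_fwd(mom$params, enc_cfg, bb$grid)$fmap)
      })
      Zj <- do.call(rbind, lapply(mom_out, function(f) f$z))
      # diffusion filter on reconstructed maps of both views
      e_i <- lapply(fwd, function(f) f$fm$fmap)
      e_j <- lapply(mom_out, function(f) f$fm)
      noisy <- lapply(c(e_i, e_j), function(e) {
        forward_diffuse(e, config$schedule, config$schedule$T_steps, rng_diff)
      })
      rec <- reconstruct_batch(noisy, config$schedule, net)
      dist <- vapply(seq_len(B), function(i) {
        structural_distance(feature_covariance(rec[[i]]),
                            feature_covariance(rec[[B + i]]))
      }, numeric(1))
      fb <- filter_batch(dist, config$filter)
      keep <- if (config$use_filter) fb$keep else rep(TRUE, B)
      nce <- info_nce_batch(Zi, Zj, queue$buffer, config$contrastive$tau,
                            weights = as.numeric(keep))
      dl <- diffusion_loss_grad(e_i, config$schedule, net, rng_diff,
                                stop_gradient = config$stop_gradient,
                                n_t_sample = config$recon$t_subsample)
      loss_joint <- joint_pretrain_loss(nce$loss, dl$loss, config$filter$lambda)
      if (!is.finite(loss_joint)) {
        stop("non-finite joint loss at step ", step + 1,
             " (contrast = ", nce$loss, ", diff = ", dl$loss, ")", call. = FALSE)
      }
      # encoder gradients: InfoNCE through the projection, diffusion
      # through the feature adapter (unless stopped)
      n_tok <- enc_cfg$feat_hw^2
      enc_grads <- NULL
      for (i in seq_len(B)) {
        f <- fwd[[i]]
        pb <- project_bwd(enc$params, enc_cfg, f$pj$cache, nce$dZi[i, ])
        dgrid <- pb$dgrid
        g <- list(stages = NULL)
        if (!is.null(dl$dE0)) {
          rows <- ((i - 1) * n_tok + 1):(i * n_tok)
          dfmap <- array(config$filter$lambda * dl$dE0[rows, ],
                         dim(f$fm$fmap))
          fmb <- feature_map_bwd(enc$params, enc_cfg, f$fm$cache, dfmap)
          dgrid <- dgrid + fmb$dgrid
          g_feat <- fmb$grads$feat
        } else {
          g_feat <- tree_zeros_like(enc$params$feat)
        }
        bb <- backbone_bwd(enc$params, enc_cfg, f$bb$caches, dgrid)
        g$stages <- bb$grads$stages
        if (!is.null(enc$params$adapter)) g$adapter <- pb$grads$adapter
        g$fc1 <- pb$grads$fc1
        g$fc2 <- pb$grads$fc2
        g$feat <- g_feat
        enc_grads <- if (is.null(enc_grads)) g else tree_add(enc_grads, g)
      }
      grads <- list(enc = enc_grads, net = dl$grads)
      st <- adam_step(list(enc = enc$params, net = net$params), grads, opt,
                      lr = config$lr)
      enc$params <- st$params$enc
      net$params <- st$params$net
      opt <- st$state
      queue <- queue_push(queue, Zj)
      mom <- ema_update(mom, enc)
      step <- step + 1L
      filter_log[[length(filter_log) + 1L]] <- data.frame(
        step = step, pair_id = vapply(pairs, `[[`, "", "source_id"),
        distance = dist, kept = keep, corrupted = corrupted)
      sums <- sums + c(nce$loss, dl$loss, loss_joint, mean(keep), 1)
    }
    epoch_log <- rbind(epoch_log, data.frame(
      epoch = ep, loss_contrast = sums[1] / sums[5],
      loss_diff = sums[2] / sums[5], loss_joint = sums[3] / sums[5],
      retention = sums[4] / sums[5]))
    if (verbose) {
      message(sprintf("epoch %d: contrast %.4f diff %.4f joint %.4f keep %.2f",
                      ep, sums[1] / sums[5], sums[2] / sums[5],
                      sums[3] / sums[5], sums[4] / sums[5]))
    }
  }
  list(encoder = enc, momentum = mom, queue = queue, recon = net,
       schedule = config$schedule, config = config, step = step,
       epoch_log = epoch_log, filter_log = do.call(rbind, filter_log))
}

#' Save / load a training checkpoint
#'
#' A single uncompressed serialized bundle; saving the same checkpoint
#' twice produces identical bytes.
#'
#' @param checkpoint a checkpoint list from [pretrain()].
#' @param path file path.
#' @export
save_checkpoint <- function(checkpoint, path) {
  saveRDS(checkpoint, path, compress = FALSE)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path)) stop("checkpoint not found: ", path, call. = FALSE)
  readRDS(path)
}

# preprocessing used consistently at fine-tuning and inference
make_preprocess <- function(config) {
  force(config)
  function(img) {
    out <- standardize_image(img, config$encoder$input_size)
    if (config$augmentation$color_normalize) {
      out <- gray_world_balance(equalize_luminance(out))
    }
    out
  }
}

#' Select a k-shot subset of a split
#'
#' @param manifest a split manifest.
#' @param k samples per class.
#' @param n_classes number of classes.
#' @param seed selection seed.
#' @param split which split to draw from (default `"train"`).
#' @return row indices into the manifest.
#' @export
kshot_indices <- function(manifest, k, n_classes, seed = 1L, split = "train") {
  rng <- new_rng(seed)
  unlist(lapply(seq_len(n_classes) - 1L, function(cls) {
    rows <- which(manifest$split == split & manifest$label == cls)
    if (length(rows) < k) {
      stop("class ", cls, " has fewer than k = ", k, " ", split, " samples",
           call. = FALSE)
    }
    rows[rng_sample(rng, seq_along(rows))][seq_len(k)]
  }))
}

#' k-shot fine-tuning on top of a pretraining checkpoint
#'
#' @param checkpoint a [pretrain()] checkpoint.
#' @param manifest split manifest.
#' @param k shots per class.
#' @param n_classes number of classes.
#' @param samples optional preloaded samples matching the manifest.
#' @param seed selection + head-initialization seed.
#' @param epochs fine-tuning epochs.
#' @param use_val early-stop on the manifest's `val` split.
#' @param prune_to optionally prune the attention heads down to this count
#'   after training (importance calibrated on the k-shot set).
#' @return a `cropclr_model` ready for [predict_probs()] / [evaluate_model()].
#' @export
finetune_pipeline <- function(checkpoint, manifest, k, n_classes,
                              samples = NULL, seed = 1L, epochs = 120L,
                              use_val = FALSE, prune_to = NULL) {
  idx <- kshot_indices(manifest, k, n_classes, seed = seed)
  all_train <- load_split_samples(manifest, "train", samples)
  train_ids <- manifest$source_id[manifest$split == "train"]
  kshot <- all_train[match(manifest$source_id[idx], train_ids)]
  val <- NULL
  if (use_val && any(manifest$split == "val")) {
    val <- load_split_samples(manifest, "val", samples)
  }
  pre <- make_preprocess(checkpoint$config)
  ft <- finetune(checkpoint$encoder, kshot, k = k, n_classes = n_classes,
                 epochs = epochs, val_samples = val, seed = seed,
                 preprocess = pre)
  head_mask <- NULL
  if (!is.null(prune_to)) {
    feats <- lapply(kshot, function(s) encode_feature_map(pre(s), checkpoint$encoder))
    imp <- head_importance(ft$head, feats)
    head_mask <- prune_heads(imp, prune_to)
  }
  structure(list(encoder = checkpoint$encoder, head = ft$head,
                 head_mask = head_mask, n_classes = n_classes,
                 preprocess = pre, history = ft$history,
                 backbone_checksum = ft$backbone_checksum),
            class = "cropclr_model")
}

#' @export
predict_probs.cropclr_model <- function(model, img) {
  fm <- encode_feature_map(model$preprocess(img), model$encoder)
  finetune_forward(fm, model$head, head_mask = model$head_mask)$yhat
}

#' Evaluate a model on a manifest split
#'
#' Single-label decoding: predicted class = argmax of the sigmoid scores.
#'
#' @param model a `cropclr_model` (or any [predict_probs()] object).
#' @param manifest split manifest.
#' @param split split name (default `"test"`).
#' @param samples optional preloaded samples.
#' @param n_classes number of classes (inferred from the manifest when NULL).
#' @return list with `accuracy`, `macro_precision`, `macro_recall`,
#'   `per_class` data.frame, the `confusion` matrix (true x predicted) and `n`.
#' @export
evaluate_model <- function(model, manifest, split = "test", samples = NULL,
                           n_classes = NULL) {
  eval_samples <- load_split_samples(manifest, split, samples)
  labs <- vapply(eval_samples, function(s) as.integer(s$label), integer(1))
  n_classes <- n_classes %||% (max(labs) + 1L)
  if (any(labs < 0 | labs >= n_classes)) stop("unknown label in manifest", call. = FALSE)
  preds <- vapply(eval_samples, function(s) {
    which.max(predict_probs(model, s)) - 1L
  }, integer(1))
  confusion <- matrix(0L, n_classes, n_classes,
                      dimnames = list(true = 0:(n_classes - 1),
                                      pred = 0:(n_classes - 1)))
  for (i in seq_along(labs)) {
    confusion[labs[i] + 1L, preds[i] + 1L] <- confusion[labs[i] + 1L, preds[i] + 1L] + 1L
  }
  per_class <- do.call(rbind, lapply(seq_len(n_classes), function(ci) {
    TP <- confusion[ci, ci]
    FP <- sum(confusion[-ci, ci])
    FN <- sum(confusion[ci, -ci])
    data.frame(class = ci - 1L, TP = TP, FP = FP, FN = FN,
               precision = if (TP + FP > 0) TP / (TP + FP) else NA_real_,
               recall = if (TP + FN > 0) TP / (TP + FN) else NA_real_)
  }))
  list(accuracy = mean(preds == labs),
       macro_precision = mean(per_class$precision, na.rm = TRUE),
       macro_recall = mean(per_class$recall, na.rm = TRUE),
       per_class = per_class, confusion = confusion, n = length(labs))
}

#' Write / read a run configuration as YAML
#'
#' The YAML mirrors [run_config()] and [augmentation_params()]
#' field-for-field.
#'
#' @param config a [run_config()].
#' @param path YAML file path.
#' @export
write_run_config <- function(config, path) {
  flat <- list(
    profile = config$profile, epochs = config$epochs,
    batch_size = config$batch_size, lr = config$lr, seed = config$seed,
    tau = config$contrastive$tau, m = config$contrastive$m,
    K = config$contrastive$K,
    T_steps = config$schedule$T_steps,
    alpha_start = config$schedule$alpha[1],
    alpha_end = config$schedule$alpha[length(config$schedule$alpha)],
    schedule_convention = config$schedule$convention,
    lambda = config$filter$lambda, delta_mode = config$filter$delta_mode,
    delta = config$filter$delta, delta_quantile = config$filter$delta_quantile,
    stop_gradient = config$stop_gradient,
    corrupt_fraction = config$corrupt_fraction,
    use_filter = config$use_filter,
    augmentation = unclass(config$augmentation)
  )
  yaml::write_yaml(flat, path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  aug <- NULL
  if (!is.null(y$augmentation)) {
    a <- y$augmentation
    aug <- augmentation_params(
      target_size = a$target_size, rotation_range = unlist(a$rotation_range),
      flip_prob = a$flip_prob, scale_range = unlist(a$scale_range),
      sigma_range = unlist(a$sigma_range),
      cutout_fraction_range = unlist(a$cutout_fraction_range),
      cutout_fill = a$cutout_fill,
      n_cutouts_range = unlist(a$n_cutouts_range),
      color_normalize = a$color_normalize)
  }
  run_config(profile = y$profile, epochs = y$epochs, batch_size = y$batch_size,
             lr = y$lr, seed = y$seed, tau = y$tau, m = y$m, K = y$K,
             T_steps = y$T_steps, alpha_start = y$alpha_start,
             alpha_end = y$alpha_end,
             schedule_convention = y$schedule_convention, lambda = y$lambda,
             delta_mode = y$delta_mode, delta = y$delta,
             delta_quantile = y$delta_quantile, stop_gradient = y$stop_gradient,
             corrupt_fraction = y$corrupt_fraction, use_filter = y$use_filter,
             augmentation = aug)
}
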