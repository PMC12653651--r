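# Evaluation metrics: precision/recall/accuracy, mIoU, average precision,
# the BCE-Dice segmentation loss, and the prediction-consistency
# robustness protocol.

#' Precision, recall and accuracy from confusion counts
#'
#' @param c list or vector with `TP`, `FP`, `FN`, `TN`.
#' @return list `(precision, recall, accuracy)`; a zero denominator yields
#'   `NA` with a warning, never a silent zero.
#' @export
precision_recall_accuracy <- function(c) {
  TP <- c[["TP"]]; FP <- c[["FP"]]; FN <- c[["FN"]]; TN <- c[["TN"]]
  stopifnot(all(c(TP, FP, FN, TN) >= 0))
  safe <- function(num, den, what) {
    if (den == 0) {
      warning(what, " undefined: zero denominator", call. = FALSE)
      return(NA_real_)
    }
    num / den
  }
  list(precision = safe(TP, TP + FP, "precision"),
       recall = safe(TP, TP + FN, "recall"),
       accuracy = safe(TP + TN, TP + TN + FP + FN, "accuracy"))
}

#' Mean intersection over union
#'
#' Mean over classes of `TP_i / (TP_i + FP_i + FN_i)`; classes with an
#' empty denominator are excluded with a warning.
#'
#' @param per_class data.frame or matrix with columns `TP`, `FP`, `FN`.
#' @export
miou <- function(per_class) {
  per_class <- as.data.frame(per_class)
  den <- per_class$TP + per_class$FP + per_class$FN
  if (all(den == 0)) stop("all classes empty: mIoU undefined", call. = FALSE)
  if (any(den == 0)) warning("excluding ", sum(den == 0), " all-empty class(es) from mIoU",
                             call. = FALSE)
  keep <- den > 0
  mean(per_class$TP[keep] / den[keep])
}

#' Average precision from a precision-recall sequence
#'
#' All-point interpolation: precision is replaced by its monotone
#' envelope (the running maximum from the high-recall end) and integrated
#' over recall.
#'
#' @param points data.frame with columns `precision` and `recall`, ordered
#'   by decreasing score threshold (recall non-decreasing).
#' @export
average_precision <- function(points) {
  if (nrow(points) == 0) stop("empty precision-recall sequence", call. = FALSE)
  r <- c(0, points$recall)
  p <- c(points$precision[1], points$precision)
  env <- rev(cummax(rev(p)))
  sum(diff(r) * env[-1])
}

#' Mean average precision over classes
#'
#' @param points_list list of per-class precision-recall data.frames.
#' @export
mean_ap <- function(points_list) {
  mean(vapply(points_list, average_precision, numeric(1)))
}

#' BCE-Dice segmentation loss
#'
#' Mean pixelwise binary cross-entropy plus one minus the smoothed Dice
#' coefficient (`eps = 1`).
#'
#' @param pred_mask predicted probabilities in `[0, 1]`.
#' @param true_mask binary ground-truth mask, same shape.
#' @param eps Dice smoothing constant.
#' @export
bce_dice_loss <- function(pred_mask, true_mask, eps = 1) {
  if (!identical(dim(pred_mask) %||% length(pred_mask),
                 dim(true_mask) %||% length(true_mask))) {
    stop("mask shapes differ", call. = FALSE)
  }
  q <- pmin(pmax(pred_mask, 1e-7), 1 - 1e-7)
  bce <- -mean(true_mask * log(q) + (1 - true_mask) * log(1 - q))
  dice <- (2 * sum(pred_mask * true_mask) + eps) /
    (sum(pred_mask) + sum(true_mask) + eps)
  bce + (1 - dice)
}

#' Class probabilities of a model on one image
#'
#' Generic prediction interface used by [evaluate_model()] and
#' [prediction_consistency()].
#'
#' @param model a fitted model (or stub).
#' @param img an [image_sample()].
#' @return numeric probability vector over classes.
#' @export
predict_probs <- function(model, img) UseMethod("predict_probs")

#' @export
predict_probs.function <- function(model, img) model(img)

#' Default robustness perturbation suite
#'
#' Rotations of 10-50 degrees, a central occlusion covering 15% of the
#' image area, and +/-20% brightness shifts.
#'
#' @return named list of functions `image_sample -> image_sample`.
#' @export
default_perturbations <- function() {
  rots <- lapply(c(10, 20, 30, 40, 50), function(a) {
    force(a)
    function(img) {
      image_sample(pmin(pmax(warp_rotate_scale(img$pixels, a, 1), 0), 255),
                   label = img$label, source_id = img$source_id)
    }
  })
  names(rots) <- paste0("rotate", c(10, 20, 30, 40, 50))
  occl <- function(img) {
    px <- img$pixels
    H <- dim(px)[1]; W <- dim(px)[2]
    h <- round(H * sqrt(0.15)); w <- round(W * sqrt(0.15))
    r0 <- (H - h) %/% 2; c0 <- (W - w) %/% 2
    px[r0 + seq_len(h), c0 + seq_len(w), ] <- 128
    image_sample(px, label = img$label, source_id = img$source_id)
  }
  bright <- function(f) {
    force(f)
    function(img) {
      image_sample(pmin(pmax(img$pixels * f, 0), 255),
                   label = img$label, source_id = img$source_id)
    }
  }
  c(rots, list(occlude15 = occl, brighten = bright(1.2), darken = bright(0.8)))
}

#' Prediction consistency under perturbation
#'
#' For every (sample, perturbation) pair, compares the argmax label and the
#' top predicted probability of the perturbed image against the original.
#'
#' @param model object with a [predict_probs()] method.
#' @param samples non-empty list of [image_sample()]s.
#' @param perturbations list of perturbation functions; defaults to
#'   [default_perturbations()].
#' @param composite also report `consistency * (1 - confidence_variation)`.
#'   This summary has no canonical definition in the literature and is
#'   labeled `composite_noncanonical` to make that explicit; the two
#'   components are more informative separately.
#' @return list with `consistency` (fraction of unchanged argmax labels),
#'   `confidence_variation` (mean absolute change of the top probability),
#'   and `suite` (the perturbation names).
#' @export
prediction_consistency <- function(model, samples,
                                   perturbations = default_perturbations(),
                                   composite = FALSE) {
  if (length(samples) == 0) stop("empty sample set", call. = FALSE)
  same <- 0L; total <- 0L; dconf <- 0
  for (s in samples) {
    p0 <- predict_probs(model, s)
    for (pert in perturbations) {
      p1 <- predict_probs(model, pert(s))
      same <- same + (which.max(p1) == which.max(p0))
      dconf <- dconf + abs(max(p1) - max(p0))
      total <- total + 1L
    }
  }
  out <- list(consistency = same / total, confidence_variation = dconf / total,
              suite = names(perturbations))
  if (composite) {
    out$composite_noncanonical <- out$consistency * (1 - out$confidence_variation)
  }
  out
}
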