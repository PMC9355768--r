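#' Tversky-index parameters
#'
#' `alpha` weights false negatives, `beta` false positives, `gamma` is the
#' focal exponent of the Focal Tversky Loss. The defaults (0.7, 0.3, 0.75)
#' bias training against missed lesion pixels and soften the loss near
#' perfect overlap. With `alpha = beta = 0.5` the Tversky index reduces to
#' the Dice coefficient.
#'
#' @param alpha false-negative weight (>= 0).
#' @param beta false-positive weight (>= 0).
#' @param gamma focal exponent (> 0); `gamma = 1` makes the Focal Tversky
#'   Loss exactly `1 - TI`.
#' @return a `TverskyParams` list.
#' @export
tversky_params <- function(alpha = 0.7, beta = 0.3, gamma = 0.75) {
  stopifnot(alpha >= 0, beta >= 0, gamma > 0)
  structure(list(alpha = alpha, beta = beta, gamma = gamma),
            class = "TverskyParams")
}

#' Pixel confusion counts between two binary masks
#'
#' @param pred,truth binary matrices/arrays of identical shape.
#' @return a `ConfusionCounts` list with `tp`, `fp`, `fn`, `tn`.
#' @export
confusion_counts <- function(pred, truth) {
  if (!all(dim(pred) == dim(truth)))
    stop("pred and truth must have identical shape")
  stopifnot(is_binary(pred), is_binary(truth))
  tp <- sum(pred == 1 & truth == 1)
  fp <- sum(pred == 1 & truth == 0)
  fn <- sum(pred == 0 & truth == 1)
  tn <- length(pred) - tp - fp - fn
  structure(list(tp = tp, fp = fp, fn = fn, tn = tn), class = "ConfusionCounts")
}

#' Dice coefficient from confusion counts
#'
#' `2 TP / (2 TP + FP + FN)`; when both masks are empty (denominator 0) the
#' score is 1, reflecting perfect agreement on absence.
#'
#' @param counts a [confusion_counts()] result.
#' @return score in \[0, 1\].
#' @export
dice <- function(counts) {
  den <- 2 * counts$tp + counts$fp + counts$fn
  if (den == 0) return(1)
  2 * counts$tp / den
}

#' Jaccard index (IoU) from confusion counts
#'
#' `TP / (TP + FN + FP)`; empty-vs-empty convention 1. Related to Dice by
#' `D = 2J / (1 + J)`.
#'
#' @inheritParams dice
#' @return score in \[0, 1\].
#' @export
jaccard <- function(counts) {
  den <- counts$tp + counts$fn + counts$fp
  if (den == 0) return(1)
  counts$tp / den
}

#' Pixel accuracy
#' @inheritParams dice
#' @return `(TN + TP) / total`.
#' @export
accuracy <- function(counts) {
  tot <- counts$tp + counts$fp + counts$fn + counts$tn
  if (tot == 0) return(1)
  (counts$tn + counts$tp) / tot
}

#' Sensitivity (recall)
#' @inheritParams dice
#' @return `TP / (TP + FN)`; 1 when the lesion class is absent in both masks.
#' @export
sensitivity <- function(counts) {
  den <- counts$tp + counts$fn
  if (den == 0) return(1)
  counts$tp / den
}

#' Specificity
#' @inheritParams dice
#' @return `TN / (TN + FP)`; 1 when the background class is absent in both.
#' @export
specificity <- function(counts) {
  den <- counts$tn + counts$fp
  if (den == 0) return(1)
  counts$tn / den
}

soft_counts <- function(pred, truth) {
  if (!all(dim(pred) == dim(truth)))
    stop("pred and truth must have identical shape")
  list(tp = sum(pred * truth),
       fp = sum(pred * (1 - truth)),
       fn = sum((1 - pred) * truth))
}

#' Soft Tversky index
#'
#' `TP / (TP + alpha FN + beta FP)` on soft counts
#' (`TP = sum(p t)`, `FP = sum(p (1 - t))`, `FN = sum((1 - p) t)`), with a
#' smoothing constant in numerator and denominator.
#'
#' @param pred numeric array of probabilities in \[0, 1\].
#' @param truth binary array, same shape.
#' @param params a [tversky_params()].
#' @param eps smoothing constant (default 1e-6).
#' @return score in (0, 1\].
#' @export
tversky_index <- function(pred, truth, params = tversky_params(), eps = 1e-6) {
  s <- soft_counts(pred, truth)
  (s$tp + eps) / (s$tp + params$alpha * s$fn + params$beta * s$fp + eps)
}

#' Soft Dice loss
#'
#' `1 - (2 sum(p t) + eps) / (sum(p) + sum(t) + eps)`.
#'
#' @inheritParams tversky_index
#' @return loss >= 0; 0 for a perfect binary prediction.
#' @export
dice_loss <- function(pred, truth, eps = 1e-6) {
  if (!all(dim(pred) == dim(truth)))
    stop("pred and truth must have identical shape")
  1 - (2 * sum(pred * truth) + eps) / (sum(pred) + sum(truth) + eps)
}

#' Gradient of the soft Dice loss with respect to the prediction
#' @inheritParams dice_loss
#' @return array of partial derivatives, same shape as `pred`.
#' @export
dice_loss_grad <- function(pred, truth, eps = 1e-6) {
  num <- 2 * sum(pred * truth) + eps
  den <- sum(pred) + sum(truth) + eps
  -(2 * truth * den - num) / den^2
}

#' Focal Tversky loss
#'
#' `(1 - TI)^gamma` by default; `gamma = 1` recovers the plain Tversky loss
#' `1 - TI`. The alternative algebraic reading `1 - TI^gamma` is available
#' via `form = "complement_power"`.
#'
#' @inheritParams tversky_index
#' @param form `"focal"` for `(1 - TI)^gamma` (default) or
#'   `"complement_power"` for `1 - TI^gamma`.
#' @return loss in \[0, 1\].
#' @export
focal_tversky_loss <- function(pred, truth, params = tversky_params(),
                               eps = 1e-6, form = c("focal", "complement_power")) {
  form <- match.arg(form)
  if (params$gamma <= 0) stop("gamma must be > 0")
  ti <- tversky_index(pred, truth, params, eps)
  if (form == "focal") (1 - ti)^params$gamma else 1 - ti^params$gamma
}

tversky_index_grad <- function(pred, truth, params, eps = 1e-6) {
  s <- soft_counts(pred, truth)
  num <- s$tp + eps
  den <- s$tp + params$alpha * s$fn + params$beta * s$fp + eps
  dden <- truth - params$alpha * truth + params$beta * (1 - truth)
  (truth * den - num * dden) / den^2
}

#' Gradient of the Focal Tversky loss with respect to the prediction
#' @inheritParams focal_tversky_loss
#' @return array of partial derivatives, same shape as `pred`.
#' @export
focal_tversky_loss_grad <- function(pred, truth, params = tversky_params(),
                                    eps = 1e-6,
                                    form = c("focal", "complement_power")) {
  form <- match.arg(form)
  ti <- tversky_index(pred, truth, params, eps)
  dti <- tversky_index_grad(pred, truth, params, eps)
  if (form == "focal") {
    if (1 - ti <= 0) return(array(0, dim(pred)))
    -params$gamma * (1 - ti)^(params$gamma - 1) * dti
  } else {
    -params$gamma * ti^(params$gamma - 1) * dti
  }
}

#' Fused Dice + Focal Tversky training loss
#'
#' `w_dl * dice_loss + w_ftl * focal_tversky_loss`; equal unit weights by
#' default. Zero exactly when the prediction matches the truth (up to the
#' smoothing constant).
#'
#' @inheritParams focal_tversky_loss
#' @param w_dl,w_ftl non-negative weights of the two terms (default 1).
#' @return loss >= 0.
#' @export
fusion_loss <- function(pred, truth, params = tversky_params(),
                        w_dl = 1, w_ftl = 1, eps = 1e-6,
                        form = c("focal", "complement_power")) {
  stopifnot(w_dl >= 0, w_ftl >= 0)
  form <- match.arg(form)
  w_dl * dice_loss(pred, truth, eps) +
    w_ftl * focal_tversky_loss(pred, truth, params, eps, form)
}

#' Gradient of the fused loss with respect to the prediction
#' @inheritParams fusion_loss
#' @return array of partial derivatives, same shape as `pred`.
#' @export
fusion_loss_grad <- function(pred, truth, params = tversky_params(),
                             w_dl = 1, w_ftl = 1, eps = 1e-6,
                             form = c("focal", "complement_power")) {
  form <- match.arg(form)
  w_dl * dice_loss_grad(pred, truth, eps) +
    w_ftl * focal_tversky_loss_grad(pred, truth, params, eps, form)
}

#' Thresholded Jaccard score
#'
#' Challenge-style average: per-image Jaccard scores below `threshold` are
#' zeroed before averaging (ISIC 2018 scoring rule, threshold 0.65).
#'
#' @param per_image_jaccards numeric vector of per-image Jaccard scores in
#'   \[0, 1\].
#' @param threshold zeroing threshold (default 0.65).
#' @return mean thresholded score.
#' @export
thresholded_jaccard <- function(per_image_jaccards, threshold = 0.65) {
  if (length(per_image_jaccards) == 0) stop("empty score list")
  stopifnot(all(per_image_jaccards >= 0 & per_image_jaccards <= 1))
  mean(ifelse(per_image_jaccards >= threshold, per_image_jaccards, 0))
}
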