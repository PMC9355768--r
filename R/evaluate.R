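#' Evaluate predicted masks against ground truth
#'
#' Computes the standard overlap metrics per image (Dice, Jaccard,
#' accuracy, sensitivity, specificity) plus the challenge-style thresholded
#' Jaccard, and summarizes them two ways: per-image averages and pooled
#' counts (confusion counts summed over all images before computing the
#' metric).
#'
#' @param preds list of binary masks.
#' @param truths list of binary masks (same length and shapes).
#' @param tj_threshold thresholded-Jaccard cutoff (default 0.65).
#' @return list with `per_image` (data.frame, one row per mask),
#'   `mean` and `pooled` (named numeric vectors).
#' @export
evaluate_predictions <- function(preds, truths, tj_threshold = 0.65) {
  stopifnot(length(preds) == length(truths), length(preds) > 0)
  rows <- vector("list", length(preds))
  pooled <- list(tp = 0, fp = 0, fn = 0, tn = 0)
  for (i in seq_along(preds)) {
    cc <- confusion_counts(preds[[i]], truths[[i]])
    for (nm in names(pooled)) pooled[[nm]] <- pooled[[nm]] + cc[[nm]]
    rows[[i]] <- data.frame(image = i, dice = dice(cc), jaccard = jaccard(cc),
                            accuracy = accuracy(cc),
                            sensitivity = sensitivity(cc),
                            specificity = specificity(cc))
  }
  per_image <- do.call(rbind, rows)
  pooled_cc <- structure(pooled, class = "ConfusionCounts")
  ms <- colMeans(per_image[, -1])
  list(per_image = per_image,
       mean = c(dice = ms[["dice"]], jaccard = ms[["jaccard"]],
                t_jaccard = thresholded_jaccard(per_image$jaccard, tj_threshold),
                accuracy = ms[["accuracy"]], sensitivity = ms[["sensitivity"]],
                specificity = ms[["specificity"]]),
       pooled = c(dice = dice(pooled_cc), jaccard = jaccard(pooled_cc),
                  accuracy = accuracy(pooled_cc),
                  sensitivity = sensitivity(pooled_cc),
                  specificity = specificity(pooled_cc)))
}
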