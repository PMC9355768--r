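#' Prediction-fusion configuration
#'
#' Controls the post-processing that merges the two branch predictions:
#' small connected components are removed from each branch, then the final
#' mask is assembled from the most-overlapping regions of the two.
#'
#' @param min_component_size components smaller than this many pixels are
#'   dropped (default 64, sized for 512 x 512 inputs; scale down for smaller
#'   images).
#' @param strategy `"component_overlap"` (default): a connected component of
#'   one branch is retained iff at least `overlap_threshold` of its area is
#'   covered by the other branch; the fused mask is the union of retained
#'   components from both branches. `"pixel_and"`: strict pixel-wise
#'   intersection.
#' @param overlap_threshold fraction in \[0, 1\] (component_overlap only).
#' @param connectivity 4 or 8 (default 8).
#' @return a `FusionConfig` list.
#' @export
fusion_config <- function(min_component_size = 64L,
                          strategy = c("component_overlap", "pixel_and"),
                          overlap_threshold = 0.5,
                          connectivity = 8L) {
  strategy <- match.arg(strategy)
  stopifnot(min_component_size >= 0, overlap_threshold >= 0,
            overlap_threshold <= 1, connectivity %in% c(4L, 8L))
  structure(list(min_component_size = as.integer(min_component_size),
                 strategy = strategy,
                 overlap_threshold = overlap_threshold,
                 connectivity = as.integer(connectivity)),
            class = "FusionConfig")
}

#' Label connected components of a binary mask
#'
#' @param mask binary matrix.
#' @param connectivity 4 or 8.
#' @return integer matrix of labels (0 = background, 1..K = components).
#' @export
label_components <- function(mask, connectivity = 8L) {
  stopifnot(is_binary(mask), connectivity %in% c(4L, 8L))
  storage.mode(mask) <- "integer"
  cpp_label_components(mask, as.integer(connectivity))
}

#' Remove small connected components
#'
#' Every connected component with fewer than `min_size` pixels is set to 0;
#' larger components are untouched.
#'
#' @param mask binary matrix.
#' @param min_size minimum component size in pixels; 0 is the identity.
#' @param connectivity 4 or 8.
#' @return filtered binary mask.
#' @export
remove_small_components <- function(mask, min_size = 64L, connectivity = 8L) {
  stopifnot(is_binary(mask), min_size >= 0)
  if (min_size == 0 || sum(mask) == 0) return(mask)
  lab <- label_components(mask, connectivity)
  sizes <- tabulate(lab[lab > 0])
  drop <- which(sizes < min_size)
  if (length(drop) > 0) mask[lab %in% drop] <- 0
  mask
}

#' Fuse two branch predictions into a final mask
#'
#' Implements the most-overlapping-regions rule. Under
#' `"component_overlap"`, a connected component `C` of either mask is
#' retained iff `|C AND other| / |C| >= overlap_threshold`; the fused mask
#' is the union of retained components. Under `"pixel_and"` the fused mask
#' is the pixel-wise intersection. In both cases the result is a subset of
#' the union of the inputs.
#'
#' @param mask_a,mask_b binary matrices of identical shape (already
#'   small-component filtered).
#' @param cfg a [fusion_config()].
#' @return fused binary mask.
#' @export
fuse_predictions <- function(mask_a, mask_b, cfg = fusion_config()) {
  if (!all(dim(mask_a) == dim(mask_b)))
    stop("mask shapes differ: ", paste(dim(mask_a), collapse = "x"), " vs ",
         paste(dim(mask_b), collapse = "x"))
  stopifnot(is_binary(mask_a), is_binary(mask_b))
  if (cfg$strategy == "pixel_and") return(mask_a * mask_b)
  retained <- matrix(0, nrow(mask_a), ncol(mask_a))
  for (pair in list(list(mask_a, mask_b), list(mask_b, mask_a))) {
    m <- pair[[1]]; other <- pair[[2]]
    if (sum(m) == 0) next
    lab <- label_components(m, cfg$connectivity)
    k <- max(lab)
    sizes <- tabulate(lab[lab > 0], nbins = k)
    overlap <- tabulate(lab[lab > 0 & other == 1], nbins = k)
    keep <- which(overlap / sizes >= cfg$overlap_threshold & sizes > 0)
    if (length(keep) > 0) retained[lab %in% keep] <- 1
  }
  retained
}

#' Threshold, clean and fuse two probability maps
#'
#' The full post-processing pipeline applied at prediction time: each
#' probability map is thresholded into a binary mask, cleaned of small
#' connected components, and the two cleaned masks are fused.
#'
#' @param prob_a,prob_b probability matrices in \[0, 1\], identical shape.
#' @param threshold binarization threshold (default 0.5).
#' @param cfg a [fusion_config()].
#' @return final fused binary mask.
#' @export
postprocess_pipeline <- function(prob_a, prob_b, threshold = 0.5,
                                 cfg = fusion_config()) {
  if (!all(dim(prob_a) == dim(prob_b))) stop("probability map shapes differ")
  a <- remove_small_components((prob_a > threshold) * 1,
                               cfg$min_component_size, cfg$connectivity)
  b <- remove_small_components((prob_b > threshold) * 1,
                               cfg$min_component_size, cfg$connectivity)
  fuse_predictions(a, b, cfg)
}
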