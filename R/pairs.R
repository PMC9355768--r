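#' Construct an image/mask pair
#'
#' The unit of every pipeline stage: one dermoscopy image, optionally paired
#' with its binary lesion mask, under a shared identifier. Intensities are
#' stored on the 0--255 scale; masks contain only 0 (skin) and 1 (lesion).
#'
#' @param id character identifier (ISIC-style, e.g. `"ISIC_0000000"`).
#' @param image numeric H x W matrix or H x W x 3 array, values in \[0, 255\].
#' @param mask optional numeric H x W matrix with values in \{0, 1\}; `NULL`
#'   at prediction time.
#' @return an object of class `ImageMaskPair`.
#' @export
image_mask_pair <- function(id, image, mask = NULL) {
  p <- structure(list(id = as.character(id), image = image, mask = mask),
                 class = "ImageMaskPair")
  validate_pair(p)
  p
}

#' Validate an image/mask pair
#'
#' Checks the structural invariants: matching height/width between image and
#' mask and mask binarity. Called by every stage that constructs pairs.
#'
#' @param pair an `ImageMaskPair`.
#' @return the pair, invisibly; errors on violation.
#' @export
validate_pair <- function(pair) {
  stopifnot(inherits(pair, "ImageMaskPair"))
  d <- dim(pair$image)
  if (is.null(d) || !(length(d) %in% c(2L, 3L)))
    stop("pair '", pair$id, "': image must be a 2-D matrix or H x W x 3 array")
  if (length(d) == 3L && d[3] != 3L)
    stop("pair '", pair$id, "': 3-D images must have 3 channels")
  if (!is.null(pair$mask)) {
    md <- dim(pair$mask)
    if (is.null(md) || length(md) != 2L)
      stop("pair '", pair$id, "': mask must be a 2-D matrix")
    if (!all(md == d[1:2]))
      stop("pair '", pair$id, "': image is ", d[1], "x", d[2],
           " but mask is ", md[1], "x", md[2])
    if (!is_binary(pair$mask))
      stop("pair '", pair$id, "': mask contains values other than 0 and 1")
  }
  invisible(pair)
}

#' @export
print.ImageMaskPair <- function(x, ...) {
  d <- dim(x$image)
  cat("<ImageMaskPair> id:", x$id, " image:", paste(d, collapse = "x"),
      if (is.null(x$mask)) " (no mask)" else
        sprintf(" mask: %d lesion px", sum(x$mask)), "\n")
  invisible(x)
}

#' Split pairs into train and test sets
#'
#' Deterministic random partition by identifier. With 2594 pairs and a test
#' fraction of 0.2 this reproduces the 2075 train / 519 test arithmetic used
#' for the ISIC 2018 training collection.
#'
#' @param pairs list of `ImageMaskPair`.
#' @param test_fraction fraction of pairs held out, strictly in (0, 1).
#' @param seed integer seed controlling the draw.
#' @return a list of class `DatasetSplit` with elements `train`, `test`,
#'   `seed`.
#' @export
split_dataset <- function(pairs, test_fraction = 0.2, seed = 1L) {
  if (length(pairs) < 2L) stop("need at least 2 pairs to split")
  if (!(test_fraction > 0 && test_fraction < 1))
    stop("test_fraction must be in (0, 1)")
  n <- length(pairs)
  n_test <- round(test_fraction * n)
  n_test <- max(1L, min(n - 1L, n_test))
  idx <- with_seed(seed, sample.int(n, n_test))
  structure(list(train = pairs[-idx], test = pairs[idx], seed = as.integer(seed)),
            class = "DatasetSplit")
}
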