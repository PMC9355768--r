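#' Preprocessing configuration
#'
#' Parameters of the enhancement chain applied before training: a robust
#' piecewise-linear contrast stretch, unsharp-mask sharpening, resizing to
#' the network's uniform input size, and (last) conversion to luma so the
#' networks consume a single channel.
#'
#' @param stretch_low_percentile,stretch_high_percentile percentile
#'   breakpoints of the stretch; intensities at/below the low percentile map
#'   to 0, at/above the high to 255, linearly between. Defaults (2, 98);
#'   (0, 100) recovers a pure min--max stretch.
#' @param sharpen_amount unsharp-mask gain (default 10).
#' @param sharpen_sigma Gaussian blur sigma of the unsharp mask (default 1).
#' @param target_size integer `(height, width)` network input size
#'   (default 512 x 512).
#' @param to_gray convert to luma as the final step (default TRUE).
#' @return a `PreprocessConfig` list.
#' @export
preprocess_config <- function(stretch_low_percentile = 2,
                              stretch_high_percentile = 98,
                              sharpen_amount = 10,
                              sharpen_sigma = 1,
                              target_size = c(512L, 512L),
                              to_gray = TRUE) {
  stopifnot(stretch_low_percentile >= 0,
            stretch_high_percentile <= 100,
            stretch_low_percentile < stretch_high_percentile,
            sharpen_amount >= 0, all(target_size > 0))
  structure(list(stretch_low_percentile = stretch_low_percentile,
                 stretch_high_percentile = stretch_high_percentile,
                 sharpen_amount = sharpen_amount,
                 sharpen_sigma = sharpen_sigma,
                 target_size = as.integer(target_size),
                 to_gray = isTRUE(to_gray)),
            class = "PreprocessConfig")
}

stretch_channel <- function(ch, lo_p, hi_p) {
  qs <- quantile(ch, c(lo_p, hi_p) / 100, names = FALSE)
  if (qs[1] == qs[2]) {
    warning("constant channel: contrast stretch is undefined, returning input")
    return(ch)
  }
  clamp((ch - qs[1]) / (qs[2] - qs[1]) * 255, 0, 255)
}

#' Piecewise-linear contrast stretch
#'
#' Monotone non-decreasing remap of intensities: values at or below the low
#' percentile go to 0, at or above the high percentile to 255, linear in
#' between. Colour images are stretched per channel.
#'
#' @param image numeric matrix or H x W x 3 array in \[0, 255\].
#' @param cfg a [preprocess_config()].
#' @return remapped image, same shape, values in \[0, 255\].
#' @export
contrast_stretch <- function(image, cfg = preprocess_config()) {
  stopifnot(length(image) > 0)
  lo <- cfg$stretch_low_percentile; hi <- cfg$stretch_high_percentile
  if (length(dim(image)) == 3L) {
    for (c in seq_len(dim(image)[3]))
      image[, , c] <- stretch_channel(image[, , c], lo, hi)
    image
  } else stretch_channel(image, lo, hi)
}

#' Unsharp-mask sharpening
#'
#' `out = clip(in + amount * (in - blur(in)), 0, 255)` with a Gaussian blur.
#' `amount = 0` is the identity; constant images pass through unchanged.
#'
#' @param image numeric matrix or H x W x 3 array in \[0, 255\].
#' @param amount non-negative gain (default 10).
#' @param sigma Gaussian blur sigma (default 1).
#' @return sharpened image, same shape.
#' @export
sharpen <- function(image, amount = 10, sigma = 1) {
  if (amount < 0) stop("sharpen amount must be >= 0")
  if (amount == 0) return(image)
  sharp1 <- function(ch) clamp(ch + amount * (ch - cpp_gauss_blur(ch, sigma)), 0, 255)
  if (length(dim(image)) == 3L) {
    for (c in seq_len(dim(image)[3])) image[, , c] <- sharp1(image[, , c])
    image
  } else sharp1(image)
}

#' Resize an image channel
#'
#' @param ch numeric matrix.
#' @param target integer `(height, width)`.
#' @param method `"bilinear"` or `"nearest"`.
#' @return resized matrix.
#' @export
resize_channel <- function(ch, target, method = c("bilinear", "nearest")) {
  method <- match.arg(method)
  H <- nrow(ch); W <- ncol(ch)
  Ho <- target[1]; Wo <- target[2]
  if (H == Ho && W == Wo) return(ch)
  # pixel-centre mapping (no corner alignment)
  rr <- (seq_len(Ho) - 0.5) * H / Ho + 0.5
  cc <- (seq_len(Wo) - 0.5) * W / Wo + 0.5
  mapr <- matrix(rr, Ho, Wo)
  mapc <- matrix(cc, Ho, Wo, byrow = TRUE)
  cpp_warp2d(ch, mapr, mapc, if (method == "bilinear") 1L else 0L)
}

resize_image <- function(image, target, method = "bilinear") {
  if (length(dim(image)) == 3L) {
    out <- array(0, c(target, dim(image)[3]))
    for (c in seq_len(dim(image)[3]))
      out[, , c] <- resize_channel(image[, , c], target, method)
    out
  } else resize_channel(image, target, method)
}

#' Resize an image/mask pair to the network input size
#'
#' The image is resampled bilinearly; the mask with nearest-neighbour so it
#' stays strictly binary.
#'
#' @param pair an `ImageMaskPair`.
#' @param target_size integer `(height, width)`.
#' @return resized `ImageMaskPair`.
#' @export
resize_pair <- function(pair, target_size = c(512L, 512L)) {
  validate_pair(pair)
  img <- resize_image(pair$image, target_size, "bilinear")
  msk <- if (is.null(pair$mask)) NULL else
    resize_channel(pair$mask, target_size, "nearest")
  image_mask_pair(pair$id, img, msk)
}

#' Apply the full enhancement chain to one pair
#'
#' Order: contrast stretch, sharpen, resize, then luma conversion, so the
#' networks receive single-channel `target_size` inputs.
#'
#' @param pair an `ImageMaskPair`.
#' @param cfg a [preprocess_config()].
#' @return preprocessed `ImageMaskPair`.
#' @export
preprocess_pair <- function(pair, cfg = preprocess_config()) {
  img <- contrast_stretch(pair$image, cfg)
  img <- sharpen(img, cfg$sharpen_amount, cfg$sharpen_sigma)
  p <- resize_pair(image_mask_pair(pair$id, img, pair$mask), cfg$target_size)
  if (cfg$to_gray) p$image <- rgb_to_luma(p$image)
  validate_pair(p)
}

#' Preprocess a list of pairs
#'
#' @param pairs list of `ImageMaskPair`.
#' @param cfg a [preprocess_config()].
#' @return list of preprocessed pairs.
#' @export
preprocess_dataset <- function(pairs, cfg = preprocess_config()) {
  lapply(pairs, preprocess_pair, cfg = cfg)
}
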