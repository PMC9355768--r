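#' Read an image file into an intensity array
#'
#' Reads PNG/JPEG/TIFF via EBImage and returns intensities on the 0--255
#' scale, H x W for grayscale or H x W x 3 for colour (alpha dropped).
#'
#' @param path file path.
#' @return numeric matrix or array.
#' @export
read_image <- function(path) {
  im <- tryCatch(EBImage::readImage(path),
                 error = function(e) stop("unreadable image file '", path,
                                          "': ", conditionMessage(e)))
  a <- as.array(im) * 255
  if (length(dim(a)) == 2L) return(t(a))
  if (dim(a)[3] >= 3L) return(aperm(a[, , 1:3, drop = FALSE], c(2L, 1L, 3L)))
  t(a[, , 1L])
}

read_mask <- function(path, threshold = 128) {
  m <- read_image(path)
  if (length(dim(m)) == 3L) m <- rgb_to_luma(m)
  (m >= threshold) * 1
}

#' Load paired images and lesion masks from directories
#'
#' Pairs `<id>.<ext>` images with `<id><mask_suffix>.png` masks (ISIC
#' convention). Masks are binarized at load: 8-bit values >= 128 become 1.
#' Images lacking a mask are skipped with a warning naming the orphan ids.
#'
#' @param image_dir directory of images (jpg/jpeg/png).
#' @param mask_dir directory of masks; defaults to `image_dir`.
#' @param mask_suffix suffix identifying mask files (default
#'   `"_segmentation"`).
#' @return list of `ImageMaskPair`, each with a mask.
#' @export
load_pairs <- function(image_dir, mask_dir = image_dir,
                       mask_suffix = "_segmentation") {
  if (!dir.exists(image_dir)) stop("image directory '", image_dir, "' does not exist")
  if (!dir.exists(mask_dir)) stop("mask directory '", mask_dir, "' does not exist")
  files <- list.files(image_dir, pattern = "\\.(png|jpe?g)$", ignore.case = TRUE)
  ids <- sub("\\.[^.]+$", "", files)
  keep <- !grepl(paste0(mask_suffix, "$"), ids)
  files <- files[keep]; ids <- ids[keep]
  if (length(files) == 0L) stop("no images found in '", image_dir, "'")
  pairs <- list(); orphans <- character()
  for (i in seq_along(files)) {
    mask_candidates <- file.path(mask_dir, paste0(ids[i], mask_suffix,
                                                  c(".png", ".PNG")))
    mask_path <- mask_candidates[file.exists(mask_candidates)][1]
    if (is.na(mask_path)) { orphans <- c(orphans, ids[i]); next }
    img <- read_image(file.path(image_dir, files[i]))
    msk <- read_mask(mask_path)
    if (!all(dim(img)[1:2] == dim(msk)))
      stop("pair '", ids[i], "': image/mask size mismatch (",
           paste(dim(img)[1:2], collapse = "x"), " vs ",
           paste(dim(msk), collapse = "x"), ")")
    pairs[[length(pairs) + 1L]] <- image_mask_pair(ids[i], img, msk)
  }
  if (length(orphans) > 0L)
    warning("skipped ", length(orphans), " image(s) without masks: ",
            paste(orphans, collapse = ", "))
  if (length(pairs) == 0L) stop("no image/mask pairs found")
  pairs
}

#' Write a binary mask as an 8-bit PNG
#'
#' Lesion pixels are written as 255, background as 0, single channel.
#' `read_mask(save_mask(m))` round-trips bit-exactly.
#'
#' @param mask numeric matrix with values in \{0, 1\}.
#' @param path output path (`.png`).
#' @export
save_mask <- function(mask, path) {
  if (!is_binary(mask)) stop("mask must be binary (values 0/1)")
  EBImage::writeImage(EBImage::Image(t(mask)), path, type = "png")
  invisible(path)
}

#' Write an intensity image as PNG
#'
#' @param image numeric matrix or H x W x 3 array, values in \[0, 255\].
#' @param path output path.
#' @export
save_image <- function(image, path) {
  a <- clamp(image, 0, 255) / 255
  im <- if (length(dim(a)) == 3L) {
    EBImage::Image(aperm(a, c(2L, 1L, 3L)), colormode = "Color")
  } else EBImage::Image(t(a))
  EBImage::writeImage(im, path, type = "png")
  invisible(path)
}

#' Write a list of pairs as ISIC-style files
#'
#' Emits `<id>.png` and `<id>_segmentation.png` per pair.
#'
#' @param pairs list of `ImageMaskPair`.
#' @param dir output directory, created if missing.
#' @param mask_suffix mask filename suffix.
#' @export
save_pairs <- function(pairs, dir, mask_suffix = "_segmentation") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (p in pairs) {
    save_image(p$image, file.path(dir, paste0(p$id, ".png")))
    if (!is.null(p$mask))
      save_mask(p$mask, file.path(dir, paste0(p$id, mask_suffix, ".png")))
  }
  invisible(dir)
}
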