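#' Augmentation configuration
#'
#' Controls the training-set augmentation recipe: horizontal/vertical flips,
#' random rotation, grid distortion, elastic deformation, and lesion-boundary
#' crops (scaling + cropping around the lesion edge, to sharpen edge
#' localization). Magnitudes default to mild, standard values.
#'
#' @param rotation_range max absolute rotation in degrees (default 30).
#' @param distortion_grid number of grid cells per side for grid distortion
#'   (default 4, minimum 2).
#' @param distortion_magnitude max control-point displacement in pixels
#'   (default 8).
#' @param elastic_alpha elastic displacement gain in pixels (default 30).
#' @param elastic_sigma smoothing sigma of the elastic field in pixels
#'   (default 4).
#' @param boundary_crop_size side length of the boundary crop in pixels
#'   (default 64).
#' @param boundary_scale_range `(min, max)` scale factors applied before the
#'   boundary crop (default `c(0.8, 1.2)`).
#' @param transform_prob probability that each transform participates in an
#'   augmented draw (default 0.5).
#' @param multiplier dataset size multiplier, >= 1; the originals count
#'   towards the total.
#' @param seed integer seed; all augmentation randomness flows from it.
#' @return an `AugmentConfig` list.
#' @export
augment_config <- function(rotation_range = 30,
                           distortion_grid = 4L,
                           distortion_magnitude = 8,
                           elastic_alpha = 30,
                           elastic_sigma = 4,
                           boundary_crop_size = 64L,
                           boundary_scale_range = c(0.8, 1.2),
                           transform_prob = 0.5,
                           multiplier = 2L,
                           seed = 1L) {
  stopifnot(rotation_range >= 0, distortion_grid >= 2,
            distortion_magnitude >= 0, elastic_alpha >= 0, elastic_sigma >= 0,
            boundary_crop_size > 0, length(boundary_scale_range) == 2,
            all(boundary_scale_range > 0), multiplier >= 1,
            transform_prob >= 0, transform_prob <= 1)
  structure(list(rotation_range = rotation_range,
                 distortion_grid = as.integer(distortion_grid),
                 distortion_magnitude = distortion_magnitude,
                 elastic_alpha = elastic_alpha, elastic_sigma = elastic_sigma,
                 boundary_crop_size = as.integer(boundary_crop_size),
                 boundary_scale_range = boundary_scale_range,
                 transform_prob = transform_prob,
                 multiplier = as.integer(multiplier),
                 seed = as.integer(seed)),
            class = "AugmentConfig")
}

# apply one source-coordinate map to image (bilinear) and mask (nearest)
warp_pair <- function(pair, mapr, mapc, id_suffix = "") {
  img <- pair$image
  if (length(dim(img)) == 3L) {
    for (c in seq_len(dim(img)[3]))
      img[, , c] <- cpp_warp2d(pair$image[, , c], mapr, mapc, 1L)
  } else img <- cpp_warp2d(img, mapr, mapc, 1L)
  msk <- if (is.null(pair$mask)) NULL else cpp_warp2d(pair$mask, mapr, mapc, 0L)
  image_mask_pair(paste0(pair$id, id_suffix), img, msk)
}

#' Flip an image/mask pair
#'
#' @param pair an `ImageMaskPair`.
#' @param axis `"horizontal"` (mirror columns) or `"vertical"` (mirror rows).
#' @return flipped pair; flipping twice restores the input.
#' @export
flip_pair <- function(pair, axis = c("horizontal", "vertical")) {
  axis <- match.arg(axis)
  validate_pair(pair)
  fl <- function(m) if (axis == "horizontal") m[, rev(seq_len(ncol(m))), drop = FALSE]
                    else m[rev(seq_len(nrow(m))), , drop = FALSE]
  img <- pair$image
  if (length(dim(img)) == 3L) {
    for (c in seq_len(dim(img)[3])) img[, , c] <- fl(pair$image[, , c])
  } else img <- fl(img)
  msk <- if (is.null(pair$mask)) NULL else fl(pair$mask)
  image_mask_pair(pair$id, img, msk)
}

rotation_maps <- function(H, W, angle_deg) {
  th <- angle_deg * pi / 180
  cr <- (H + 1) / 2; cc <- (W + 1) / 2
  dr <- matrix(seq_len(H) - cr, H, W)
  dc <- matrix(seq_len(W) - cc, H, W, byrow = TRUE)
  list(mapr = cr + cos(th) * dr + sin(th) * dc,
       mapc = cc - sin(th) * dr + cos(th) * dc)
}

#' Rotate a pair by a random angle
#'
#' Angle drawn uniformly in `[-angle_range, angle_range]` degrees from the
#' current RNG state; image resampled bilinearly, mask nearest-neighbour,
#' reflected at the borders; output size unchanged.
#'
#' @param pair an `ImageMaskPair`.
#' @param angle_range max absolute angle in degrees.
#' @param angle fixed angle (overrides the random draw when not `NULL`).
#' @return rotated pair.
#' @export
random_rotation <- function(pair, angle_range = 30, angle = NULL) {
  a <- angle %||% runif(1, -angle_range, angle_range)
  if (a == 0) return(pair)
  d <- dim(pair$image)
  m <- rotation_maps(d[1], d[2], a)
  warp_pair(pair, m$mapr, m$mapc)
}

#' Elastic deformation of a pair
#'
#' Random displacement fields (uniform in \[-1, 1\]) are Gaussian-smoothed
#' with `sigma` and scaled by `alpha`, then applied identically to image
#' (bilinear) and mask (nearest-neighbour).
#'
#' @param pair an `ImageMaskPair`.
#' @param alpha displacement gain in pixels (>= 0); 0 is the identity.
#' @param sigma smoothing sigma in pixels.
#' @return deformed pair.
#' @export
elastic_transform <- function(pair, alpha = 30, sigma = 4) {
  stopifnot(alpha >= 0, sigma >= 0)
  d <- dim(pair$image)
  H <- d[1]; W <- d[2]
  fr <- matrix(runif(H * W, -1, 1), H, W)
  fc <- matrix(runif(H * W, -1, 1), H, W)
  if (alpha == 0) return(pair)
  dr <- alpha * cpp_gauss_blur(fr, sigma)
  dc <- alpha * cpp_gauss_blur(fc, sigma)
  base_r <- matrix(seq_len(H), H, W)
  base_c <- matrix(seq_len(W), H, W, byrow = TRUE)
  warp_pair(pair, base_r + dr, base_c + dc)
}

#' Grid distortion of a pair
#'
#' A `(grid+1) x (grid+1)` lattice of control points is displaced uniformly
#' in \[-magnitude, magnitude\] pixels; the displacement field is
#' bilinearly interpolated to full resolution and applied to image and mask.
#'
#' @param pair an `ImageMaskPair`.
#' @param grid number of grid cells per side (>= 2).
#' @param magnitude max control-point displacement in pixels; 0 is the
#'   identity.
#' @return distorted pair.
#' @export
random_distortion <- function(pair, grid = 4L, magnitude = 8) {
  stopifnot(grid >= 2, magnitude >= 0)
  d <- dim(pair$image)
  H <- d[1]; W <- d[2]; g <- grid + 1L
  ctrl_r <- matrix(runif(g * g, -magnitude, magnitude), g, g)
  ctrl_c <- matrix(runif(g * g, -magnitude, magnitude), g, g)
  if (magnitude == 0) return(pair)
  dr <- resize_channel(ctrl_r, c(H, W), "bilinear")
  dc <- resize_channel(ctrl_c, c(H, W), "bilinear")
  base_r <- matrix(seq_len(H), H, W)
  base_c <- matrix(seq_len(W), H, W, byrow = TRUE)
  warp_pair(pair, base_r + dr, base_c + dc)
}

# lesion pixels with at least one background 4-neighbour
boundary_pixels <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  pad <- matrix(1, H + 2, W + 2)  # frame treated as lesion: frame-touching
  pad[2:(H + 1), 2:(W + 1)] <- mask  # lesion pixels are not boundary there
  core <- pad[2:(H + 1), 2:(W + 1)]
  nb_bg <- (pad[1:H, 2:(W + 1)] == 0) | (pad[3:(H + 2), 2:(W + 1)] == 0) |
           (pad[2:(H + 1), 1:W] == 0) | (pad[2:(H + 1), 3:(W + 2)] == 0)
  which(core == 1 & nb_bg, arr.ind = TRUE)
}

#' Lesion-boundary crop augmentation
#'
#' Scales the pair, crops a `crop_size` window centred on a uniformly
#' sampled lesion-boundary pixel (a lesion pixel with a background
#' 4-neighbour), and resizes the crop back to the input size. Every output
#' contains both lesion and background pixels.
#'
#' @param pair an `ImageMaskPair` with a mask containing both classes.
#' @param crop_size crop side length in pixels.
#' @param scale scale factor applied before cropping; drawn from
#'   `scale_range` when `NULL`.
#' @param scale_range `(min, max)` for the random scale.
#' @return cropped-and-resized pair, same size as the input.
#' @export
boundary_crop <- function(pair, crop_size = 64L, scale = NULL,
                          scale_range = c(0.8, 1.2)) {
  validate_pair(pair)
  if (is.null(pair$mask) || sum(pair$mask) == 0 || all(pair$mask == 1))
    stop("boundary_crop requires a mask containing both lesion and background")
  scale <- scale %||% runif(1, scale_range[1], scale_range[2])
  d0 <- dim(pair$image)[1:2]
  sz <- pmax(c(2L, 2L), round(d0 * scale))
  sp <- resize_pair(pair, sz)
  bp <- boundary_pixels(sp$mask)
  if (nrow(bp) == 0) stop("scaled mask has no boundary pixels")
  b <- bp[sample.int(nrow(bp), 1L), ]
  cs <- min(crop_size, min(dim(sp$mask)))
  r0 <- clamp(b[1] - cs %/% 2, 1, nrow(sp$mask) - cs + 1)
  c0 <- clamp(b[2] - cs %/% 2, 1, ncol(sp$mask) - cs + 1)
  rows <- r0:(r0 + cs - 1); cols <- c0:(c0 + cs - 1)
  crop_m <- sp$mask[rows, cols, drop = FALSE]
  # the window always contains the boundary pixel; if its background
  # neighbour fell just outside, nudge the window one pixel
  if (all(crop_m == 1) || all(crop_m == 0)) {
    r0 <- clamp(r0 - 1, 1, nrow(sp$mask) - cs + 1)
    c0 <- clamp(c0 - 1, 1, ncol(sp$mask) - cs + 1)
    rows <- r0:(r0 + cs - 1); cols <- c0:(c0 + cs - 1)
    crop_m <- sp$mask[rows, cols, drop = FALSE]
  }
  img <- if (length(d0 <- dim(sp$image)) == 3L) {
    sp$image[rows, cols, , drop = FALSE]
  } else sp$image[rows, cols, drop = FALSE]
  out <- resize_pair(image_mask_pair(pair$id, img, crop_m), dim(pair$mask))
  if (sum(out$mask) == 0 || all(out$mask == 1))
    stop("boundary crop degenerated to a single class")
  out
}

augment_once <- function(pair, cfg) {
  p <- pair; pr <- cfg$transform_prob
  if (runif(1) < pr) p <- flip_pair(p, "horizontal")
  if (runif(1) < pr) p <- flip_pair(p, "vertical")
  if (runif(1) < pr) p <- random_rotation(p, cfg$rotation_range)
  if (runif(1) < pr) p <- random_distortion(p, cfg$distortion_grid,
                                            cfg$distortion_magnitude)
  if (runif(1) < pr) p <- elastic_transform(p, cfg$elastic_alpha,
                                            cfg$elastic_sigma)
  has_boundary <- !is.null(p$mask) && sum(p$mask) > 0 && !all(p$mask == 1)
  if (has_boundary && runif(1) < pr)
    p <- boundary_crop(p, cfg$boundary_crop_size,
                       scale_range = cfg$boundary_scale_range)
  p
}

#' Augment a training set
#'
#' Returns `multiplier * length(pairs)` pairs: the originals plus
#' `(multiplier - 1)` augmented draws of each. Each draw composes the five
#' transforms, each participating with `transform_prob`, in the fixed order
#' flips, rotation, distortion, elastic, boundary crop. Fully reproducible
#' from `cfg$seed`.
#'
#' @param pairs nonempty list of `ImageMaskPair`.
#' @param cfg an [augment_config()].
#' @return list of augmented `ImageMaskPair`.
#' @export
augment_dataset <- function(pairs, cfg = augment_config()) {
  stopifnot(length(pairs) > 0)
  with_seed(cfg$seed, {
    out <- pairs
    if (cfg$multiplier > 1L) {
      for (m in seq_len(cfg$multiplier - 1L)) {
        for (i in seq_along(pairs)) {
          p <- augment_once(pairs[[i]], cfg)
          p$id <- paste0(pairs[[i]]$id, "_aug", m)
          out[[length(out) + 1L]] <- p
        }
      }
    }
    out
  })
}
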