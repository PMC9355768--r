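#' Synthetic dermoscopy image configuration
#'
#' Parameters of the synthetic image generator used to exercise the whole
#' pipeline at desk scale. Images emulate the salient difficulties of real
#' dermoscopy: a skin-toned background, one irregular-border lesion darker
#' than the skin by a controllable contrast, dark hair-like curvilinear
#' artifacts drawn over the image only, and sensor noise.
#'
#' @param size image side length in pixels (default 128).
#' @param lesion_radius_range `(min, max)` base lesion radius as a fraction
#'   of `size`, within (0, 0.5).
#' @param border_irregularity amplitude of the radial border perturbation
#'   (0 gives an exact disc).
#' @param contrast lesion-to-skin intensity gap in \[0, 1\]; 0 makes the
#'   lesion invisible (hard case), values near 1 give a near-black lesion.
#' @param n_hairs number of hair artifacts (>= 0).
#' @param noise_sigma Gaussian noise sigma on the 0--255 intensity scale.
#' @param seed integer seed.
#' @return a `SynthConfig` list.
#' @export
synth_config <- function(size = 128L,
                         lesion_radius_range = c(0.15, 0.35),
                         border_irregularity = 0.15,
                         contrast = 0.5,
                         n_hairs = 3L,
                         noise_sigma = 8,
                         seed = 1L) {
  stopifnot(size >= 8, length(lesion_radius_range) == 2,
            all(lesion_radius_range > 0), all(lesion_radius_range < 0.5),
            lesion_radius_range[1] <= lesion_radius_range[2],
            border_irregularity >= 0, contrast >= 0, contrast <= 1,
            n_hairs >= 0, noise_sigma >= 0)
  structure(list(size = as.integer(size),
                 lesion_radius_range = lesion_radius_range,
                 border_irregularity = border_irregularity,
                 contrast = contrast, n_hairs = as.integer(n_hairs),
                 noise_sigma = noise_sigma, seed = as.integer(seed)),
            class = "SynthConfig")
}

# star-convex radial border: r(theta) = r0 * (1 + irr * s(theta)) where s is
# a low-order random Fourier series normalized to max |s| = 1
radial_profile <- function(irr) {
  ks <- 2:5
  a <- rnorm(length(ks)) / ks
  b <- rnorm(length(ks)) / ks
  function(theta) {
    s <- rep(0, length(theta))
    for (i in seq_along(ks))
      s <- s + a[i] * cos(ks[i] * theta) + b[i] * sin(ks[i] * theta)
    smax <- max(abs(s), 1e-12)
    1 + irr * s / smax
  }
}

draw_hair <- function(img, size) {
  # quadratic Bezier with random endpoints and control point; dark, thin
  p0 <- runif(2, 1, size); p2 <- runif(2, 1, size)
  p1 <- (p0 + p2) / 2 + runif(2, -size / 3, size / 3)
  tt <- seq(0, 1, length.out = 4L * size)
  pts <- outer((1 - tt)^2, p0) + outer(2 * tt * (1 - tt), p1) + outer(tt^2, p2)
  shade <- runif(1, 10, 50)
  ri <- round(pts[, 1]); ci <- round(pts[, 2])
  ok <- ri >= 1 & ri <= size & ci >= 1 & ci <= size
  idx <- unique(cbind(ri[ok], ci[ok]))
  for (c in seq_len(dim(img)[3])) {
    ch <- img[, , c]
    ch[idx] <- shade
    img[, , c] <- ch
  }
  img
}

#' Generate one synthetic image/mask pair
#'
#' Draws lesion radius, border shape, centre, hairs and noise from the
#' current RNG state (seed via [generate_dataset()] or `set.seed`). The mask
#' is the exact lesion region; hairs never enter the mask.
#'
#' @param cfg a [synth_config()].
#' @param id identifier for the pair.
#' @return an `ImageMaskPair` with an RGB image and binary mask.
#' @export
generate_pair <- function(cfg = synth_config(), id = "synth_0001") {
  sz <- cfg$size
  r0 <- runif(1, cfg$lesion_radius_range[1], cfg$lesion_radius_range[2]) * sz
  rmax <- r0 * (1 + cfg$border_irregularity)
  if (rmax >= sz / 2)
    stop("degenerate lesion radius: ", round(rmax, 1),
         " px would exceed the ", sz, "-px frame")
  margin <- sz / 2 - rmax
  cy <- sz / 2 + runif(1, -margin, margin) * 0.8
  cx <- sz / 2 + runif(1, -margin, margin) * 0.8
  prof <- radial_profile(cfg$border_irregularity)

  rr <- matrix(seq_len(sz), sz, sz) - cy
  cc <- matrix(seq_len(sz), sz, sz, byrow = TRUE) - cx
  rho <- sqrt(rr^2 + cc^2)
  theta <- atan2(cc, rr)
  mask <- (rho <= r0 * prof(theta)) * 1

  skin <- c(224, 172, 148) * runif(1, 0.9, 1.05)  # skin-tone base
  img <- array(0, c(sz, sz, 3))
  for (c in 1:3) {
    ch <- matrix(skin[c], sz, sz)
    ch[mask == 1] <- skin[c] * (1 - cfg$contrast)
    img[, , c] <- ch
  }
  if (cfg$n_hairs > 0)
    for (h in seq_len(cfg$n_hairs)) img <- draw_hair(img, sz)
  if (cfg$noise_sigma > 0)
    img <- img + array(rnorm(length(img), 0, cfg$noise_sigma), dim(img))
  img <- clamp(img, 0, 255)
  image_mask_pair(id, img, mask)
}

#' Generate a synthetic dataset
#'
#' @param n number of pairs (>= 1).
#' @param cfg a [synth_config()]; per-pair parameters are drawn within its
#'   ranges.
#' @param seed integer seed; defaults to `cfg$seed`.
#' @return list of `n` `ImageMaskPair`s, reproducible under the seed.
#' @export
generate_dataset <- function(n, cfg = synth_config(), seed = cfg$seed) {
  stopifnot(n >= 1)
  with_seed(seed, lapply(seq_len(n), function(i)
    generate_pair(cfg, id = sprintf("synth_%04d", i))))
}
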