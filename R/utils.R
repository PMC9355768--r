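`%||%` <- function(a, b) if (is.null(a)) b else a

#' Convert an RGB image array to luma (grayscale)
#'
#' Uses the Rec. 601 weights 0.299 R + 0.587 G + 0.114 B. A 2-D input is
#' returned unchanged.
#'
#' @param image numeric matrix (H x W) or array (H x W x 3) of intensities.
#' @return numeric H x W matrix.
#' @export
rgb_to_luma <- function(image) {
  if (length(dim(image)) == 2) return(image)
  stopifnot(length(dim(image)) == 3, dim(image)[3] == 3)
  0.299 * image[, , 1] + 0.587 * image[, , 2] + 0.114 * image[, , 3]
}

is_binary <- function(m) {
  all(m == 0 | m == 1)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# deterministic fan-out of one user seed into per-stage seeds (kept < 2^31)
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 7919 + offset * 104729) %% 2147483629L)
}

# run expr with a temporary RNG state seeded from `seed`
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
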