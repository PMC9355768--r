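# Independent oracles and small fixtures used across the suite.

# brute-force flood-fill labeller (iterative stack), independent of the
# package's BFS implementation
flood_fill_label <- function(mask, connectivity = 8L) {
  H <- nrow(mask); W <- ncol(mask)
  lab <- matrix(0L, H, W)
  nbr <- if (connectivity == 8L) {
    cbind(c(-1, -1, -1, 0, 0, 1, 1, 1), c(-1, 0, 1, -1, 1, -1, 0, 1))
  } else cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  k <- 0L
  for (j in seq_len(W)) for (i in seq_len(H)) {
    if (mask[i, j] == 0 || lab[i, j] != 0L) next
    k <- k + 1L
    stack <- list(c(i, j)); lab[i, j] <- k
    while (length(stack) > 0) {
      p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      for (d in seq_len(nrow(nbr))) {
        ni <- p[1] + nbr[d, 1]; nj <- p[2] + nbr[d, 2]
        if (ni >= 1 && ni <= H && nj >= 1 && nj <= W &&
            mask[ni, nj] == 1 && lab[ni, nj] == 0L) {
          lab[ni, nj] <- k
          stack[[length(stack) + 1L]] <- c(ni, nj)
        }
      }
    }
  }
  lab
}

# oracle small-component removal on top of the oracle labeller
oracle_remove_small <- function(mask, min_size, connectivity) {
  lab <- flood_fill_label(mask, connectivity)
  if (max(lab) == 0) return(mask)
  sizes <- tabulate(lab[lab > 0])
  out <- mask
  out[lab %in% which(sizes < min_size)] <- 0
  out
}

# Otsu threshold: maximize between-class variance over candidate cuts
otsu_threshold <- function(v) {
  cand <- quantile(v, seq(0.02, 0.98, by = 0.01), names = FALSE)
  best <- cand[1]; best_var <- -1
  for (t in cand) {
    lo <- v[v < t]; hi <- v[v >= t]
    if (length(lo) == 0 || length(hi) == 0) next
    bv <- length(lo) * length(hi) * (mean(lo) - mean(hi))^2
    if (bv > best_var) { best_var <- bv; best <- t }
  }
  best
}

# deterministic disc-lesion fixture
make_disc_pair <- function(size = 64L, radius = size / 4, contrast = 0.6,
                           id = "disc") {
  cy <- cx <- (size + 1) / 2
  rr <- matrix(seq_len(size), size, size) - cy
  cc <- matrix(seq_len(size), size, size, byrow = TRUE) - cx
  mask <- (sqrt(rr^2 + cc^2) <= radius) * 1
  img <- matrix(200, size, size)
  img[mask == 1] <- 200 * (1 - contrast)
  image_mask_pair(id, img, mask)
}

tiny_spec <- function(name, size = 64L, base_width = 8L, depth = 3L, seed = 1L) {
  model_spec(name, input_size = c(size, size, 1L), base_width = base_width,
             depth = depth, seed = seed)
}

# central finite differences of f at a sample of elements of x
fd_gradient_at <- function(f, x, idx, h = 1e-5) {
  vapply(idx, function(i) {
    xp <- x; xp[i] <- xp[i] + h
    xm <- x; xm[i] <- xm[i] - h
    (f(xp) - f(xm)) / (2 * h)
  }, 0)
}

counts_from <- function(tp, fp, fn, tn) {
  structure(list(tp = tp, fp = fp, fn = fn, tn = tn), class = "ConfusionCounts")
}
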