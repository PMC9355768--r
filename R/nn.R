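# Minimal reverse-mode CNN primitives. Tensors are numeric arrays shaped
# (H, W, C, N); each primitive returns list(y, back) where back(gy) returns
# the gradient w.r.t. the input and accumulates parameter gradients into the
# shared gradient environment `genv$g` (keyed by parameter name).

acc_grad <- function(genv, name, g) {
  if (is.null(genv)) return(invisible(NULL))
  cur <- genv$g[[name]]
  genv$g[[name]] <- if (is.null(cur)) g else cur + g
  invisible(NULL)
}

nn_conv <- function(P, genv, name, x, stride = 1L, pad = 1L) {
  w <- P[[paste0(name, ".w")]]
  b <- P[[paste0(name, ".b")]]
  y <- cpp_conv2d_fw(x, w, b, as.integer(stride), as.integer(pad))
  back <- function(gy) {
    r <- cpp_conv2d_bw(x, w, gy, as.integer(stride), as.integer(pad))
    acc_grad(genv, paste0(name, ".w"), r$gw)
    acc_grad(genv, paste0(name, ".b"), r$gb)
    r$gx
  }
  list(y = y, back = back)
}

nn_tconv <- function(P, genv, name, x, stride = 2L) {
  w <- P[[paste0(name, ".w")]]
  b <- P[[paste0(name, ".b")]]
  y <- cpp_tconv2d_fw(x, w, b, as.integer(stride))
  back <- function(gy) {
    r <- cpp_tconv2d_bw(x, w, gy, as.integer(stride))
    acc_grad(genv, paste0(name, ".w"), r$gw)
    acc_grad(genv, paste0(name, ".b"), r$gb)
    r$gx
  }
  list(y = y, back = back)
}

nn_relu <- function(x) {
  pos <- x > 0
  y <- x * pos
  list(y = y, back = function(gy) gy * pos)
}

nn_sigmoid <- function(x) {
  y <- 1 / (1 + exp(-x))
  list(y = y, back = function(gy) gy * y * (1 - y))
}

nn_maxpool <- function(x) {
  r <- cpp_maxpool2_fw(x)
  xd <- dim(x)
  list(y = r$y, back = function(gy) cpp_maxpool2_bw(gy, r$idx, xd))
}

nn_add <- function(a, b) list(y = a$y + b$y,
                              back_a = a$back, back_b = b$back)

# channel map helper: per-channel vector -> full (H,W,C,N) multiplier vector
chan_map <- function(v, HW, N) rep(rep(v, each = HW), times = N)

nn_groupnorm <- function(P, genv, name, x, groups, eps = 1e-5) {
  d <- dim(x); HW <- d[1] * d[2]; C <- d[3]; N <- d[4]
  stopifnot(C %% groups == 0)
  Cg <- C %/% groups
  M <- HW * Cg                    # elements per (group, sample)
  xm <- matrix(x, M, groups * N)  # channels in a group are contiguous
  mu <- colMeans(xm)
  va <- colMeans(xm * xm) - mu^2
  istd <- 1 / sqrt(va + eps)
  xhat <- (xm - rep(mu, each = M)) * rep(istd, each = M)
  gamma <- P[[paste0(name, ".gamma")]]
  beta <- P[[paste0(name, ".beta")]]
  y <- array(as.vector(xhat) * chan_map(gamma, HW, N) + chan_map(beta, HW, N), d)
  back <- function(gy) {
    gyv <- as.vector(gy)
    xhv <- as.vector(xhat)
    # per-channel sums over (H, W, N)
    cs1 <- rowSums(matrix(colSums(matrix(gyv, HW, C * N)), C, N))
    cs2 <- rowSums(matrix(colSums(matrix(gyv * xhv, HW, C * N)), C, N))
    acc_grad(genv, paste0(name, ".beta"), cs1)
    acc_grad(genv, paste0(name, ".gamma"), cs2)
    gxh <- matrix(gyv * chan_map(gamma, HW, N), M, groups * N)
    m1 <- colMeans(gxh)
    m2 <- colMeans(gxh * xhat)
    gx <- rep(istd, each = M) *
      (gxh - rep(m1, each = M) - xhat * rep(m2, each = M))
    array(gx, d)
  }
  list(y = y, back = back)
}

nn_batchnorm <- function(P, genv, state, name, x, training,
                         momentum = 0.1, eps = 1e-5) {
  d <- dim(x); HW <- d[1] * d[2]; C <- d[3]; N <- d[4]
  gamma <- P[[paste0(name, ".gamma")]]
  beta <- P[[paste0(name, ".beta")]]
  if (training) {
    xm <- matrix(x, HW, C * N)
    mu <- rowMeans(matrix(colMeans(xm), C, N))
    e2 <- rowMeans(matrix(colMeans(xm * xm), C, N))
    va <- pmax(e2 - mu^2, 0)
    rm_key <- paste0(name, ".rmean"); rv_key <- paste0(name, ".rvar")
    state[[rm_key]] <- (1 - momentum) * (state[[rm_key]] %||% mu) + momentum * mu
    state[[rv_key]] <- (1 - momentum) * (state[[rv_key]] %||% va) + momentum * va
  } else {
    mu <- state[[paste0(name, ".rmean")]] %||% numeric(C)
    va <- state[[paste0(name, ".rvar")]] %||% rep(1, C)
  }
  istd <- 1 / sqrt(va + eps)
  xhat_v <- (as.vector(x) - chan_map(mu, HW, N)) * chan_map(istd, HW, N)
  y <- array(xhat_v * chan_map(gamma, HW, N) + chan_map(beta, HW, N), d)
  back <- function(gy) {
    gyv <- as.vector(gy)
    cs1 <- rowSums(matrix(colSums(matrix(gyv, HW, C * N)), C, N))
    cs2 <- rowSums(matrix(colSums(matrix(gyv * xhat_v, HW, C * N)), C, N))
    acc_grad(genv, paste0(name, ".beta"), cs1)
    acc_grad(genv, paste0(name, ".gamma"), cs2)
    gxh <- gyv * chan_map(gamma, HW, N)
    if (!training) return(array(gxh * chan_map(istd, HW, N), d))
    Mn <- HW * N
    t1 <- rowSums(matrix(colSums(matrix(gxh, HW, C * N)), C, N)) / Mn
    t2 <- rowSums(matrix(colSums(matrix(gxh * xhat_v, HW, C * N)), C, N)) / Mn
    gx <- chan_map(istd, HW, N) *
      (gxh - chan_map(t1, HW, N) - xhat_v * chan_map(t2, HW, N))
    array(gx, d)
  }
  list(y = y, back = back)
}

# normalization dispatcher: group (stateless) or batch (running stats)
nn_norm <- function(P, genv, model, name, x, training) {
  if (model$spec$norm == "group") {
    g <- min(model$spec$groups, dim(x)[3])
    while (dim(x)[3] %% g != 0) g <- g - 1
    nn_groupnorm(P, genv, name, x, g)
  } else {
    nn_batchnorm(P, genv, model$state, name, x, training)
  }
}

concat_channels <- function(a, b) {
  da <- dim(a); db <- dim(b)
  stopifnot(all(da[c(1, 2, 4)] == db[c(1, 2, 4)]))
  y <- array(0, c(da[1], da[2], da[3] + db[3], da[4]))
  y[, , seq_len(da[3]), ] <- a
  y[, , da[3] + seq_len(db[3]), ] <- b
  y
}

split_channels <- function(g, c1) {
  list(a = g[, , seq_len(c1), , drop = FALSE],
       b = g[, , (c1 + 1):dim(g)[3], , drop = FALSE])
}
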