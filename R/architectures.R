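#' Declarative description of one segmentation branch
#'
#' Encoder--decoder topology shared by both branches: `depth` resolution
#' levels with channel widths `base_width * 2^level`, capped at
#' `max_width` (the reference configuration runs 32 to 512). The V-Net
#' branch uses residual stages with 1/2/3 convolutions at levels 1/2/3+,
#' strided-convolution downsampling and group normalization; the
#' U-Net+ResNet branch uses two-convolution residual blocks, 2 x 2
#' max-pooling and batch normalization. Both decoders mirror their encoders
#' with transposed-convolution upsampling and skip concatenation, ending in
#' a 1 x 1 convolution with a sigmoid head.
#'
#' @param name `"vnet2d"` or `"unet_resnet2d"`.
#' @param input_size `(H, W, channels)`; channels is 1 (luma input).
#' @param base_width channels at the first level (default 32; use 8 for
#'   desk-scale tests).
#' @param max_width channel cap (default 512).
#' @param depth number of encoder levels (default 5, minimum 2).
#' @param norm `"group"` or `"batch"`; defaults to group for vnet2d, batch
#'   for unet_resnet2d.
#' @param groups group count for group normalization (default 8).
#' @param seed seed for weight initialization.
#' @return a `ModelSpec` list.
#' @export
model_spec <- function(name = c("vnet2d", "unet_resnet2d"),
                       input_size = c(512L, 512L, 1L),
                       base_width = 32L, max_width = 512L, depth = 5L,
                       norm = NULL, groups = 8L, seed = 1L) {
  name <- match.arg(name)
  if (depth < 2) stop("depth must be >= 2")
  stopifnot(base_width > 0, max_width >= base_width, groups >= 1)
  norm <- norm %||% if (name == "vnet2d") "group" else "batch"
  stopifnot(norm %in% c("group", "batch"))
  structure(list(name = name, input_size = as.integer(input_size),
                 base_width = as.integer(base_width),
                 max_width = as.integer(max_width), depth = as.integer(depth),
                 norm = norm, groups = as.integer(groups),
                 seed = as.integer(seed)),
            class = "ModelSpec")
}

spec_widths <- function(spec) {
  pmin(spec$base_width * 2^(seq_len(spec$depth) - 1L), spec$max_width)
}

n_stage_convs <- function(spec, s) {
  if (spec$name == "vnet2d") min(s, 3L) else 2L
}

add_conv_param <- function(env, name, k, cin, cout, tconv = FALSE) {
  dims <- if (tconv) c(k, k, cout, cin) else c(k, k, cin, cout)
  env$params[[paste0(name, ".w")]] <- array(0, dims)
  env$params[[paste0(name, ".b")]] <- numeric(cout)
  env$meta[[paste0(name, ".w")]] <- list(kind = "weight",
                                         fan_in = k * k * cin,
                                         fan_out = k * k * cout)
  env$meta[[paste0(name, ".b")]] <- list(kind = "bias")
}

add_norm_param <- function(env, name, c) {
  env$params[[paste0(name, ".gamma")]] <- rep(1, c)
  env$params[[paste0(name, ".beta")]] <- numeric(c)
  env$meta[[paste0(name, ".gamma")]] <- list(kind = "gamma")
  env$meta[[paste0(name, ".beta")]] <- list(kind = "beta")
}

add_stage_params <- function(env, prefix, in_ch, w, n_convs) {
  for (i in seq_len(n_convs)) {
    add_conv_param(env, paste0(prefix, ".conv", i), 3L,
                   if (i == 1) in_ch else w, w)
    add_norm_param(env, paste0(prefix, ".norm", i), w)
  }
  if (in_ch != w) add_conv_param(env, paste0(prefix, ".proj"), 1L, in_ch, w)
}

build_params <- function(spec) {
  env <- new.env()
  env$params <- list(); env$meta <- list()
  D <- spec$depth; w <- spec_widths(spec)
  in_ch <- spec$input_size[3]
  for (s in seq_len(D)) {
    stage_in <- if (s == 1) in_ch else {
      if (spec$name == "vnet2d") w[s] else w[s - 1]
    }
    add_stage_params(env, paste0("enc", s), stage_in, w[s], n_stage_convs(spec, s))
    if (s < D && spec$name == "vnet2d") {
      add_conv_param(env, paste0("down", s, ".conv"), 2L, w[s], w[s + 1])
      add_norm_param(env, paste0("down", s, ".norm"), w[s + 1])
    }
  }
  for (s in rev(seq_len(D - 1))) {
    add_conv_param(env, paste0("up", s, ".conv"), 2L, w[s + 1], w[s], tconv = TRUE)
    add_norm_param(env, paste0("up", s, ".norm"), w[s])
    add_stage_params(env, paste0("dec", s), 2L * w[s], w[s], n_stage_convs(spec, s))
  }
  add_conv_param(env, "head", 1L, w[1], 1L)
  list(params = env$params, meta = env$meta)
}

#' Re-initialize model weights with the Xavier/Glorot scheme
#'
#' Convolution weights are drawn from N(0, 2 / (fan_in + fan_out)); biases
#' are zero, normalization scales one and shifts zero. Deterministic under
#' the seed.
#'
#' @param model a `SegmentationModel`.
#' @param seed integer seed.
#' @return the model with fresh weights.
#' @export
init_weights_xavier <- function(model, seed = model$spec$seed) {
  with_seed(seed, {
    for (nm in names(model$params)) {
      kind <- model$meta[[nm]]$kind
      p <- model$params[[nm]]
      model$params[[nm]] <- switch(kind,
        weight = {
          m <- model$meta[[nm]]
          array(rnorm(length(p), 0, sqrt(2 / (m$fan_in + m$fan_out))), dim(p))
        },
        bias = numeric(length(p)),
        gamma = rep(1, length(p)),
        beta = numeric(length(p)))
    }
  })
  model
}

#' Build a segmentation branch from its spec
#'
#' @param spec a [model_spec()].
#' @return a `SegmentationModel` with Xavier-initialized weights.
#' @export
build_model <- function(spec) {
  parts <- build_params(spec)
  model <- structure(list(spec = spec, params = parts$params,
                          meta = parts$meta, state = new.env(parent = emptyenv())),
                     class = "SegmentationModel")
  init_weights_xavier(model, spec$seed)
}

#' Build the 2-D V-Net branch
#'
#' Residual encoder stages with 1, 2 then 3 convolutions, group
#' normalization, strided 2 x 2 convolution downsampling, mirrored decoder
#' with transposed convolutions and skip concatenation, sigmoid 1 x 1 head.
#'
#' @param spec a [model_spec()] with `name = "vnet2d"`.
#' @return a `SegmentationModel`.
#' @export
build_vnet2d <- function(spec = model_spec("vnet2d")) {
  if (spec$name != "vnet2d") stop("spec$name must be 'vnet2d'")
  build_model(spec)
}

#' Build the U-Net branch with residual blocks
#'
#' Classic U-Net topology with every double convolution replaced by a
#' residual block, batch normalization, 2 x 2 max-pooling downsampling,
#' transposed-convolution upsampling with skip concatenation, sigmoid
#' 1 x 1 head.
#'
#' @param spec a [model_spec()] with `name = "unet_resnet2d"`.
#' @return a `SegmentationModel`.
#' @export
build_unet_resnet2d <- function(spec = model_spec("unet_resnet2d")) {
  if (spec$name != "unet_resnet2d") stop("spec$name must be 'unet_resnet2d'")
  build_model(spec)
}

# residual stage: (conv -> norm -> relu)^(n-1) -> conv -> norm, plus
# identity-or-projection shortcut, final ReLU
res_stage <- function(P, genv, model, prefix, x, n_convs, training) {
  backs <- list()
  h <- x
  for (i in seq_len(n_convs)) {
    cv <- nn_conv(P, genv, paste0(prefix, ".conv", i), h, 1L, 1L)
    backs[[length(backs) + 1L]] <- cv$back; h <- cv$y
    no <- nn_norm(P, genv, model, paste0(prefix, ".norm", i), h, training)
    backs[[length(backs) + 1L]] <- no$back; h <- no$y
    if (i < n_convs) {
      rl <- nn_relu(h)
      backs[[length(backs) + 1L]] <- rl$back; h <- rl$y
    }
  }
  has_proj <- !is.null(P[[paste0(prefix, ".proj.w")]])
  if (has_proj) {
    pj <- nn_conv(P, genv, paste0(prefix, ".proj"), x, 1L, 0L)
    sc <- pj$y
  } else sc <- x
  out <- nn_relu(h + sc)
  back <- function(gy) {
    g <- out$back(gy)
    gz <- g
    for (b in rev(backs)) gz <- b(gz)
    gs <- if (has_proj) pj$back(g) else g
    gz + gs
  }
  list(y = out$y, back = back)
}

down_strided <- function(P, genv, model, prefix, x, training) {
  cv <- nn_conv(P, genv, paste0(prefix, ".conv"), x, 2L, 0L)
  no <- nn_norm(P, genv, model, paste0(prefix, ".norm"), cv$y, training)
  rl <- nn_relu(no$y)
  list(y = rl$y, back = function(gy) cv$back(no$back(rl$back(gy))))
}

up_layer <- function(P, genv, model, prefix, x, training) {
  tc <- nn_tconv(P, genv, paste0(prefix, ".conv"), x, 2L)
  no <- nn_norm(P, genv, model, paste0(prefix, ".norm"), tc$y, training)
  rl <- nn_relu(no$y)
  list(y = rl$y, back = function(gy) tc$back(no$back(rl$back(gy))))
}

#' Forward pass of a segmentation model
#'
#' Runs the network on a batch and returns the probability maps together
#' with a reverse-mode closure: `back(gy)` backpropagates a gradient
#' w.r.t. the output and returns the named list of parameter gradients.
#'
#' @param model a `SegmentationModel`.
#' @param x numeric array `(H, W, 1, N)`; H and W must be divisible by
#'   `2^(depth - 1)`.
#' @param training logical; `TRUE` uses batch statistics (and updates
#'   running statistics) in batch-norm layers.
#' @return `list(y, back)` with `y` in (0, 1), same spatial shape as `x`.
#' @export
model_forward <- function(model, x, training = FALSE) {
  spec <- model$spec
  d <- dim(x)
  if (length(d) == 3L) { dim(x) <- c(d, 1L); d <- dim(x) }
  div <- 2^(spec$depth - 1L)
  if (d[1] %% div != 0 || d[2] %% div != 0)
    stop("input ", d[1], "x", d[2], " not divisible by ", div,
         "; pad the image to a multiple of ", div)
  P <- model$params
  genv <- new.env(); genv$g <- list()
  D <- spec$depth; w <- spec_widths(spec)
  enc_backs <- vector("list", D)
  down_backs <- vector("list", D)
  skips <- vector("list", D)
  h <- x
  for (s in seq_len(D)) {
    st <- res_stage(P, genv, model, paste0("enc", s), h,
                    n_stage_convs(spec, s), training)
    h <- st$y; enc_backs[[s]] <- st$back
    if (s < D) {
      skips[[s]] <- h
      if (spec$name == "vnet2d") {
        dn <- down_strided(P, genv, model, paste0("down", s), h, training)
      } else dn <- nn_maxpool(h)
      h <- dn$y; down_backs[[s]] <- dn$back
    }
  }
  up_backs <- vector("list", D)
  dec_backs <- vector("list", D)
  for (s in rev(seq_len(D - 1L))) {
    up <- up_layer(P, genv, model, paste0("up", s), h, training)
    hcat <- concat_channels(skips[[s]], up$y)
    st <- res_stage(P, genv, model, paste0("dec", s), hcat,
                    n_stage_convs(spec, s), training)
    h <- st$y
    up_backs[[s]] <- up$back; dec_backs[[s]] <- st$back
  }
  hd <- nn_conv(P, genv, "head", h, 1L, 0L)
  sg <- nn_sigmoid(hd$y)
  back <- function(gy) {
    g <- sg$back(gy)
    g <- hd$back(g)
    skip_grads <- vector("list", D)
    for (s in seq_len(D - 1L)) {
      g <- dec_backs[[s]](g)
      sp <- split_channels(g, w[s])
      skip_grads[[s]] <- sp$a
      g <- up_backs[[s]](sp$b)
    }
    for (s in rev(seq_len(D))) {
      if (s < D) g <- down_backs[[s]](g) + skip_grads[[s]]
      g <- enc_backs[[s]](g)
    }
    genv$g
  }
  list(y = sg$y, back = back)
}

#' Predict binary masks for a set of images
#'
#' Forwards each image in evaluation mode and thresholds the sigmoid
#' probability map: pixels with probability strictly greater than
#' `threshold` become lesion.
#'
#' @param model a `SegmentationModel`.
#' @param images list of H x W matrices (0--255 scale) or `ImageMaskPair`s.
#' @param threshold probability threshold (default 0.5).
#' @param batch_size images per forward pass.
#' @return list of binary H x W masks.
#' @export
predict_masks <- function(model, images, threshold = 0.5, batch_size = 4L) {
  imgs <- lapply(images, function(p) {
    m <- if (inherits(p, "ImageMaskPair")) rgb_to_luma(p$image) else p
    m / 255
  })
  out <- vector("list", length(imgs))
  i <- 1L
  while (i <= length(imgs)) {
    j <- min(i + batch_size - 1L, length(imgs))
    d <- dim(imgs[[i]])
    x <- array(0, c(d[1], d[2], 1L, j - i + 1L))
    for (t in i:j) x[, , 1L, t - i + 1L] <- imgs[[t]]
    y <- model_forward(model, x, training = FALSE)$y
    for (t in i:j) out[[t]] <- (y[, , 1L, t - i + 1L] > threshold) * 1
    i <- j + 1L
  }
  out
}

#' Number of learnable parameters
#' @param model a `SegmentationModel`.
#' @return integer count.
#' @export
count_parameters <- function(model) sum(vapply(model$params, length, 1L))

#' Serialize a model (spec embedded) to a file
#'
#' The checkpoint carries the spec, parameters and normalization state, so
#' [load_model()] can rebuild the network from the file alone.
#'
#' @param model a `SegmentationModel`.
#' @param path output path (`.rds`).
#' @export
save_model <- function(model, path) {
  saveRDS(list(spec = model$spec, params = model$params, meta = model$meta,
               state = as.list(model$state)), path)
  invisible(path)
}

#' Load a model serialized with [save_model()]
#' @param path checkpoint path.
#' @return a `SegmentationModel`.
#' @export
load_model <- function(path) {
  obj <- readRDS(path)
  st <- new.env(parent = emptyenv())
  for (nm in names(obj$state)) st[[nm]] <- obj$state[[nm]]
  structure(list(spec = obj$spec, params = obj$params, meta = obj$meta,
                 state = st), class = "SegmentationModel")
}

#' @export
print.SegmentationModel <- function(x, ...) {
  cat("<SegmentationModel>", x$spec$name, "depth", x$spec$depth,
      "widths", paste(spec_widths(x$spec), collapse = "/"),
      "norm", x$spec$norm, "-", count_parameters(x), "parameters\n")
  invisible(x)
}
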