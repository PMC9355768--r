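#' Training configuration
#'
#' ADAM optimization of a configurable segmentation loss. Reference
#' settings: learning rate 1e-3, batch size 4, fused Dice + Focal Tversky
#' loss; the published run used 100,000 optimizer steps at full scale, here
#' exposed as `max_steps` for desk-scale work.
#'
#' @param learning_rate ADAM step size (> 0; 0 is allowed and freezes the
#'   parameters, useful for dry runs).
#' @param batch_size images per step (>= 1, default 4).
#' @param max_steps number of optimizer steps.
#' @param val_fraction fraction of the training pairs held out for
#'   validation, in (0, 1) (default 0.2).
#' @param loss `"fusion"` (default), `"dice"` or `"ftl"`.
#' @param tversky a [tversky_params()].
#' @param seed seed for batching and any stochastic choices.
#' @param eval_every validation/history cadence in steps.
#' @param threshold probability threshold for dice evaluation (default 0.5).
#' @param early_stop_dice optional dice target; training stops once the
#'   monitored dice reaches it.
#' @param monitor `"val"` (default) or `"train"`: which dice both drives
#'   best-checkpoint selection and the early stop.
#' @param beta1,beta2,adam_eps ADAM moment decay rates and stabilizer.
#' @return a `TrainConfig` list.
#' @export
train_config <- function(learning_rate = 1e-3, batch_size = 4L,
                         max_steps = 200L, val_fraction = 0.2,
                         loss = c("fusion", "dice", "ftl"),
                         tversky = tversky_params(), seed = 1L,
                         eval_every = 10L, threshold = 0.5,
                         early_stop_dice = NULL,
                         monitor = c("val", "train"),
                         beta1 = 0.9, beta2 = 0.999, adam_eps = 1e-8) {
  loss <- match.arg(loss); monitor <- match.arg(monitor)
  stopifnot(learning_rate >= 0, batch_size >= 1, max_steps >= 1,
            val_fraction > 0, val_fraction < 1)
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 max_steps = as.integer(max_steps),
                 val_fraction = val_fraction, loss = loss, tversky = tversky,
                 seed = as.integer(seed), eval_every = as.integer(eval_every),
                 threshold = threshold, early_stop_dice = early_stop_dice,
                 monitor = monitor, beta1 = beta1, beta2 = beta2,
                 adam_eps = adam_eps),
            class = "TrainConfig")
}

pairs_to_batch <- function(pairs, idx) {
  d <- dim(pairs[[idx[1]]]$image)
  x <- array(0, c(d[1], d[2], 1L, length(idx)))
  t <- array(0, c(d[1], d[2], 1L, length(idx)))
  for (i in seq_along(idx)) {
    p <- pairs[[idx[i]]]
    x[, , 1L, i] <- rgb_to_luma(p$image) / 255
    t[, , 1L, i] <- p$mask
  }
  list(x = x, t = t)
}

loss_and_grad <- function(pred, truth, cfg) {
  switch(cfg$loss,
    dice = list(loss = dice_loss(pred, truth),
                grad = dice_loss_grad(pred, truth)),
    ftl = list(loss = focal_tversky_loss(pred, truth, cfg$tversky),
               grad = focal_tversky_loss_grad(pred, truth, cfg$tversky)),
    fusion = list(loss = fusion_loss(pred, truth, cfg$tversky),
                  grad = fusion_loss_grad(pred, truth, cfg$tversky)))
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

adam_step <- function(params, grads, opt, cfg) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - cfg$beta1^opt$t
  bc2 <- 1 - cfg$beta2^opt$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    opt$m[[nm]] <- cfg$beta1 * opt$m[[nm]] + (1 - cfg$beta1) * g
    opt$v[[nm]] <- cfg$beta2 * opt$v[[nm]] + (1 - cfg$beta2) * g^2
    params[[nm]] <- params[[nm]] - cfg$learning_rate *
      (opt$m[[nm]] / bc1) / (sqrt(opt$v[[nm]] / bc2) + cfg$adam_eps)
  }
  list(params = params, opt = opt)
}

# one evaluation sweep: per-image dice/accuracy/loss from a single forward
# pass per chunk, in evaluation mode
mean_metric_row <- function(model, pairs, threshold, cfg, chunk = 8L) {
  dices <- accs <- losses <- numeric(length(pairs))
  i <- 1L
  while (i <= length(pairs)) {
    j <- min(i + chunk - 1L, length(pairs))
    b <- pairs_to_batch(pairs, i:j)
    p <- model_forward(model, b$x, training = FALSE)$y
    for (t in i:j) {
      k <- t - i + 1L
      pk <- p[, , 1L, k]; tk <- b$t[, , 1L, k]
      cc <- confusion_counts((pk > threshold) * 1, tk)
      dices[t] <- dice(cc); accs[t] <- accuracy(cc)
      losses[t] <- loss_and_grad(pk, tk, cfg)$loss
    }
    i <- j + 1L
  }
  list(dice = mean(dices), acc = mean(accs), loss = mean(losses))
}

mean_dice_on <- function(model, pairs, threshold, cap = 16L) {
  if (length(pairs) == 0) return(NA_real_)
  pairs <- pairs[seq_len(min(cap, length(pairs)))]
  preds <- predict_masks(model, pairs, threshold, batch_size = 8L)
  mean(vapply(seq_along(pairs), function(i)
    dice(confusion_counts(preds[[i]], pairs[[i]]$mask)), 0))
}

#' Train a segmentation branch
#'
#' ADAM optimization of the configured loss with deterministic shuffled
#' batching under `cfg$seed`. A `val_fraction` share of the training pairs
#' is held out for validation; the returned model is the checkpoint with
#' the best monitored dice. Aborts with a diagnostic if the loss becomes
#' non-finite.
#'
#' @param model a `SegmentationModel` (Xavier-initialized by the builder).
#' @param data a `DatasetSplit` (its `train` element is used) or a plain
#'   list of `ImageMaskPair`.
#' @param cfg a [train_config()].
#' @return `list(model, history)`; `history` is a data.frame of per-eval
#'   step, train loss/dice and validation loss/accuracy/dice.
#' @export
train <- function(model, data, cfg = train_config()) {
  pairs <- if (inherits(data, "DatasetSplit")) data$train else data
  if (length(pairs) == 0) stop("training set is empty")
  n_val <- max(1L, round(cfg$val_fraction * length(pairs)))
  if (n_val >= length(pairs)) stop("validation split leaves no training pairs")
  hist_rows <- list()
  best <- list(dice = -Inf, params = model$params, state = as.list(model$state))
  with_seed(cfg$seed, {
    vidx <- sample.int(length(pairs), n_val)
    val_pairs <- pairs[vidx]
    tr_pairs <- pairs[-vidx]
    if (length(val_pairs) == 0) stop("validation split is empty")
    opt <- adam_init(model$params)
    order_pool <- integer(0)
    step <- 0L
    running_loss <- NA_real_
    while (step < cfg$max_steps) {
      step <- step + 1L
      while (length(order_pool) < cfg$batch_size)
        order_pool <- c(order_pool, sample.int(length(tr_pairs)))
      idx <- order_pool[seq_len(cfg$batch_size)]
      order_pool <- order_pool[-seq_len(cfg$batch_size)]
      b <- pairs_to_batch(tr_pairs, idx)
      fw <- model_forward(model, b$x, training = TRUE)
      lg <- loss_and_grad(fw$y, b$t, cfg)
      if (!is.finite(lg$loss))
        stop("non-finite training loss at step ", step,
             " (loss = ", lg$loss, "); lower the learning rate")
      running_loss <- if (is.na(running_loss)) lg$loss else
        0.9 * running_loss + 0.1 * lg$loss
      grads <- fw$back(array(lg$grad, dim(b$x)))
      upd <- adam_step(model$params, grads, opt, cfg)
      model$params <- upd$params; opt <- upd$opt
      if (step %% cfg$eval_every == 0 || step == cfg$max_steps) {
        val <- mean_metric_row(model, val_pairs, cfg$threshold, cfg)
        tr_dice <- mean_dice_on(model, tr_pairs, cfg$threshold)
        hist_rows[[length(hist_rows) + 1L]] <- data.frame(
          step = step, train_loss = lg$loss, train_dice = tr_dice,
          val_loss = val$loss, val_acc = val$acc, val_dice = val$dice)
        mon <- if (cfg$monitor == "val") val$dice else tr_dice
        if (is.finite(mon) && mon > best$dice)
          best <- list(dice = mon, params = model$params,
                       state = as.list(model$state))
        if (!is.null(cfg$early_stop_dice) && is.finite(mon) &&
            mon >= cfg$early_stop_dice) break
      }
    }
  })
  model$params <- best$params
  for (nm in names(best$state)) model$state[[nm]] <- best$state[[nm]]
  history <- if (length(hist_rows)) do.call(rbind, hist_rows) else
    data.frame(step = integer(), train_loss = numeric(), train_dice = numeric(),
               val_loss = numeric(), val_acc = numeric(), val_dice = numeric())
  list(model = model, history = history)
}
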