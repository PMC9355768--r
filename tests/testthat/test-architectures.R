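test_that("channel widths double per level and cap at the maximum", {
  sp <- model_spec("vnet2d")
  expect_equal(lesionfuse:::spec_widths(sp), c(32, 64, 128, 256, 512))
  deep <- model_spec("vnet2d", depth = 6L)
  expect_equal(lesionfuse:::spec_widths(deep), c(32, 64, 128, 256, 512, 512))
  # realized in the built parameters of a desk-scale model
  m <- build_vnet2d(tiny_spec("vnet2d"))
  expect_equal(dim(m$params[["enc1.conv1.w"]])[4], 8)
  expect_equal(dim(m$params[["enc2.conv1.w"]])[4], 16)
  expect_equal(dim(m$params[["enc3.conv1.w"]])[4], 32)
  expect_error(model_spec("vnet2d", depth = 1L), "depth")
})

test_that("both networks map (H, W) inputs to same-shape probability maps", {
  set.seed(20)
  x <- array(runif(64 * 64 * 2), c(64, 64, 1, 2))
  for (nm in c("vnet2d", "unet_resnet2d")) {
    m <- build_model(tiny_spec(nm))
    y <- model_forward(m, x)$y
    expect_equal(dim(y), c(64L, 64L, 1L, 2L))
    expect_true(all(y > 0 & y < 1))
    # fully convolutional: another divisible size passes through unchanged
    x2 <- array(runif(32 * 48), c(32, 48, 1, 1))
    expect_equal(dim(model_forward(m, x2)$y), c(32L, 48L, 1L, 1L))
    expect_error(model_forward(m, array(0, c(30, 30, 1, 1))), "divisible")
  }
})

test_that("residual stages with zeroed branches behave as their shortcut", {
  m <- build_vnet2d(tiny_spec("vnet2d", size = 16L, base_width = 4L, depth = 2L))
  # zero the conv weights/biases and normalization shifts of stage enc2
  for (nm in grep("^enc2\\.(conv|norm)", names(m$params), value = TRUE))
    if (grepl("\\.(w|b|beta)$", nm)) m$params[[nm]] <- m$params[[nm]] * 0
  x <- array(abs(rnorm(8 * 8 * 8)), c(8, 8, 8, 1))  # enc2 width: 8 channels
  genv <- new.env(); genv$g <- list()
  st <- lesionfuse:::res_stage(m$params, genv, m, "enc2", x, 2L, training = FALSE)
  expect_equal(st$y, x, tolerance = 1e-12)  # in == out channels: identity path
})

test_that("model builds are deterministic under the seed", {
  checksum <- function(m) sum(vapply(m$params, function(p) sum(abs(p)), 0))
  a <- build_model(tiny_spec("vnet2d", seed = 42L))
  b <- build_model(tiny_spec("vnet2d", seed = 42L))
  c <- build_model(tiny_spec("vnet2d", seed = 43L))
  expect_identical(checksum(a), checksum(b))
  expect_false(identical(checksum(a), checksum(c)))
})

test_that("Xavier initialization has the Glorot variance and zero biases", {
  m <- build_model(tiny_spec("unet_resnet2d", base_width = 16L))
  m2 <- init_weights_xavier(m, seed = 7L)
  m3 <- init_weights_xavier(m, seed = 7L)
  expect_identical(m2$params, m3$params)
  for (nm in names(m2$params)) {
    meta <- m2$meta[[nm]]
    if (meta$kind == "bias") expect_true(all(m2$params[[nm]] == 0))
    if (meta$kind == "weight" && length(m2$params[[nm]]) >= 1e4) {
      v_target <- 2 / (meta$fan_in + meta$fan_out)
      expect_lt(abs(var(as.vector(m2$params[[nm]])) - v_target) / v_target, 0.1)
    }
  }
  # at least one layer is large enough to exercise the variance check
  expect_true(any(vapply(m2$params, length, 1L) >= 1e4))
})

test_that("one fused-loss backward pass reaches every parameter", {
  set.seed(21)
  x <- array(runif(32 * 32 * 2), c(32, 32, 1, 2))
  t <- array(rbinom(32 * 32 * 2, 1, 0.4), c(32, 32, 1, 2))
  for (nm in c("vnet2d", "unet_resnet2d")) {
    m <- build_model(tiny_spec(nm, size = 32L, base_width = 4L))
    fw <- model_forward(m, x, training = TRUE)
    g <- fw$back(array(fusion_loss_grad(fw$y, t), dim(x)))
    expect_setequal(names(g), names(m$params))
    nonzero <- vapply(g, function(z) any(z != 0), TRUE)
    expect_true(all(nonzero),
                info = paste(nm, "dead:", paste(names(g)[!nonzero], collapse = ",")))
  }
})

test_that("serialized checkpoints rebuild the network from file alone", {
  dir <- withr::local_tempdir()
  m <- build_model(tiny_spec("unet_resnet2d", size = 32L, base_width = 4L))
  x <- array(runif(32 * 32), c(32, 32, 1, 1))
  invisible(model_forward(m, x, training = TRUE))  # populate BN running stats
  y1 <- model_forward(m, x)$y
  f <- file.path(dir, "ckpt.rds")
  save_model(m, f)
  m2 <- load_model(f)
  expect_equal(model_forward(m2, x)$y, y1, tolerance = 1e-12)
  expect_equal(m2$spec, m$spec)
})
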