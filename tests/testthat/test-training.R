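make_train_pairs <- function(n = 6, size = 32L, seed = 30) {
  generate_dataset(n, synth_config(size = size, contrast = 0.8,
                                   noise_sigma = 4, n_hairs = 1L), seed = seed)
}

test_that("a zero learning rate leaves the parameters untouched", {
  pairs <- make_train_pairs(4)
  m <- build_model(tiny_spec("vnet2d", size = 32L, base_width = 4L, depth = 2L))
  r <- train(m, pairs, train_config(learning_rate = 0, max_steps = 5L,
                                    batch_size = 2L, val_fraction = 0.25,
                                    eval_every = 5L))
  expect_identical(r$model$params, m$params)
})

test_that("training is deterministic under the seed", {
  pairs <- make_train_pairs(4, size = 16L)
  cfg <- train_config(max_steps = 8L, batch_size = 2L, val_fraction = 0.25,
                      eval_every = 4L, seed = 5L)
  spec <- tiny_spec("vnet2d", size = 16L, base_width = 2L, depth = 2L, seed = 9L)
  r1 <- train(build_model(spec), pairs, cfg)
  r2 <- train(build_model(spec), pairs, cfg)
  expect_identical(r1$history, r2$history)
  expect_identical(r1$model$params, r2$model$params)
})

test_that("the minibatch loss trends downwards early in an overfit run", {
  pairs <- make_train_pairs(4, size = 32L)
  cfg <- train_config(max_steps = 50L, batch_size = 4L, val_fraction = 0.25,
                      eval_every = 5L, seed = 2L)
  r <- train(build_model(tiny_spec("unet_resnet2d", size = 32L,
                                   base_width = 4L, depth = 2L)),
             pairs, cfg)
  h <- r$history
  expect_true(all(diff(h$step) > 0))
  expect_true(all(is.finite(unlist(h[-1]))))
  # trend, allowing transient increases: late losses below early losses
  expect_lt(mean(tail(h$train_loss, 3)), mean(head(h$train_loss, 3)))
})

test_that("histories serialize and reload losslessly", {
  dir <- withr::local_tempdir()
  pairs <- make_train_pairs(4, size = 16L)
  r <- train(build_model(tiny_spec("vnet2d", size = 16L, base_width = 2L,
                                   depth = 2L)),
             pairs, train_config(max_steps = 6L, batch_size = 2L,
                                 val_fraction = 0.25, eval_every = 3L))
  f <- file.path(dir, "h.csv")
  write.csv(r$history, f, row.names = FALSE)
  expect_equal(read.csv(f), r$history, tolerance = 1e-12)
})

test_that("prediction thresholding is monotone with the stated extremes", {
  set.seed(31)
  m <- build_model(tiny_spec("vnet2d", size = 32L, base_width = 2L, depth = 2L))
  img <- matrix(runif(32 * 32, 0, 255), 32, 32)
  all_on <- predict_masks(m, list(img), threshold = 0)[[1]]
  all_off <- predict_masks(m, list(img), threshold = 1)[[1]]
  expect_true(all(all_on == 1))   # sigmoid probabilities are strictly > 0
  expect_true(all(all_off == 0))
  prev <- all_on
  for (th in c(0.2, 0.4, 0.6, 0.8)) {
    cur <- predict_masks(m, list(img), threshold = th)[[1]]
    expect_true(all(cur <= prev))  # raising the threshold never adds pixels
    prev <- cur
  }
  expect_error(predict_masks(m, list(matrix(0, 31, 31))), "pad")
})

test_that("degenerate validation splits are rejected", {
  pairs <- make_train_pairs(2, size = 16L)
  expect_error(train(build_model(tiny_spec("vnet2d", size = 16L,
                                           base_width = 2L, depth = 2L)),
                     pairs[1], train_config(val_fraction = 0.5)),
               "validation")
  expect_error(train(build_model(tiny_spec("vnet2d", size = 16L,
                                           base_width = 2L, depth = 2L)),
                     list(), train_config()), "empty")
})
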