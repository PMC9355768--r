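test_that("confusion counts match a per-pixel tally", {
  expect_equal(unclass(confusion_counts(matrix(1, 2, 2), matrix(1, 2, 2))),
               list(tp = 4, fp = 0, fn = 0, tn = 0))
  expect_equal(unclass(confusion_counts(matrix(1, 2, 2), matrix(0, 2, 2))),
               list(tp = 0, fp = 4, fn = 0, tn = 0))
  cc <- confusion_counts(matrix(c(1, 1, 0, 0), 2), matrix(c(1, 0, 1, 0), 2))
  expect_equal(unclass(cc), list(tp = 1, fp = 1, fn = 1, tn = 1))
  expect_error(confusion_counts(matrix(1, 2, 2), matrix(1, 3, 3)), "shape")
})

test_that("overlap metrics reproduce their hand-evaluated values", {
  expect_equal(dice(counts_from(4, 0, 0, 0)), 1)
  expect_equal(dice(counts_from(0, 2, 3, 0)), 0)
  expect_equal(dice(counts_from(3, 1, 2, 0)), 6 / 9)
  expect_equal(jaccard(counts_from(3, 1, 2, 0)), 0.5)
  expect_equal(jaccard(counts_from(5, 0, 0, 5)), 1)

  cc <- counts_from(1, 1, 1, 1)
  expect_equal(accuracy(cc), 0.5)
  expect_equal(sensitivity(cc), 0.5)
  expect_equal(specificity(cc), 0.5)
  perfect <- counts_from(4, 0, 0, 4)
  expect_equal(c(accuracy(perfect), sensitivity(perfect), specificity(perfect)),
               c(1, 1, 1))
  # absent-class conventions
  allbg <- confusion_counts(matrix(0, 2, 2), matrix(0, 2, 2))
  expect_equal(sensitivity(allbg), 1)
  expect_equal(dice(allbg), 1)
  allfg <- confusion_counts(matrix(1, 2, 2), matrix(1, 2, 2))
  expect_equal(specificity(allfg), 1)
})

test_that("dice and jaccard satisfy D = 2J/(1+J) on fuzzed masks", {
  set.seed(14)
  for (i in 1:300) {
    a <- matrix(rbinom(64, 1, runif(1, 0.1, 0.9)), 8)
    b <- matrix(rbinom(64, 1, runif(1, 0.1, 0.9)), 8)
    cc <- confusion_counts(a, b)
    d <- dice(cc); j <- jaccard(cc)
    expect_equal(d, 2 * j / (1 + j), tolerance = 1e-12)
    expect_equal(j, d / (2 - d), tolerance = 1e-12)
    expect_true(d >= 0 && d <= 1 && j >= 0 && j <= 1)
  }
})

test_that("the Tversky index generalizes Dice and matches Eq-style values", {
  # alpha = beta = 0.5 equals Dice on binary predictions
  set.seed(15)
  for (i in 1:200) {
    a <- matrix(rbinom(64, 1, 0.5), 8)
    b <- matrix(rbinom(64, 1, 0.5), 8)
    expect_equal(tversky_index(a, b, tversky_params(0.5, 0.5)),
                 dice(confusion_counts(a, b)), tolerance = 1e-5)
  }
  t <- matrix(c(rep(1, 5), rep(0, 4)), 3)   # tp=3, fn=2, fp=1 with pred below
  p <- matrix(c(1, 1, 1, 0, 0, 1, 0, 0, 0), 3)
  expect_equal(tversky_index(p, t, tversky_params(0.7, 0.3)),
               3 / 4.7, tolerance = 1e-6)
  expect_equal(tversky_index(t, t), 1, tolerance = 1e-6)
})

test_that("losses reproduce their hand evaluations", {
  p <- matrix(c(1, 1, 0, 0), 2); t <- matrix(c(1, 0, 1, 0), 2)
  expect_equal(dice_loss(p, t), 0.5, tolerance = 1e-6)
  expect_equal(dice_loss(t, t), 0, tolerance = 1e-6)
  expect_equal(dice_loss(1 - t, t), 1, tolerance = 1e-5)

  # focal form scalar checks via constructed TI values
  prm <- tversky_params(0.7, 0.3, 0.75)
  expect_equal(focal_tversky_loss(t, t, prm), 0, tolerance = 1e-4)
  expect_equal(focal_tversky_loss(1 - t, t, prm), 1, tolerance = 1e-4)
  # p vs t above gives TI = 1 / (1 + 0.7 + 0.3) = 0.5
  expect_equal(focal_tversky_loss(p, t, prm), 0.5^0.75, tolerance = 1e-6)
  expect_equal(fusion_loss(p, t, prm), 0.5 + 0.5^0.75, tolerance = 1e-6)
  expect_equal(fusion_loss(t, t, prm), 0, tolerance = 1e-5)
  expect_equal(fusion_loss(1 - t, t, prm), 2, tolerance = 1e-4)
  expect_error(tversky_params(gamma = 0), "gamma")
})

test_that("gamma = 1 recovers the Tversky loss; FTL decreases in TI", {
  set.seed(16)
  p <- matrix(runif(64), 8); t <- matrix(rbinom(64, 1, 0.5), 8)
  prm1 <- tversky_params(0.7, 0.3, 1)
  expect_identical(focal_tversky_loss(p, t, prm1),
                   1 - tversky_index(p, t, prm1))
  # predictions interpolating towards the truth give increasing TI and
  # strictly decreasing FTL
  prm <- tversky_params()
  s <- seq(0.1, 0.9, by = 0.1)
  tis <- vapply(s, function(a) tversky_index(a * t, t, prm), 0)
  ftls <- vapply(s, function(a) focal_tversky_loss(a * t, t, prm), 0)
  expect_true(all(diff(tis) > 0))
  expect_true(all(diff(ftls) < 0))
})

test_that("the complement-power reading of the focal loss is available", {
  p <- matrix(runif(16), 4); t <- matrix(rbinom(16, 1, 0.5), 4)
  prm <- tversky_params()
  ti <- tversky_index(p, t, prm)
  expect_equal(focal_tversky_loss(p, t, prm, form = "complement_power"),
               1 - ti^prm$gamma, tolerance = 1e-12)
})

test_that("analytic loss gradients match finite differences", {
  set.seed(17)
  p <- matrix(runif(64, 0.05, 0.95), 8)
  t <- matrix(rbinom(64, 1, 0.5), 8)
  prm <- tversky_params()
  idx <- sample(64, 12)
  cases <- list(
    list(f = function(x) dice_loss(x, t),
         g = dice_loss_grad(p, t)),
    list(f = function(x) focal_tversky_loss(x, t, prm),
         g = focal_tversky_loss_grad(p, t, prm)),
    list(f = function(x) fusion_loss(x, t, prm),
         g = fusion_loss_grad(p, t, prm)))
  for (cs in cases) {
    num <- fd_gradient_at(cs$f, p, idx)
    ana <- cs$g[idx]
    expect_lt(max(abs(num - ana) / pmax(abs(num) + abs(ana), 1e-8)), 1e-4)
  }
})

test_that("thresholded Jaccard implements the challenge zeroing rule", {
  expect_equal(thresholded_jaccard(c(1, 1, 1)), 1)
  expect_equal(thresholded_jaccard(c(0.7, 0.6)), 0.35)
  set.seed(18)
  js <- runif(20)
  expect_equal(thresholded_jaccard(js, threshold = 0), mean(js))
  expect_error(thresholded_jaccard(numeric(0)), "empty")
})

test_that("the fused loss is zero iff the prediction is perfect", {
  set.seed(19)
  for (i in 1:50) {
    t <- matrix(rbinom(64, 1, 0.5), 8)
    expect_lt(fusion_loss(t, t), 1e-5)
    p <- pmin(pmax(t + matrix(rnorm(64, 0, 0.2), 8), 0), 1)
    if (any(abs(p - t) > 0.05)) expect_gt(fusion_loss(p, t), 1e-4)
  }
})
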