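test_that("small-component removal drops exactly the undersized blobs", {
  m <- matrix(0, 20, 20)
  m[2:11, 2:11] <- 1          # 100-pixel component
  m[15:17, 15] <- 1           # 3-pixel component
  out <- remove_small_components(m, min_size = 10)
  expect_equal(sum(out), 100)
  expect_true(all(out[2:11, 2:11] == 1))

  expect_equal(remove_small_components(matrix(0, 5, 5), 10), matrix(0, 5, 5))
  expect_identical(remove_small_components(m, 0), m)
})

test_that("component labelling and filtering agree with a flood-fill oracle", {
  set.seed(40)
  for (i in 1:30) {
    m <- matrix(rbinom(32 * 32, 1, 0.35), 32, 32)
    for (conn in c(4L, 8L)) {
      lab <- label_components(m, conn)
      oracle <- flood_fill_label(m, conn)
      # same partition: label images agree up to renumbering
      expect_equal(max(lab), max(oracle))
      expect_true(all((lab > 0) == (oracle > 0)))
      key <- paste(lab, oracle)
      expect_equal(length(unique(key[lab > 0])), max(lab))
      ms <- sample(1:40, 1)
      expect_equal(remove_small_components(m, ms, conn),
                   oracle_remove_small(m, ms, conn))
    }
  }
})

test_that("fusion keeps the most-overlapping regions", {
  a <- matrix(0, 12, 12); a[2:6, 2:6] <- 1
  expect_identical(fuse_predictions(a, a), a)
  expect_identical(fuse_predictions(a, a, fusion_config(strategy = "pixel_and")), a * a)

  b <- matrix(0, 12, 12); b[8:11, 8:11] <- 1
  expect_true(all(fuse_predictions(a, b) == 0))
  expect_true(all(fuse_predictions(a, b, fusion_config(strategy = "pixel_and")) == 0))

  # 10-pixel component of A overlapping B on 6 pixels, threshold 0.5
  a2 <- matrix(0, 10, 10); a2[3, 1:10] <- 1
  b2 <- matrix(0, 10, 10); b2[2:4, 1:6] <- 1
  f_comp <- fuse_predictions(a2, b2, fusion_config(overlap_threshold = 0.5))
  expect_true(all(f_comp[a2 == 1] == 1))  # A's component retained whole
  f_and <- fuse_predictions(a2, b2, fusion_config(strategy = "pixel_and"))
  expect_equal(sum(f_and), 6)
  expect_true(all(f_and == a2 * b2))
  # at a stricter threshold the 60%-covered component is dropped
  f_strict <- fuse_predictions(a2, b2, fusion_config(overlap_threshold = 0.7))
  expect_true(all(f_strict[a2 == 1 & b2 == 0] == 0))

  expect_error(fuse_predictions(a, matrix(0, 5, 5)), "shape")
})

test_that("fused masks are subsets of the union; pixel_and bounds the FPs", {
  set.seed(41)
  for (i in 1:60) {
    a <- remove_small_components(matrix(rbinom(256, 1, 0.4), 16), 3)
    b <- remove_small_components(matrix(rbinom(256, 1, 0.4), 16), 3)
    tr <- matrix(rbinom(256, 1, 0.4), 16)
    f1 <- fuse_predictions(a, b, fusion_config(overlap_threshold = 0.5))
    f2 <- fuse_predictions(a, b, fusion_config(strategy = "pixel_and"))
    expect_true(all(f1 <= pmax(a, b)))
    expect_true(all(f2 <= a) && all(f2 <= b))
    fp <- function(p) confusion_counts(p, tr)$fp
    expect_lte(fp(f2), min(fp(a), fp(b)))
    expect_gte(specificity(confusion_counts(f2, tr)),
               max(specificity(confusion_counts(a, tr)),
                   specificity(confusion_counts(b, tr))))
  }
})

test_that("component retention is invariant to geometric relabelling order", {
  set.seed(42)
  for (i in 1:20) {
    a <- matrix(rbinom(400, 1, 0.35), 20)
    b <- matrix(rbinom(400, 1, 0.35), 20)
    f <- fuse_predictions(a, b)
    # flipping both inputs flips the fusion: retention cannot depend on the
    # scan order in which components are discovered
    flip <- function(m) m[nrow(m):1, ncol(m):1]
    expect_identical(fuse_predictions(flip(a), flip(b)), flip(f))
    expect_identical(fuse_predictions(t(a), t(b)), t(f))
  }
})

test_that("the postprocess pipeline thresholds, cleans, then fuses", {
  truth <- make_disc_pair(32, radius = 9)$mask
  pa <- truth * 0.9 + 0.02
  pb <- truth * 0.85 + 0.05
  cfg <- fusion_config(min_component_size = 10L)
  expect_identical(postprocess_pipeline(pa, pb, 0.5, cfg), truth)

  # a small spurious blob on one branch is removed before fusion
  pa2 <- pa; pa2[1:2, 1:2] <- 0.99   # 4-pixel blob, min size 10
  out <- postprocess_pipeline(pa2, pb, 0.5, cfg)
  expect_identical(out, truth)
  expect_error(postprocess_pipeline(pa, matrix(0.1, 5, 5), 0.5, cfg), "shape")
})
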