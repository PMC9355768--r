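test_that("flips are involutions and mirror the lesion centroid", {
  p <- generate_dataset(1, synth_config(size = 48L), seed = 2)[[1]]
  expect_equal(flip_pair(flip_pair(p, "horizontal"), "horizontal"), p)
  expect_equal(flip_pair(flip_pair(p, "vertical"), "vertical"), p)

  sym <- make_disc_pair(33)  # disc centred on the middle pixel
  expect_equal(flip_pair(sym, "horizontal")$mask, sym$mask)

  W <- ncol(p$mask)
  c0 <- mean(which(p$mask == 1, arr.ind = TRUE)[, 2])
  c1 <- mean(which(flip_pair(p, "horizontal")$mask == 1, arr.ind = TRUE)[, 2])
  expect_equal(c1, W + 1 - c0, tolerance = 1e-9)
})

test_that("rotation: zero angle is identity, 180 degrees equals double flip", {
  p <- generate_dataset(1, synth_config(size = 32L), seed = 6)[[1]]
  expect_equal(random_rotation(p, angle = 0), p)
  r180 <- random_rotation(p, angle = 180)
  ff <- flip_pair(flip_pair(p, "horizontal"), "vertical")
  expect_equal(r180$image, ff$image, tolerance = 1e-9)
  expect_equal(r180$mask, ff$mask)

  set.seed(4); a <- random_rotation(p, 30)
  set.seed(4); b <- random_rotation(p, 30)
  expect_identical(a, b)
})

test_that("image and mask undergo the same geometric map", {
  # a binary pattern encoded both as mask and as 0/255 image: a grid-exact
  # rotation (90 degrees, odd size) must transform both identically
  m <- make_disc_pair(33)$mask
  m[5:10, 3:7] <- 1
  p <- image_mask_pair("enc", m * 255, m)
  r <- random_rotation(p, angle = 90)
  expect_equal(r$image, r$mask * 255, tolerance = 1e-9)
})

test_that("elastic transform keeps masks binary and areas stable", {
  p <- make_disc_pair(128, radius = 32)
  expect_equal(elastic_transform(p, alpha = 0, sigma = 4), p)

  rel_change <- vapply(1:25, function(s) {
    set.seed(s)
    q <- elastic_transform(p, alpha = 30, sigma = 4)
    expect_true(all(q$mask %in% c(0, 1)))
    abs(sum(q$mask) - sum(p$mask)) / sum(p$mask)
  }, 0)
  expect_lt(max(rel_change), 0.2)

  set.seed(3); a <- elastic_transform(p, 20, 4)
  set.seed(3); b <- elastic_transform(p, 20, 4)
  expect_identical(a, b)
})

test_that("grid distortion keeps masks binary and is seed-reproducible", {
  p <- make_disc_pair(64)
  expect_equal(random_distortion(p, grid = 4, magnitude = 0), p)
  set.seed(5); a <- random_distortion(p, 4, 8)
  set.seed(5); b <- random_distortion(p, 4, 8)
  expect_identical(a, b)
  expect_true(all(a$mask %in% c(0, 1)))
  expect_error(random_distortion(p, grid = 1), "grid")
})

test_that("boundary crops are centred on the lesion edge and keep both classes", {
  p <- make_disc_pair(64, radius = 16)
  set.seed(11)
  crop <- boundary_crop(p, crop_size = 32L, scale = 1)
  # with scale 1 the crop centre sits on the rim: the central window of the
  # upscaled output contains the lesion/background transition
  ctr <- 28:37
  expect_true(any(crop$mask[ctr, ctr] == 1) && any(crop$mask[ctr, ctr] == 0))
  expect_equal(dim(crop$mask), dim(p$mask))

  for (s in 1:10) {
    set.seed(s)
    q <- boundary_crop(p, crop_size = 24L)
    expect_true(any(q$mask == 1) && any(q$mask == 0))
  }
  expect_error(boundary_crop(image_mask_pair("e", matrix(0, 8, 8),
                                             matrix(0, 8, 8))), "boundary")
  expect_error(boundary_crop(image_mask_pair("f", matrix(0, 8, 8),
                                             matrix(1, 8, 8))), "boundary")
})

test_that("augment_dataset multiplies the set deterministically", {
  pairs <- generate_dataset(10, synth_config(size = 32L), seed = 12)
  expect_identical(augment_dataset(pairs, augment_config(multiplier = 1L)), pairs)

  cfg <- augment_config(multiplier = 5L, seed = 99L,
                        boundary_crop_size = 16L)
  out <- augment_dataset(pairs, cfg)
  expect_length(out, 50)
  for (p in out) {
    expect_true(all(p$mask %in% c(0, 1)))
    expect_equal(dim(p$image)[1:2], dim(p$mask))
  }
  out2 <- augment_dataset(pairs, cfg)
  expect_identical(out, out2)
})
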