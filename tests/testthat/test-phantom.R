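test_that("the generator is bitwise deterministic for a fixed seed", {
  cfg <- phantom_config(seed = 12)
  a <- generate_phantom(cfg)
  b <- generate_phantom(cfg)
  expect_identical(a, b)
  expect_false(identical(a, generate_phantom(phantom_config(seed = 13))))
})

test_that("the noiseless limit is exactly two-valued with the mask as threshold", {
  cfg <- phantom_config(speckle_strength = 0, boundary_blur_sigma = 0,
                        inhomogeneity_strength = 0, seed = 3)
  s <- generate_phantom(cfg)
  lv <- sort(unique(as.numeric(s$image)))
  expect_length(lv, 2L)
  expect_identical((s$image > mean(lv)) * 1, s$mask)
})

test_that("phantom masks are single 4-connected components within area bounds", {
  cfg <- phantom_config(seed = 500)
  lo <- cfg$area_fraction_range[1]; hi <- cfg$area_fraction_range[2]
  samples <- generate_phantoms(300, cfg)
  fracs <- vapply(samples, function(s) mean(s$mask), numeric(1))
  expect_true(all(fracs >= lo & fracs <= hi))
  ok4 <- vapply(samples, function(s) mask_is_single_4connected(s$mask),
                logical(1))
  expect_true(all(ok4))
  expect_true(all(vapply(samples, function(s)
    all(s$image >= 0 & s$image <= 1), logical(1))))
  # cross-check component count with an independent labeling routine
  if (requireNamespace("EBImage", quietly = TRUE)) {
    ncomp <- vapply(samples[1:50], function(s)
      max(EBImage::bwlabel(s$mask)), numeric(1))
    expect_true(all(ncomp == 1))
  }
})

test_that("normalization centres and scales per channel", {
  set.seed(2)
  x <- array(runif(8 * 8 * 2, 3, 9), c(8, 8, 2))
  z <- normalize_image(x)
  for (c in 1:2) {
    expect_lt(abs(mean(z[, , c])), 1e-12)
    expect_equal(sqrt(mean(z[, , c]^2)), 1, tolerance = 1e-12)
  }
  expect_identical(normalize_image(matrix(5, 4, 4)), matrix(0, 4, 4))
  # invariance under positive affine maps of the input
  expect_equal(normalize_image(3.7 * x + 11), z, tolerance = 1e-9)
})

test_that("a zero-magnitude augmentation is the identity", {
  s <- generate_phantom(phantom_config(seed = 5))
  cfg <- augmentation_config(max_translation_fraction = 0, crop_fraction = 1,
                             hflip_probability = 0)
  expect_identical(augment_sample(s, cfg), s)
})

test_that("a certain horizontal flip is an involution", {
  s <- generate_phantom(phantom_config(seed = 6))
  cfg <- augmentation_config(max_translation_fraction = 0, crop_fraction = 1,
                             hflip_probability = 1)
  once <- augment_sample(s, cfg)
  expect_false(identical(once$image, s$image))
  expect_identical(augment_sample(once, cfg), s)
})

test_that("augmentation preserves shape and mask binarity across random draws", {
  s <- generate_phantom(phantom_config(seed = 7))
  cfg <- augmentation_config()
  set.seed(42)
  for (i in 1:100) {
    a <- augment_sample(s, cfg)
    expect_identical(dim(a$image), dim(s$image))
    expect_identical(dim(a$mask), dim(s$mask))
    expect_true(all(a$mask %in% c(0, 1)))
    expect_true(all(a$image >= 0 & a$image <= 1))
  }
})

test_that("samples survive a save/load round trip and bad files are rejected", {
  dir <- withr::local_tempdir()
  s <- generate_phantom(phantom_config(seed = 9))
  ip <- file.path(dir, "img.png"); mp <- file.path(dir, "msk.png")
  save_sample(s, ip, mp)
  r <- load_sample(ip, mp)
  # image quantized to 8 bits on save; mask exactly preserved
  expect_lt(max(abs(r$image - s$image)), 1 / 255)
  expect_identical(r$mask, s$mask)
  expect_identical(load_sample(ip, mp), load_sample(ip, mp))

  # grayscale TIFF accepted on read
  tp <- file.path(dir, "img.tif")
  tiff::writeTIFF(r$image, tp)
  expect_equal(load_sample(tp, mp)$image, r$image)

  # non-binary mask file
  bad <- file.path(dir, "bad.png")
  png::writePNG(matrix(runif(64 * 64), 64, 64), bad)
  expect_error(load_sample(ip, bad), "non-binary mask")

  # shape mismatch names both shapes
  small <- file.path(dir, "small.png")
  png::writePNG(matrix(0, 32, 32), small)
  expect_error(load_sample(ip, small), "64 x 64.*32 x 32")

  # missing mask loads an image-only pair
  p <- load_sample(ip)
  expect_null(p$mask)
  expect_identical(p$image, r$image)
})

test_that("dataset splitting reproduces the printed 780/123/154 partition", {
  sp <- split_dataset(1057, seed = 4)
  expect_length(sp$train, 780)
  expect_length(sp$val, 123)
  expect_length(sp$test, 154)
  all_idx <- sort(c(sp$train, sp$val, sp$test))
  expect_identical(all_idx, 1:1057)            # disjoint and exhaustive

  sp10 <- split_dataset(10, fractions = c(0.8, 0.1, 0.1), seed = 1)
  expect_identical(lengths(sp10), c(train = 8L, val = 1L, test = 1L))

  expect_identical(split_dataset(50, seed = 2), split_dataset(50, seed = 2))
  expect_false(identical(split_dataset(50, seed = 2)$train,
                         split_dataset(50, seed = 3)$train))
  expect_error(split_dataset(3, fractions = c(0.98, 0.01, 0.01)), "empty")
})
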