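test_that("images round-trip through PNG with sidecar pixel size", {
  dir <- withr::local_tempdir()
  px <- matrix(sample(0:255, 100 * 80, replace = TRUE), 100, 80)
  img <- scalar_image(px, 0.1)
  path <- file.path(dir, "img.png")
  write_image(img, path)
  back <- read_image(path, 0.1)
  expect_identical(back$pixels, px + 0)
  expect_equal(back$pixel_size, 0.1)
  # pixel size comes from the sidecar when not given
  expect_equal(read_image(path)$pixel_size, 0.1)
  # second write/read is the identity
  write_image(back, file.path(dir, "img2.png"))
  expect_identical(read_image(file.path(dir, "img2.png"), 0.1)$pixels,
                   back$pixels)
})

test_that("invalid image inputs are rejected", {
  expect_error(scalar_image(matrix(1, 2, 2), 0), "positive")
  expect_error(read_image("no/such/file.png", 0.1), "not found")
  dir <- withr::local_tempdir()
  rgb <- array(runif(12), dim = c(2, 2, 3))
  png::writePNG(rgb, file.path(dir, "rgb.png"))
  expect_error(read_image(file.path(dir, "rgb.png"), 0.1), "grayscale")
})

test_that("mask decode/encode is an exact identity on the 0/127/255 alphabet", {
  lab <- matrix(c(0, 127, 255, 255, 0, 127), 2, 3)
  mask <- decode_mask(lab, 0.1)
  expect_identical(sort(unique(as.vector(mask$classes))), c(0L, 1L, 2L))
  expect_identical(encode_mask(mask), matrix(as.integer(lab), 2, 3))
  # all-axon and all-background extremes
  expect_true(all(decode_mask(matrix(255, 4, 4), 0.1)$classes == 2L))
  expect_true(all(decode_mask(matrix(0, 4, 4), 0.1)$classes == 0L))
  # out-of-alphabet values are named in the error
  expect_error(decode_mask(matrix(c(0, 64), 1, 2), 0.1), "64")
})

test_that("bilinear resampling follows round(shape * ratio)", {
  img <- scalar_image(matrix(runif(100 * 100, 0, 255), 100, 100), 0.2)
  up <- resample_image(img, 0.1)
  expect_identical(dim(up$pixels), c(200L, 200L))
  expect_equal(up$pixel_size, 0.1)
  # identity when the target equals the current pixel size (bitwise)
  expect_identical(resample_image(img, 0.2)$pixels, img$pixels)
  # 512 at 0.13 um -> round(512 * 1.3) = 666
  img2 <- scalar_image(matrix(0, 512, 512), 0.13)
  expect_identical(dim(resample_image(img2, 0.1)$pixels), c(666L, 666L))
  # non-square images resize per axis
  img3 <- scalar_image(matrix(0, 100, 80), 0.2)
  expect_identical(dim(resample_image(img3, 0.1)$pixels), c(200L, 160L))
  expect_error(resample_image(scalar_image(matrix(0, 2, 2), 0.1), 1e3),
               "degenerate")
})

test_that("mask resampling is nearest-neighbor and class-preserving", {
  cls <- matrix(0L, 8, 8)
  cls[4, 5] <- 2L
  mask <- segmentation_mask(cls, 0.1)
  up <- resample_mask(mask, 0.05)
  expect_identical(dim(up$classes), c(16L, 16L))
  expect_equal(sum(up$classes == 2L), 4L)  # one pixel becomes a 2x2 block
  # round trip on an even factor restores the mask exactly
  back <- resample_mask(up, 0.1)
  expect_identical(back$classes, mask$classes)
  # constant masks stay constant under any factor
  uni <- segmentation_mask(matrix(1L, 5, 5), 0.1)
  expect_true(all(resample_mask(uni, 0.073)$classes == 1L))
})

test_that("patch extraction tiles a mirror-padded canvas and restitches", {
  mk_pair <- function(n) {
    img <- scalar_image(matrix(runif(n * n, 0, 255), n, n), 0.1)
    cls <- matrix(sample(0:2, n * n, replace = TRUE), n, n)
    list(img = img, mask = segmentation_mask(cls, 0.1))
  }
  p <- mk_pair(1024)
  ps <- extract_patches(p$img, p$mask, 512)
  expect_length(ps$images, 4L)
  expect_identical(restitch_patches(ps), p$img$pixels)
  # non-multiple side: 600 -> padded to 1024 -> 4 patches
  p2 <- mk_pair(600)
  ps2 <- extract_patches(p2$img, p2$mask, 512)
  expect_length(ps2$images, 4L)
  expect_identical(ps2$padded_shape, c(1024L, 1024L))
  expect_identical(restitch_patches(ps2), p2$img$pixels)
  expect_identical(restitch_patches(ps2, "masks"), p2$mask$classes + 0)
  # exact single patch
  p3 <- mk_pair(512)
  ps3 <- extract_patches(p3$img, p3$mask, 512)
  expect_length(ps3$images, 1L)
  expect_identical(ps3$images[[1]], p3$img$pixels)
  # mismatched shapes rejected
  expect_error(extract_patches(p3$img, p2$mask), "shapes differ")
})

test_that("patch normalization equalizes then standardizes", {
  set.seed(4)
  patch <- matrix(sample(0:255, 64 * 64, replace = TRUE), 64, 64)
  z <- normalize_patch(patch)
  expect_lt(abs(mean(z)), 1e-6)
  expect_lt(abs(sqrt(mean((z - mean(z))^2)) - 1), 1e-6)
  # constant patch maps to all zeros via the variance floor
  expect_true(all(normalize_patch(matrix(7, 16, 16)) == 0))
  # two-level patch: equalization then standardization gives two equal-sized
  # level sets of opposite sign
  two <- matrix(c(rep(0, 128), rep(255, 128)), 16, 16)
  z2 <- normalize_patch(two)
  expect_length(unique(as.vector(z2)), 2L)
  expect_equal(sum(z2 > 0), 128L)
  expect_equal(sort(unique(as.vector(z2))), c(-1, 1), tolerance = 1e-12)
})

test_that("train/validation split is seeded, sized, and warns at the boundary", {
  img <- scalar_image(matrix(0, 1024, 1280), 0.1)
  ps <- extract_patches(img, patch_size = 256)  # 4 x 5 = 20 patches
  s1 <- split_train_val(ps, 0.7, seed = 42)
  expect_equal(sum(s1$split == "train"), round(0.7 * 20))
  expect_equal(sum(s1$split == "val"), 20 - round(0.7 * 20))
  s2 <- split_train_val(ps, 0.7, seed = 42)
  expect_identical(s1$split, s2$split)
  s3 <- split_train_val(ps, 0.7, seed = 43)
  expect_false(identical(s1$split, s3$split))
  expect_warning(split_train_val(ps, 1.0, seed = 1), "empty validation")
  one <- extract_patches(scalar_image(matrix(0, 8, 8), 0.1), patch_size = 8)
  expect_error(split_train_val(one, 0.7), "at least 2")
})

test_that("patch sets persist as paired PNGs plus an index TSV", {
  dir <- withr::local_tempdir()
  img <- scalar_image(matrix(sample(0:255, 600 * 600, TRUE), 600, 600), 0.1)
  cls <- matrix(sample(0:2, 600 * 600, TRUE), 600, 600)
  ps <- split_train_val(
    extract_patches(img, segmentation_mask(cls, 0.1), 512), 0.7, seed = 1)
  save_patchset(ps, dir)
  expect_true(file.exists(file.path(dir, "index.tsv")))
  back <- load_patchset(dir)
  expect_equal(back$origins, ps$origins, ignore_attr = TRUE)
  expect_identical(back$split, ps$split)
  expect_identical(back$masks, ps$masks)
  expect_identical(back$images, ps$images)  # integer intensities survive
})
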