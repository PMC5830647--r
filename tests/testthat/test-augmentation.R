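# A small image/mask pair with one off-center annular fiber, blur-free so
# image and mask structure can be compared after joint warps.
fiber_pair <- function(n = 96, center = c(30, 40), r_ax = 8, r_out = 12) {
  d2 <- outer((seq_len(n) - center[1])^2, (seq_len(n) - center[2])^2, `+`)
  mask <- matrix(0L, n, n)
  mask[d2 <= r_out^2] <- 1L
  mask[d2 <= r_ax^2] <- 2L
  img <- matrix(130, n, n)
  img[mask == 1L] <- 50
  img[mask == 2L] <- 200
  list(img = img, mask = mask)
}

mask_centroid <- function(mask, cls = 2L) {
  idx <- which(mask == cls, arr.ind = TRUE)
  colMeans(idx)
}

image_blob_centroid <- function(img) {
  idx <- which(img > 180, arr.ind = TRUE)
  colMeans(idx)
}

test_that("shift offsets are bounded, mirror-filled, and joint", {
  p <- fiber_pair()
  set.seed(1)
  for (i in 1:20) {
    out <- random_shift(p$img, p$mask, shift_max = 0.10)
    expect_true(all(out$mask %in% 0:2))
    shift <- mask_centroid(out$mask) - mask_centroid(p$mask)
    expect_true(all(abs(shift) <= 0.10 * 96 + 0.5))
    # image blob moves with the mask
    expect_lt(max(abs(image_blob_centroid(out$image) -
                        mask_centroid(out$mask))), 1)
  }
})

test_that("rotations stay in range and approximately invert", {
  p <- fiber_pair()
  A <- fiberseg:::rotation_matrix(30, 96, 96)
  B <- fiberseg:::rotation_matrix(-30, 96, 96)
  fwd <- fiberseg:::cpp_warp_affine(p$img, A, TRUE)
  back <- fiberseg:::cpp_warp_affine(fwd, B, TRUE)
  interior <- 20:76
  expect_lt(mean(abs(back[interior, interior] - p$img[interior, interior])),
            3)
  set.seed(2)
  for (i in 1:20) {
    out <- random_rotation(p$img, p$mask)
    expect_true(all(out$mask %in% 0:2))
    # the drawn magnitude lies in [5, 89]: the fiber must actually move
    rot <- mask_centroid(out$mask) - c((96 + 1) / 2, (96 + 1) / 2)
    ref <- mask_centroid(p$mask) - c((96 + 1) / 2, (96 + 1) / 2)
    ang <- abs(atan2(rot[2], rot[1]) - atan2(ref[2], ref[1])) * 180 / pi
    ang <- min(ang, 360 - ang)
    expect_gt(ang, 4)
    expect_lt(ang, 90)
  }
})

test_that("rescale crops or pads back to the patch size", {
  p <- fiber_pair()
  # factor 1.2 takes the central floor(96/1.2) = 80 region
  up <- fiberseg:::rescale_one(p$img, 1.2)
  expect_identical(dim(up), c(96L, 96L))
  crop <- p$img[8 + 1:80, 8 + 1:80]
  expect_equal(up, fiberseg:::resize_mat(crop, 96, 96), tolerance = 1e-12)
  expect_identical(fiberseg:::rescale_one(p$img, 1), p$img)
  set.seed(3)
  for (i in 1:10) {
    out <- random_rescale(p$img, p$mask)
    expect_identical(dim(out$image), c(96L, 96L))
    expect_identical(dim(out$mask), c(96L, 96L))
    expect_true(all(out$mask %in% 0:2))
  }
})

test_that("flips reflect both patches about the same axis", {
  p <- fiber_pair()
  set.seed(4)
  out <- random_flip(p$img, p$mask)
  # pixel multisets unchanged
  expect_identical(sort(as.vector(out$image)), sort(as.vector(p$img)))
  ctr <- mask_centroid(out$mask)
  ref <- mask_centroid(p$mask)
  flipped_row <- abs(ctr[1] - (96 + 1 - ref[1])) < 1e-6 && abs(ctr[2] - ref[2]) < 1e-6
  flipped_col <- abs(ctr[2] - (96 + 1 - ref[2])) < 1e-6 && abs(ctr[1] - ref[1]) < 1e-6
  expect_true(flipped_row || flipped_col)
  # flipping twice about one axis is the identity
  expect_identical(p$img[96:1, ][96:1, ], p$img)
})

test_that("blur smooths the image only and preserves constants", {
  p <- fiber_pair()
  expect_identical(fiberseg:::cpp_gaussian_blur(p$img, 0), p$img)
  blurred <- fiberseg:::cpp_gaussian_blur(p$img, 2)
  expect_lt(var(as.vector(blurred)), var(as.vector(p$img)))
  cst <- matrix(42, 32, 32)
  expect_equal(fiberseg:::cpp_gaussian_blur(cst, 3), cst, tolerance = 1e-12)
})

test_that("elastic deformation bounds displacement by alpha", {
  p <- fiber_pair()
  set.seed(5)
  # alpha forced to 0 gives the identity
  out0 <- elastic_deform(p$img, p$mask, alpha = 0)
  expect_equal(out0$image, p$img, tolerance = 1e-12)
  expect_identical(out0$mask, p$mask)
  # warping a coordinate ramp reveals the displacement field: the smoothed
  # fields are averages of values in [-1, 1] scaled by alpha
  ramp <- matrix(rep(seq_len(96), 96), 96, 96)
  for (a in c(2, 5)) {
    outr <- elastic_deform(ramp, p$mask, alpha = a)
    interior <- (a + 2):(96 - a - 1)
    expect_lte(max(abs(outr$image[interior, interior] -
                         ramp[interior, interior])), a + 1e-8)
    expect_true(all(outr$mask %in% 0:2))
  }
})

test_that("the augmentation chain is seeded, probabilistic, and joint", {
  p <- fiber_pair(64, center = c(22, 28), r_ax = 6, r_out = 9)
  spec0 <- augmentation_spec(p = 0)
  out0 <- augment(p$img, p$mask, spec0)
  expect_identical(out0$image, p$img)
  expect_identical(out0$mask, p$mask)
  # same seed, same output
  spec <- augmentation_spec(p = 0.5)
  set.seed(77)
  a1 <- augment(p$img, p$mask, spec)
  set.seed(77)
  a2 <- augment(p$img, p$mask, spec)
  expect_identical(a1, a2)
  expect_true(all(a1$mask %in% 0:2))
  # empirical per-transform application rate within 5 points of p
  set.seed(8)
  tiny <- fiber_pair(16, center = c(8, 8), r_ax = 3, r_out = 5)
  rates <- rowMeans(replicate(2500, augment(tiny$img, tiny$mask, spec)$applied))
  expect_true(all(abs(rates - 0.5) < 0.05))
  # image and mask centroids move together under the joint warps (blur off)
  spec_geom <- augmentation_spec(p = 1, blur_range = c(0, 0))
  set.seed(9)
  for (i in 1:5) {
    out <- augment(p$img, p$mask, spec_geom)
    if (sum(out$mask == 2L) < 20) next  # fiber mostly left the frame
    expect_lt(max(abs(image_blob_centroid(out$image) -
                        mask_centroid(out$mask))), 1.5)
  }
})
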