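test_that("fiber placement respects non-overlap and canvas bounds", {
  pop <- sample_population(50, canvas_size_um = 100, pixel_size = 0.1,
                           seed = 7)
  f <- pop$fibers
  expect_equal(nrow(f), 50L)
  r_out <- f$axon_diameter_um / (2 * f$g_ratio)
  # pairwise center distance at least the sum of outer radii
  d <- as.matrix(dist(f[, c("center_row_um", "center_col_um")]))
  sums <- outer(r_out, r_out, `+`)
  expect_true(all(d[upper.tri(d)] >= sums[upper.tri(sums)]))
  # fully inside the canvas
  expect_true(all(f$center_row_um - r_out >= 0 &
                  f$center_row_um + r_out <= 100))
  # determinism under the seed; single-fiber case trivially valid
  pop2 <- sample_population(50, canvas_size_um = 100, pixel_size = 0.1,
                            seed = 7)
  expect_identical(pop$fibers, pop2$fibers)
  expect_equal(nrow(sample_population(1, seed = 1)$fibers), 1L)
  # an impossible packing fails with a clear message
  expect_error(sample_population(500, canvas_size_um = 10, seed = 1,
                                 max_attempts = 50),
               "crowded")
})

test_that("rasterized disk and annulus areas match the analytic geometry", {
  pop <- structure(list(
    fibers = data.frame(center_row_um = 5, center_col_um = 5,
                        axon_diameter_um = 2, g_ratio = 1 / sqrt(2)),
    canvas_size_um = 10, pixel_size = 0.1), class = "fiber_population")
  mask <- rasterize(pop)
  ax_px <- sum(mask$classes == 2L)
  fib_px <- sum(mask$classes > 0L)
  expect_lt(abs(ax_px - pi * 10^2) / (pi * 10^2), 0.05)
  r_out_px <- (1 / (1 / sqrt(2))) * 10          # 14.14 px
  expect_lt(abs(fib_px - pi * r_out_px^2) / (pi * r_out_px^2), 0.05)
  # g -> 1: annulus thickness (and myelin pixel count) goes to ~0
  pop$fibers$g_ratio <- 0.999
  thin <- rasterize(pop)
  expect_lt(sum(thin$classes == 1L), 0.1 * sum(thin$classes == 2L))
  # empty population: all background
  pop$fibers <- pop$fibers[0, ]
  expect_true(all(rasterize(pop)$classes == 0L))
})

test_that("rendering paints class means, noise and blur as specified", {
  pop <- sample_population(10, canvas_size_um = 25.6, pixel_size = 0.1,
                           seed = 3)
  mask <- rasterize(pop)
  clean <- render(mask, render_spec("tem", noise_sd = 0, blur_sd = 0))
  expect_identical(sort(unique(as.vector(clean$pixels))), c(50, 130, 200))
  # noise SD recovered per class away from clip bounds
  noisy <- render(mask, render_spec("tem", noise_sd = 10, blur_sd = 0),
                  seed = 9)
  for (cls in 0:2) {
    s <- sd(noisy$pixels[mask$classes == cls])
    expect_lt(abs(s - 10) / 10, 0.15)
  }
  # seeded determinism
  expect_identical(render(mask, render_spec("tem"), seed = 4)$pixels,
                   render(mask, render_spec("tem"), seed = 4)$pixels)
  # SEM polarity renders myelin brighter than background, TEM darker
  sem <- render_spec("sem")
  expect_gt(sem$myelin, sem$background)
  tem <- render_spec("tem")
  expect_lt(tem$myelin, tem$background)
})

test_that("dataset generation writes paired files and a faithful truth table", {
  dir <- withr::local_tempdir()
  truth <- generate_dataset(dir, n_images = 3, n_fibers = 15,
                            canvas_size_um = 25.6, seed = 2)
  expect_length(list.files(dir, "^image_.*png$"), 3L)
  expect_length(list.files(dir, "^mask_.*png$"), 3L)
  expect_true(file.exists(file.path(dir, "fibers.tsv")))
  expect_equal(nrow(truth), 45L)
  # rerun with the same seed is byte-identical
  dir2 <- withr::local_tempdir()
  generate_dataset(dir2, n_images = 3, n_fibers = 15,
                   canvas_size_um = 25.6, seed = 2)
  expect_identical(unname(tools::md5sum(file.path(dir, "fibers.tsv"))),
                   unname(tools::md5sum(file.path(dir2, "fibers.tsv"))))
  # written masks decode to exactly the rasterized population
  m1 <- read_mask(file.path(dir, "mask_001.png"))
  expect_identical(sort(unique(as.vector(m1$classes))), c(0L, 1L, 2L))
  expect_equal(m1$pixel_size, 0.1)
})

test_that("generated g-ratios track the configured distribution", {
  dir <- withr::local_tempdir()
  truth <- generate_dataset(dir, n_images = 6, n_fibers = 60,
                            canvas_size_um = 102.4, seed = 11)
  # 360 draws from a truncated normal (mean 0.7, sd 0.05): the sample mean
  # stays within 0.01 of the configured mean
  expect_lt(abs(mean(truth$g_ratio) - 0.7), 0.01)
  expect_true(all(truth$g_ratio > 0.4 & truth$g_ratio < 0.95))
})
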