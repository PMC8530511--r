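# Signal-to-mask processing chain.

test_that("median filter: constants, hot voxels, and the sort oracle", {
  g <- make_grid(array(3, c(6, 6, 3)))
  expect_equal(median_filter(g)$values, g$values)

  hot <- array(0, c(7, 7, 3)); hot[4, 4, 2] <- 100
  mf <- median_filter(make_grid(hot), radius = c(1, 1, 1))
  expect_equal(max(mf$values), 0)

  set.seed(11)
  v <- array(runif(343), c(7, 7, 7))
  got <- median_filter(make_grid(v), radius = c(1, 1, 1))$values
  want <- brute_rank(v, se_offsets(c(1, 1, 1), "box"), median)
  expect_equal(got, want)
})

test_that("top-hat background subtraction removes ramps, keeps small blobs", {
  g <- make_grid(array(50, c(20, 20, 3)))
  expect_equal(max(subtract_background(g, c(3, 3, 0))$values), 0)

  # linear ramp: residual bounded by SE half-width times the gradient
  ramp <- add_noise_and_background(make_grid(array(0, c(40, 20, 3))),
                                   0, 39)   # gradient 1 per voxel
  th <- subtract_background(ramp, c(5, 5, 0))
  expect_lte(max(th$values), 5 + 1e-9)
  expect_true(all(th$values >= 0))
  expect_true(all(th$values <= ramp$values + 1e-12))

  # small bright blob (diameter < SE) on the ramp survives within 5%;
  # oracle: brute-force neighbourhood min-then-max opening on a small grid
  v <- ramp$values[1:25, , ]
  v[18:20, 9:11, 2] <- v[18:20, 9:11, 2] + 80
  g2 <- make_grid(v)
  out <- subtract_background(g2, c(4, 4, 0))
  expect_gt(max(out$values[, , 2]), 0.95 * 80)
  off <- se_offsets(c(4, 4, 0), "ellipsoid")
  opened <- brute_rank(brute_rank(v, off, min), off, max)
  oracle <- pmax(v - opened, 0)
  expect_equal(out$values, oracle)
})

test_that("median threshold implements the pooled-median cutoff rule", {
  v <- array(c(rep(0, 500), rep(100, 500)), c(10, 10, 10))
  m <- median_threshold(make_grid(v))
  expect_equal(attr(m, "cutoff"), 50)
  expect_equal(sum(m$values), 500)
  expect_true(all(m$values[v >= 50]))

  # all-equal positive grid: nothing is strictly below the median
  mc <- median_threshold(make_grid(array(7, c(5, 5, 2))))
  expect_true(all(mc$values))

  # the foreground fraction never exceeds half plus the tie mass
  set.seed(4)
  vr <- array(runif(4000), c(20, 20, 10))
  mr <- median_threshold(make_grid(vr))
  expect_lte(mean(mr$values), 0.5 + mean(vr == median(vr)) + 1e-9)
})

test_that("series pooling shares one cutoff; frame pooling does not", {
  g1 <- make_grid(array(c(rep(0, 200), rep(10, 800)), c(10, 10, 10)))
  g2 <- make_grid(array(c(rep(0, 800), rep(100, 200)), c(10, 10, 10)))
  series <- median_threshold(list(g1, g2), pool = "series")
  frames <- median_threshold(list(g1, g2), pool = "frame")
  expect_equal(attr(series[[1]], "cutoff"), attr(series[[2]], "cutoff"))
  expect_false(attr(frames[[1]], "cutoff") == attr(frames[[2]], "cutoff"))
})

test_that("thresholding a noisy shell phantom recovers the true mask", {
  sp <- phantom_spec(spacing = c(1, 1, 1), shell_mid_radius = 25,
                     shell_thickness_by_frame = 8, frame_times = 17,
                     angular_coverage = 1, noise_sd = 5,
                     background_ramp_amplitude = 0, seed = 2)
  ph <- generate_shell_stack(sp)
  m <- median_threshold(median_filter(ph$stacks[[1]]))
  truth <- ph$truth$clean_masks[[1]]$values
  recall <- sum(m$values & truth) / sum(truth)
  expect_gte(recall, 0.99)
})

test_that("grey-scale closing fills gaps and is idempotent", {
  g <- make_grid(array(4, c(8, 8, 3)))
  expect_equal(close_nuclei(g, c(1, 1, 0))$values, g$values)

  # two bright nuclei with a 2-voxel gap (< SE diameter) along x
  v <- array(0, c(20, 9, 3))
  v[5:8, 4:6, 2] <- 100; v[11:14, 4:6, 2] <- 100
  cl <- close_nuclei(make_grid(v), c(2, 2, 0), shape = "box")
  expect_equal(cl$values[9:10, 5, 2], c(100, 100))
  skip_if_not_installed("EBImage")
  # EBImage works on [0, 1] intensities; rescale for the oracle
  oracle <- EBImage::closing(v[, , 2] / 100, EBImage::makeBrush(5, "box"))
  expect_equal(cl$values[, , 2], 100 * unclass(oracle), ignore_attr = TRUE)

  cl2 <- close_nuclei(cl, c(2, 2, 0), shape = "box")
  expect_equal(cl2$values, cl$values)
})

test_that("hull prefilter: zeros, closing-like behaviour, order sensitivity", {
  z <- make_grid(array(0, c(10, 10, 3)))
  expect_equal(hull_prefilter(z)$values, z$values)

  # max-then-min at sigma 0 behaves like a closing: foreground superset
  v <- array(0, c(15, 15, 3)); v[4:6, 4:6, 2] <- 50; v[9:11, 9:11, 2] <- 50
  pf <- hull_prefilter(make_grid(v), max_radius = c(2, 2, 0), blur_sigma = 0,
                       min_radius = c(2, 2, 0))
  expect_true(all(pf$values[v > 0] > 0))
  skip_if_not_installed("EBImage")
  oracle <- EBImage::closing(v[, , 2] / 50, EBImage::makeBrush(5, "disc"))
  expect_equal(pf$values[, , 2], 50 * unclass(oracle), ignore_attr = TRUE)

  # permuting the max/blur/min order changes the result on two blobs
  g2 <- make_grid(v)
  a <- hull_prefilter(g2, c(2, 2, 0), 1, c(2, 2, 0))
  b <- grey_dilate(gaussian_blur(grey_erode(g2, se_offsets(c(2, 2, 0))), 1),
                   se_offsets(c(2, 2, 0)))
  expect_false(isTRUE(all.equal(a$values, b$values)))
})

test_that("every preprocessing op preserves geometry and spacing exactly", {
  g <- voxel_grid(array(runif(240, 1, 2), c(10, 8, 3)),
                  spacing = c(0.62, 0.62, 1.37), time = 18, origin = c(1, 2, 3))
  for (out in list(median_filter(g), subtract_background(g, c(2, 2, 0)),
                   close_nuclei(g, c(1, 1, 0)), hull_prefilter(g),
                   gaussian_blur(g, 1), median_threshold(g))) {
    expect_identical(dim(out$values), dim(g$values))
    expect_identical(out$spacing, g$spacing)
    expect_identical(out$origin, g$origin)
    expect_identical(out$time, g$time)
  }
  sb <- subtract_background(g, c(2, 2, 1))
  expect_true(all(sb$values >= 0) && all(sb$values <= g$values + 1e-12))
})
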