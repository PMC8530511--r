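# Tissue-scale metrics: volume, fitted-surface area, thickness, blocks,
# convex hull.

test_that("voxel volume is count times voxel size", {
  empty <- seg_mask(make_grid(array(0, c(5, 5, 2))), array(FALSE, c(5, 5, 2)))
  expect_equal(voxel_volume(empty), 0)

  fg <- array(FALSE, c(10, 10, 10)); fg[seq_len(1000)] <- TRUE
  m <- seg_mask(voxel_grid(array(0, c(10, 10, 10)),
                           spacing = c(0.62, 0.62, 1.37)), fg)
  expect_equal(voxel_volume(m), 1000 * 0.62 * 0.62 * 1.37)
})

test_that("digitized solid sphere volume matches the closed form within 1%", {
  ax <- seq(-21, 21, by = 0.5)
  r2 <- outer(outer(ax^2, ax^2, "+"), ax^2, "+")
  fg <- r2 <= 20^2
  m <- seg_mask(voxel_grid(array(0, dim(fg)), spacing = c(0.5, 0.5, 0.5)), fg)
  expect_lt(abs(voxel_volume(m) / (4 * pi / 3 * 20^3) - 1), 0.01)
})

test_that("surface fit recovers planes exactly", {
  # flat slab x = const over a 40 x 60 µm footprint
  fg <- array(FALSE, c(5, 41, 31)); fg[3, , ] <- TRUE
  m <- seg_mask(voxel_grid(array(0, c(5, 41, 31)), spacing = c(1, 1, 2)), fg)
  f <- fit_surface(m)
  expect_equal(f$area, 41 * 31 * 1 * 2)
  expect_equal(unname(f$coefficients[-1]), rep(0, 5), tolerance = 1e-8)
  expect_equal(f$rms, 0, tolerance = 1e-8)

  # tilted plane x = y: area = sqrt(2) x footprint
  fg2 <- array(FALSE, c(45, 41, 11))
  for (j in 1:41) fg2[j, j, ] <- TRUE
  m2 <- seg_mask(make_grid(array(0, c(45, 41, 11))), fg2)
  f2 <- fit_surface(m2)
  expect_equal(f2$area, sqrt(2) * 41 * 11, tolerance = 1e-8)
})

test_that("shallow spherical cap area matches the analytic cap formula", {
  # R = 100 µm, cap half-angle 20 deg, thin shell, opening along x
  R <- 100; theta <- 20 * pi / 180
  cov <- (1 - cos(theta)) / 2
  sp <- quiet_spec(spacing = c(0.8, 0.8, 0.8), shell_mid_radius = R,
                   shell_thickness_by_frame = 6, frame_times = 17,
                   angular_coverage = cov)
  ph <- generate_shell_stack(sp)
  f <- fit_surface(ph$truth$clean_masks[[1]])
  analytic <- 2 * pi * R^2 * (1 - cos(theta))
  expect_lt(abs(f$area / analytic - 1), 0.05)
  # quadrature check: triangulated mesh of the same fitted sheet
  mesh <- mesh_area_oracle(f, ph$truth$clean_masks[[1]])
  expect_lt(abs(f$area / mesh - 1), 0.01)
})

test_that("degenerate footprints are rejected as rank-deficient", {
  fg <- array(FALSE, c(5, 7, 7))
  fg[3, 4, ] <- TRUE   # single y column: quadratic in y unidentifiable
  m <- seg_mask(make_grid(array(0, c(5, 7, 7))), fg)
  expect_error(fit_surface(m), "distinct y|rank")
  fg2 <- array(FALSE, c(5, 7, 7)); fg2[3, 4, 4] <- TRUE
  expect_error(fit_surface(seg_mask(make_grid(array(0, c(5, 7, 7))), fg2)),
               ">= 6")
})

test_that("thickness is volume over surface, with guarded division", {
  expect_equal(tissue_thickness(100, 50), 2)
  expect_error(tissue_thickness(100, 0), "surface")
})

test_that("thickness is invariant under rigid translation of the mask", {
  sp <- quiet_spec(spacing = c(1, 1, 1), shell_mid_radius = 40,
                   shell_thickness_by_frame = 6, frame_times = 17)
  ph <- generate_shell_stack(sp)
  m <- ph$truth$clean_masks[[1]]
  th1 <- tissue_thickness(voxel_volume(m), fit_surface(m)$area)
  shifted <- m; shifted$origin <- m$origin + c(13.7, -8.1, 5.9)
  th2 <- tissue_thickness(voxel_volume(shifted), fit_surface(shifted)$area)
  expect_equal(th1, th2, tolerance = 1e-9)
})

test_that("pipeline thickness approaches truth for thin shells", {
  # t/R = 0.2, the stated validity edge of the volume/surface definition
  sp <- quiet_spec(spacing = c(1, 1, 1), shell_mid_radius = 60,
                   shell_thickness_by_frame = 12, frame_times = 17)
  ph <- generate_shell_stack(sp)
  m <- ph$truth$clean_masks[[1]]
  th <- tissue_thickness(voxel_volume(m), fit_surface(m)$area)
  expect_lt(abs(th / 12 - 1), 0.10)
})

test_that("block discretization partitions volume exactly", {
  # uniform bar spanning 70 x-columns: 7 equal blocks
  fg <- array(FALSE, c(70, 5, 3)); fg[, 2:4, ] <- TRUE
  m <- seg_mask(make_grid(array(0, c(70, 5, 3))), fg)
  part <- discretize_blocks(m, 7)
  vols <- vapply(part$masks, voxel_volume, 0)
  expect_equal(vols, rep(vols[1], 7))
  expect_equal(sum(vols), voxel_volume(m))

  # random blob: sums preserved and assignment matches per-voxel binning
  set.seed(8)
  fg2 <- array(runif(70 * 5 * 3) < 0.4, c(70, 5, 3))
  fg2[1, 1, 1] <- fg2[70, 5, 3] <- TRUE
  m2 <- seg_mask(make_grid(array(0, c(70, 5, 3))), fg2)
  part2 <- discretize_blocks(m2, 7)
  expect_equal(sum(vapply(part2$masks, voxel_volume, 0)), voxel_volume(m2))
  # exhaustive binning oracle over voxel x coordinates
  pts <- mask_coords(m2)
  brk <- part2$breaks
  oracle <- pmin(7, findInterval(pts[, 1], brk, rightmost.closed = TRUE))
  expect_identical(part2$assignment, as.integer(oracle))

  expect_error(discretize_blocks(m, 71), "fewer distinct x columns")
})

test_that("CMZ exclusion drops 0, 1 then 2 anterior blocks", {
  fg <- array(FALSE, c(70, 5, 3)); fg[, 2:4, ] <- TRUE
  m <- seg_mask(make_grid(array(0, c(70, 5, 3))), fg)
  part <- discretize_blocks(m, 7)
  times <- c(18, 20, 21)
  kept <- vapply(times, function(t) {
    p <- exclude_cmz_blocks(part, t, t_cmz = 20, frame_times = times)
    7 - length(p$excluded)
  }, 0)
  expect_equal(kept, c(7, 6, 5))
  # anterior is +x: the dropped block is the last one
  p20 <- exclude_cmz_blocks(part, 20, t_cmz = 20, frame_times = times)
  expect_equal(p20$excluded, 7L)
  p21m <- exclude_cmz_blocks(part, 21, t_cmz = 20, frame_times = times,
                             anterior = "-x")
  expect_equal(sort(p21m$excluded), c(1L, 2L))
  # excluding blocks never increases the retained whole-tissue volume
  tm_all <- tissue_metrics(m, part)
  tm_excl <- tissue_metrics(m, p20)
  expect_lte(tm_excl$volume_um3[1], tm_all$volume_um3[1])
})

test_that("convex hull volume matches analytic solids and scipy freeze", {
  fg <- array(FALSE, c(12, 12, 12)); fg[2:11, 2:11, 2:11] <- TRUE
  m <- seg_mask(make_grid(array(0, c(12, 12, 12))), fg)
  expect_equal(convex_hull_volume(m), 9^3)

  # voxelized tetrahedron with vertices (0,0,0)(60,0,0)(0,60,0)(0,0,60)
  n <- 61; co <- expand.grid(x = 0:60, y = 0:60, z = 0:60)
  fg2 <- array(FALSE, c(n, n, n))
  fg2[as.matrix(co[co$x + co$y + co$z <= 60, ]) + 1] <- TRUE
  m2 <- seg_mask(make_grid(array(0, c(n, n, n))), fg2)
  expect_lt(abs(convex_hull_volume(m2) / 36000 - 1), 0.03)

  # frozen oracle: scipy.spatial.ConvexHull volume for this exact point set
  set.seed(20)
  pts <- matrix(rnorm(180), ncol = 3) %*% diag(c(10, 6, 3))
  expect_equal(rpemorph:::convhull_volume_3d(pts), 5081.2126295153,
               tolerance = 1e-10)

  # degenerate (coplanar) foreground is an explicit error
  fg3 <- array(FALSE, c(6, 6, 6)); fg3[, , 3] <- TRUE
  expect_error(convex_hull_volume(seg_mask(make_grid(array(0, c(6, 6, 6))),
                                           fg3)), "coplanar|degenerate")
})

test_that("hull volume is at least the voxel volume, cavities included", {
  set.seed(5)
  for (rep in 1:3) {
    fg <- array(runif(20 * 18 * 8) < 0.1, c(20, 18, 8))
    fg[c(1, 20), 1, 1] <- TRUE; fg[1, 18, 8] <- TRUE; fg[20, 18, 1] <- TRUE
    m <- seg_mask(voxel_grid(array(0, c(20, 18, 8)),
                             spacing = c(0.62, 0.62, 1.37)), fg)
    expect_gte(convex_hull_volume(m) + 1e-9, voxel_volume(m))
  }
  # C-shaped cup: hull includes the cavity
  sp <- quiet_spec(spacing = c(2, 2, 2), frame_times = 17,
                   invagination_angle_by_frame = 100,
                   shell_thickness_by_frame = 10)
  cup <- generate_cup_sequence(sp)
  eye <- cup$truth$clean_masks[[1]]$eye
  expect_gt(convex_hull_volume(eye), voxel_volume(eye))
})
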