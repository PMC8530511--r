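# Synthetic phantom generators and their analytic ground truth.

test_that("degenerate zero-thickness shell is empty with zero truth volume", {
  sp <- quiet_spec(spacing = c(1, 1, 1), shell_mid_radius = 20,
                   shell_thickness_by_frame = 0, frame_times = 17,
                   angular_coverage = 1)
  ph <- generate_shell_stack(sp)
  expect_equal(sum(ph$stacks[[1]]$values), 0)
  expect_equal(ph$truth$true_volume, 0)
})

test_that("voxelized full-shell volume matches the closed form", {
  # R = 30, t = 10: analytic 4pi/3 (35^3 - 25^3)
  analytic <- 4 * pi / 3 * (35^3 - 25^3)
  sp <- quiet_spec(spacing = c(0.5, 0.5, 0.5), shell_mid_radius = 30,
                   shell_thickness_by_frame = 10, frame_times = 17,
                   angular_coverage = 1)
  ph <- generate_shell_stack(sp)
  expect_equal(ph$truth$true_volume, analytic)
  v <- voxel_volume(ph$truth$clean_masks[[1]])
  expect_lt(abs(v / analytic - 1), 0.02)

  # same shell at the anisotropic acquisition spacing: coarser, still close
  sp2 <- quiet_spec(spacing = c(0.62, 0.62, 1.37), shell_mid_radius = 30,
                    shell_thickness_by_frame = 10, frame_times = 17,
                    angular_coverage = 1)
  ph2 <- generate_shell_stack(sp2)
  v2 <- voxel_volume(ph2$truth$clean_masks[[1]])
  expect_lt(abs(v2 / analytic - 1), 0.10)
})

test_that("truth thickness equals volume/surface within the curvature factor", {
  for (tR in c(0.05, 0.1, 0.2, 0.3)) {
    R <- 60; t <- tR * R
    tr <- rpemorph:::shell_truth_frame(R, t, 0.03)
    ratio <- (tr$volume / tr$surface) / tr$thickness
    expect_lt(abs(ratio - 1), (t / (2 * R))^2 + 1e-6)
    tr_full <- rpemorph:::shell_truth_frame(R, t, 1)
    ratio_full <- (tr_full$volume / tr_full$surface) / tr_full$thickness
    expect_lt(abs(ratio_full - 1), (t / (2 * R))^2 + 1e-6)
  }
})

test_that("generators are bit-reproducible under a fixed seed", {
  sp <- phantom_spec(spacing = c(2, 2, 2), shell_mid_radius = 30,
                     shell_thickness_by_frame = c(8, 6), frame_times = c(17, 18),
                     angular_coverage = 1, noise_sd = 5,
                     background_ramp_amplitude = 10, seed = 42)
  a <- generate_shell_stack(sp)
  b <- generate_shell_stack(sp)
  expect_identical(lapply(a$stacks, `[[`, "values"),
                   lapply(b$stacks, `[[`, "values"))

  spn <- phantom_spec(n_nuclei = 30, labelled_fraction = 0.5, seed = 9,
                      noise_sd = 3)
  n1 <- generate_nuclei_stack(spn)
  n2 <- generate_nuclei_stack(spn)
  expect_identical(n1$stacks$total$values, n2$stacks$total$values)
  expect_identical(n1$truth$centres, n2$truth$centres)
})

test_that("a shell larger than an explicit image_shape is rejected", {
  sp <- quiet_spec(image_shape = c(10, 10, 10), spacing = c(1, 1, 1),
                   shell_mid_radius = 40, shell_thickness_by_frame = 10,
                   frame_times = 17, angular_coverage = 1)
  expect_error(generate_shell_stack(sp), "exceeds image bounds")
})

test_that("labelled-nucleus count is exactly round(fraction * n)", {
  for (f in c(0, 0.25, 0.49, 0.515, 0.70, 1)) {
    sp <- quiet_spec(n_nuclei = 40, labelled_fraction = f, seed = 3)
    nu <- generate_nuclei_stack(sp)
    expect_identical(nu$truth$n_labelled, round(f * 40))
    expect_identical(sum(nu$truth$labelled), as.integer(round(f * 40)))
    if (f == 0) expect_equal(max(nu$stacks$labelled$values), 0)
  }
})

test_that("nuclei placement fails loudly when the region cannot hold them", {
  sp <- quiet_spec(n_nuclei = 200, nucleus_radius = 4, spacing = c(1, 1, 1))
  box <- seg_mask(voxel_grid(array(0, c(20, 20, 10)), c(1, 1, 1)),
                  array(TRUE, c(20, 20, 10)))
  expect_error(generate_nuclei_stack(sp, region = box, max_tries = 2000),
               "region too small")
})

test_that("cup truth volumes lie exactly on the prescribed line", {
  sp <- quiet_spec(spacing = c(2, 2, 2), frame_times = seq(17, 22, 1),
                   invagination_angle_by_frame = seq(170, 90, length.out = 6),
                   shell_thickness_by_frame = 10,
                   eye_volume_start = 2e5, eye_volume_slope = 5.54e4)
  cup <- generate_cup_sequence(sp)
  fit <- fit_growth_slope(cup$truth$time, cup$truth$true_eye_volume,
                          c(17, 22))
  expect_equal(fit$slope, 5.54e4, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)

  # constant-volume sequence -> truth slope 0
  sp0 <- quiet_spec(spacing = c(2, 2, 2), frame_times = c(17, 18, 19),
                    invagination_angle_by_frame = c(150, 120, 100),
                    shell_thickness_by_frame = 8,
                    eye_volume_start = 2e5, eye_volume_slope = 0)
  cup0 <- generate_cup_sequence(sp0)
  expect_equal(diff(cup0$truth$true_eye_volume), c(0, 0))
})

test_that("a 180-degree frame is unfolded with collinear hinge points", {
  sp <- quiet_spec(spacing = c(2, 2, 2), frame_times = c(17, 18),
                   invagination_angle_by_frame = c(180, 120),
                   shell_thickness_by_frame = 8)
  cup <- generate_cup_sequence(sp)
  h <- cup$truth$hinge[[1]]
  expect_equal(cup$truth$true_angle[1], 180)
  expect_equal(invagination_angle(h$vertex, h$edges[1, ], h$edges[2, ]), 180)
  # angle rejection outside (0, 180]
  expect_error(quiet_spec(frame_times = 17,
                          invagination_angle_by_frame = 190),
               "angles")
})

test_that("noise/ramp model: identity, exact ramp field, seeded noise", {
  g <- make_grid(array(7, c(12, 8, 3)))
  expect_identical(add_noise_and_background(g, 0, 0)$values, g$values)

  r <- add_noise_and_background(make_grid(array(0, c(11, 8, 3))),
                                noise_sd = 0, ramp_amplitude = 20)
  # the added field is exactly linear along x: recompute it directly
  expected <- 20 * (0:10) / 10
  expect_equal(r$values[, 5, 2], expected)
  expect_equal(r$values[3, , ], array(expected[3], c(8, 3)))

  n1 <- add_noise_and_background(g, noise_sd = 4, ramp_amplitude = 0,
                                 seed = 77)
  n2 <- add_noise_and_background(g, noise_sd = 4, ramp_amplitude = 0,
                                 seed = 77)
  expect_identical(n1$values, n2$values)
  expect_true(all(n1$values >= 0))
})

test_that("phantom_spec validates its invariants", {
  expect_error(phantom_spec(frame_times = c(18, 17)), "increasing")
  expect_error(phantom_spec(labelled_fraction = 1.2), "labelled_fraction")
  expect_error(phantom_spec(spacing = c(0.62, 0, 1.37)), "spacing")
  expect_error(phantom_spec(shell_mid_radius = 10,
                            shell_thickness_by_frame = 30), "thickness")
})
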