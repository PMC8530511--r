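# Synthetic voxel phantoms with exact analytic ground truth.
#
# Three generators emulate the data the morphometric pipeline was designed
# for: a curved epithelial shell whose thickness/surface/volume follow
# prescribed trajectories (tissue-reporter channel), a folding cup with a
# defined invagination angle (tissue + whole-eye channels), and nuclear
# channels with a prescribed labelled fraction. Every generator returns the
# stacks plus a `phantom_truth` object carrying closed-form geometry, which
# downstream tests use as the oracle.

#' Phantom specification
#'
#' Collects every knob of the synthetic-stack generators, with defaults
#' chosen to emulate early zebrafish optic-vesicle recordings: voxel spacing
#' (0.62, 0.62, 1.37) µm, frame interval 0.5 hr from 17 to 21 hpf, shell
#' thickness declining linearly 24 to 8 µm, tissue amplitude 100 over a
#' background of Gaussian noise (sd 5) plus a linear intensity ramp
#' (amplitude 10) along x.
#'
#' @param image_shape Integer length-3 voxel counts, or `NULL` to size the
#'   grid automatically around the requested geometry.
#' @param spacing µm per voxel along (x, y, z).
#' @param shell_mid_radius Mid-surface radius R of the shell phantom (µm);
#'   scalar or one value per frame (a growing radius prescribes a growing
#'   surface area at constant angular coverage).
#'   The default is large relative to the thickest shell so that the
#'   volume/surface thickness definition (which assumes t << R) is valid
#'   over the whole trajectory.
#' @param shell_thickness_by_frame Shell thickness per frame (µm); recycled
#'   to the number of frames. A value of 0 produces an empty frame.
#' @param angular_coverage Fraction of the full sphere covered by the shell
#'   (0, 1]. Values <= 0.5 are realized as a cap; 1 is the full shell.
#' @param frame_times Strictly increasing frame times (hpf).
#' @param invagination_angle_by_frame Cup-phantom folding angle per frame
#'   (degrees in (0, 180]); `NULL` for shell/nuclei phantoms.
#' @param eye_volume_start,eye_volume_slope Whole-eye volume at the first
#'   frame (µm³) and its linear growth rate (µm³/hr) for the cup phantom.
#' @param cup_indent_ratio Radius of the invaginating (neural-retina) sphere
#'   relative to the eye radius.
#' @param n_nuclei,labelled_fraction,nucleus_radius Nuclei phantom: count,
#'   labelled proportion in [0, 1], and sphere radius (µm).
#' @param amplitude Foreground intensity before noise.
#' @param noise_sd,background_ramp_amplitude Gaussian noise sd and linear
#'   background ramp amplitude (intensity units) added by
#'   [add_noise_and_background()].
#' @param quantize Round intensities to integers (as integer-valued
#'   microscopy formats do) after noise addition.
#' @param flip_x Flip the anterior axis (the shell/cup opening faces +x by
#'   default).
#' @param seed Integer seed making every stochastic component reproducible.
#'
#' @return A validated list of class `phantom_spec`.
#' @export
phantom_spec <- function(image_shape = NULL,
                         spacing = c(0.62, 0.62, 1.37),
                         shell_mid_radius = 120,
                         shell_thickness_by_frame = seq(24, 8, length.out = 9),
                         angular_coverage = 0.03,
                         frame_times = seq(17, 21, by = 0.5),
                         invagination_angle_by_frame = NULL,
                         eye_volume_start = 2e5,
                         eye_volume_slope = 5.54e4,
                         cup_indent_ratio = 0.8,
                         n_nuclei = 200,
                         labelled_fraction = 0.49,
                         nucleus_radius = 3,
                         amplitude = 100,
                         noise_sd = 5,
                         background_ramp_amplitude = 10,
                         quantize = TRUE,
                         flip_x = FALSE,
                         seed = 1L) {
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("spacing must be 3 strictly positive values", call. = FALSE)
  frame_times <- as.numeric(frame_times)
  if (length(frame_times) < 1L || is.unsorted(frame_times, strictly = TRUE))
    stop("frame_times must be strictly increasing", call. = FALSE)
  th <- rep_len(as.numeric(shell_thickness_by_frame), length(frame_times))
  shell_mid_radius <- rep_len(as.numeric(shell_mid_radius),
                              length(frame_times))
  if (any(th < 0)) stop("shell thickness must be >= 0", call. = FALSE)
  if (any(th >= 2 * shell_mid_radius))
    stop("shell thickness must be < 2 * shell_mid_radius", call. = FALSE)
  if (angular_coverage <= 0 || angular_coverage > 1)
    stop("angular_coverage must be in (0, 1]", call. = FALSE)
  if (labelled_fraction < 0 || labelled_fraction > 1)
    stop("labelled_fraction must be in [0, 1]", call. = FALSE)
  if (!is.null(invagination_angle_by_frame)) {
    a <- rep_len(as.numeric(invagination_angle_by_frame), length(frame_times))
    if (any(a <= 0 | a > 180))
      stop("invagination angles must be in (0, 180] degrees", call. = FALSE)
    invagination_angle_by_frame <- a
  }
  if (!is.null(image_shape)) {
    image_shape <- as.integer(image_shape)
    if (length(image_shape) != 3L || any(image_shape < 1L))
      stop("image_shape must be 3 positive integers", call. = FALSE)
  }
  if (n_nuclei < 1) stop("n_nuclei must be >= 1", call. = FALSE)
  structure(list(
    image_shape = image_shape, spacing = spacing,
    shell_mid_radius = shell_mid_radius,
    shell_thickness_by_frame = th,
    angular_coverage = angular_coverage,
    frame_times = frame_times,
    invagination_angle_by_frame = invagination_angle_by_frame,
    eye_volume_start = eye_volume_start,
    eye_volume_slope = eye_volume_slope,
    cup_indent_ratio = cup_indent_ratio,
    n_nuclei = as.integer(n_nuclei),
    labelled_fraction = labelled_fraction,
    nucleus_radius = nucleus_radius,
    amplitude = amplitude, noise_sd = noise_sd,
    background_ramp_amplitude = background_ramp_amplitude,
    quantize = isTRUE(quantize), flip_x = isTRUE(flip_x),
    seed = as.integer(seed)), class = "phantom_spec")
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf("<phantom_spec> %d frame(s) %g-%g hpf, spacing (%g, %g, %g) µm, seed %d\n",
              length(x$frame_times), min(x$frame_times), max(x$frame_times),
              x$spacing[1], x$spacing[2], x$spacing[3], x$seed))
  invisible(x)
}

# ---- analytic geometry helpers ------------------------------------------

# Volume of the upper (single-graph) part of a ball of radius s inside the
# coaxial cylinder rho <= a: integral over the disk of sqrt(s^2 - rho^2).
cap_cyl_volume <- function(s, a) {
  if (s <= 0) return(0)
  (2 * pi / 3) * (s^3 - max(s^2 - a^2, 0)^1.5)
}

# Spherical-cap area of a sphere radius R cut by the cylinder rho <= a.
cap_area <- function(R, a) 2 * pi * R * (R - sqrt(max(R^2 - a^2, 0)))

# Sphere-sphere overlap (lens) volume; radii s, ri at centre distance d.
lens_volume <- function(s, ri, d) {
  if (s <= 0 || ri <= 0 || d >= s + ri) return(0)
  if (d <= abs(s - ri)) return((4 * pi / 3) * min(s, ri)^3)
  pi * (s + ri - d)^2 *
    (d^2 + 2 * d * ri - 3 * ri^2 + 2 * d * s + 6 * ri * s - 3 * s^2) /
    (12 * d)
}

# Shell truth for one frame: exact volume and mid-surface area.
shell_truth_frame <- function(R, t, coverage) {
  if (t <= 0) return(list(volume = 0, surface = 0, thickness = 0))
  h <- t / 2
  if (coverage >= 1) {
    vol <- (4 * pi / 3) * ((R + h)^3 - (R - h)^3)
    surf <- 4 * pi * R^2
  } else if (coverage <= 0.5) {
    theta <- acos(1 - 2 * coverage)
    a <- R * sin(theta)
    vol <- cap_cyl_volume(R + h, a) - cap_cyl_volume(R - h, a)
    surf <- cap_area(R, a)
  } else {
    # steep partial shells: cone cut at the stated solid angle
    vol <- coverage * (4 * pi / 3) * ((R + h)^3 - (R - h)^3)
    surf <- coverage * 4 * pi * R^2
  }
  list(volume = vol, surface = surf, thickness = t)
}

# ---- shell phantom -------------------------------------------------------

#' Generate a time series of shell phantoms
#'
#' Renders, per frame, a partial spherical shell (mid-radius R, thickness t,
#' concave opening facing +x) at the requested anisotropic spacing. For
#' coverage <= 0.5 the cap is cut by the coaxial cylinder of radius
#' `R * sin(theta)`, so the mid-surface is exactly a graph over (y, z) — the
#' geometry the fitted-surface area estimator assumes — and the truth volume
#' and mid-surface area are exact closed forms. Noise and a background ramp
#' are added when the spec requests them.
#'
#' @param spec A [phantom_spec()].
#' @return List with `stacks` (list of tissue-channel [voxel_grid()]s, one
#'   per frame) and `truth` (a `phantom_truth` with per-frame
#'   `true_volume`, `true_surface`, `true_thickness` and the clean masks).
#' @export
generate_shell_stack <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  Rv <- spec$shell_mid_radius
  cov <- spec$angular_coverage
  th <- spec$shell_thickness_by_frame
  margin <- 4

  theta <- if (cov < 1) acos(1 - 2 * min(cov, 0.5)) else pi
  outer_r <- Rv + th / 2
  if (cov >= 1) {
    lo <- rep(-max(outer_r) - margin, 3)
    hi <- rep(max(outer_r) + margin, 3)
  } else {
    a <- Rv * sin(theta)
    # opening faces +x: apex (most negative x) at -(R + h)
    xlow <- sqrt(pmax((Rv - th / 2)^2 - a^2, 0))
    lo <- c(-max(outer_r) - margin, -max(a) - margin, -max(a) - margin)
    hi <- c(-min(xlow) + margin, max(a) + margin, max(a) + margin)
  }
  geom <- phantom_grid_geometry(spec, lo, hi)

  ax <- list(x = geom$origin[1] + (seq_len(geom$shape[1]) - 1) * spec$spacing[1],
             y = geom$origin[2] + (seq_len(geom$shape[2]) - 1) * spec$spacing[2],
             z = geom$origin[3] + (seq_len(geom$shape[3]) - 1) * spec$spacing[3])

  r2 <- outer(outer(ax$x^2, ax$y^2, "+"), ax$z^2, "+")
  rho2 <- outer(outer(rep(0, length(ax$x)), ax$y^2, "+"), ax$z^2, "+")
  xcube <- array(ax$x, dim = geom$shape)

  stacks <- vector("list", length(th))
  frames <- vector("list", length(th))
  tv <- ts <- tt <- numeric(length(th))
  for (i in seq_along(th)) {
    t_i <- th[i]
    R <- Rv[i]
    h <- t_i / 2
    if (t_i <= 0) {
      fg <- array(FALSE, geom$shape)
    } else if (cov >= 1) {
      fg <- r2 >= (R - h)^2 & r2 <= (R + h)^2
    } else if (cov <= 0.5) {
      a <- R * sin(acos(1 - 2 * cov))
      fg <- r2 >= (R - h)^2 & r2 <= (R + h)^2 & rho2 <= a^2 & xcube <= 0
    } else {
      cos_th <- 1 - 2 * cov
      r <- sqrt(r2)
      fg <- r2 >= (R - h)^2 & r2 <= (R + h)^2 & (-xcube / pmax(r, 1e-12)) >= cos_th
    }
    tr <- shell_truth_frame(R, t_i, cov)
    tv[i] <- tr$volume; ts[i] <- tr$surface; tt[i] <- tr$thickness

    vals <- array(0, geom$shape)
    vals[fg] <- spec$amplitude
    if (spec$flip_x) {
      vals <- vals[rev(seq_len(geom$shape[1])), , , drop = FALSE]
      fg <- fg[rev(seq_len(geom$shape[1])), , , drop = FALSE]
    }
    g <- voxel_grid(vals, spec$spacing, time = spec$frame_times[i],
                    channel = "tissue", origin = geom$origin)
    g <- maybe_corrupt(g, spec, frame_seed(spec$seed, i))
    stacks[[i]] <- g
    frames[[i]] <- seg_mask(g, fg)
  }
  truth <- structure(list(
    kind = "shell",
    time = spec$frame_times,
    true_volume = tv, true_surface = ts, true_thickness = tt,
    clean_masks = frames, spec = spec), class = "phantom_truth")
  list(stacks = stacks, truth = truth)
}

# shared grid-geometry resolution (auto-shape unless the spec fixes one)
phantom_grid_geometry <- function(spec, lo, hi) {
  if (is.null(spec$image_shape)) {
    shape <- pmax(2L, as.integer(ceiling((hi - lo) / spec$spacing)) + 1L)
  } else {
    shape <- spec$image_shape
    # centre the requested physical window inside the fixed grid
    span <- (shape - 1L) * spec$spacing
    need <- hi - lo
    if (any(span < need - 1e-9))
      stop("requested geometry exceeds image bounds (",
           paste(shape, collapse = "x"), " voxels too small)", call. = FALSE)
    lo <- lo - (span - need) / 2
  }
  list(shape = shape, origin = lo)
}

frame_seed <- function(seed, i) (seed * 1000L + i) %% .Machine$integer.max

maybe_corrupt <- function(g, spec, seed) {
  if (spec$noise_sd > 0 || spec$background_ramp_amplitude > 0 ||
      spec$quantize) {
    g <- add_noise_and_background(g, noise_sd = spec$noise_sd,
                                  ramp_amplitude = spec$background_ramp_amplitude,
                                  seed = seed, quantize = spec$quantize)
  }
  g
}

# ---- cup phantom ---------------------------------------------------------

# Scale-free cup shape: unit eye sphere indented by a sphere of radius k at
# centre distance delta on the +x axis. Returns the invagination angle at
# the basal vertex and the unit eye volume.
cup_unit_shape <- function(delta, k) {
  xc <- (delta^2 + 1 - k^2) / (2 * delta)
  yc <- sqrt(max(1 - xc^2, 0))
  vx <- delta - k
  angle <- 2 * atan2(yc, xc - vx) * 180 / pi
  vol <- 4 * pi / 3 - lens_volume(1, k, delta)
  list(angle = angle, volume = vol, xc = xc, yc = yc, vx = vx)
}

solve_cup_delta <- function(alpha, k) {
  f <- function(d) cup_unit_shape(d, k)$angle - alpha
  lo <- abs(1 - k) + 1e-6
  hi <- 1 + k - 1e-9
  # angle -> 180 as the indentation vanishes (d -> 1 + k); deepens as d drops
  stats::uniroot(f, c(lo, hi), tol = 1e-10)$root
}

#' Generate a folding-cup phantom sequence (tissue + whole-eye channels)
#'
#' The whole-eye channel is a solid sphere indented by a second sphere from
#' the +x side; the indentation depth is solved so that the basal
#' invagination angle matches `invagination_angle_by_frame`, and the eye
#' radius is solved so that the analytic eye volume lies exactly on the line
#' `eye_volume_start + eye_volume_slope * (t - t0)`. The tissue channel is
#' the outer shell of the eye with the spec's per-frame thickness. A frame
#' at 180 degrees renders the pre-folding stage as an unindented sphere with
#' collinear hinge points.
#'
#' @param spec A [phantom_spec()] with `invagination_angle_by_frame` set.
#' @return List with `stacks` (per frame, list of `tissue` and `eye`
#'   [voxel_grid()]s) and `truth` (per-frame angle, eye and tissue volumes,
#'   hinge-point triples, clean masks).
#' @export
generate_cup_sequence <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (is.null(spec$invagination_angle_by_frame))
    stop("cup phantom needs invagination_angle_by_frame", call. = FALSE)
  alphas <- spec$invagination_angle_by_frame
  k <- spec$cup_indent_ratio
  times <- spec$frame_times
  th <- spec$shell_thickness_by_frame
  v_target <- spec$eye_volume_start +
    spec$eye_volume_slope * (times - times[1])
  if (any(v_target <= 0)) stop("eye volume trajectory must stay positive",
                               call. = FALSE)

  # solve per-frame geometry first so the grid can hold every frame
  geo <- lapply(seq_along(times), function(i) {
    if (alphas[i] >= 180 - 1e-9) {
      re <- (3 * v_target[i] / (4 * pi))^(1 / 3)
      list(alpha = 180, re = re, ri = 0, d = Inf,
           vertex = c(re, 0, 0), edges = rbind(c(re, re / 2, 0),
                                               c(re, -re / 2, 0)))
    } else {
      delta <- solve_cup_delta(alphas[i], k)
      sh <- cup_unit_shape(delta, k)
      re <- (v_target[i] / sh$volume)^(1 / 3)
      list(alpha = alphas[i], re = re, ri = k * re, d = delta * re,
           vertex = c(sh$vx * re, 0, 0),
           edges = rbind(c(sh$xc * re, sh$yc * re, 0),
                         c(sh$xc * re, -sh$yc * re, 0)))
    }
  })
  re_max <- max(vapply(geo, function(g) g$re, 0))
  margin <- 4
  geom <- phantom_grid_geometry(spec, rep(-re_max - margin, 3),
                                rep(re_max + margin, 3))
  ax <- list(x = geom$origin[1] + (seq_len(geom$shape[1]) - 1) * spec$spacing[1],
             y = geom$origin[2] + (seq_len(geom$shape[2]) - 1) * spec$spacing[2],
             z = geom$origin[3] + (seq_len(geom$shape[3]) - 1) * spec$spacing[3])
  r2 <- outer(outer(ax$x^2, ax$y^2, "+"), ax$z^2, "+")

  stacks <- vector("list", length(times))
  masks <- vector("list", length(times))
  eye_v <- tis_v <- numeric(length(times))
  for (i in seq_along(times)) {
    g <- geo[[i]]
    in_eye_ball <- r2 <= g$re^2
    if (is.finite(g$d)) {
      di2 <- outer(outer((ax$x - g$d)^2, ax$y^2, "+"), ax$z^2, "+")
      in_indent <- di2 < g$ri^2
    } else {
      in_indent <- array(FALSE, geom$shape)
    }
    eye_fg <- in_eye_ball & !in_indent
    t_i <- th[i]
    tis_fg <- eye_fg & r2 >= (g$re - t_i)^2

    eye_v[i] <- v_target[i]
    tis_v[i] <- (4 * pi / 3) * (g$re^3 - max(g$re - t_i, 0)^3) -
      (lens_volume(g$re, g$ri, g$d) -
         lens_volume(max(g$re - t_i, 0), g$ri, g$d))

    mk <- function(fg, channel) {
      vals <- array(0, geom$shape)
      vals[fg] <- spec$amplitude
      gg <- voxel_grid(vals, spec$spacing, time = times[i],
                       channel = channel, origin = geom$origin)
      maybe_corrupt(gg, spec, frame_seed(spec$seed, i * 2L +
                                           (channel == "eye")))
    }
    eg <- mk(eye_fg, "eye")
    tg <- mk(tis_fg, "tissue")
    stacks[[i]] <- list(tissue = tg, eye = eg)
    masks[[i]] <- list(tissue = seg_mask(tg, tis_fg),
                       eye = seg_mask(eg, eye_fg))
  }
  truth <- structure(list(
    kind = "cup", time = times,
    true_angle = vapply(geo, function(g) g$alpha, 0),
    true_eye_volume = eye_v, true_tissue_volume = tis_v,
    eye_volume_slope = spec$eye_volume_slope,
    hinge = lapply(geo, function(g) list(vertex = g$vertex,
                                         edges = g$edges)),
    clean_masks = masks, spec = spec), class = "phantom_truth")
  list(stacks = stacks, truth = truth)
}

# ---- nuclei phantom ------------------------------------------------------

#' Generate a two-channel nuclei phantom (total + labelled)
#'
#' Places `n_nuclei` non-overlapping spheres (hard-core separation of one
#' diameter plus a small guard gap so digitized nuclei never touch) inside a
#' region mask, then copies exactly `round(labelled_fraction * n_nuclei)` of
#' them — a seeded random subset — into the labelled channel, emulating
#' BrdU/Ki67 co-staining over a nuclear counterstain.
#'
#' @param spec A [phantom_spec()].
#' @param region Optional [seg_mask()] restricting nucleus centres; default
#'   is the whole (auto-sized) grid inset by one nucleus radius.
#' @param max_tries Total rejection-sampling budget before giving up.
#' @return List with `stacks` (`total` and `labelled` [voxel_grid()]s),
#'   and `truth` (centre coordinates, labelled flags, counts, region mask).
#' @export
generate_nuclei_stack <- function(spec, region = NULL, max_tries = NULL) {
  stopifnot(inherits(spec, "phantom_spec"))
  n <- spec$n_nuclei
  r <- spec$nucleus_radius
  sep <- 2 * r + 2 * max(spec$spacing)   # guard gap: no digitized contact
  if (is.null(max_tries)) max_tries <- 2000L * n

  if (is.null(region)) {
    # size the box for ~4x the packed nucleus volume
    side <- max(4 * r + 2, ((4 * n * (2 * r + 2)^3))^(1 / 3))
    lo <- rep(0, 3)
    hi <- rep(side, 3)
    geom <- phantom_grid_geometry(spec, lo, hi)
    template <- voxel_grid(array(0, geom$shape), spec$spacing,
                           time = spec$frame_times[1], channel = "nuclei",
                           origin = geom$origin)
    region <- seg_mask(template, array(TRUE, geom$shape))
  } else {
    stopifnot(inherits(region, "seg_mask"))
    template <- with_values(region, array(0, dim(region$values)))
    class(template) <- "voxel_grid"
  }
  ax <- voxel_axes(template)
  bounds <- rbind(range(ax$x), range(ax$y), range(ax$z))

  old_seed <- save_rng()
  on.exit(restore_rng(old_seed), add = TRUE)
  set.seed(spec$seed)

  centres <- matrix(NA_real_, n, 3)
  placed <- 0L
  tries <- 0L
  while (placed < n) {
    if (tries >= max_tries)
      stop(sprintf("could not place %d nuclei after %d tries; region too small",
                   n, max_tries), call. = FALSE)
    tries <- tries + 1L
    p <- bounds[, 1] + runif(3) * (bounds[, 2] - bounds[, 1])
    # keep whole sphere inside grid and centre inside region
    if (any(p - r < bounds[, 1]) || any(p + r > bounds[, 2])) next
    ijk <- pmin(pmax(round((p - template$origin) / template$spacing) + 1, 1),
                dim(template$values))
    if (!region$values[ijk[1], ijk[2], ijk[3]]) next
    if (placed > 0L) {
      d2 <- colSums((t(centres[seq_len(placed), , drop = FALSE]) - p)^2)
      if (any(d2 < sep^2)) next
    }
    placed <- placed + 1L
    centres[placed, ] <- p
  }

  m <- round(spec$labelled_fraction * n)
  labelled <- rep(FALSE, n)
  if (m > 0) labelled[sample.int(n, m)] <- TRUE

  rasterize <- function(which_nuclei) {
    vals <- array(0, dim(template$values))
    for (j in which_nuclei) {
      p <- centres[j, ]
      i0 <- pmax(1L, floor((p - r - template$origin) / template$spacing) + 1L)
      i1 <- pmin(dim(template$values),
                 ceiling((p + r - template$origin) / template$spacing) + 1L)
      xs <- ax$x[i0[1]:i1[1]]; ys <- ax$y[i0[2]:i1[2]]; zs <- ax$z[i0[3]:i1[3]]
      d2 <- outer(outer((xs - p[1])^2, (ys - p[2])^2, "+"), (zs - p[3])^2, "+")
      sub <- vals[i0[1]:i1[1], i0[2]:i1[2], i0[3]:i1[3], drop = FALSE]
      sub[d2 <= r^2] <- spec$amplitude
      vals[i0[1]:i1[1], i0[2]:i1[2], i0[3]:i1[3]] <- sub
    }
    vals
  }
  total_vals <- rasterize(seq_len(n))
  lab_vals <- rasterize(which(labelled))
  total <- voxel_grid(total_vals, spec$spacing, time = spec$frame_times[1],
                      channel = "nuclei_total", origin = template$origin)
  lab <- voxel_grid(lab_vals, spec$spacing, time = spec$frame_times[1],
                    channel = "nuclei_labelled", origin = template$origin)
  total <- maybe_corrupt(total, spec, frame_seed(spec$seed, 101L))
  lab <- maybe_corrupt(lab, spec, frame_seed(spec$seed, 102L))

  truth <- structure(list(
    kind = "nuclei",
    centres = centres, labelled = labelled,
    n_total = n, n_labelled = m,
    labelled_fraction = spec$labelled_fraction,
    region = region, spec = spec), class = "phantom_truth")
  list(stacks = list(total = total, labelled = lab), truth = truth)
}

#' @export
print.phantom_truth <- function(x, ...) {
  cat(sprintf("<phantom_truth: %s>\n", x$kind))
  if (x$kind == "shell") {
    cat(sprintf("  %d frames; thickness %g -> %g µm\n",
                length(x$time), x$true_thickness[1],
                x$true_thickness[length(x$time)]))
  } else if (x$kind == "cup") {
    cat(sprintf("  %d frames; angle %g -> %g deg; eye slope %g µm³/hr\n",
                length(x$time), x$true_angle[1],
                x$true_angle[length(x$time)], x$eye_volume_slope))
  } else {
    cat(sprintf("  %d nuclei, %d labelled (%.1f%%)\n", x$n_total,
                x$n_labelled, 100 * x$n_labelled / x$n_total))
  }
  invisible(x)
}

# ---- noise model ---------------------------------------------------------

save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
restore_rng <- function(seed) {
  if (!is.null(seed)) assign(".Random.seed", seed, envir = globalenv())
}

#' Add a background ramp and Gaussian noise to a grid
#'
#' Adds a smooth linear intensity ramp along x (from 0 at the first plane to
#' `ramp_amplitude` at the last) plus i.i.d. Gaussian noise, then clips at
#' zero; optionally rounds to integer intensities as integer-valued
#' microscopy formats do. Deterministic under `seed`; the caller's RNG state
#' is left untouched.
#'
#' @param grid A [voxel_grid()].
#' @param noise_sd Gaussian noise standard deviation (intensity units).
#' @param ramp_amplitude Ramp amplitude (intensity units).
#' @param seed Integer seed.
#' @param quantize Round the result to integers.
#' @return A [voxel_grid()] of identical geometry.
#' @export
add_noise_and_background <- function(grid, noise_sd = 0, ramp_amplitude = 0,
                                     seed = 1L, quantize = FALSE) {
  stopifnot(inherits(grid, "voxel_grid"))
  if (noise_sd < 0 || ramp_amplitude < 0)
    stop("noise_sd and ramp_amplitude must be non-negative", call. = FALSE)
  d <- dim(grid$values)
  v <- grid$values
  if (ramp_amplitude > 0 && d[1] > 1) {
    ramp <- ramp_amplitude * (seq_len(d[1]) - 1) / (d[1] - 1)
    v <- v + array(ramp, dim = d)   # recycles along x, the first axis
  }
  if (noise_sd > 0) {
    old_seed <- save_rng()
    on.exit(restore_rng(old_seed), add = TRUE)
    set.seed(seed)
    v <- v + array(rnorm(length(v), sd = noise_sd), dim = d)
  }
  v <- pmax(v, 0)
  if (quantize) v <- round(v)
  with_values(grid, v)
}
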