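# Tissue-scale morphometrics: voxel-count volume, fitted-surface area,
# volume/surface thickness, anterior-posterior block decomposition with
# CMZ exclusion, and convex-hull whole-eye volume.

#' Tissue volume from a segmentation mask
#'
#' Volume (µm³) is the number of foreground voxels times the physical voxel
#' size — the voxel-count definition used for reporter-signal volumes.
#'
#' @param mask A [seg_mask()].
#' @return Volume in µm³.
#' @export
voxel_volume <- function(mask) {
  stopifnot(inherits(mask, "seg_mask"))
  sum(mask$values) * voxel_size(mask)
}

#' Quadratic surface fit and fitted-surface area
#'
#' Regresses the depth coordinate x on a full second-order polynomial in
#' (y, z) over the foreground voxel centres (physical µm) — the
#' "second-order adjustment on the YZ plane", the plane of the optic-cup
#' hinges. The tissue surface area is the graph area of the fitted sheet
#' over the mask's (y, z) footprint:
#' `sum over footprint columns of sqrt(1 + fy^2 + fz^2) * sy * sz`.
#'
#' @param mask A [seg_mask()] with at least 6 foreground voxels spanning at
#'   least 2 distinct y and z values.
#' @return An object of class `surface_fit`: quadratic `coefficients`
#'   (1, y, z, y², yz, z²), `area` (µm²), `rms` residual (µm), and the
#'   footprint column count.
#' @export
fit_surface <- function(mask) {
  stopifnot(inherits(mask, "seg_mask"))
  pts <- mask_coords(mask)
  if (nrow(pts) < 6)
    stop("surface fit needs >= 6 foreground voxels", call. = FALSE)
  if (length(unique(pts[, 2])) < 2 || length(unique(pts[, 3])) < 2)
    stop("surface fit needs >= 2 distinct y and z values", call. = FALSE)
  X <- cbind(1, pts[, 2], pts[, 3], pts[, 2]^2, pts[, 2] * pts[, 3],
             pts[, 3]^2)
  qrX <- qr(X)
  if (qrX$rank < 6L)
    stop("degenerate footprint: quadratic surface fit is rank-deficient",
         call. = FALSE)
  beta <- qr.coef(qrX, pts[, 1])
  resid <- pts[, 1] - X %*% beta

  # footprint: (y, z) columns of the z-projection holding any foreground
  proj <- apply(mask$values, c(2, 3), any)
  ax <- voxel_axes(mask)
  cols <- which(proj, arr.ind = TRUE)
  yy <- ax$y[cols[, 1]]
  zz <- ax$z[cols[, 2]]
  fy <- beta[2] + 2 * beta[4] * yy + beta[5] * zz
  fz <- beta[3] + beta[5] * yy + 2 * beta[6] * zz
  area <- sum(sqrt(1 + fy^2 + fz^2)) * mask$spacing[2] * mask$spacing[3]

  structure(list(
    coefficients = setNames(as.numeric(beta),
                            c("1", "y", "z", "y2", "yz", "z2")),
    area = area,
    rms = sqrt(mean(resid^2)),
    n_columns = nrow(cols),
    n_voxels = nrow(pts),
    spacing = mask$spacing), class = "surface_fit")
}

#' @export
print.surface_fit <- function(x, ...) {
  cat(sprintf("<surface_fit> area %.4g µm² over %d columns, residual RMS %.3g µm\n",
              x$area, x$n_columns, x$rms))
  invisible(x)
}

#' Mean tissue thickness as volume / surface
#'
#' The operational thickness of a curved epithelial sheet: tissue volume
#' divided by its fitted surface area. Exact for a flat slab and accurate
#' to second order in (t / 2R) for a curved shell of thickness t and radius
#' R.
#'
#' @param volume Tissue volume (µm³).
#' @param surface Fitted surface area (µm²), strictly positive.
#' @return Thickness in µm.
#' @export
tissue_thickness <- function(volume, surface) {
  if (any(surface <= 0))
    stop("thickness is undefined for surface <= 0", call. = FALSE)
  volume / surface
}

#' Split a mask into equal-width anterior-posterior blocks
#'
#' The x extent of the z-projected foreground bounding box is divided into
#' `n_blocks` contiguous equal-width intervals; every foreground voxel is
#' assigned to a block by its x coordinate. Block volumes sum exactly to
#' the whole-tissue volume.
#'
#' @param mask A non-empty [seg_mask()].
#' @param n_blocks Number of blocks (7 in the reference analysis).
#' @return An object of class `block_partition`: `breaks` (µm, length
#'   n_blocks + 1), per-block [seg_mask()]s in `masks`, the block
#'   `assignment` of each foreground voxel, and `excluded` (empty until
#'   [exclude_cmz_blocks()] marks blocks).
#' @export
discretize_blocks <- function(mask, n_blocks = 7L) {
  stopifnot(inherits(mask, "seg_mask"), n_blocks >= 1L)
  pts <- mask_coords(mask)
  if (nrow(pts) == 0) stop("cannot partition an empty mask", call. = FALSE)
  xs <- pts[, 1]
  if (length(unique(xs)) < n_blocks)
    stop(sprintf("fewer distinct x columns (%d) than blocks (%d)",
                 length(unique(xs)), n_blocks), call. = FALSE)
  rng <- range(xs)
  breaks <- seq(rng[1], rng[2], length.out = n_blocks + 1L)
  w <- diff(rng) / n_blocks
  bin <- pmin(n_blocks, floor((xs - rng[1]) / w) + 1L)

  idx <- which(mask$values, arr.ind = TRUE)
  masks <- lapply(seq_len(n_blocks), function(b) {
    fg <- array(FALSE, dim(mask$values))
    fg[idx[bin == b, , drop = FALSE]] <- TRUE
    seg_mask(mask, fg)
  })
  structure(list(n_blocks = as.integer(n_blocks), breaks = breaks,
                 assignment = as.integer(bin), masks = masks,
                 excluded = integer(0), time = mask$time),
            class = "block_partition")
}

#' @export
print.block_partition <- function(x, ...) {
  cat(sprintf("<block_partition> %d blocks over x in [%.4g, %.4g] µm",
              x$n_blocks, x$breaks[1], x$breaks[length(x$breaks)]))
  if (length(x$excluded))
    cat(sprintf("; excluded: %s", paste(x$excluded, collapse = ", ")))
  cat("\n")
  invisible(x)
}

#' Exclude anterior (CMZ-contaminated) blocks by frame time
#'
#' Once the reporter turns on in the arising ciliary marginal zone, the
#' anterior-most block no longer measures RPE. Frames before `t_cmz` keep
#' all blocks; the first frame at or after `t_cmz` drops the single most
#' anterior block; later frames drop the two most anterior blocks.
#'
#' @param partition A [discretize_blocks()] result.
#' @param time Frame time (hpf).
#' @param t_cmz Onset of CMZ reporter expression (hpf); 20 in the reference
#'   analysis.
#' @param frame_times Optional full vector of frame times, used to identify
#'   "the frame at `t_cmz`" as the first frame at or after it; without it,
#'   only an exact `time == t_cmz` drops one block.
#' @param anterior Direction of the anterior end along x (`"+x"` is the
#'   phantom convention; real data must state it).
#' @return The partition with `excluded` set to the dropped block ids.
#' @export
exclude_cmz_blocks <- function(partition, time, t_cmz = 20,
                               frame_times = NULL,
                               anterior = c("+x", "-x")) {
  stopifnot(inherits(partition, "block_partition"))
  anterior <- match.arg(anterior)
  first_at <- if (!is.null(frame_times)) {
    after <- frame_times[frame_times >= t_cmz]
    if (length(after)) min(after) else Inf
  } else t_cmz
  n_drop <- if (time < t_cmz) 0L else if (time <= first_at) 1L else 2L
  order_ids <- if (anterior == "+x")
    rev(seq_len(partition$n_blocks)) else seq_len(partition$n_blocks)
  partition$excluded <- if (n_drop > 0) order_ids[seq_len(n_drop)] else
    integer(0)
  partition
}

#' Per-block and whole-tissue metrics table
#'
#' Computes volume, fitted-surface area and volume/surface thickness for
#' the whole mask (block 0) and for each retained block of a partition.
#' When a partition with exclusions is given, the whole-tissue row is
#' recomputed over the surviving blocks only.
#'
#' @param mask A [seg_mask()].
#' @param partition Optional [discretize_blocks()] result (possibly with
#'   CMZ exclusions applied).
#' @return A data.frame with columns `time_hpf`, `block` (0 = whole),
#'   `volume_um3`, `surface_um2`, `thickness_um`, `excluded`.
#' @export
tissue_metrics <- function(mask, partition = NULL) {
  stopifnot(inherits(mask, "seg_mask"))
  one <- function(m, block, excluded) {
    vol <- voxel_volume(m)
    surf <- tryCatch(fit_surface(m)$area, error = function(e) NA_real_)
    data.frame(time_hpf = mask$time, block = block,
               volume_um3 = vol, surface_um2 = surf,
               thickness_um = if (!is.na(surf) && surf > 0)
                 tissue_thickness(vol, surf) else NA_real_,
               excluded = excluded)
  }
  if (is.null(partition)) return(one(mask, 0L, FALSE))
  keep <- setdiff(seq_len(partition$n_blocks), partition$excluded)
  whole_fg <- Reduce(`|`, lapply(partition$masks[keep],
                                 function(m) m$values))
  rows <- list(one(seg_mask(mask, whole_fg), 0L, FALSE))
  for (b in seq_len(partition$n_blocks)) {
    rows[[b + 1L]] <- one(partition$masks[[b]], b,
                          b %in% partition$excluded)
  }
  do.call(rbind, rows)
}

#' Convex-hull volume of the foreground (whole-eye volume)
#'
#' Volume (µm³) of the 3D convex hull of all foreground voxel centres —
#' the geometrical shape covering every positive voxel, lens cavity
#' included. Built by an incremental hull over the candidate extreme
#' points (per-slice 2D hull prefilter), so only regions present in the
#' image contribute.
#'
#' @param grid A [voxel_grid()] (foreground = strictly positive values) or
#'   a [seg_mask()].
#' @return Hull volume in µm³.
#' @export
convex_hull_volume <- function(grid) {
  stopifnot(inherits(grid, "voxel_grid"))
  fg <- if (inherits(grid, "seg_mask")) grid$values else grid$values > 0
  idx <- which(fg, arr.ind = TRUE)
  if (nrow(idx) < 4)
    stop("convex hull needs >= 4 foreground voxels", call. = FALSE)
  ax <- voxel_axes(grid)
  pts <- cbind(ax$x[idx[, 1]], ax$y[idx[, 2]], ax$z[idx[, 3]])
  pts <- hull_candidate_points(pts, idx)
  convhull_volume_3d(pts)
}

# Reduce a voxel point cloud to candidates that can be 3D hull vertices:
# per-(y,z)-column x extremes, then the 2D hull of each z slice.
hull_candidate_points <- function(pts, idx) {
  ny <- max(idx[, 2])
  key <- idx[, 2] + (ny + 1) * idx[, 3]
  ord <- order(key, pts[, 1])
  keep <- ord[!duplicated(key[ord])]                 # column minima
  ord2 <- order(key, -pts[, 1])
  keep <- union(keep, ord2[!duplicated(key[ord2])])  # column maxima
  pts <- pts[keep, , drop = FALSE]
  slice <- split(seq_len(nrow(pts)), pts[, 3])
  sel <- unlist(lapply(slice, function(s) {
    if (length(s) <= 3) return(s)
    s[chull(pts[s, 1], pts[s, 2])]
  }), use.names = FALSE)
  pts[sel, , drop = FALSE]
}
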