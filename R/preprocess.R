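# Signal -> mask processing chain: median filter, top-hat background
# neutralization, median-intensity threshold, nuclei closing, and the
# max/blur/min prefilter used before convex-hull volume estimation.

#' Median filter
#'
#' Rank-median filter with reflective border handling; geometry preserved.
#' The default neighbourhood is 3x3x1 (in-plane), respecting the typical z
#' anisotropy of confocal stacks.
#'
#' @param grid A [voxel_grid()].
#' @param radius Half-width in voxels per axis (scalar recycled); e.g.
#'   `c(1, 1, 0)` is 3x3x1. At least one entry must be >= 1.
#' @param shape SE shape, `"box"` or `"ellipsoid"`.
#' @return Filtered [voxel_grid()].
#' @export
median_filter <- function(grid, radius = c(1, 1, 0), shape = "box") {
  stopifnot(inherits(grid, "voxel_grid"))
  radius <- rep_len(as.integer(radius), 3L)
  if (all(radius < 1)) stop("median filter radius must be >= 1", call. = FALSE)
  rank_apply(grid, se_offsets(radius, shape), 2L)
}

#' Background neutralization by white top-hat
#'
#' Subtracts from the image its own grey-scale opening (the morphological
#' background estimate): `out = grid - opening(grid, SE)`. The result is
#' non-negative and never exceeds the input; smooth ramps wider than the SE
#' are removed. The SE must be larger than the widest bright structure that
#' should survive — an SE smaller than the tissue removes the tissue
#' interior along with the background.
#'
#' @param grid A [voxel_grid()].
#' @param se_radius SE half-width. In voxels per axis by default; in µm when
#'   `units = "um"` (converted per axis, honouring anisotropy).
#' @param shape `"ellipsoid"` (default, matching a rolling-ball background)
#'   or `"box"` (separable, much faster for large SEs).
#' @param units `"voxels"` or `"um"`.
#' @return Background-subtracted [voxel_grid()].
#' @export
subtract_background <- function(grid, se_radius = c(15, 15, 0),
                                shape = c("ellipsoid", "box"),
                                units = c("voxels", "um")) {
  stopifnot(inherits(grid, "voxel_grid"))
  shape <- match.arg(shape)
  units <- match.arg(units)
  spacing <- if (units == "um") grid$spacing else NULL
  r <- rep_len(as.numeric(se_radius), 3L)
  if (all((if (is.null(spacing)) r else r / spacing) < 1))
    stop("structuring element must span at least one voxel", call. = FALSE)
  if (shape == "box") {
    rv <- if (is.null(spacing)) r else r / spacing
    opened <- box_rank(box_rank(grid, as.integer(floor(rv)), 0L),
                       as.integer(floor(rv)), 1L)
  } else {
    off <- se_offsets(r, "ellipsoid", spacing = spacing)
    opened <- grey_open(grid, off)
  }
  with_values(grid, pmax(grid$values - opened$values, 0))
}

#' Median-intensity threshold
#'
#' Establishes the median intensity of the pooled voxels as the cutoff
#' separating background from signal: voxels strictly below the cutoff are
#' background; voxels at or above it are signal. Exact-zero voxels are
#' never signal (tissue volume is defined over strictly positive
#' intensities), so a grid whose majority is exactly zero thresholds to its
#' positive voxels rather than to everything. An all-equal positive grid
#' yields all-foreground, since nothing is strictly below its median.
#'
#' @param grid A [voxel_grid()] or a list of them (a time series).
#' @param pool `"series"` pools intensities over all frames to set one
#'   cutoff; `"frame"` sets a cutoff per frame.
#' @param roi Optional [seg_mask()] (or list of masks, one per frame)
#'   restricting both the pooled statistics and the resulting foreground —
#'   the stand-in for the semi-manual isolation of the tissue region.
#' @return A [seg_mask()] (or list of them), with attribute `cutoff`.
#' @export
median_threshold <- function(grid, pool = c("series", "frame"), roi = NULL) {
  pool <- match.arg(pool)
  single <- inherits(grid, "voxel_grid")
  grids <- if (single) list(grid) else grid
  stopifnot(length(grids) >= 1, all(vapply(grids, inherits, TRUE, "voxel_grid")))
  rois <- NULL
  if (!is.null(roi)) {
    rois <- if (inherits(roi, "seg_mask")) rep(list(roi), length(grids)) else roi
    stopifnot(length(rois) == length(grids))
  }
  pooled_values <- function(i) {
    v <- grids[[i]]$values
    if (!is.null(rois)) v[rois[[i]]$values] else as.numeric(v)
  }
  cutoffs <- if (pool == "series") {
    rep(median(unlist(lapply(seq_along(grids), pooled_values))),
        length(grids))
  } else {
    vapply(seq_along(grids), function(i) median(pooled_values(i)), 0)
  }
  out <- lapply(seq_along(grids), function(i) {
    fg <- grids[[i]]$values >= cutoffs[i] & grids[[i]]$values > 0
    if (!is.null(rois)) fg <- fg & rois[[i]]$values
    m <- seg_mask(grids[[i]], fg)
    attr(m, "cutoff") <- cutoffs[i]
    m
  })
  if (single) out[[1]] else out
}

#' Grey-scale closing of a nuclear channel
#'
#' Dilation followed by erosion, filling the dark gaps between adjacent
#' nuclei so that a nuclear reporter approximates the tissue it labels.
#'
#' @param grid A [voxel_grid()].
#' @param se_radius SE half-width in voxels per axis (scalar recycled).
#' @param shape SE shape.
#' @return Closed [voxel_grid()].
#' @export
close_nuclei <- function(grid, se_radius = c(2, 2, 1), shape = "ellipsoid") {
  stopifnot(inherits(grid, "voxel_grid"))
  r <- rep_len(as.numeric(se_radius), 3L)
  if (all(r < 1)) stop("se_radius must be >= 1", call. = FALSE)
  grey_close(grid, se_offsets(r, shape))
}

#' Maximum / Gaussian blur / minimum prefilter
#'
#' The smoothing chain applied to a nuclear channel before convex-hull
#' volume estimation: a maximum filter closes gaps, the Gaussian blur
#' smooths, and the minimum filter restores the envelope extent. Applied in
#' exactly that order (the operations do not commute).
#'
#' @param grid A [voxel_grid()].
#' @param max_radius,min_radius Rank-filter half-widths in voxels per axis.
#' @param blur_sigma Gaussian sigma in µm (0 disables the blur).
#' @return Filtered [voxel_grid()].
#' @export
hull_prefilter <- function(grid, max_radius = c(2, 2, 1), blur_sigma = 1,
                           min_radius = max_radius) {
  stopifnot(inherits(grid, "voxel_grid"))
  out <- grid
  if (any(rep_len(max_radius, 3L) >= 1))
    out <- grey_dilate(out, se_offsets(max_radius, "ellipsoid"))
  if (any(blur_sigma > 0)) out <- gaussian_blur(out, blur_sigma)
  if (any(rep_len(min_radius, 3L) >= 1))
    out <- grey_erode(out, se_offsets(min_radius, "ellipsoid"))
  out
}
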