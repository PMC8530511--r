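# Grey-scale rank morphology on anisotropic 3D grids.
#
# Structuring elements (SEs) are ellipsoids or boxes specified either in
# voxels per axis or in physical micrometres (converted per axis, so z
# anisotropy is honoured). All filters use reflective borders.

#' Structuring-element voxel offsets
#'
#' @param radius Numeric length 1 or 3. Half-width of the SE along (x, y, z).
#'   A scalar is recycled; a zero entry makes the SE flat along that axis.
#' @param shape `"ellipsoid"` (voxel centres within the ellipsoid) or
#'   `"box"`.
#' @param spacing If given (µm per voxel), `radius` is interpreted in µm and
#'   converted to voxels per axis; otherwise `radius` is in voxels.
#' @return Integer matrix (k x 3) of voxel offsets, including the origin.
#' @export
se_offsets <- function(radius, shape = c("ellipsoid", "box"), spacing = NULL) {
  shape <- match.arg(shape)
  radius <- rep_len(as.numeric(radius), 3L)
  if (any(radius < 0) || any(!is.finite(radius)))
    stop("SE radius must be non-negative and finite", call. = FALSE)
  rv <- if (is.null(spacing)) radius else radius / rep_len(spacing, 3L)
  ri <- pmax(0L, as.integer(floor(rv + 1e-9)))
  g <- expand.grid(x = -ri[1]:ri[1], y = -ri[2]:ri[2], z = -ri[3]:ri[3])
  off <- as.matrix(g)
  if (shape == "ellipsoid") {
    rr <- pmax(rv, 1e-9)
    keep <- (off[, 1] / rr[1])^2 + (off[, 2] / rr[2])^2 +
      (off[, 3] / rr[3])^2 <= 1 + 1e-9
    off <- off[keep, , drop = FALSE]
  }
  storage.mode(off) <- "integer"
  off
}

rank_apply <- function(grid, offsets, type) {
  v <- .rank_filter3d(as.numeric(grid$values), dim(grid$values),
                      offsets, type)
  with_values(grid, v)
}

#' Grey-scale erosion / dilation / opening / closing
#'
#' Flat (rank-order) morphology: erosion is the neighbourhood minimum,
#' dilation the maximum; opening = erosion then dilation, closing the
#' reverse. Geometry and spacing are preserved exactly.
#'
#' @param grid A [voxel_grid()].
#' @param offsets SE offsets from [se_offsets()].
#' @return A [voxel_grid()] of the same geometry.
#' @export
grey_erode <- function(grid, offsets) rank_apply(grid, offsets, 0L)

#' @rdname grey_erode
#' @export
grey_dilate <- function(grid, offsets) rank_apply(grid, offsets, 1L)

#' @rdname grey_erode
#' @export
grey_open <- function(grid, offsets) {
  grey_dilate(grey_erode(grid, offsets), structure(-offsets,
                                                   dim = dim(offsets)))
}

#' @rdname grey_erode
#' @export
grey_close <- function(grid, offsets) {
  grey_erode(grey_dilate(grid, offsets), structure(-offsets,
                                                   dim = dim(offsets)))
}

# Separable fast path for box SEs: three axis-aligned line SEs.
box_rank <- function(grid, half_widths_vox, type) {
  out <- grid
  for (axis in 1:3) {
    r <- half_widths_vox[axis]
    if (r < 1) next
    off <- matrix(0L, nrow = 2L * r + 1L, ncol = 3L)
    off[, axis] <- as.integer(-r:r)
    out <- rank_apply(out, off, type)
  }
  out
}

#' Separable Gaussian smoothing
#'
#' Sigma is given in physical micrometres and converted per axis, so the
#' blur is isotropic in tissue space even on anisotropic grids. Kernels are
#' truncated at 3 sigma and renormalized; `sigma = 0` returns the input.
#'
#' @param grid A [voxel_grid()].
#' @param sigma_um Gaussian sigma in µm (scalar, or length 3 per axis).
#' @return A [voxel_grid()] of the same geometry.
#' @export
gaussian_blur <- function(grid, sigma_um) {
  stopifnot(inherits(grid, "voxel_grid"))
  sigma_um <- rep_len(as.numeric(sigma_um), 3L)
  if (any(sigma_um < 0)) stop("sigma must be non-negative", call. = FALSE)
  v <- as.numeric(grid$values)
  d <- dim(grid$values)
  for (axis in 1:3) {
    s <- sigma_um[axis] / grid$spacing[axis]
    if (s <= 0) next
    r <- max(1L, as.integer(ceiling(3 * s)))
    k <- exp(-0.5 * ((-r:r) / s)^2)
    k <- k / sum(k)
    v <- .conv_axis3d(v, d, k, axis - 1L)
  }
  with_values(grid, v)
}

#' Label connected components of a mask
#'
#' 26-connectivity in 3D (8-connectivity within a single z-plane, which is a
#' special case of the same neighbourhood).
#'
#' @param mask A [seg_mask()].
#' @return Integer array of component labels (0 = background) with attribute
#'   `n_components`.
#' @export
label_components <- function(mask) {
  stopifnot(inherits(mask, "seg_mask"))
  lab <- .label3d(as.logical(mask$values), dim(mask$values))
  array(lab, dim = dim(mask$values)) -> out
  attr(out, "n_components") <- attr(lab, "n_components")
  out
}
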