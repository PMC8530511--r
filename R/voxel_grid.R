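#' Voxel grid: a 3D scalar image with anisotropic physical spacing
#'
#' The universal carrier between pipeline stages. Values are finite,
#' non-negative intensities; `spacing` gives the physical size of one voxel
#' along each array axis in micrometres. Array dimensions are ordered
#' `(x, y, z)`, with `z` the optical-section axis (typically the coarsest
#' spacing in confocal stacks).
#'
#' @param values 3D numeric array of non-negative, finite intensities.
#' @param spacing Numeric length-3, micrometres per voxel along (x, y, z).
#' @param time Frame time in hours post fertilization (hpf), or `NA`.
#' @param channel Free-text channel label (e.g. `"tissue"`, `"eye"`).
#' @param origin Physical coordinate (µm) of the centre of voxel (1,1,1).
#'
#' @return An object of class `voxel_grid`.
#' @examples
#' g <- voxel_grid(array(0, c(4, 4, 2)), spacing = c(0.62, 0.62, 1.37))
#' voxel_size(g)
#' @export
voxel_grid <- function(values, spacing, time = NA_real_, channel = "",
                       origin = c(0, 0, 0)) {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("`values` must be a 3D array", call. = FALSE)
  storage.mode(values) <- "double"
  if (anyNA(values) || any(!is.finite(values)))
    stop("`values` must be finite", call. = FALSE)
  if (any(values < 0))
    stop("`values` must be non-negative", call. = FALSE)
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be 3 strictly positive values (µm)", call. = FALSE)
  structure(
    list(values = values, spacing = spacing, time = as.numeric(time)[1],
         channel = as.character(channel)[1], origin = as.numeric(origin)),
    class = "voxel_grid"
  )
}

#' Segmentation mask sharing a voxel grid's geometry
#'
#' @param source A [voxel_grid()] providing geometry (spacing, origin, time).
#' @param foreground Logical 3D array, same dimensions as the source values.
#' @return An object of class `c("seg_mask", "voxel_grid")` whose `values`
#'   are logical.
#' @export
seg_mask <- function(source, foreground) {
  stopifnot(inherits(source, "voxel_grid"))
  if (!identical(dim(foreground), dim(source$values)))
    stop("mask geometry must match its source grid", call. = FALSE)
  m <- source
  m$values <- array(as.logical(foreground), dim = dim(foreground))
  class(m) <- c("seg_mask", "voxel_grid")
  m
}

#' @export
print.voxel_grid <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<voxel_grid> %d x %d x %d voxels, spacing (%g, %g, %g) µm",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]))
  if (!is.na(x$time)) cat(sprintf(", t = %g hpf", x$time))
  if (nzchar(x$channel)) cat(sprintf(", channel '%s'", x$channel))
  cat("\n")
  if (inherits(x, "seg_mask")) {
    cat(sprintf("  foreground: %d voxels (%.3g µm³)\n",
                sum(x$values), voxel_volume(x)))
  } else {
    cat(sprintf("  intensity range: [%g, %g]\n",
                min(x$values), max(x$values)))
  }
  invisible(x)
}

#' Physical volume of one voxel (µm³)
#' @param grid A [voxel_grid()].
#' @return Scalar, product of the three spacings.
#' @export
voxel_size <- function(grid) {
  stopifnot(inherits(grid, "voxel_grid"))
  prod(grid$spacing)
}

#' Physical coordinates of voxel centres along each axis
#'
#' Voxel `i` (1-based) along an axis with spacing `s` is centred at
#' `origin + (i - 1) * s`; the voxel occupies the half-open interval
#' `[centre - s/2, centre + s/2)`.
#'
#' @param grid A [voxel_grid()].
#' @return List with numeric vectors `x`, `y`, `z` (µm).
#' @export
voxel_axes <- function(grid) {
  stopifnot(inherits(grid, "voxel_grid"))
  d <- dim(grid$values)
  list(x = grid$origin[1] + (seq_len(d[1]) - 1) * grid$spacing[1],
       y = grid$origin[2] + (seq_len(d[2]) - 1) * grid$spacing[2],
       z = grid$origin[3] + (seq_len(d[3]) - 1) * grid$spacing[3])
}

#' Physical coordinates (µm) of foreground voxel centres
#' @param mask A [seg_mask()].
#' @return n x 3 matrix of (x, y, z) coordinates.
#' @export
mask_coords <- function(mask) {
  stopifnot(inherits(mask, "seg_mask"))
  idx <- which(mask$values, arr.ind = TRUE)
  ax <- voxel_axes(mask)
  cbind(x = ax$x[idx[, 1]], y = ax$y[idx[, 2]], z = ax$z[idx[, 3]])
}

# Shared geometry check used by every stage: operations must never change it.
same_geometry <- function(a, b) {
  identical(dim(a$values), dim(b$values)) &&
    isTRUE(all.equal(a$spacing, b$spacing)) &&
    isTRUE(all.equal(a$origin, b$origin))
}

# Internal: rebuild a grid with new values, geometry untouched.
with_values <- function(grid, values) {
  out <- grid
  out$values <- array(values, dim = dim(grid$values))
  out
}
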