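# Stack I/O: multi-page TIFF per channel per frame, with a JSON sidecar
# carrying the physical metadata TIFF cannot (z spacing, frame time,
# intensity scale). Intensities are stored as 16-bit integers — the native
# representation of the microscopy data this pipeline emulates — so writes
# round-trip exactly for integer-valued grids.

#' Write a voxel grid as a multi-page TIFF plus JSON sidecar
#'
#' Pages are z planes. Values must be non-negative integers (quantized
#' intensities); a scale factor recorded in the sidecar maps them into the
#' 16-bit range. The sidecar (`<path>.json`) stores spacing, origin, frame
#' time, channel and the scale, so [read_stack()] can restore the grid
#' exactly.
#'
#' @param grid A [voxel_grid()] with integer-valued intensities.
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(grid, path) {
  stopifnot(inherits(grid, "voxel_grid"))
  v <- grid$values
  if (max(abs(v - round(v))) > 1e-9)
    stop("write_stack stores integer intensities; quantize the grid first",
         call. = FALSE)
  v <- round(v)
  scale <- max(1, max(v))
  pages <- lapply(seq_len(dim(v)[3]), function(k) t(v[, , k]) / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  meta <- list(spacing_um = grid$spacing, origin_um = grid$origin,
               time_hpf = grid$time, channel = grid$channel,
               intensity_scale = scale, dim = dim(v))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, na = "null")
  invisible(path)
}

#' Read a multi-page TIFF into a voxel grid
#'
#' Spacing comes from the JSON sidecar when present; otherwise the
#' `spacing` argument is required — the reader never silently assumes
#' isotropic voxels. A `spacing` argument always overrides the sidecar.
#' 8- and 16-bit inputs load to a common numeric intensity scale.
#'
#' @param path TIFF path.
#' @param spacing Optional µm-per-voxel override, length 3.
#' @param time,channel Optional metadata overrides.
#' @return A [voxel_grid()].
#' @export
read_stack <- function(path, spacing = NULL, time = NULL, channel = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  pages <- tiff::readTIFF(path, all = TRUE, info = FALSE)
  if (!is.list(pages)) pages <- list(pages)
  sidecar <- paste0(path, ".json")
  meta <- if (file.exists(sidecar)) jsonlite::read_json(sidecar,
                                                        simplifyVector = TRUE)
  else NULL
  if (is.null(spacing)) spacing <- meta$spacing_um
  if (is.null(spacing))
    stop("no voxel spacing: provide `spacing` or a sidecar; ",
         "isotropy is never assumed", call. = FALSE)
  scale <- if (!is.null(meta$intensity_scale)) meta$intensity_scale else
    65535
  pages <- lapply(pages, function(p) {
    if (length(dim(p)) == 3) p <- p[, , 1]   # tolerate grey-stored-as-RGB
    p
  })
  nz <- length(pages)
  v <- array(0, c(ncol(pages[[1]]), nrow(pages[[1]]), nz))
  for (k in seq_len(nz)) v[, , k] <- t(pages[[k]])
  v <- round(v * scale)
  voxel_grid(v, spacing,
             time = if (!is.null(time)) time else
               if (!is.null(meta$time_hpf)) meta$time_hpf else NA_real_,
             channel = if (!is.null(channel)) channel else
               if (!is.null(meta$channel)) meta$channel else "",
             origin = if (!is.null(meta$origin_um)) meta$origin_um else
               c(0, 0, 0))
}

#' Write / read phantom truth as JSON
#'
#' Persists the scalar ground-truth trajectories of a `phantom_truth`
#' (times, volumes, surfaces, thicknesses, angles, nucleus centres and
#' flags) next to the generated stacks. Masks and the generating spec are
#' not serialized.
#'
#' @param truth A `phantom_truth`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  stopifnot(inherits(truth, "phantom_truth"))
  keep <- setdiff(names(truth), c("clean_masks", "region", "spec", "hinge"))
  obj <- truth[keep]
  if (!is.null(truth$hinge))
    obj$hinge <- lapply(truth$hinge, function(h)
      list(vertex = h$vertex, edges = h$edges))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(obj, class = "phantom_truth")
}
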