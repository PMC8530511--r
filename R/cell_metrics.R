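# Cell- and eye-shape measurements: apical polygon area, apico-basal
# length, contralateral normalization, invagination angle.

#' Planar cell outline
#'
#' An ordered vertex list (µm) of a drawn apical cell contour, optionally
#' tagged with the imaging plane and cell class.
#'
#' @param vertices n x 2 numeric matrix of (y, z) or (x, y) coordinates in
#'   µm, n >= 3, describing a simple (non-self-intersecting) polygon.
#' @param plane Optional plane identifier.
#' @param class_label Optional cell class (`"progenitor"`, `"NR"`, `"RPE"`).
#' @return Object of class `cell_outline`.
#' @export
cell_outline <- function(vertices, plane = NA, class_label = NA_character_) {
  vertices <- as.matrix(vertices)
  if (ncol(vertices) != 2 || nrow(vertices) < 3)
    stop("an outline needs >= 3 planar vertices", call. = FALSE)
  structure(list(vertices = vertices, plane = plane,
                 class_label = class_label), class = "cell_outline")
}

# Proper segment crossing test for the simplicity check.
segments_cross <- function(p1, p2, p3, p4) {
  d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) -
    (b[2] - a[2]) * (c[1] - a[1])
  d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2)
  d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
  (d1 * d2 < 0) && (d3 * d4 < 0)
}

#' Apical polygon area (shoelace)
#'
#' Orientation-independent planar polygon area in µm². Self-intersecting
#' outlines are rejected.
#'
#' @param outline A [cell_outline()] or an n x 2 vertex matrix (µm).
#' @return Area in µm².
#' @export
polygon_area <- function(outline) {
  v <- if (inherits(outline, "cell_outline")) outline$vertices else
    as.matrix(outline)
  if (ncol(v) != 2 || nrow(v) < 3)
    stop("polygon area needs >= 3 planar vertices", call. = FALSE)
  n <- nrow(v)
  # simplicity: no two non-adjacent edges may properly cross
  edges <- cbind(seq_len(n), c(seq_len(n)[-1], 1L))
  for (i in seq_len(n - 2)) {
    for (j in (i + 2):n) {
      if (i == 1 && j == n) next  # adjacent through the closing edge
      if (segments_cross(v[edges[i, 1], ], v[edges[i, 2], ],
                         v[edges[j, 1], ], v[edges[j, 2], ]))
        stop("self-intersecting outline", call. = FALSE)
    }
  }
  x <- v[, 1]; y <- v[, 2]
  xs <- c(x[-1], x[1]); ys <- c(y[-1], y[1])
  abs(sum(x * ys - xs * y)) / 2
}

#' Apico-basal length
#'
#' Euclidean distance (µm) between the basal and apical membrane points of
#' a traced cell axis.
#'
#' @param basal,apical Numeric coordinate vectors (µm), equal length (2D or
#'   3D), distinct.
#' @return Length in µm.
#' @export
ab_length <- function(basal, apical) {
  basal <- as.numeric(basal); apical <- as.numeric(apical)
  stopifnot(length(basal) == length(apical))
  d <- sqrt(sum((apical - basal)^2))
  if (d == 0) stop("basal and apical points coincide", call. = FALSE)
  d
}

#' Normalize a measurement to the contralateral control eye
#'
#' Experimental value divided by the untreated contralateral value, to
#' absorb developmental asynchrony. For apico-basal lengths, ratios above 1
#' indicate less cell flattening in the treated eye.
#'
#' @param experimental,control Values in the same units; `control > 0`.
#' @return Dimensionless ratio(s).
#' @export
normalize_to_contralateral <- function(experimental, control) {
  if (any(control <= 0))
    stop("control value must be strictly positive", call. = FALSE)
  experimental / control
}

#' Invagination angle at the neural-retina basal surface
#'
#' Interior angle (degrees) at `vertex` between the two vectors drawn to
#' the cup edges, computed from the normalized dot product (via atan2 for
#' numerical stability). Smaller angles mean deeper folding.
#'
#' @param vertex Angle vertex (µm), placed at the centre of the NR basal
#'   surface; 2D or 3D coordinates.
#' @param edge1,edge2 Points at the two cup (CMZ) edges.
#' @return Angle in degrees, in (0, 180].
#' @export
invagination_angle <- function(vertex, edge1, edge2) {
  vertex <- as.numeric(vertex)
  u <- as.numeric(edge1) - vertex
  v <- as.numeric(edge2) - vertex
  if (length(u) == 2) { u <- c(u, 0); v <- c(v, 0) }
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0)
    stop("edge point coincides with the vertex", call. = FALSE)
  cross <- c(u[2] * v[3] - u[3] * v[2],
             u[3] * v[1] - u[1] * v[3],
             u[1] * v[2] - u[2] * v[1])
  atan2(sqrt(sum(cross^2)), sum(u * v)) * 180 / pi
}

#' Measure the invagination angle from a cup mask
#'
#' Operationalizes the manual angle tool on a voxel cup: in the central z
#' plane (largest foreground section), the vertex is the deepest point of
#' the invaginating basal surface (the most +x foreground voxel on the
#' central row, the cup opening facing +x) and the edge points are the rim
#' voxels at the extreme of the opening axis on either side.
#'
#' @param mask A [seg_mask()] of the whole-eye channel.
#' @return List with `angle` (degrees), `vertex` and `edges` (µm).
#' @export
measure_cup_angle <- function(mask) {
  stopifnot(inherits(mask, "seg_mask"))
  counts <- apply(mask$values, 3, sum)
  if (max(counts) == 0) stop("empty mask", call. = FALSE)
  k <- which.max(counts)
  sl <- mask$values[, , k]
  ax <- voxel_axes(mask)
  idx <- which(sl, arr.ind = TRUE)
  xs <- ax$x[idx[, 1]]; ys <- ax$y[idx[, 2]]
  # central row: y column nearest the foreground centroid
  yc <- mean(ys)
  row_j <- idx[, 2][which.min(abs(ys - yc))]
  on_row <- idx[, 2] == row_j
  vertex <- c(max(xs[on_row]), ax$y[row_j])
  # rim: foreground at the maximal x of the slice, one edge per side
  rim <- xs >= max(xs) - 1.5 * mask$spacing[1]
  up <- rim & ys > vertex[2]; dn <- rim & ys < vertex[2]
  if (!any(up) || !any(dn))
    stop("no rim points on both sides; not a cup section", call. = FALSE)
  e1 <- c(xs[up][which.max(ys[up])], max(ys[up]))
  e2 <- c(xs[dn][which.min(ys[dn])], min(ys[dn]))
  list(angle = invagination_angle(vertex, e1, e2),
       vertex = vertex, edges = rbind(e1, e2))
}
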