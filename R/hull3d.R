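# Incremental 3D convex hull (beneath-beyond), volume only.
#
# Points are added one at a time; faces visible from the new point are
# replaced by the cone from its horizon edges. Orientation is kept outward
# relative to an interior reference point, so the hull volume is the sum of
# positively oriented tetrahedra. Adequate for the voxel point clouds this
# package produces once they are reduced to candidate extreme points.

convhull_volume_3d <- function(pts, tol = NULL) {
  pts <- unique(as.matrix(pts))
  n <- nrow(pts)
  if (n < 4) stop("convex hull needs >= 4 distinct points", call. = FALSE)
  scale <- max(apply(pts, 2, function(v) diff(range(v))))
  if (scale <= 0) stop("degenerate point set (single point)", call. = FALSE)
  if (is.null(tol)) tol <- 1e-9 * scale

  # initial tetrahedron from extremes
  i1 <- which.min(pts[, 1])
  d1 <- rowSums((pts - rep(pts[i1, ], each = n))^2)
  i2 <- which.max(d1)
  e12 <- pts[i2, ] - pts[i1, ]
  cr <- function(u, v) c(u[2] * v[3] - u[3] * v[2],
                         u[3] * v[1] - u[1] * v[3],
                         u[1] * v[2] - u[2] * v[1])
  v1 <- sweep(pts, 2, pts[i1, ])
  cross_all <- cbind(v1[, 2] * e12[3] - v1[, 3] * e12[2],
                     v1[, 3] * e12[1] - v1[, 1] * e12[3],
                     v1[, 1] * e12[2] - v1[, 2] * e12[1])
  area2 <- rowSums(cross_all^2)
  i3 <- which.max(area2)
  if (sqrt(area2[i3]) <= tol * sqrt(sum(e12^2)))
    stop("degenerate point set: all points collinear", call. = FALSE)
  nrm <- cr(pts[i2, ] - pts[i1, ], pts[i3, ] - pts[i1, ])
  nrm <- nrm / sqrt(sum(nrm^2))
  h <- abs(v1 %*% nrm)
  i4 <- which.max(h)
  if (h[i4] <= tol)
    stop("degenerate point set: all points coplanar", call. = FALSE)

  o <- colMeans(pts[c(i1, i2, i3, i4), ])   # interior reference point
  faces <- rbind(c(i1, i2, i3), c(i1, i2, i4), c(i1, i3, i4), c(i2, i3, i4))
  orient <- function(f) {
    nn <- cr(pts[f[2], ] - pts[f[1], ], pts[f[3], ] - pts[f[1], ])
    if (sum(nn * (o - pts[f[1], ])) > 0) f[c(1, 3, 2)] else f
  }
  faces <- t(apply(faces, 1, orient))
  face_geo <- function(faces) {
    a <- pts[faces[, 1], , drop = FALSE]
    b <- pts[faces[, 2], , drop = FALSE]
    c_ <- pts[faces[, 3], , drop = FALSE]
    u <- b - a; v <- c_ - a
    nn <- cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
                u[, 3] * v[, 1] - u[, 1] * v[, 3],
                u[, 1] * v[, 2] - u[, 2] * v[, 1])
    list(normal = nn, d = rowSums(nn * a))
  }
  geo <- face_geo(faces)

  rest <- setdiff(seq_len(n), c(i1, i2, i3, i4))
  for (p in rest) {
    dist <- as.numeric(geo$normal %*% pts[p, ]) - geo$d
    nscale <- sqrt(rowSums(geo$normal^2))
    visible <- dist > tol * nscale
    if (!any(visible)) next
    vis <- faces[visible, , drop = FALSE]
    # horizon: directed edges of visible faces whose reverse is not visible
    ed <- rbind(vis[, c(1, 2)], vis[, c(2, 3)], vis[, c(3, 1)])
    fwd <- paste(ed[, 1], ed[, 2])
    rev_ <- paste(ed[, 2], ed[, 1])
    horizon <- ed[!(fwd %in% rev_), , drop = FALSE]
    new_faces <- cbind(horizon, p)
    new_faces <- t(apply(new_faces, 1, orient))
    faces <- rbind(faces[!visible, , drop = FALSE], new_faces)
    geo <- face_geo(faces)
  }

  a <- pts[faces[, 1], , drop = FALSE]
  b <- pts[faces[, 2], , drop = FALSE]
  c_ <- pts[faces[, 3], , drop = FALSE]
  ao <- sweep(a, 2, o); bo <- sweep(b, 2, o); co <- sweep(c_, 2, o)
  cx <- cbind(bo[, 2] * co[, 3] - bo[, 3] * co[, 2],
              bo[, 3] * co[, 1] - bo[, 1] * co[, 3],
              bo[, 1] * co[, 2] - bo[, 2] * co[, 1])
  sum(rowSums(ao * cx)) / 6
}
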