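# Shared fixtures and independent brute-force oracles. Every oracle here
# recomputes a quantity by a different route than the implementation
# (explicit loops, closed forms, or EBImage 2D morphology).

make_grid <- function(values, spacing = c(1, 1, 1), ...) {
  voxel_grid(values, spacing, ...)
}

# brute-force rank filter with the same edge-reflection rule
reflect_idx <- function(i, n) {
  while (any(bad <- i < 1 | i > n)) {
    i[i < 1] <- 1 - i[i < 1]
    i[i > n] <- 2 * n + 1 - i[i > n]
  }
  i
}

brute_rank <- function(values, offsets, fun) {
  d <- dim(values)
  out <- array(NA_real_, d)
  for (k in seq_len(d[3])) for (j in seq_len(d[2])) for (i in seq_len(d[1])) {
    ii <- reflect_idx(i + offsets[, 1], d[1])
    jj <- reflect_idx(j + offsets[, 2], d[2])
    kk <- reflect_idx(k + offsets[, 3], d[3])
    out[i, j, k] <- fun(values[cbind(ii, jj, kk)])
  }
  out
}

# triangulated-mesh area of a fitted quadratic over the mask footprint:
# each footprint column cell is split into two triangles whose vertices sit
# on the fitted surface
mesh_area_oracle <- function(fit, mask) {
  proj <- apply(mask$values, c(2, 3), any)
  ax <- voxel_axes(mask)
  cols <- which(proj, arr.ind = TRUE)
  b <- fit$coefficients
  f <- function(y, z) b[1] + b[2] * y + b[3] * z + b[4] * y^2 +
    b[5] * y * z + b[6] * z^2
  sy <- mask$spacing[2]; sz <- mask$spacing[3]
  tri_area <- function(p1, p2, p3) {
    u <- p2 - p1; v <- p3 - p1
    cr <- c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3],
            u[1] * v[2] - u[2] * v[1])
    sqrt(sum(cr^2)) / 2
  }
  total <- 0
  for (r in seq_len(nrow(cols))) {
    y0 <- ax$y[cols[r, 1]] - sy / 2; y1 <- y0 + sy
    z0 <- ax$z[cols[r, 2]] - sz / 2; z1 <- z0 + sz
    p00 <- c(f(y0, z0), y0, z0); p10 <- c(f(y1, z0), y1, z0)
    p01 <- c(f(y0, z1), y0, z1); p11 <- c(f(y1, z1), y1, z1)
    total <- total + tri_area(p00, p10, p11) + tri_area(p00, p11, p01)
  }
  total
}

# quiet phantom defaults for unit tests: clean signal unless overridden
quiet_spec <- function(...) {
  args <- list(...)
  if (is.null(args$noise_sd)) args$noise_sd <- 0
  if (is.null(args$background_ramp_amplitude))
    args$background_ramp_amplitude <- 0
  do.call(phantom_spec, args)
}

# rasterize a convex polygon on a pixel grid and return pixel-count area
raster_polygon_area <- function(vertices, pixel) {
  rng <- apply(vertices, 2, range)
  px <- seq(rng[1, 1] - pixel, rng[2, 1] + pixel, by = pixel)
  py <- seq(rng[1, 2] - pixel, rng[2, 2] + pixel, by = pixel)
  gr <- expand.grid(x = px, y = py)
  inside <- rep(TRUE, nrow(gr))
  n <- nrow(vertices)
  for (i in seq_len(n)) {
    j <- i %% n + 1
    e <- vertices[j, ] - vertices[i, ]
    inside <- inside &
      (e[1] * (gr$y - vertices[i, 2]) - e[2] * (gr$x - vertices[i, 1]) >= 0)
  }
  sum(inside) * pixel^2
}

# regular hexagon (counter-clockwise) with the given area
regular_hexagon <- function(area) {
  s <- sqrt(area / (3 * sqrt(3) / 2))
  ang <- (0:5) * pi / 3
  cbind(s * cos(ang), s * sin(ang))
}
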