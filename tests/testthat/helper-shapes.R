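# Rasterized reference shapes used across the morphometry tests.
# Masks follow the package convention: rows = y, cols = x, pixel centers at
# integer coordinates.

raster_disk <- function(radius, pad = 6, cx = NULL, cy = NULL, value = 1L) {
  sz <- ceiling(2 * (radius + pad))
  if (is.null(cx)) cx <- sz / 2
  if (is.null(cy)) cy <- sz / 2
  xs <- matrix(rep(seq_len(sz), each = sz), sz, sz)
  ys <- matrix(rep(seq_len(sz), times = sz), sz, sz)
  matrix(as.integer((xs - cx)^2 + (ys - cy)^2 <= radius^2), sz, sz) * value
}

# axis-aligned (or rotated) ellipse with semi-axes a >= b, rotation in rad
raster_ellipse <- function(a, b, theta = 0, pad = 6) {
  sz <- ceiling(2 * (a + pad))
  c0 <- sz / 2
  xs <- matrix(rep(seq_len(sz), each = sz), sz, sz)
  ys <- matrix(rep(seq_len(sz), times = sz), sz, sz)
  u <- (xs - c0) * cos(theta) + (ys - c0) * sin(theta)
  v <- -(xs - c0) * sin(theta) + (ys - c0) * cos(theta)
  matrix(as.integer((u / a)^2 + (v / b)^2 <= 1), sz, sz)
}

# disk with sinusoidal radial perturbation r(phi) = r (1 + eps sin(k phi))
raster_star <- function(radius, eps, k, pad = 10) {
  sz <- ceiling(2 * (radius * (1 + eps) + pad))
  c0 <- sz / 2
  xs <- matrix(rep(seq_len(sz), each = sz), sz, sz)
  ys <- matrix(rep(seq_len(sz), times = sz), sz, sz)
  phi <- atan2(ys - c0, xs - c0)
  rb <- radius * (1 + eps * sin(k * phi))
  matrix(as.integer((xs - c0)^2 + (ys - c0)^2 <= rb^2), sz, sz)
}

one_instance <- function(mask, intensity = NULL, mpp = 1) {
  nucleus_instances(mask, intensity = intensity, mpp = mpp)[[1]]
}

# random simple star-shaped polygon around a center, for tiling oracles.
# An angular gap above pi can let a chord leave its wedge and self-
# intersect, so gaps are kept below pi by construction.
random_star_polygon <- function(center, r_mean, n_vertices = 9) {
  repeat {
    gaps <- stats::runif(n_vertices)
    ang <- 2 * pi * cumsum(gaps) / sum(gaps)
    if (max(diff(c(0, ang))) < pi) break
  }
  r <- stats::runif(n_vertices, 0.4 * r_mean, 1.6 * r_mean)
  cbind(center[1] + r * cos(ang), center[2] + r * sin(ang))
}

# brute-force tiling oracle: enumerate every stride-lattice origin whose
# patch fits in the ROI bounding box (and the slide), keep by intersection
# fraction.  Independent loop structure from tile_roi.
brute_force_tiling <- function(polygon, cfg) {
  st <- cfg$stride; ps <- cfg$patch_size
  xs <- seq(0, cfg$slide_width - ps, by = st)
  ys <- seq(0, cfg$slide_height - ps, by = st)
  bx <- range(polygon[, 1]); by <- range(polygon[, 2])
  out <- NULL
  for (y0 in ys) for (x0 in xs) {
    if (x0 < floor(bx[1] / st) * st || x0 > bx[2] - ps) next
    if (y0 < floor(by[1] / st) * st || y0 > by[2] - ps) next
    f <- patch_area_fraction(x0, y0, ps, polygon)
    if (f >= cfg$min_intersection_fraction)
      out <- rbind(out, data.frame(x0 = x0, y0 = y0, fraction = f))
  }
  out
}

# independent area oracle: fraction of pixel centers inside the polygon
# over the patch window (discretization error O(perimeter / patch area))
raster_patch_fraction <- function(x0, y0, size, polygon) {
  gx <- seq(x0 + 0.5, x0 + size - 0.5, by = 1)
  gy <- seq(y0 + 0.5, y0 + size - 0.5, by = 1)
  pts <- expand.grid(x = gx, y = gy)
  mean(gliomorph:::points_in_polygon(pts$x, pts$y, polygon))
}
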