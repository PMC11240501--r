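# Planar geometry primitives used by the ROI and tiling code.
# Polygons are n x 2 numeric matrices of vertices (not repeated at the end);
# pixel coordinates, x right, y down.

#' Signed and absolute polygon area (shoelace formula)
#'
#' @param polygon n x 2 numeric matrix of vertices.
#' @param signed return the signed area (positive for counter-clockwise in a
#'   y-up frame) instead of its absolute value.
#' @return Area in squared coordinate units.
#' @export
#' @examples
#' polygon_area(rbind(c(0, 0), c(512, 0), c(0, 512)))
polygon_area <- function(polygon, signed = FALSE) {
  polygon <- as_polygon_matrix(polygon)
  x <- polygon[, 1]; y <- polygon[, 2]
  a <- sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y) / 2
  if (signed) a else abs(a)
}

as_polygon_matrix <- function(polygon) {
  polygon <- as.matrix(polygon)
  storage.mode(polygon) <- "double"
  if (ncol(polygon) != 2 || nrow(polygon) < 3)
    stop("a polygon needs an n x 2 matrix with n >= 3 vertices")
  # drop a repeated closing vertex if present
  n <- nrow(polygon)
  if (all(polygon[1, ] == polygon[n, ])) polygon <- polygon[-n, , drop = FALSE]
  polygon
}

# Proper segment-crossing test for the simple-polygon check.  Shared
# endpoints between adjacent edges are not crossings.
segments_cross <- function(p1, p2, q1, q2) {
  d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  d1 <- d(q1, q2, p1); d2 <- d(q1, q2, p2)
  d3 <- d(p1, p2, q1); d4 <- d(p1, p2, q2)
  if (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
      ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))) return(TRUE)
  on_seg <- function(a, b, c) {
    d(a, b, c) == 0 &&
      min(a[1], b[1]) <= c[1] && c[1] <= max(a[1], b[1]) &&
      min(a[2], b[2]) <= c[2] && c[2] <= max(a[2], b[2])
  }
  (on_seg(q1, q2, p1) || on_seg(q1, q2, p2) ||
     on_seg(p1, p2, q1) || on_seg(p1, p2, q2))
}

# TRUE iff the polygon is simple (no two non-adjacent edges intersect).
is_simple_polygon <- function(polygon) {
  polygon <- as_polygon_matrix(polygon)
  n <- nrow(polygon)
  nxt <- c(2:n, 1)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      # skip adjacent edges (they share a vertex by construction)
      if (j == i || nxt[i] == j || nxt[j] == i) next
      if (segments_cross(polygon[i, ], polygon[nxt[i], ],
                         polygon[j, ], polygon[nxt[j], ])) return(FALSE)
    }
  }
  TRUE
}

# Sutherland-Hodgman clip of an arbitrary simple polygon against an
# axis-aligned rectangle [x0, x1] x [y0, y1].  For concave subjects the
# output may contain zero-width bridges, which do not affect the enclosed
# area -- the only quantity the tiling filter needs.
clip_polygon_rect <- function(polygon, x0, y0, x1, y1) {
  polygon <- as_polygon_matrix(polygon)
  clip_halfplane <- function(pts, inside, intersect) {
    if (nrow(pts) == 0) return(pts)
    n <- nrow(pts)
    out <- matrix(numeric(0), ncol = 2)
    for (i in seq_len(n)) {
      cur <- pts[i, ]; prv <- pts[if (i == 1) n else i - 1, ]
      cin <- inside(cur); pin <- inside(prv)
      if (cin) {
        if (!pin) out <- rbind(out, intersect(prv, cur))
        out <- rbind(out, cur)
      } else if (pin) {
        out <- rbind(out, intersect(prv, cur))
      }
    }
    out
  }
  ix <- function(a, b, coord, val) {
    t <- (val - a[coord]) / (b[coord] - a[coord])
    a + t * (b - a)
  }
  pts <- polygon
  pts <- clip_halfplane(pts, function(p) p[1] >= x0, function(a, b) ix(a, b, 1, x0))
  pts <- clip_halfplane(pts, function(p) p[1] <= x1, function(a, b) ix(a, b, 1, x1))
  pts <- clip_halfplane(pts, function(p) p[2] >= y0, function(a, b) ix(a, b, 2, y0))
  pts <- clip_halfplane(pts, function(p) p[2] <= y1, function(a, b) ix(a, b, 2, y1))
  pts
}

# Even-odd point-in-polygon test, vectorised over points.
points_in_polygon <- function(px, py, polygon) {
  polygon <- as_polygon_matrix(polygon)
  n <- nrow(polygon)
  inside <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- polygon[i, 1]; yi <- polygon[i, 2]
    xj <- polygon[j, 1]; yj <- polygon[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}
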