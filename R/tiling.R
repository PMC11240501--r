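# Patch extraction from annotated ROIs: a stride lattice over the ROI
# bounding box, filtered by the fraction of each patch covered by the ROI
# polygon.  Intersection areas are exact (polygon clipping), not rasterized.

#' Tiling configuration
#'
#' Defaults follow common whole-slide practice: 512 x 512 patches, stride
#' half the patch size, and rejection of margin patches with less than half
#' their area inside the ROI.
#'
#' @param patch_size patch side length in pixels (> 0).
#' @param stride lattice spacing in pixels (0 < stride <= patch_size).
#' @param min_intersection_fraction minimum fraction of the patch area that
#'   must lie inside the ROI polygon, in (0, 1]; the boundary is inclusive
#'   (a patch exactly at the threshold is kept).
#' @param slide_width,slide_height slide dimensions in pixels; patches never
#'   extend past the slide.
#' @return Object of class `tiling_config`.
#' @export
tiling_config <- function(patch_size = 512L, stride = 256L,
                          min_intersection_fraction = 0.5,
                          slide_width, slide_height) {
  stopifnot(patch_size > 0, stride > 0, stride <= patch_size,
            min_intersection_fraction > 0, min_intersection_fraction <= 1,
            slide_width >= patch_size, slide_height >= patch_size)
  structure(list(patch_size = as.integer(patch_size),
                 stride = as.integer(stride),
                 min_intersection_fraction = min_intersection_fraction,
                 slide_width = as.integer(slide_width),
                 slide_height = as.integer(slide_height)),
            class = "tiling_config")
}

#' Fraction of a square patch covered by a polygon
#'
#' Exact continuous-geometry area of the intersection between the half-open
#' patch `[x0, x0 + size) x [y0, y0 + size)` and a simple polygon, divided
#' by the patch area.
#'
#' @param x0,y0 top-left patch corner in pixels (0-based).
#' @param size patch side length in pixels.
#' @param polygon n x 2 vertex matrix.
#' @return Fraction in \[0, 1\].
#' @export
#' @examples
#' sq <- rbind(c(0, 0), c(512, 0), c(512, 512), c(0, 512))
#' patch_area_fraction(0, 0, 512, sq)
patch_area_fraction <- function(x0, y0, size, polygon) {
  clipped <- clip_polygon_rect(polygon, x0, y0, x0 + size, y0 + size)
  if (nrow(clipped) < 3) return(0)
  min(polygon_area(clipped) / size^2, 1)
}

#' Tile an ROI into patches
#'
#' Candidate patch origins lie on the stride lattice in slide coordinates
#' (anchored at multiples of the stride, starting from the ROI bounding box
#' snapped down), so tiling is invariant to translating the ROI by stride
#' multiples.  Candidate patches lie within the extent of the ROI bounding
#' box; a candidate is kept iff the fraction of its area inside the ROI
#' polygon is at least `min_intersection_fraction`.  Origins that would
#' push a patch past the slide bounds (or the bbox extent) are not
#' generated, so an ROI narrower than the patch size yields no patches.
#'
#' @param roi an `roi_annotation` (see [generate_roi()]).
#' @param cfg a [tiling_config()].
#' @return data.frame with one row per kept patch: `slide_id`, `roi_id`,
#'   `category`, `x0`, `y0`, `size`, `fraction`, sorted row-major
#'   (by `y0`, then `x0`).
#' @export
#' @examples
#' roi <- generate_roi(rbind(c(0, 0), c(1024, 0), c(1024, 1024), c(0, 1024)),
#'                     "diffuse astrocytoma")
#' cfg <- tiling_config(slide_width = 1024, slide_height = 1024)
#' nrow(tile_roi(roi, cfg))   # 9
tile_roi <- function(roi, cfg) {
  stopifnot(inherits(roi, "roi_annotation"), inherits(cfg, "tiling_config"))
  empty <- data.frame(slide_id = character(0), roi_id = character(0),
                      category = character(0), x0 = integer(0),
                      y0 = integer(0), size = integer(0),
                      fraction = numeric(0))
  if (polygon_area(roi$polygon) == 0) {
    warning("degenerate ROI polygon (zero area); no patches")
    return(empty)
  }
  ps <- cfg$patch_size; st <- cfg$stride
  bb_x <- range(roi$polygon[, 1]); bb_y <- range(roi$polygon[, 2])
  # stride lattice covering the ROI bounding box, anchored at the bbox
  # top-left snapped down to a stride multiple in slide coordinates;
  # candidate patches lie within the bbox extent and the slide
  x_start <- max(0L, floor(bb_x[1] / st) * st)
  y_start <- max(0L, floor(bb_y[1] / st) * st)
  x_max <- min(cfg$slide_width - ps, bb_x[2] - ps)
  y_max <- min(cfg$slide_height - ps, bb_y[2] - ps)
  if (x_start > x_max || y_start > y_max) return(empty)
  xs <- seq(x_start, x_max, by = st)
  ys <- seq(y_start, y_max, by = st)
  grid <- expand.grid(x0 = xs, y0 = ys)   # row-major: y slow, x fast
  frac <- mapply(function(x0, y0) patch_area_fraction(x0, y0, ps, roi$polygon),
                 grid$x0, grid$y0)
  keep <- frac >= cfg$min_intersection_fraction
  if (!any(keep)) return(empty)
  data.frame(slide_id = roi$slide_id, roi_id = roi$roi_id,
             category = roi$category,
             x0 = as.integer(grid$x0[keep]), y0 = as.integer(grid$y0[keep]),
             size = ps, fraction = frac[keep],
             row.names = NULL)
}

#' Tile several ROIs with one configuration
#'
#' @param rois list of `roi_annotation` objects.
#' @param cfg a [tiling_config()].
#' @return Row-bound data.frame of [tile_roi()] outputs.  Overlapping ROIs
#'   can yield duplicate patch coordinates, each attributed to the ROI that
#'   generated it.
#' @export
tile_rois <- function(rois, cfg) {
  do.call(rbind, lapply(rois, tile_roi, cfg = cfg))
}
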