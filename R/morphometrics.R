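# Cellularity and the six nuclear morphological features (axis ratio,
# circularity, entropy, area, irregularity, perimeter) computed from
# instance label masks, with four-moment summaries per aggregation unit.
#
# Image convention: matrices with rows = y, columns = x; pixel centers at
# integer coordinates.

# --- boundary extraction ----------------------------------------------------

# Sub-pixel contour of a binary mask via marching squares (contourLines at
# level 0.5) followed by a circular moving-average smoothing that removes
# the staircase length bias.  Returns an m x 2 matrix of (x, y) vertices.
trace_boundary <- function(mask01, smooth_window = 5L) {
  padded <- matrix(0L, nrow(mask01) + 2L, ncol(mask01) + 2L)
  padded[2:(nrow(mask01) + 1L), 2:(ncol(mask01) + 1L)] <- mask01
  cl <- grDevices::contourLines(x = seq_len(nrow(padded)) - 1,
                                y = seq_len(ncol(padded)) - 1,
                                z = padded, levels = 0.5)
  if (length(cl) == 0) return(matrix(numeric(0), ncol = 2))
  best <- cl[[which.max(vapply(cl, function(ct) length(ct$x), 0))]]
  # contourLines' x follows matrix rows (= y); drop the repeated end vertex
  by <- best$x; bx <- best$y
  n <- length(bx)
  if (n > 1 && bx[1] == bx[n] && by[1] == by[n]) { bx <- bx[-n]; by <- by[-n] }
  n <- length(bx)
  w <- min(smooth_window, if (n %% 2 == 1) n else n - 1)
  if (n >= 8 && w >= 3) {
    k <- (w - 1) / 2
    circ <- function(v) {
      vv <- v[c((n - k + 1):n, 1:n, 1:k)]
      as.numeric(stats::filter(vv, rep(1 / w, w))[(k + 1):(n + k)])
    }
    bx <- circ(bx); by <- circ(by)
  }
  cbind(x = bx, y = by)
}

# --- instance extraction ----------------------------------------------------

#' Extract nucleus instances from an integer label mask
#'
#' Splits a label mask (0 = background, 1..N = instances) into per-nucleus
#' objects carrying the pixel set, centroid, a sub-pixel boundary contour,
#' optional intensity values and the physical scale.
#'
#' @param label_mask integer matrix of instance labels.
#' @param intensity optional integer matrix of gray values (0-255), same
#'   dimensions.
#' @param mpp microns per pixel.
#' @return List of objects of class `nucleus_instance` with fields
#'   `instance_id`, `px`/`py` (pixel coordinates), `centroid`, `boundary`
#'   (m x 2 sub-pixel vertices), `intensity_values` (or NULL), `mpp`, and
#'   `border` (TRUE if the nucleus touches the image border).
#' @export
nucleus_instances <- function(label_mask, intensity = NULL, mpp = 0.46) {
  stopifnot(is.matrix(label_mask), mpp > 0)
  if (!is.null(intensity)) stopifnot(dim(intensity) == dim(label_mask))
  idx <- which(label_mask != 0L)
  if (length(idx) == 0) return(list())
  labs <- label_mask[idx]
  rows <- ((idx - 1L) %% nrow(label_mask)) + 1L
  cols <- ((idx - 1L) %/% nrow(label_mask)) + 1L
  split_idx <- split(seq_along(idx), labs)
  lapply(split_idx, function(ii) {
    py <- rows[ii]; px <- cols[ii]
    r0 <- min(py); r1 <- max(py); c0 <- min(px); c1 <- max(px)
    sub <- matrix(0L, r1 - r0 + 1L, c1 - c0 + 1L)
    sub[cbind(py - r0 + 1L, px - c0 + 1L)] <- 1L
    boundary <- trace_boundary(sub)
    if (nrow(boundary) > 0) {
      boundary[, 1] <- boundary[, 1] + c0 - 1L
      boundary[, 2] <- boundary[, 2] + r0 - 1L
    }
    structure(list(
      instance_id = labs[ii[1]],
      px = px, py = py,
      centroid = c(x = mean(px), y = mean(py)),
      boundary = boundary,
      intensity_values = if (is.null(intensity)) NULL
                         else intensity[cbind(py, px)],
      mpp = mpp,
      border = (r0 == 1L || c0 == 1L ||
                  r1 == nrow(label_mask) || c1 == ncol(label_mask))),
      class = "nucleus_instance")
  })
}

# --- cellularity ------------------------------------------------------------

#' Cellularity of a region
#'
#' The ratio of the area occupied by cells (nonzero mask pixels) to the
#' total area of the region.
#'
#' @param label_mask integer matrix; nonzero pixels are cell area.
#' @param mpp microns per pixel.
#' @param unit_id identifier of the aggregation unit (ROI or patch).
#' @return One-row data.frame: `unit_id`, `cell_area` and `total_area`
#'   (square microns), `cellularity` in \[0, 1\].
#' @export
#' @examples
#' m <- matrix(0L, 64, 64); m[1:16, ] <- 1L
#' cellularity(m, mpp = 1)$cellularity   # 0.25
cellularity <- function(label_mask, mpp = 0.46, unit_id = "unit_1") {
  stopifnot(is.matrix(label_mask), length(label_mask) > 0, mpp > 0)
  n_cell <- sum(label_mask != 0L)
  data.frame(unit_id = unit_id,
             cell_area = n_cell * mpp^2,
             total_area = length(label_mask) * mpp^2,
             cellularity = n_cell / length(label_mask))
}

# --- the six nuclear features ----------------------------------------------

#' Long-to-short axis ratio of a nucleus
#'
#' Ratio of the major to the minor axis of the ellipse with the same second
#' central moments as the pixel set (with the 1/12 square-pixel moment
#' correction), always >= 1.
#'
#' @param n a `nucleus_instance`.
#' @return Dimensionless ratio, or NA (degenerate, collinear pixel set).
#' @export
axis_ratio <- function(n) {
  stopifnot(inherits(n, "nucleus_instance"))
  if (length(n$px) < 5) return(NA_real_)
  cc <- stats::cov(cbind(n$px, n$py)) * (length(n$px) - 1) / length(n$px)
  cc <- cc + diag(2) / 12   # each pixel is a unit square, not a point
  ev <- eigen(cc, symmetric = TRUE, only.values = TRUE)$values
  if (ev[2] <= 0) return(NA_real_)
  sqrt(ev[1] / ev[2])
}

#' Circularity of a nucleus
#'
#' Overlap between the nucleus and the concentric equal-area disk: the
#' fraction of nucleus pixels lying within the disk centered at the
#' centroid whose area equals the nucleus area.  1 for a disk; decreases
#' with elongation and irregularity.
#'
#' @param n a `nucleus_instance`.
#' @return Value in \[0, 1\].
#' @export
circularity <- function(n) {
  stopifnot(inherits(n, "nucleus_instance"))
  if (length(n$px) < 5) return(NA_real_)
  r2 <- length(n$px) / pi
  d2 <- (n$px - n$centroid["x"])^2 + (n$py - n$centroid["y"])^2
  mean(d2 <= r2)
}

#' Shannon entropy of nucleus intensities
#'
#' Base-2 Shannon entropy of the 256-bin histogram of gray values over the
#' nucleus pixels; quantifies pixel randomness, 0 (constant) to 8 bits.
#'
#' @param n a `nucleus_instance` with `intensity_values`.
#' @param bins number of histogram bins (default 256 for 8-bit images).
#' @return Entropy in bits, or NA if intensities are missing.
#' @export
nucleus_entropy <- function(n, bins = 256L) {
  stopifnot(inherits(n, "nucleus_instance"))
  v <- n$intensity_values
  if (is.null(v) || length(v) == 0) return(NA_real_)
  b <- findInterval(v, seq(0, 256, length.out = bins + 1),
                    rightmost.closed = TRUE)
  p <- tabulate(b, nbins = bins)
  p <- p[p > 0] / length(v)
  -sum(p * log2(p))
}

#' Nuclear area
#'
#' Pixel count times the squared physical scale.
#'
#' @param n a `nucleus_instance`.
#' @return Area in square microns.
#' @export
nucleus_area <- function(n) {
  stopifnot(inherits(n, "nucleus_instance"))
  length(n$px) * n$mpp^2
}

#' Boundary irregularity
#'
#' Population variance of the distances (in microns) from the nucleus
#' centroid to each vertex of the sub-pixel boundary contour.  Zero for a
#' perfect circle up to discretization.
#'
#' @param n a `nucleus_instance`.
#' @return Variance in square microns, or NA if the boundary has fewer than
#'   8 vertices.
#' @export
irregularity <- function(n) {
  stopifnot(inherits(n, "nucleus_instance"))
  if (nrow(n$boundary) < 8) return(NA_real_)
  d <- sqrt((n$boundary[, 1] - n$centroid["x"])^2 +
              (n$boundary[, 2] - n$centroid["y"])^2) * n$mpp
  mean((d - mean(d))^2)
}

#' Nuclear perimeter
#'
#' Length of the closed sub-pixel boundary contour times the physical
#' scale.
#'
#' @param n a `nucleus_instance`.
#' @return Perimeter in microns, or NA without a boundary.
#' @export
nucleus_perimeter <- function(n) {
  stopifnot(inherits(n, "nucleus_instance"))
  b <- n$boundary
  if (nrow(b) < 3) return(NA_real_)
  sum(sqrt(diff(c(b[, 1], b[1, 1]))^2 + diff(c(b[, 2], b[1, 2]))^2)) * n$mpp
}

# --- per-image measurement table -------------------------------------------

#' Measure all nuclei in a label mask
#'
#' Computes the six nuclear features for every instance.  Nuclei touching
#' the image border are excluded from shape measurement by default
#' (truncated shapes bias morphometry) but still count toward
#' [cellularity()], which uses the mask directly.
#'
#' @param label_mask integer instance label matrix.
#' @param intensity optional gray-value matrix (needed for entropy).
#' @param mpp microns per pixel.
#' @param min_px minimum pixel count for a measurable nucleus.
#' @param exclude_border drop border-touching nuclei (default TRUE).
#' @return data.frame with one row per measured nucleus: `instance_id`,
#'   `n_px`, `border`, `axis_ratio`, `circularity`, `entropy`, `area`,
#'   `irregularity`, `perimeter`.
#' @export
measure_nuclei <- function(label_mask, intensity = NULL, mpp = 0.46,
                           min_px = 5L, exclude_border = TRUE) {
  inst <- nucleus_instances(label_mask, intensity, mpp)
  inst <- Filter(function(n) length(n$px) >= min_px, inst)
  if (exclude_border) inst <- Filter(function(n) !n$border, inst)
  if (length(inst) == 0)
    return(data.frame(instance_id = integer(0), n_px = integer(0),
                      border = logical(0), axis_ratio = numeric(0),
                      circularity = numeric(0), entropy = numeric(0),
                      area = numeric(0), irregularity = numeric(0),
                      perimeter = numeric(0)))
  do.call(rbind, lapply(inst, function(n) data.frame(
    instance_id = n$instance_id, n_px = length(n$px), border = n$border,
    axis_ratio = axis_ratio(n), circularity = circularity(n),
    entropy = nucleus_entropy(n), area = nucleus_area(n),
    irregularity = irregularity(n), perimeter = nucleus_perimeter(n),
    row.names = NULL)))
}

#' Seven-descriptor feature vector for one unit
#'
#' Cellularity of the unit plus the mean of each of the six nuclear
#' features over its measurable nuclei -- the input row for the
#' gradient-boosting feature model.
#'
#' @inheritParams measure_nuclei
#' @return Named numeric vector: `cellularity`, `axis_ratio`,
#'   `circularity`, `entropy`, `area`, `irregularity`, `perimeter`.
#' @export
unit_feature_vector <- function(label_mask, intensity = NULL, mpp = 0.46) {
  m <- measure_nuclei(label_mask, intensity, mpp)
  feats <- c("axis_ratio", "circularity", "entropy", "area",
             "irregularity", "perimeter")
  c(cellularity = cellularity(label_mask, mpp)$cellularity,
    vapply(feats, function(f) mean(m[[f]], na.rm = TRUE), numeric(1)))
}

# --- moment summaries -------------------------------------------------------

#' Four-moment summary of a feature distribution
#'
#' Mean, sample variance (n - 1 denominator), Fisher skewness and excess
#' kurtosis (normal distribution -> 0), the summary used to compare feature
#' distributions between categories.  Skewness and kurtosis are undefined
#' (NA) when n < 4 or the values are constant.
#'
#' @param values numeric vector of per-nucleus feature values.
#' @param unit_id identifier of the aggregation unit.
#' @return One-row data.frame: `unit_id`, `n`, `mean`, `variance`,
#'   `skewness`, `kurtosis`.
#' @export
#' @examples
#' moment_summary(c(1, 2, 3, 4, 5))   # mean 3, variance 2.5
moment_summary <- function(values, unit_id = "unit_1") {
  values <- values[is.finite(values)]
  n <- length(values)
  if (n == 0)
    return(data.frame(unit_id = unit_id, n = 0L, mean = NA_real_,
                      variance = NA_real_, skewness = NA_real_,
                      kurtosis = NA_real_))
  v <- if (n >= 2) stats::var(values) else NA_real_
  higher_ok <- n >= 4 && isTRUE(v > 0)
  data.frame(unit_id = unit_id, n = n,
             mean = mean(values), variance = v,
             skewness = if (higher_ok) e1071::skewness(values, type = 1)
                        else NA_real_,
             kurtosis = if (higher_ok) e1071::kurtosis(values, type = 1)
                        else NA_real_)
}
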