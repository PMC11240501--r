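# Synthetic inputs for the pipeline: class-conditional nucleus-mask images,
# ROI geometries and per-case patch-prediction count tables.  Nuclei are
# radially perturbed ellipses, so every morphometric descriptor has an
# analytic (or near-analytic) ground truth.

#' Class profile for the synthetic nucleus generator
#'
#' Describes one characteristic pathological feature category as a
#' generative model: how densely nuclei occur, how large and how elongated
#' they are, how noisy their boundaries are, and how many distinct gray
#' levels their chromatin texture carries.
#'
#' @param category one of [feature_categories()].
#' @param nucleus_density expected nuclei per 100 x 100 micron tile (>= 0).
#' @param area_mean,area_sd mean and SD of nuclear area in square microns;
#'   areas are lognormal.
#' @param axis_ratio_mean,axis_ratio_sd mean and SD of the long-to-short
#'   axis ratio (dimensionless, >= 1).  The ratio is sampled as
#'   1 + lognormal so the support is guaranteed and the mean is exact.
#' @param boundary_noise relative amplitude of the sinusoidal radial
#'   boundary perturbation, in \[0, 0.5\].
#' @param texture_levels number of distinct, equiprobable gray levels per
#'   nucleus (>= 1); target entropy is log2(texture_levels) bits.
#' @param rng_seed integer seed making images reproducible.
#' @return An object of class `class_profile`.
#' @export
#' @examples
#' class_profile("diffuse astrocytoma", nucleus_density = 25,
#'               area_mean = 21, area_sd = 9, rng_seed = 1)
class_profile <- function(category,
                          nucleus_density,
                          area_mean, area_sd,
                          axis_ratio_mean = 1.5, axis_ratio_sd = 0.2,
                          boundary_noise = 0.08,
                          texture_levels = 28L,
                          rng_seed = 1L) {
  stopifnot(category %in% feature_categories(),
            nucleus_density >= 0,
            area_mean > 0, area_sd >= 0,
            axis_ratio_mean >= 1, axis_ratio_sd >= 0,
            boundary_noise >= 0, boundary_noise <= 0.5,
            texture_levels >= 1, texture_levels <= 256)
  structure(list(category = category,
                 nucleus_density = nucleus_density,
                 area_mean = area_mean, area_sd = area_sd,
                 axis_ratio_mean = axis_ratio_mean,
                 axis_ratio_sd = axis_ratio_sd,
                 boundary_noise = boundary_noise,
                 texture_levels = as.integer(texture_levels),
                 rng_seed = as.integer(rng_seed)),
            class = "class_profile")
}

#' Default class profiles for the five feature categories
#'
#' Densities, areas, axis ratios, boundary noise and texture levels are
#' chosen so that the expected per-class means rank the way the cellularity
#' and nuclear-feature means of astrocytic tumor tissue do: cellularity
#' highest in glioblastoma tumor cell area, then anaplastic astrocytoma,
#' then microvascular proliferation, then diffuse astrocytoma, with
#' necrosis near zero.  Expected cellularity for a profile is
#' `nucleus_density * area_mean / 1e4`.
#'
#' @param rng_seed base seed; profile i uses `rng_seed + i`.
#' @return Named list of five [class_profile()] objects.
#' @export
default_class_profiles <- function(rng_seed = 20L) {
  cats <- feature_categories()
  # per-category: density (/100x100um), area mean/sd (um^2), axis ratio
  # mean/sd, boundary noise, texture levels
  tab <- data.frame(
    density = c(24.4, 69.2, 63.9, 2.2, 48.2),
    area_mean = c(21.3, 26.0, 30.5, 13.7, 25.3),
    area_sd = c(6.5, 9.0, 10.5, 5.0, 9.5),
    ar_mean = c(1.44, 1.54, 1.57, 1.50, 1.73),
    ar_sd = c(0.20, 0.25, 0.25, 0.22, 0.33),
    noise = c(0.06, 0.10, 0.12, 0.05, 0.14),
    levels = c(30L, 27L, 28L, 30L, 26L))
  profiles <- lapply(seq_along(cats), function(i) {
    class_profile(cats[i],
                  nucleus_density = tab$density[i],
                  area_mean = tab$area_mean[i], area_sd = tab$area_sd[i],
                  axis_ratio_mean = tab$ar_mean[i], axis_ratio_sd = tab$ar_sd[i],
                  boundary_noise = tab$noise[i],
                  texture_levels = tab$levels[i],
                  rng_seed = rng_seed + i)
  })
  names(profiles) <- cats
  profiles
}

# lognormal with a given arithmetic mean and SD; sd = 0 degenerates to the
# constant mean.
rlnorm_mean_sd <- function(n, mean, sd) {
  if (mean <= 0) stop("lognormal mean must be positive")
  if (sd == 0) return(rep(mean, n))
  sdlog2 <- log(1 + (sd / mean)^2)
  stats::rlnorm(n, meanlog = log(mean) - sdlog2 / 2, sdlog = sqrt(sdlog2))
}

# run code with a private RNG stream, restoring the caller's state
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(code)
}

#' Generate a synthetic nucleus-instance image
#'
#' Places non-overlapping radially perturbed ellipses on an empty field by
#' rejection sampling (at most 100 position tries per nucleus; placement
#' failures reduce the count and are reported, never retried forever).
#' Each nucleus's boundary is `r(phi) = r_ellipse(phi) * (1 + eps *
#' sin(k * phi + phase))` in its own frame, with the semi-axes rescaled by
#' `1/sqrt(1 + eps^2/2)` so the enclosed area equals the sampled target
#' area.  Intensities inside a nucleus are drawn equiprobably from
#' `texture_levels` distinct gray values, making the target Shannon entropy
#' `log2(texture_levels)` bits.
#'
#' @param profile a [class_profile()].
#' @param width_px,height_px image dimensions in pixels (>= 64).
#' @param mpp microns per pixel (default 0.46, a typical 20x scan).
#' @return A list of class `nucleus_image` with elements `label_mask`
#'   (integer matrix, 0 = background, 1..N = instances), `intensity`
#'   (integer matrix, gray 0-255), `truth` (data.frame of sampled per-
#'   nucleus parameters), `n_requested`, `n_placed`, `mpp`, `profile`.
#' @export
#' @examples
#' p <- class_profile("diffuse astrocytoma", 20, 25, 5, rng_seed = 7)
#' img <- generate_nucleus_image(p, 256, 256)
#' img$n_placed
generate_nucleus_image <- function(profile, width_px, height_px, mpp = 0.46) {
  stopifnot(inherits(profile, "class_profile"),
            width_px >= 64, height_px >= 64, mpp > 0)
  with_seed(profile$rng_seed, {
    n_target <- round(profile$nucleus_density *
                        (width_px * mpp) * (height_px * mpp) / 1e4)
    label <- matrix(0L, nrow = height_px, ncol = width_px)
    intensity <- matrix(230L, nrow = height_px, ncol = width_px)
    eps <- profile$boundary_noise
    area_scale <- 1 / (1 + eps^2 / 2)   # undo perturbation's area inflation
    truth <- vector("list", n_target)
    next_id <- 0L
    for (i in seq_len(n_target)) {
      area_um2 <- rlnorm_mean_sd(1, profile$area_mean, profile$area_sd)
      q <- if (profile$axis_ratio_mean == 1 && profile$axis_ratio_sd == 0) 1
           else 1 + rlnorm_mean_sd(1, max(profile$axis_ratio_mean - 1, 1e-9),
                                   profile$axis_ratio_sd)
      theta <- stats::runif(1, 0, pi)
      k <- sample(2:5, 1)
      phase <- stats::runif(1, 0, 2 * pi)
      area_px <- area_um2 / mpp^2
      b <- sqrt(area_px * area_scale / (pi * q))
      a <- q * b
      rmax <- a * (1 + eps)
      lo_x <- ceiling(rmax) + 2; hi_x <- width_px - ceiling(rmax) - 1
      lo_y <- ceiling(rmax) + 2; hi_y <- height_px - ceiling(rmax) - 1
      if (lo_x >= hi_x || lo_y >= hi_y) next   # nucleus larger than field
      placed <- FALSE
      for (try in 1:100) {
        cx <- stats::runif(1, lo_x, hi_x)
        cy <- stats::runif(1, lo_y, hi_y)
        cols <- floor(cx - rmax - 1):ceiling(cx + rmax + 1)
        rows <- floor(cy - rmax - 1):ceiling(cy + rmax + 1)
        dx <- rep(cols, each = length(rows)) - cx
        dy <- rep(rows, times = length(cols)) - cy
        u <- dx * cos(theta) + dy * sin(theta)
        v <- -dx * sin(theta) + dy * cos(theta)
        phi <- atan2(v, u)
        rb <- a * b / sqrt((b * cos(phi))^2 + (a * sin(phi))^2) *
          (1 + eps * sin(k * phi + phase))
        inside <- (dx^2 + dy^2) <= rb^2
        if (!any(inside)) break
        idx <- cbind(rep(rows, times = length(cols))[inside],
                     rep(cols, each = length(rows))[inside])
        if (any(label[idx] != 0L)) next       # collision: resample position
        next_id <- next_id + 1L
        label[idx] <- next_id
        levels <- sample.int(256L, profile$texture_levels) - 1L
        intensity[idx] <- if (length(levels) == 1) levels
                          else sample(levels, nrow(idx), replace = TRUE)
        truth[[i]] <- data.frame(instance_id = next_id,
                                 cx = cx, cy = cy,
                                 area_um2 = area_um2, axis_ratio = q,
                                 theta = theta, harmonic = k, phase = phase,
                                 boundary_noise = eps, n_px = nrow(idx))
        placed <- TRUE
        break
      }
    }
    truth <- do.call(rbind, truth[!vapply(truth, is.null, TRUE)])
    if (is.null(truth)) truth <- data.frame(instance_id = integer(0),
                                            cx = numeric(0), cy = numeric(0),
                                            area_um2 = numeric(0),
                                            axis_ratio = numeric(0),
                                            theta = numeric(0),
                                            harmonic = integer(0),
                                            phase = numeric(0),
                                            boundary_noise = numeric(0),
                                            n_px = integer(0))
    if (nrow(truth) < n_target)
      message(sprintf("placed %d of %d requested nuclei (%s)",
                      nrow(truth), n_target, profile$category))
    structure(list(label_mask = label, intensity = intensity, truth = truth,
                   n_requested = n_target, n_placed = nrow(truth),
                   mpp = mpp, profile = profile),
              class = "nucleus_image")
  })
}

#' @export
print.nucleus_image <- function(x, ...) {
  cat(sprintf("<nucleus_image> %d x %d px (%.2f um/px), %d/%d nuclei, category: %s\n",
              ncol(x$label_mask), nrow(x$label_mask), x$mpp,
              x$n_placed, x$n_requested, x$profile$category))
  invisible(x)
}

#' Mixture specification for one synthetic case
#'
#' The composition of predicted patch categories for a case is drawn from a
#' Dirichlet distribution; patch counts are then multinomial.
#'
#' @param true_diagnosis one of [diagnosis_levels()].
#' @param dirichlet_alphas five positive reals over the predicted
#'   categories, in [feature_categories()] order.
#' @param n_patches positive integer, total patches for the case.
#' @param case_id optional identifier.
#' @return Object of class `mixture_spec`.
#' @export
mixture_spec <- function(true_diagnosis, dirichlet_alphas, n_patches,
                         case_id = NULL) {
  stopifnot(true_diagnosis %in% diagnosis_levels(),
            length(dirichlet_alphas) == 5, all(dirichlet_alphas > 0),
            n_patches >= 1)
  structure(list(true_diagnosis = true_diagnosis,
                 dirichlet_alphas = as.numeric(dirichlet_alphas),
                 n_patches = as.integer(n_patches),
                 case_id = case_id),
            class = "mixture_spec")
}

# column names used for the five per-category patch counts
count_columns <- function() {
  c("diffuse", "anaplastic", "gbm_tumor", "gbm_necrosis", "gbm_mvp")
}

#' Generate a per-case patch-prediction count table
#'
#' For each case the category composition is Dirichlet(`alphas`) and the
#' counts are multinomial with that composition.
#'
#' @param specs non-empty list of [mixture_spec()] objects.
#' @param seed integer seed; the same seed reproduces the table exactly.
#' @return data.frame with `case_id`, `true_diagnosis` and five count
#'   columns (`diffuse`, `anaplastic`, `gbm_tumor`, `gbm_necrosis`,
#'   `gbm_mvp`), one row per case.
#' @export
#' @examples
#' sp <- mixture_spec("glioblastoma", c(1, 1, 8, 2, 1), 200)
#' generate_patch_count_table(list(sp), seed = 3)
generate_patch_count_table <- function(specs, seed) {
  stopifnot(is.list(specs), length(specs) >= 1,
            all(vapply(specs, inherits, TRUE, "mixture_spec")))
  with_seed(seed, {
    rows <- lapply(seq_along(specs), function(i) {
      sp <- specs[[i]]
      g <- stats::rgamma(5, shape = sp$dirichlet_alphas)
      p <- g / sum(g)
      counts <- as.integer(stats::rmultinom(1, sp$n_patches, p))
      out <- data.frame(case_id = if (is.null(sp$case_id))
                          sprintf("case_%02d", i) else sp$case_id,
                        true_diagnosis = sp$true_diagnosis)
      out[count_columns()] <- as.list(counts)
      out
    })
    do.call(rbind, rows)
  })
}

#' Construct an ROI annotation
#'
#' @param vertices n x 2 matrix (or data.frame) of pixel-coordinate polygon
#'   vertices; must form a simple polygon of positive area.
#' @param category one of [feature_categories()].
#' @param roi_id,slide_id identifiers.
#' @return Object of class `roi_annotation`.
#' @export
#' @examples
#' generate_roi(rbind(c(0, 0), c(1024, 0), c(1024, 1024), c(0, 1024)),
#'              "glioblastoma tumor cell area")
generate_roi <- function(vertices, category = feature_categories()[1],
                         roi_id = "roi_1", slide_id = "slide_1") {
  polygon <- as_polygon_matrix(vertices)
  if (!is_simple_polygon(polygon))
    stop("ROI polygon is self-intersecting; vertices must form a simple polygon")
  if (polygon_area(polygon) <= 0)
    stop("ROI polygon has zero area")
  stopifnot(category %in% feature_categories())
  structure(list(roi_id = roi_id, slide_id = slide_id,
                 category = category, polygon = polygon),
            class = "roi_annotation")
}

#' @export
print.roi_annotation <- function(x, ...) {
  cat(sprintf("<roi_annotation> %s (%s), %d vertices, area %.0f px^2\n",
              x$roi_id, x$category, nrow(x$polygon), polygon_area(x$polygon)))
  invisible(x)
}

#' Write / read ROI annotations as GeoJSON
#'
#' Stored as a FeatureCollection of Polygons with pixel-unit coordinates and
#' `category`, `roi_id`, `slide_id` properties.
#'
#' @param rois a single `roi_annotation` or a list of them.
#' @param path file path.
#' @return `write_roi_geojson` returns `path` invisibly; `read_roi_geojson`
#'   returns a list of `roi_annotation` objects.
#' @export
write_roi_geojson <- function(rois, path) {
  if (inherits(rois, "roi_annotation")) rois <- list(rois)
  features <- lapply(rois, function(r) {
    ring <- rbind(r$polygon, r$polygon[1, ])
    list(type = "Feature",
         geometry = list(type = "Polygon",
                         coordinates = list(lapply(seq_len(nrow(ring)),
                                                   function(i) ring[i, ]))),
         properties = list(category = r$category,
                           roi_id = r$roi_id,
                           slide_id = r$slide_id))
  })
  fc <- list(type = "FeatureCollection", features = features)
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_roi_geojson
#' @export
read_roi_geojson <- function(path) {
  fc <- jsonlite::read_json(path)
  stopifnot(identical(fc$type, "FeatureCollection"))
  lapply(fc$features, function(f) {
    ring <- do.call(rbind, lapply(f$geometry$coordinates[[1]], unlist))
    generate_roi(ring, category = f$properties$category,
                 roi_id = f$properties$roi_id,
                 slide_id = f$properties$slide_id)
  })
}

#' Write / read instance label masks and intensity images
#'
#' Label masks are written as 16-bit single-channel TIFF (instance ids up
#' to 65535); intensity images as 8-bit grayscale PNG.
#'
#' @param mask integer matrix of instance labels (0 = background).
#' @param intensity integer matrix of gray values 0-255.
#' @param path file path (`.tif`/`.tiff` for masks, `.png` for intensity).
#' @return Writers return `path` invisibly; readers the integer matrix.
#' @export
write_label_mask <- function(mask, path) {
  stopifnot(max(mask) <= 65535)
  tiff::writeTIFF(mask / 65535, path, bits.per.sample = 16)
  invisible(path)
}

#' @rdname write_label_mask
#' @export
read_label_mask <- function(path) {
  m <- tiff::readTIFF(path)
  if (length(dim(m)) == 3) m <- m[, , 1]
  matrix(as.integer(round(m * 65535)), nrow = nrow(m))
}

#' @rdname write_label_mask
#' @export
write_intensity_image <- function(intensity, path) {
  stopifnot(max(intensity) <= 255, min(intensity) >= 0)
  png::writePNG(intensity / 255, path)
  invisible(path)
}

#' @rdname write_label_mask
#' @export
read_intensity_image <- function(path) {
  m <- png::readPNG(path)
  if (length(dim(m)) == 3) m <- m[, , 1]
  matrix(as.integer(round(m * 255)), nrow = nrow(m))
}
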