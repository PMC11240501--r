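test_that("cellularity is the exact foreground area fraction", {
  m0 <- matrix(0L, 64, 64)
  expect_equal(cellularity(m0, mpp = 1)$cellularity, 0)
  expect_equal(cellularity(m0 + 1L, mpp = 1)$cellularity, 1)
  m <- matrix(0L, 512, 512)
  m[seq_len(13107)] <- 1L
  rec <- cellularity(m, mpp = 0.46, unit_id = "roi_1")
  expect_equal(rec$cellularity, 13107 / 262144)
  expect_equal(rec$cell_area, 13107 * 0.46^2)
  expect_error(cellularity(matrix(integer(0), 0, 0)), "positive|> 0|length")
})

test_that("axis ratio matches analytic ellipse moments and is rotation invariant", {
  expect_lt(abs(axis_ratio(one_instance(raster_disk(20))) - 1), 0.02)
  expect_lt(abs(axis_ratio(one_instance(raster_ellipse(40, 20))) - 2), 0.05)
  r30 <- axis_ratio(one_instance(raster_ellipse(40, 20, theta = pi / 6)))
  expect_lt(abs(r30 - 2), 0.05)
  expect_lt(abs(r30 - axis_ratio(one_instance(raster_ellipse(40, 20)))), 0.05)
})

test_that("circularity is 1 for disks and decreases with elongation", {
  expect_gte(circularity(one_instance(raster_disk(20))), 0.98)
  c2 <- circularity(one_instance(raster_ellipse(40, 20)))
  c4 <- circularity(one_instance(raster_ellipse(60, 15)))
  expect_lt(c4, c2)
  # brute-force pixel oracle for the 2:1 ellipse
  n <- one_instance(raster_ellipse(40, 20))
  r2 <- length(n$px) / pi
  oracle <- mean((n$px - mean(n$px))^2 + (n$py - mean(n$py))^2 <= r2)
  expect_equal(c2, oracle)
  # thin L-shaped region is far from a disk
  L <- matrix(0L, 120, 120)
  L[10:110, 10:17] <- 1L
  L[103:110, 10:110] <- 1L
  expect_lt(circularity(one_instance(L)), 0.7)
})

test_that("entropy follows the closed forms for discrete intensity mixes", {
  mask <- raster_disk(20)
  const <- mask * 0L + 37L
  expect_equal(nucleus_entropy(one_instance(mask, intensity = const)), 0)
  # two gray values in (as near as possible) equal proportion
  n_px <- sum(mask)
  two <- mask
  two[mask == 1L] <- rep(c(10L, 200L), length.out = n_px)
  expect_lt(abs(nucleus_entropy(one_instance(mask, intensity = two)) - 1),
            0.001)
  # 16 equiprobable gray values over >= 1000 px
  set.seed(4)
  sixteen <- mask
  sixteen[mask == 1L] <- sample(seq(0L, 255L, by = 17L), n_px, replace = TRUE)
  expect_gt(n_px, 1000)
  expect_lt(abs(nucleus_entropy(one_instance(mask, intensity = sixteen)) - 4),
            0.1)
  # intensities missing -> flagged NA, never silently 0
  expect_true(is.na(nucleus_entropy(one_instance(mask))))
})

test_that("area is the pixel count scaled by mpp^2", {
  m <- matrix(0L, 20, 20); m[3:12, 3:12] <- 1L   # 100 px
  expect_equal(nucleus_area(one_instance(m, mpp = 0.5)), 25)
  expect_equal(nucleus_area(one_instance(m, mpp = 1)) * 4,
               nucleus_area(one_instance(m, mpp = 2)))
  disk <- one_instance(raster_disk(10), mpp = 1)
  expect_lt(abs(nucleus_area(disk) - pi * 100), 7)
})

test_that("irregularity matches radial-variance oracles", {
  # circle: variance is pure discretization noise, tiny vs mean radius^2
  disk <- one_instance(raster_disk(20), mpp = 1)
  d <- sqrt((disk$boundary[, 1] - disk$centroid["x"])^2 +
              (disk$boundary[, 2] - disk$centroid["y"])^2)
  expect_lt(irregularity(disk) / mean(d)^2, 0.05)

  # ellipse a = 2b: arc-length-weighted radial variance oracle
  a <- 40; b <- 20
  t <- seq(0, 2 * pi, length.out = 20001)[-1]
  xs <- a * cos(t); ys <- b * sin(t)
  ds <- sqrt(diff(c(xs, xs[1]))^2 + diff(c(ys, ys[1]))^2)
  r <- sqrt(xs^2 + ys^2)
  w <- ds / sum(ds)
  oracle <- sum(w * (r - sum(w * r))^2)
  got <- irregularity(one_instance(raster_ellipse(a, b), mpp = 1))
  expect_lt(abs(got / oracle - 1), 0.05)

  # sinusoidally perturbed disk: var(r) ~ eps^2 r^2 / 2
  eps <- 0.15; r0 <- 40
  star <- one_instance(raster_star(r0, eps, k = 5), mpp = 1)
  expect_lt(abs(irregularity(star) / (eps^2 * r0^2 / 2) - 1), 0.1)
})

test_that("perimeter matches closed forms and scales linearly", {
  sq <- matrix(0L, 120, 120); sq[11:110, 11:110] <- 1L
  expect_lt(abs(nucleus_perimeter(one_instance(sq, mpp = 1)) / 400 - 1), 0.02)
  disk <- one_instance(raster_disk(50), mpp = 1)
  expect_lt(abs(nucleus_perimeter(disk) / (2 * pi * 50) - 1), 0.03)
  p30 <- nucleus_perimeter(one_instance(raster_disk(30), mpp = 1))
  p60 <- nucleus_perimeter(one_instance(raster_disk(60), mpp = 1))
  expect_lt(abs(p60 / (2 * p30) - 1), 0.01)
  # physical scaling: mpp doubles -> perimeter doubles exactly
  expect_equal(nucleus_perimeter(one_instance(raster_disk(30), mpp = 2)),
               2 * p30)
})

test_that("features are translation invariant", {
  base <- raster_ellipse(30, 18, theta = 0.4)
  shifted <- matrix(0L, nrow(base) + 40, ncol(base) + 40)
  shifted[31:(30 + nrow(base)), 26:(25 + ncol(base))] <- base
  a <- one_instance(base, mpp = 1); b <- one_instance(shifted, mpp = 1)
  expect_equal(axis_ratio(a), axis_ratio(b))
  expect_equal(circularity(a), circularity(b))
  expect_equal(nucleus_area(a), nucleus_area(b))
  expect_equal(irregularity(a), irregularity(b), tolerance = 1e-10)
  expect_equal(nucleus_perimeter(a), nucleus_perimeter(b), tolerance = 1e-10)
})

test_that("moment summaries use n-1 variance, Fisher skewness, excess kurtosis", {
  s <- moment_summary(rep(7, 10))
  expect_equal(s$variance, 0)
  expect_true(is.na(s$skewness) && is.na(s$kurtosis))
  s2 <- moment_summary(c(1, 2, 3, 4, 5))
  expect_equal(s2$mean, 3); expect_equal(s2$variance, 2.5)
  set.seed(8)
  z <- rnorm(1e5)
  s3 <- moment_summary(z)
  expect_lt(abs(s3$skewness), 0.03)
  expect_lt(abs(s3$kurtosis), 0.06)   # excess convention: normal -> 0
  # fewer than 4 values: higher moments flagged
  s4 <- moment_summary(c(1, 2, 5))
  expect_false(is.na(s4$variance))
  expect_true(is.na(s4$skewness))
})

test_that("border-touching nuclei are excluded from shape features by default", {
  m <- matrix(0L, 60, 60)
  m[1:12, 5:16] <- 1L          # touches the top border
  m[30:41, 30:41] <- 2L        # interior
  res <- measure_nuclei(m, mpp = 1)
  expect_equal(res$instance_id, 2)
  res_all <- measure_nuclei(m, mpp = 1, exclude_border = FALSE)
  expect_equal(nrow(res_all), 2)
  # cellularity still counts the border nucleus
  expect_equal(cellularity(m, mpp = 1)$cellularity, (144 + 144) / 3600)
})
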