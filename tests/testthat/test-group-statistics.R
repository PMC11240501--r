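test_that("welch_bonferroni tests every pair with the right correction", {
  g <- list(a = c(1, 2, 3, 4), b = c(1, 2, 3, 4))
  res <- welch_bonferroni(g)
  expect_equal(res$t_statistic, 0)
  expect_equal(res$p_raw, 1)
  expect_false(res$significant)

  set.seed(5)
  g5 <- setNames(lapply(1:5, function(i) rnorm(10)), letters[1:5])
  res5 <- welch_bonferroni(g5)
  expect_equal(nrow(res5), choose(5, 2))
  expect_equal(res5$p_adjusted, pmin(1, res5$p_raw * 10))
  # cross-check one pair against the manual Welch formula
  a <- g5$a; b <- g5$b
  tt <- (mean(a) - mean(b)) / sqrt(var(a) / 10 + var(b) / 10)
  expect_equal(res5$t_statistic[1], tt, tolerance = 1e-12)
})

test_that("groups with n < 2 are skipped with a diagnostic", {
  g <- list(a = rnorm(10), b = 3, c = rnorm(10, 1))
  expect_warning(res <- welch_bonferroni(g), "skipped")
  expect_equal(nrow(res), 1)
  expect_equal(res$p_adjusted, pmin(1, res$p_raw * 1))
})

test_that("generator cellularity separations are significant in all pairs", {
  # per-image cellularity of the default class profiles: the between-class
  # separations dwarf the generator's per-image spread, so every pairwise
  # comparison is significant, mirroring the all-pairs-significant pattern
  # of well-separated tissue categories
  profs <- default_class_profiles()
  groups <- lapply(profs, function(p) {
    vapply(1:8, function(s) {
      p$rng_seed <- 1000L + 10L * s + p$rng_seed
      img <- generate_nucleus_image(p, 256, 256)
      cellularity(img$label_mask, img$mpp)$cellularity
    }, numeric(1))
  })
  res <- welch_bonferroni(groups)
  expect_equal(nrow(res), 10)
  expect_true(all(res$significant))
  # and the class ordering of mean cellularity is the expected one
  ord <- names(sort(vapply(groups, mean, numeric(1)), decreasing = TRUE))
  expect_equal(ord, c("glioblastoma tumor cell area",
                      "anaplastic astrocytoma",
                      "glioblastoma microvascular proliferation area",
                      "diffuse astrocytoma",
                      "glioblastoma necrosis area"))
})

test_that("one-way ANOVA matches a from-scratch sum-of-squares oracle", {
  set.seed(13)
  for (i in 1:20) {
    k <- sample(2:5, 1)
    groups <- lapply(seq_len(k), function(j) rnorm(sample(3:12, 1), mean = j))
    names(groups) <- paste0("g", seq_len(k))
    got <- one_way_anova(groups)
    values <- unlist(groups); f <- rep(seq_len(k), lengths(groups))
    grand <- mean(values)
    ssb <- sum(tapply(values, f, length) * (tapply(values, f, mean) - grand)^2)
    ssw <- sum((values - ave(values, f))^2)
    oracle <- (ssb / (k - 1)) / (ssw / (length(values) - k))
    expect_lt(abs(got$f_statistic - oracle), 1e-10)
    # and agreement with the standard equal-variance implementation
    ow <- oneway.test(values ~ factor(f), var.equal = TRUE)
    expect_lt(abs(got$f_statistic - unname(ow$statistic)), 1e-8)
    expect_lt(abs(got$p_value - ow$p.value), 1e-10)
  }
})

test_that("with two groups F equals the squared pooled-variance t statistic", {
  set.seed(17)
  a <- rnorm(12); b <- rnorm(15, 0.8)
  f <- one_way_anova(list(a = a, b = b))$f_statistic
  t2 <- unname(t.test(a, b, var.equal = TRUE)$statistic)^2
  expect_lt(abs(f - t2), 1e-10)
})

test_that("shifted groups are detected with high power", {
  set.seed(23)
  hits <- 0L
  for (i in 1:100) {
    groups <- lapply(0:4, function(m) rnorm(50, mean = m))  # delta = 1 SD
    names(groups) <- paste0("g", 1:5)
    if (one_way_anova(groups)$p_value < 0.001) hits <- hits + 1L
  }
  expect_gte(hits, 95)
})

test_that("all-constant groups are flagged as degenerate", {
  res <- one_way_anova(list(a = c(2, 2, 2), b = c(5, 5, 5)))
  expect_true(res$degenerate)
  expect_true(is.infinite(res$f_statistic))
  same <- one_way_anova(list(a = c(2, 2, 2), b = c(2, 2, 2)))
  expect_true(same$degenerate)
})

test_that("moment_anova compares per-unit moments across groups", {
  set.seed(31)
  dat <- do.call(rbind, lapply(1:3, function(g)
    do.call(rbind, lapply(1:6, function(u) data.frame(
      category = paste0("cat", g), case_id = paste0("c", g, "_", u),
      area = rnorm(30, mean = 10 * g))))))
  res <- moment_anova(dat, "area")
  expect_setequal(res$moment, c("mean", "variance", "skewness", "kurtosis"))
  expect_lt(res$p_value[res$moment == "mean"], 1e-6)
})

test_that("bootstrap CIs are seeded, degenerate correctly, and shrink with n", {
  correct <- data.frame(truth = rep("a", 30), pred = rep("a", 30))
  acc <- function(d) mean(d$truth == d$pred)
  ci <- bootstrap_ci(correct, acc, n_resamples = 50, seed = 2)
  expect_equal(ci$lower, 1); expect_equal(ci$upper, 1)
  expect_equal(ci$point_estimate, 1)

  ci_mean <- bootstrap_ci(1:100, mean, n_resamples = 2000, seed = 3)
  expect_lt(ci_mean$lower, 50.5); expect_gt(ci_mean$upper, 50.5)
  expect_equal(ci_mean$point_estimate, 50.5)

  expect_identical(bootstrap_ci(1:40, mean, seed = 7),
                   bootstrap_ci(1:40, mean, seed = 7))

  set.seed(41)
  widths <- sapply(c(25, 100, 400, 1600), function(n) {
    w <- replicate(20, {
      x <- rnorm(n)
      ci <- bootstrap_ci(x, mean, n_resamples = 50,
                         seed = sample.int(1e6, 1))
      ci$upper - ci$lower
    })
    mean(w)
  })
  expect_true(all(diff(widths) < 0))
})

test_that("a statistic undefined on some resamples triggers logged redraws", {
  x <- c(rep(NA_real_, 2), rnorm(20))
  st <- function(v) mean(v)   # NA when an NA lands in the resample... mean is NA
  ci <- bootstrap_ci(x, function(v) mean(v), n_resamples = 50, seed = 11)
  expect_gt(ci$n_redrawn, 0)
  expect_true(is.finite(ci$lower) && is.finite(ci$upper))
})
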