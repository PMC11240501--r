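# Group-comparison machinery: Welch's t with Bonferroni correction for all
# pairwise cellularity comparisons, classical one-way ANOVA per moment per
# feature, and percentile bootstrap confidence intervals.

#' Pairwise Welch's t-tests with Bonferroni correction
#'
#' Tests equality of means for every unordered pair of groups with Welch's
#' unequal-variance t-test; p-values are Bonferroni-adjusted by the number
#' of comparisons performed (10 for five groups).
#'
#' @param groups named list mapping group name to a numeric vector.
#' @param alpha family significance level (default 0.05).
#' @return data.frame with one row per pair: `group_a`, `group_b`,
#'   `t_statistic`, `df` (Welch-Satterthwaite), `p_raw`,
#'   `p_adjusted` (= min(1, p_raw x m)), `significant`.  Pairs involving a
#'   group with fewer than 2 values are skipped with a warning.
#' @export
#' @examples
#' g <- list(a = rnorm(20), b = rnorm(20, 2), c = rnorm(20, 4))
#' welch_bonferroni(g)
welch_bonferroni <- function(groups, alpha = 0.05) {
  stopifnot(is.list(groups), length(groups) >= 2, !is.null(names(groups)))
  ok <- vapply(groups, function(g) sum(is.finite(g)) >= 2, TRUE)
  if (any(!ok))
    warning("groups skipped (n < 2): ", paste(names(groups)[!ok], collapse = ", "))
  groups <- lapply(groups[ok], function(g) g[is.finite(g)])
  nm <- names(groups)
  pairs <- utils::combn(nm, 2)
  m <- ncol(pairs)
  res <- lapply(seq_len(m), function(i) {
    a <- groups[[pairs[1, i]]]; b <- groups[[pairs[2, i]]]
    if (stats::var(a) + stats::var(b) > 0) {
      tt <- stats::t.test(a, b, var.equal = FALSE)
      data.frame(group_a = pairs[1, i], group_b = pairs[2, i],
                 t_statistic = unname(tt$statistic),
                 df = unname(tt$parameter), p_raw = tt$p.value)
    } else {
      # both groups constant: t is 0/0 if means agree, +-Inf otherwise
      equal <- mean(a) == mean(b)
      data.frame(group_a = pairs[1, i], group_b = pairs[2, i],
                 t_statistic = if (equal) 0 else sign(mean(a) - mean(b)) * Inf,
                 df = NA_real_, p_raw = if (equal) 1 else 0)
    }
  })
  res <- do.call(rbind, res)
  res$p_adjusted <- pmin(1, res$p_raw * m)
  res$significant <- res$p_adjusted < alpha
  res
}

#' Classical one-way ANOVA
#'
#' Between/within mean-square F-test of equal group means with pooled
#' (equal) variances, as used to compare feature-moment distributions
#' between categories.  With two groups the F statistic equals the square
#' of the pooled-variance t statistic.
#'
#' @param groups named list mapping group name to a numeric vector (>= 2
#'   groups, each with >= 2 values).
#' @param feature,moment optional labels carried into the result.
#' @return One-row data.frame: `feature`, `moment`, `f_statistic`,
#'   `df_between`, `df_within`, `p_value`, `degenerate` (TRUE when the
#'   within-group variance is zero everywhere, in which case F is Inf for
#'   separated means, NaN for identical constants).
#' @export
one_way_anova <- function(groups, feature = NA_character_,
                          moment = NA_character_) {
  stopifnot(is.list(groups), length(groups) >= 2)
  groups <- lapply(groups, function(g) g[is.finite(g)])
  stopifnot(all(vapply(groups, length, 0L) >= 2))
  values <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), vapply(groups, length, 0L)))
  k <- nlevels(g); n <- length(values)
  ss_within <- sum(tapply(values, g, function(v) sum((v - mean(v))^2)))
  ss_between <- sum(tapply(values, g, length) *
                      (tapply(values, g, mean) - mean(values))^2)
  df_b <- k - 1; df_w <- n - k
  degenerate <- ss_within == 0
  f <- (ss_between / df_b) / (ss_within / df_w)
  p <- if (degenerate) {
    if (ss_between > 0) 0 else NA_real_
  } else stats::pf(f, df_b, df_w, lower.tail = FALSE)
  data.frame(feature = feature, moment = moment, f_statistic = f,
             df_between = df_b, df_within = df_w, p_value = p,
             degenerate = degenerate)
}

#' Per-moment ANOVA across categories for every feature
#'
#' For each feature column, summarises values per unit with
#' [moment_summary()] and runs [one_way_anova()] on each moment across the
#' groups -- the shape of a moments-by-features comparison table.
#'
#' @param data data.frame of per-nucleus feature values with a group column
#'   and a unit column (the aggregation unit, e.g. case).
#' @param feature_cols character vector of feature column names.
#' @param group_col,unit_col names of the group and unit columns.
#' @return data.frame of [one_way_anova()] rows, one per feature x moment.
#' @export
moment_anova <- function(data, feature_cols,
                         group_col = "category", unit_col = "case_id") {
  stopifnot(all(c(feature_cols, group_col, unit_col) %in% names(data)))
  moments <- c("mean", "variance", "skewness", "kurtosis")
  out <- list()
  for (f in feature_cols) {
    per_unit <- do.call(rbind, lapply(
      split(data, data[c(group_col, unit_col)], drop = TRUE),
      function(d) cbind(group = d[[group_col]][1],
                        moment_summary(d[[f]], unit_id = d[[unit_col]][1]))))
    for (mo in moments) {
      groups <- split(per_unit[[mo]], per_unit$group)
      groups <- lapply(groups, function(v) v[is.finite(v)])
      groups <- groups[vapply(groups, length, 0L) >= 2]
      if (length(groups) >= 2)
        out[[paste(f, mo)]] <- one_way_anova(groups, feature = f, moment = mo)
    }
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Percentile bootstrap confidence interval
#'
#' Resamples the items with replacement at full size `n_resamples` times
#' and reads the 2.5/97.5 empirical percentiles of the statistic as the
#' 95% interval; the point estimate is the statistic of the full sample.
#' A resample on which the statistic is undefined (NA/error) is redrawn and
#' logged.
#'
#' @param items numeric vector, or data.frame resampled by row (e.g. pairs
#'   of truth and prediction).
#' @param statistic function of one argument (the resampled items).
#' @param n_resamples number of bootstrap resamples (default 50).
#' @param seed integer seed; the same seed reproduces the interval exactly.
#' @param conf confidence level (default 0.95).
#' @return List of class `bootstrap_ci`: `point_estimate`, `lower`,
#'   `upper`, `n_resamples`, `seed`, `resample_values`, `n_redrawn`.
#' @export
#' @examples
#' bootstrap_ci(1:100, mean, n_resamples = 50, seed = 1)
bootstrap_ci <- function(items, statistic, n_resamples = 50L, seed = 1L,
                         conf = 0.95) {
  n <- if (is.data.frame(items)) nrow(items) else length(items)
  stopifnot(n >= 2, n_resamples >= 1)
  take <- function(idx) if (is.data.frame(items)) items[idx, , drop = FALSE]
                        else items[idx]
  point <- statistic(take(seq_len(n)))
  with_seed(seed, {
    vals <- numeric(n_resamples)
    redrawn <- 0L
    for (i in seq_len(n_resamples)) {
      repeat {
        v <- tryCatch(statistic(take(sample.int(n, n, replace = TRUE))),
                      error = function(e) NA_real_)
        if (is.finite(v)) break
        redrawn <- redrawn + 1L
        if (redrawn > 100L * n_resamples)
          stop("statistic undefined on too many bootstrap resamples")
      }
      vals[i] <- v
    }
    qq <- stats::quantile(vals, c((1 - conf) / 2, 1 - (1 - conf) / 2),
                          names = FALSE)
    structure(list(point_estimate = point, lower = qq[1], upper = qq[2],
                   n_resamples = as.integer(n_resamples),
                   seed = as.integer(seed),
                   resample_values = vals, n_redrawn = redrawn),
              class = "bootstrap_ci")
  })
}

#' @export
print.bootstrap_ci <- function(x, ...) {
  cat(sprintf("<bootstrap_ci> %.4f [%.4f, %.4f] (%d resamples)\n",
              x$point_estimate, x$lower, x$upper, x$n_resamples))
  invisible(x)
}
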