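# Gradient-boosted-tree classification of feature category from the seven
# quantified descriptors, and bootstrap-CI importance weighting by split
# counts.

#' Names of the seven morphometric descriptors
#'
#' Cellularity plus the six nuclear feature means, in canonical order --
#' the column contract for the feature model.
#'
#' @return Character vector of length 7.
#' @export
feature_names <- function() {
  c("cellularity", "axis_ratio", "circularity", "entropy", "area",
    "irregularity", "perimeter")
}

default_xgb_params <- function() {
  list(max_depth = 6, eta = 0.3, nrounds = 100)
}

#' Fit a gradient-boosted classifier on morphometric descriptors
#'
#' Multiclass XGBoost (softprob objective) over the seven descriptors
#' (cellularity plus the six nuclear feature means).  Single-threaded and
#' seeded, so refits are bit-reproducible.
#'
#' @param features data.frame or matrix of numeric descriptor columns.
#' @param labels character/factor vector of category labels (>= 2 classes).
#' @param hyperparams list with `max_depth`, `eta`, `nrounds` (defaults
#'   6 / 0.3 / 100).
#' @param seed integer seed.
#' @return Object of class `feature_classifier` with the fitted booster,
#'   feature names and class levels.
#' @export
fit_feature_classifier <- function(features, labels,
                                   hyperparams = default_xgb_params(),
                                   seed = 1L) {
  features <- as.matrix(features)
  storage.mode(features) <- "double"
  labels <- factor(labels)
  if (nlevels(labels) < 2)
    stop("need at least 2 classes to fit a classifier")
  stopifnot(nrow(features) == length(labels))
  hp <- utils::modifyList(default_xgb_params(), hyperparams)
  with_seed(seed, {
    dtrain <- xgboost::xgb.DMatrix(features,
                                   label = as.integer(labels) - 1L)
    booster <- xgboost::xgb.train(
      params = list(objective = "multi:softprob",
                    num_class = nlevels(labels),
                    max_depth = hp$max_depth, eta = hp$eta,
                    nthread = 1, seed = seed),
      data = dtrain, nrounds = hp$nrounds, verbose = 0)
    structure(list(booster = booster,
                   feature_names = colnames(features),
                   levels = levels(labels),
                   hyperparams = hp, seed = as.integer(seed)),
              class = "feature_classifier")
  })
}

#' Predict categories from a fitted feature classifier
#'
#' @param object a `feature_classifier`.
#' @param newdata data.frame or matrix with the training feature columns.
#' @param ... unused.
#' @return Character vector of predicted category labels.
#' @export
predict.feature_classifier <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  storage.mode(newdata) <- "double"
  p <- predict(object$booster, xgboost::xgb.DMatrix(newdata))
  if (!is.matrix(p))
    p <- matrix(p, ncol = length(object$levels), byrow = TRUE)
  object$levels[max.col(p, ties.method = "first")]
}

#' Split-count ("weight") importance of each feature
#'
#' The number of tree splits using each feature across the whole boosted
#' ensemble: nonnegative integers summing to the total split count.
#' Features never used split zero times and are included.
#'
#' @param model a `feature_classifier`.
#' @return Named integer vector over the training features.
#' @export
split_count_importance <- function(model) {
  stopifnot(inherits(model, "feature_classifier"))
  tr <- xgboost::xgb.model.dt.tree(model = model$booster)
  used <- tr$Feature[tr$Feature != "Leaf"]
  counts <- table(factor(used, levels = model$feature_names))
  out <- as.integer(counts)
  names(out) <- model$feature_names
  out
}

#' Bootstrap-CI importance weighting
#'
#' Refits the classifier on `n_resamples` bootstrap resamples of the rows
#' and summarises each feature's split-count importance by the full-sample
#' value with percentile 95% bounds over the resamples.  Resamples that
#' lose all but one class are redrawn.
#'
#' @param features data.frame/matrix of descriptor columns.
#' @param labels category labels.
#' @param n_resamples bootstrap resamples (default 50).
#' @param seed integer seed.
#' @param hyperparams passed to [fit_feature_classifier()].
#' @return data.frame of class `importance_report`: `feature`, `weight`
#'   (full-sample split count), `lower_95`, `upper_95`, `rank` (1 = most
#'   important).
#' @export
importance_with_ci <- function(features, labels, n_resamples = 50L,
                               seed = 1L,
                               hyperparams = default_xgb_params()) {
  features <- as.matrix(features)
  labels <- factor(labels)
  n <- nrow(features)
  point <- split_count_importance(
    fit_feature_classifier(features, labels, hyperparams, seed = seed))
  with_seed(seed, {
    draws <- matrix(NA_real_, n_resamples, length(point),
                    dimnames = list(NULL, names(point)))
    for (i in seq_len(n_resamples)) {
      repeat {
        idx <- sample.int(n, n, replace = TRUE)
        if (length(unique(labels[idx])) >= 2) break
      }
      fit <- fit_feature_classifier(features[idx, , drop = FALSE],
                                    droplevels(labels[idx]),
                                    hyperparams, seed = seed + i)
      draws[i, ] <- split_count_importance(fit)
    }
    ci <- apply(draws, 2, stats::quantile, probs = c(0.025, 0.975),
                names = FALSE)
    out <- data.frame(feature = names(point), weight = as.numeric(point),
                      lower_95 = ci[1, ], upper_95 = ci[2, ],
                      row.names = NULL)
    out$rank <- rank(-out$weight, ties.method = "first")
    class(out) <- c("importance_report", "data.frame")
    out[order(out$rank), ]
  })
}
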