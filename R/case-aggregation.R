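# Case-level diagnosis from per-case patch-prediction counts: ratios,
# inclusion criteria, and a highest-grade-wins decision over the passing
# categories.

#' Patch-count ratios for one case
#'
#' @param counts five nonnegative integers, one per predicted category in
#'   [feature_categories()] order, summing to at least 1.
#' @return Numeric vector of five ratios summing to 1.  Classification uses
#'   these unrounded values; for display, round to 3 decimals as in
#'   published per-case tables.
#' @export
#' @examples
#' round(compute_ratios(c(5025, 3, 0, 9, 0)), 3)
compute_ratios <- function(counts) {
  stopifnot(length(counts) == 5, all(counts >= 0),
            all(counts == floor(counts)))
  total <- sum(counts)
  if (total == 0) stop("case has zero patches; ratios undefined")
  as.numeric(counts) / total
}

#' Inclusion criterion
#'
#' The minimum patch ratio a predicted category must reach to participate
#' in case-level classification.  `tau = 0` means any category with a
#' strictly positive ratio participates ("any predicted patch ratio is
#' considered"); for `tau > 0` participation requires `ratio >= tau`
#' (boundary inclusive).
#'
#' @param tau real in \[0, 1).
#' @return Object of class `inclusion_criterion`.
#' @export
inclusion_criterion <- function(tau) {
  stopifnot(is.numeric(tau), length(tau) == 1, tau >= 0, tau < 1)
  structure(list(tau = tau), class = "inclusion_criterion")
}

#' Classify one case from its category ratios
#'
#' Categories whose ratio passes the inclusion criterion form the passing
#' set; the predicted diagnosis is the highest WHO grade among them (any of
#' the three glioblastoma sub-categories implies glioblastoma > anaplastic
#' astrocytoma > diffuse astrocytoma).  The determinant is the
#' highest-grade passing category (ties within the top grade broken by the
#' larger ratio).  If no category passes -- possible only for tau > 0.2 --
#' the argmax-ratio category decides.
#'
#' @param ratios five ratios (or raw counts; they are normalised).
#' @param tau an [inclusion_criterion()] or a bare numeric in \[0, 1).
#' @return List of class `case_classification`: `tau`, `ratios`,
#'   `passing` (logical 5-vector), `determinant` (category),
#'   `predicted_diagnosis`.
#' @export
#' @examples
#' classify_case(c(5025, 3, 0, 9, 0), 0.02)$predicted_diagnosis
classify_case <- function(ratios, tau) {
  if (inherits(tau, "inclusion_criterion")) tau <- tau$tau
  stopifnot(is.numeric(tau), length(tau) == 1, tau >= 0, tau < 1)
  stopifnot(length(ratios) == 5, all(ratios >= 0), sum(ratios) > 0)
  ratios <- ratios / sum(ratios)
  passing <- if (tau == 0) ratios > 0 else ratios >= tau
  cats <- feature_categories()
  cand <- if (any(passing)) which(passing) else which.max(ratios)
  grades <- category_grade(cats[cand])
  top <- cand[grades == max(grades)]
  determinant <- cats[top[which.max(ratios[top])]]
  structure(list(tau = tau, ratios = ratios, passing = passing,
                 determinant = determinant,
                 predicted_diagnosis = category_diagnosis(determinant)),
            class = "case_classification")
}

#' @export
print.case_classification <- function(x, ...) {
  cat(sprintf("<case_classification> tau %.2f -> %s (determinant: %s)\n",
              x$tau, x$predicted_diagnosis, x$determinant))
  invisible(x)
}

#' Classify every case in a patch-count table
#'
#' @param table data.frame with columns `case_id`, `true_diagnosis` and the
#'   five count columns `diffuse`, `anaplastic`, `gbm_tumor`,
#'   `gbm_necrosis`, `gbm_mvp` (see [generate_patch_count_table()]).
#' @param taus numeric vector of inclusion criteria (default the three
#'   published ones: 0, 0.02, 0.05).
#' @return List with `classifications` (data.frame: `case_id`,
#'   `true_diagnosis`, `tau`, `predicted_diagnosis`, `determinant`),
#'   `confusion` (per-tau list of 3 x 3 matrices, rows = true, columns =
#'   predicted) and `accuracy` (named per-tau vector, trace / total).
#' @export
classify_table <- function(table, taus = c(0, 0.02, 0.05)) {
  stopifnot(all(c("case_id", "true_diagnosis", count_columns()) %in%
                  names(table)))
  if (!all(table$true_diagnosis %in% diagnosis_levels()))
    stop("unknown diagnosis label in true_diagnosis")
  counts <- as.matrix(table[count_columns()])
  lv <- diagnosis_levels()
  cls <- do.call(rbind, lapply(taus, function(tau) {
    preds <- apply(counts, 1, function(cnt) {
      cc <- classify_case(compute_ratios(cnt), tau)
      c(cc$predicted_diagnosis, cc$determinant)
    })
    data.frame(case_id = table$case_id,
               true_diagnosis = table$true_diagnosis,
               tau = tau,
               predicted_diagnosis = preds[1, ],
               determinant = preds[2, ],
               row.names = NULL)
  }))
  confusion <- lapply(taus, function(tau) {
    sub <- cls[cls$tau == tau, ]
    table(factor(sub$true_diagnosis, levels = lv),
          factor(sub$predicted_diagnosis, levels = lv),
          dnn = c("true", "predicted"))
  })
  names(confusion) <- format(taus, nsmall = 2)
  accuracy <- vapply(confusion, function(m) sum(diag(m)) / sum(m), numeric(1))
  list(classifications = cls, confusion = confusion, accuracy = accuracy)
}

#' Worked per-case patch-count example table
#'
#' The packaged nine-case table of patch-prediction counts from testing
#' cases with at least one misclassification, shipped as plain CSV.  Used
#' by the examples and by the verification suite.
#'
#' @param reported if TRUE, return the companion table of reported 3-dp
#'   ratios and case decisions at the three inclusion criteria instead of
#'   the counts.
#' @return data.frame.
#' @export
#' @examples
#' head(worked_case_table())
worked_case_table <- function(reported = FALSE) {
  f <- if (reported) "table2_reported.csv" else "table2_patch_counts.csv"
  path <- system.file("extdata", f, package = "gliomorph", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
}
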