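#' Characteristic pathological feature categories
#'
#' The five annotation categories used throughout the pipeline, in canonical
#' order: diffuse astrocytoma, anaplastic astrocytoma, and the three
#' glioblastoma sub-categories (tumor cell area, necrosis area,
#' microvascular proliferation area).
#'
#' @return Character vector of length 5.
#' @export
#' @examples
#' feature_categories()
feature_categories <- function() {
  c("diffuse astrocytoma",
    "anaplastic astrocytoma",
    "glioblastoma tumor cell area",
    "glioblastoma necrosis area",
    "glioblastoma microvascular proliferation area")
}

#' Case-level diagnosis labels
#'
#' @return Character vector of the three case-level diagnoses, ordered by
#'   WHO grade (II, III, IV).
#' @export
diagnosis_levels <- function() {
  c("diffuse astrocytoma", "anaplastic astrocytoma", "glioblastoma")
}

#' Map a feature category to its case-level diagnosis
#'
#' Each of the three glioblastoma sub-categories (tumor cell, necrosis,
#' microvascular proliferation area) maps to the glioblastoma diagnosis;
#' diffuse and anaplastic astrocytoma map to themselves.
#'
#' @param category character vector of feature categories.
#' @return Character vector of diagnoses, same length as `category`.
#' @export
#' @examples
#' category_diagnosis("glioblastoma necrosis area")
category_diagnosis <- function(category) {
  stopifnot(all(category %in% feature_categories()))
  ifelse(category %in% feature_categories()[3:5], "glioblastoma", category)
}

# WHO grade of the diagnosis a category maps to: II = 2, III = 3, IV = 4.
category_grade <- function(category) {
  c(2L, 3L, 4L)[match(category_diagnosis(category), diagnosis_levels())]
}
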