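#' Tidy a cross-validation result
#'
#' @param x An `heq_cv` object from [lopo_cv()].
#' @param ... Unused.
#' @return A tibble with one row per slice: `patient_id`, `slice_id`,
#'   `true_score`, `predicted_score`, `correct`.
#' @export
tidy.heq_cv <- function(x, ...) {
  dplyr::mutate(x$predictions,
                correct = .data$true_score == .data$predicted_score)
}

#' @rdname tidy.heq_cv
#' @return `glance()`: a one-row tibble with `accuracy`, `weighted_kappa`,
#'   `n_slices`, `n_patients`, `n_trees`, `feature_fraction`,
#'   `keep_fraction`.
#' @export
glance.heq_cv <- function(x, ...) {
  tab <- contingency_table(x)
  tibble::tibble(
    accuracy = x$accuracy,
    weighted_kappa = suppressWarnings(weighted_kappa(tab)),
    n_slices = nrow(x$predictions),
    n_patients = dplyr::n_distinct(x$predictions$patient_id),
    n_trees = x$config$n_trees,
    feature_fraction = x$config$feature_fraction,
    keep_fraction = x$config$keep_fraction)
}

#' Tidy a grid search
#'
#' @param x An `heq_grid_search` object.
#' @param ... Unused.
#' @return A tibble with one row per configuration (`n_trees`,
#'   `feature_fraction`, `accuracy`), ordered as evaluated.
#' @export
tidy.heq_grid_search <- function(x, ...) {
  dplyr::select(x$results, -dplyr::all_of("cv"))
}

#' @rdname tidy.heq_grid_search
#' @export
glance.heq_grid_search <- function(x, ...) {
  glance(x$best)
}
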