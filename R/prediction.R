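#' Random-Forest hyperparameter grid
#'
#' The default grid crosses the number of trees (10, 100, 1000) with the
#' fraction of the feature vector considered at each split (0.1, 0.3, 0.5,
#' 0.7, 0.9); the per-split feature count is `max(1, round(fraction * p))`
#' with half-up rounding.
#'
#' @param n_trees Integer vector of forest sizes.
#' @param feature_fraction Numeric vector of per-split feature fractions in
#'   (0, 1].
#' @return A tibble with columns `n_trees` and `feature_fraction`, one row
#'   per configuration (15 by default).
#' @export
rf_grid <- function(n_trees = c(10L, 100L, 1000L),
                    feature_fraction = c(0.1, 0.3, 0.5, 0.7, 0.9)) {
  if (any(n_trees < 1)) abort("n_trees must be positive")
  if (any(feature_fraction <= 0 | feature_fraction > 1)) {
    abort("feature_fraction must lie in (0, 1]")
  }
  tidyr::expand_grid(n_trees = as.integer(n_trees),
                     feature_fraction = feature_fraction)
}

score_levels <- as.character(0:5)

# fit a forest on a training fold and predict the test fold.
# A single-class training fold yields that class for every test slice.
fit_fold <- function(x_train, y_train, x_test, n_trees, feature_fraction) {
  y_train <- factor(y_train, levels = score_levels)
  observed <- droplevels(y_train)
  if (nlevels(observed) == 1L) {
    return(rep(levels(observed), nrow(x_test)))
  }
  mtry <- max(1L, round_half_up(feature_fraction * ncol(x_train)))
  fit <- randomForest::randomForest(x = x_train, y = observed,
                                    ntree = n_trees, mtry = mtry)
  as.character(predict(fit, x_test))
}

#' Importance-based feature selection on a training fold
#'
#' Fits a forest on the training fold only, ranks features by mean decrease
#' in Gini impurity, and keeps the top `ceiling(keep_fraction * p)` of them.
#' Inside [lopo_cv()] this runs within each training partition, so the held
#' out patient never influences which features survive.
#'
#' @param x Numeric training feature matrix.
#' @param y Training scores.
#' @param n_trees,feature_fraction Forest configuration used for the ranking
#'   fit.
#' @param keep_fraction Fraction of features to retain, in (0, 1];
#'   `1` keeps every feature.
#' @return Integer indices of the retained columns of `x`, in original
#'   column order.
#' @export
select_features <- function(x, y, n_trees = 100L, feature_fraction = 0.3,
                            keep_fraction = 1) {
  if (keep_fraction <= 0 || keep_fraction > 1) {
    abort("keep_fraction must lie in (0, 1]")
  }
  p <- ncol(x)
  n_keep <- ceiling(keep_fraction * p)
  if (n_keep == p) return(seq_len(p))
  y <- droplevels(factor(y, levels = score_levels))
  mtry <- max(1L, round_half_up(feature_fraction * p))
  fit <- randomForest::randomForest(x = x, y = y, ntree = n_trees,
                                    mtry = mtry, importance = FALSE)
  imp <- randomForest::importance(fit, type = 2)[, 1]
  sort(order(imp, decreasing = TRUE)[seq_len(n_keep)])
}

#' Leave-one-patient-out cross-validated score prediction
#'
#' For each patient in turn, trains a Random Forest on every other patient's
#' slices and predicts the held-out patient's slices, so no slice of a
#' patient ever informs that patient's predictions. Optionally performs
#' importance-based feature selection within each training partition before
#' the final fit ([select_features()]).
#'
#' @param features An `heq_features` tibble with `patient_id`, `slice_id`
#'   and `score` columns (see [build_features()]).
#' @param n_trees,feature_fraction Forest configuration (see [rf_grid()]).
#' @param keep_fraction Per-fold feature-selection fraction; 1 disables
#'   selection.
#' @param seed Integer seed; results are reproducible given the same
#'   features, configuration and seed.
#' @return An object of class `heq_cv`: per-slice predictions, the
#'   configuration, and overall accuracy. Use [tidy()] for the per-slice
#'   records and [glance()] for a one-row summary.
#' @export
lopo_cv <- function(features, n_trees = 100L, feature_fraction = 0.3,
                    keep_fraction = 1, seed = 1L) {
  if (!all(c("patient_id", "slice_id", "score") %in% names(features))) {
    abort("features must carry patient_id, slice_id and score")
  }
  if (!all(features$score %in% 0:5)) abort("scores must lie in 0..5")
  patients <- sort(unique(features$patient_id))
  if (length(patients) < 2) abort("leave-one-patient-out needs at least 2 patients")

  x <- feature_matrix(features)
  y <- as.character(features$score)
  set.seed(seed)
  preds <- purrr::map(patients, function(p) {
    test_idx <- which(features$patient_id == p)
    train_idx <- which(features$patient_id != p)
    x_train <- x[train_idx, , drop = FALSE]
    y_train <- y[train_idx]
    keep <- select_features(x_train, y_train, n_trees, feature_fraction,
                            keep_fraction)
    pred <- fit_fold(x_train[, keep, drop = FALSE], y_train,
                     x[test_idx, keep, drop = FALSE],
                     n_trees, feature_fraction)
    tibble::tibble(patient_id = p,
                   slice_id = features$slice_id[test_idx],
                   true_score = features$score[test_idx],
                   predicted_score = as.integer(pred))
  })
  preds <- dplyr::bind_rows(preds)
  structure(
    list(predictions = preds,
         accuracy = mean(preds$true_score == preds$predicted_score),
         config = list(n_trees = as.integer(n_trees),
                       feature_fraction = feature_fraction,
                       keep_fraction = keep_fraction, seed = as.integer(seed)),
         kind = attr(features, "kind"),
         grid = attr(features, "grid")),
    class = "heq_cv")
}

#' @export
print.heq_cv <- function(x, ...) {
  cat(sprintf(
    "Leave-one-patient-out CV (%s features): accuracy %.1f%% on %d slices\n",
    x$kind %||% "?", 100 * x$accuracy, nrow(x$predictions)))
  cat(sprintf("  trees = %d, feature fraction = %.1f, keep fraction = %.1f\n",
              x$config$n_trees, x$config$feature_fraction,
              x$config$keep_fraction))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Hyperparameter grid search under leave-one-patient-out CV
#'
#' Runs [lopo_cv()] for every configuration and selects the most accurate
#' one; ties are broken in favour of fewer trees, then a smaller feature
#' fraction. Note the selection uses the same cross-validation that is
#' reported, so the best accuracy is optimistically biased.
#'
#' @inheritParams lopo_cv
#' @param configs Tibble of configurations from [rf_grid()].
#' @return An object of class `heq_grid_search`: `best` (an `heq_cv`) and
#'   `results`, a tibble with one row per configuration (columns `n_trees`,
#'   `feature_fraction`, `accuracy`, and the fitted `cv` object).
#' @export
grid_search <- function(features, configs = rf_grid(), keep_fraction = 1,
                        seed = 1L) {
  if (nrow(configs) < 1) abort("need at least one configuration")
  fits <- purrr::pmap(configs, function(n_trees, feature_fraction) {
    lopo_cv(features, n_trees = n_trees, feature_fraction = feature_fraction,
            keep_fraction = keep_fraction, seed = seed)
  })
  results <- dplyr::mutate(configs,
                           accuracy = purrr::map_dbl(fits, "accuracy"),
                           cv = fits)
  ord <- order(-results$accuracy, results$n_trees, results$feature_fraction)
  structure(list(best = results$cv[[ord[1]]], results = results),
            class = "heq_grid_search")
}

#' @export
print.heq_grid_search <- function(x, ...) {
  cat(sprintf("Grid search over %d configurations; best:\n", nrow(x$results)))
  print(x$best)
  invisible(x)
}

#' Accuracy over every threshold sub-range
#'
#' Rebuilds the feature vectors for each of the 21 threshold sub-ranges
#' ([range_grid()]), runs a [grid_search()] on each, and tabulates the best
#' cross-validated accuracy per (lower, upper) cell — the lower-triangular
#' accuracy table.
#'
#' @inheritParams grid_search
#' @param curves Long quantification curves covering the full -1000..-700
#'   HU range (see [quantify_cohort()]).
#' @param kind `"laa"` or `"heq"`.
#' @param grids List of [threshold_grid()]s (default [range_grid()]).
#' @return A tibble with columns `lower_hu`, `upper_hu`, `accuracy`,
#'   `n_trees`, `feature_fraction` (the winning configuration per cell).
#' @export
range_sweep <- function(curves, kind = c("heq", "laa"), configs = rf_grid(),
                        grids = range_grid(), seed = 1L) {
  kind <- match.arg(kind)
  cells <- purrr::map(grids, function(g) {
    gs <- grid_search(build_features(curves, g, kind), configs, seed = seed)
    tibble::tibble(lower_hu = g$lower_hu, upper_hu = g$upper_hu,
                   accuracy = gs$best$accuracy,
                   n_trees = gs$best$config$n_trees,
                   feature_fraction = gs$best$config$feature_fraction)
  })
  dplyr::bind_rows(cells)
}
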