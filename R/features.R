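#' Threshold grids for the HU filtration
#'
#' A grid is the half-open range `[lower_hu, upper_hu)` sampled every
#' `step_hu` HU, so the default full range -1000 to -700 HU in 5 HU steps
#' has exactly 60 levels (-1000, -995, ..., -705).
#'
#' @param lower_hu,upper_hu Integer range bounds, `lower_hu < upper_hu`,
#'   with the difference divisible by `step_hu`.
#' @param step_hu Step size in HU (default 5).
#' @return An object of class `threshold_grid`.
#' @export
threshold_grid <- function(lower_hu = -1000L, upper_hu = -700L, step_hu = 5L) {
  if (lower_hu >= upper_hu) abort("lower_hu must be below upper_hu")
  if ((upper_hu - lower_hu) %% step_hu != 0) {
    abort("threshold range must be divisible by step_hu")
  }
  structure(list(lower_hu = as.integer(lower_hu),
                 upper_hu = as.integer(upper_hu),
                 step_hu = as.integer(step_hu)),
            class = "threshold_grid")
}

#' @rdname threshold_grid
#' @param grid A `threshold_grid`.
#' @return `thresholds()`: the integer vector of levels; `n_levels()`: its
#'   length.
#' @export
thresholds <- function(grid) {
  stopifnot(inherits(grid, "threshold_grid"))
  seq(grid$lower_hu, grid$upper_hu - grid$step_hu, by = grid$step_hu)
}

#' @rdname threshold_grid
#' @export
n_levels <- function(grid) length(thresholds(grid))

#' All threshold sub-ranges evaluated in the range sweep
#'
#' Enumerates every ordered pair of a lower limit in
#' \{-1000, -950, -900, -850, -800, -750\} and an upper limit in
#' \{-950, -900, -850, -800, -750, -700\} with lower < upper: the 21 cells
#' of the lower-triangular accuracy tables.
#'
#' @return A list of 21 [threshold_grid()] objects.
#' @export
range_grid <- function() {
  lowers <- seq(-1000L, -750L, by = 50L)
  uppers <- seq(-950L, -700L, by = 50L)
  grids <- list()
  for (lo in lowers) {
    for (up in uppers) {
      if (lo < up) grids[[length(grids) + 1L]] <- threshold_grid(lo, up)
    }
  }
  grids
}

feature_quantities <- function(kind) {
  switch(kind,
         laa = "laa_pct",
         heq = c("nb0", "nb1"),
         abort("kind must be 'laa' or 'heq'"))
}

#' Build classifier feature vectors from quantification curves
#'
#' Converts long per-slice quantification curves into one feature row per
#' slice over a threshold sub-range. For `kind = "laa"` the vector is LAA%
#' at each level, in ascending threshold order (length = number of levels);
#' for `kind = "heq"` it is the `nb0` block followed by the `nb1` block,
#' each ascending (twice the number of levels). Feature columns are named
#' `<quantity>_<threshold>`.
#'
#' @param curves A long `heq_curves` tibble (from [quantify_cohort()] or
#'   row-bound [quantify_slice()] results) with `slice_id`, `patient_id` and
#'   optionally `score` columns.
#' @param grid A [threshold_grid()]; every level must be present in
#'   `curves` for every slice.
#' @param kind `"laa"` or `"heq"`.
#' @return A tibble of class `heq_features`: `patient_id`, `slice_id`,
#'   `score` (if present), then the ordered feature columns. The feature
#'   schema is stored in `attr(, "schema")`.
#' @export
build_features <- function(curves, grid = threshold_grid(),
                           kind = c("heq", "laa")) {
  kind <- match.arg(kind)
  if (!all(c("slice_id", "patient_id") %in% names(curves))) {
    abort("curves must carry slice_id and patient_id")
  }
  lev <- thresholds(grid)
  missing_lev <- setdiff(lev, unique(curves$threshold_hu))
  if (length(missing_lev) > 0) {
    abort(paste0("curves are missing threshold level(s): ",
                 paste(missing_lev, collapse = ", "), " HU"))
  }
  quantities <- feature_quantities(kind)
  schema <- tidyr::expand_grid(quantity = quantities, threshold_hu = lev)
  sub <- dplyr::filter(curves, .data$threshold_hu %in% lev)

  per_slice <- table(sub$slice_id)
  if (any(per_slice != length(lev))) {
    bad <- names(per_slice)[per_slice != length(lev)][1]
    abort(paste0("slice ", bad, " does not cover every threshold level"))
  }

  id_cols <- intersect(c("patient_id", "slice_id", "score"), names(curves))
  long <- tidyr::pivot_longer(
    dplyr::select(sub, dplyr::all_of(c(id_cols, "threshold_hu", quantities))),
    cols = dplyr::all_of(quantities),
    names_to = "quantity", values_to = "value")
  long$feature <- paste0(long$quantity, "_", long$threshold_hu)
  wide <- tidyr::pivot_wider(
    dplyr::select(long, -dplyr::all_of(c("quantity", "threshold_hu"))),
    names_from = "feature", values_from = "value")

  feat_names <- paste0(schema$quantity, "_", schema$threshold_hu)
  wide <- dplyr::select(wide, dplyr::all_of(c(id_cols, feat_names)))
  if (any(!is.finite(as.matrix(wide[feat_names])))) {
    abort("non-finite feature values")
  }
  structure(wide, schema = schema, kind = kind, grid = grid,
            class = c("heq_features", class(wide)))
}

feature_names <- function(features) {
  schema <- attr(features, "schema")
  if (is.null(schema)) {
    # attributes can be dropped by subsetting; fall back on column layout
    return(setdiff(names(features), c("patient_id", "slice_id", "score")))
  }
  paste0(schema$quantity, "_", schema$threshold_hu)
}

feature_matrix <- function(features) {
  as.matrix(features[feature_names(features)])
}
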