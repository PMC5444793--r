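#' Read and write HU slices as NIfTI
#'
#' Slices are stored as int16 NIfTI (`.nii` / `.nii.gz`). Multi-slice
#' volumes are addressed with `slice_index` (third dimension). Non-integer
#' values after any scaling are rounded with a warning.
#'
#' @param path File path.
#' @param slice_index Optional index into the third dimension of a volume.
#' @return `read_slice()`: an integer HU matrix; `write_slice()`: `path`,
#'   invisibly.
#' @export
read_slice <- function(path, slice_index = NULL) {
  if (!file.exists(path)) abort(paste0("image file not found: ", path))
  arr <- as.array(RNifti::readNifti(path))
  arr <- drop(arr)
  if (length(dim(arr)) == 3) {
    if (is.null(slice_index)) {
      abort("volume has multiple slices: supply slice_index")
    }
    arr <- arr[, , slice_index]
  }
  if (length(dim(arr)) != 2) abort("expected a 2-D slice")
  if (any(arr != round(arr))) {
    warn("non-integer HU values: rounding")
    arr <- round_half_up(arr)
  }
  matrix(as.integer(arr), nrow(arr), ncol(arr))
}

#' @rdname read_slice
#' @param image Integer HU matrix to write.
#' @export
write_slice <- function(image, path) {
  check_hu_matrix(image)
  RNifti::writeNifti(RNifti::asNifti(image, datatype = "int16"), path)
  invisible(path)
}

#' Read and write quantification curves as CSV
#'
#' Columns: `threshold_hu`, `laa_pct`, `b0`, `b1`, `nb0`, `nb1`,
#' `lung_pixels`, plus `slice_id`, `patient_id` and `score` when present.
#'
#' @param curves An `heq_curves` tibble.
#' @param path CSV file path.
#' @return `read_curves()`: an `heq_curves` tibble; `write_curves()`:
#'   `path`, invisibly.
#' @export
write_curves <- function(curves, path) {
  readr::write_csv(curves, path)
  invisible(path)
}

#' @rdname write_curves
#' @export
read_curves <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE)
  out <- dplyr::mutate(out, dplyr::across(
    dplyr::any_of(c("threshold_hu", "b0", "b1", "lung_pixels", "score")),
    as.integer))
  class(out) <- c("heq_curves", class(out))
  out
}

#' Write a cohort to disk (images, masks, manifest)
#'
#' Writes every slice as int16 NIfTI, every mask as uint8 NIfTI, and a
#' manifest CSV with columns `patient_id`, `slice_id`, `score`,
#' `image_path`, `mask_path`.
#'
#' @param cohort An `heq_cohort` tibble (see [make_cohort()]).
#' @param dir Output directory, created if needed.
#' @return Path of the manifest CSV, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- dplyr::mutate(
    dplyr::select(cohort, dplyr::all_of(c("patient_id", "slice_id", "score"))),
    image_path = file.path(dir, paste0(.data$slice_id, "_img.nii.gz")),
    mask_path = file.path(dir, paste0(.data$slice_id, "_mask.nii.gz")))
  purrr::pwalk(list(cohort$image, cohort$mask,
                    manifest$image_path, manifest$mask_path),
               function(img, msk, ip, mp) {
                 write_slice(img, ip)
                 write_mask(msk, mp)
               })
  manifest_path <- file.path(dir, "manifest.csv")
  readr::write_csv(manifest, manifest_path)
  invisible(manifest_path)
}

#' Read a cohort from a manifest CSV
#'
#' @param manifest_path CSV with columns `patient_id`, `slice_id`, `score`,
#'   `image_path` and optionally `mask_path`; relative paths are resolved
#'   against the manifest's directory. Missing masks are left `NULL` and
#'   can be filled by segmentation.
#' @return An `heq_cohort` tibble.
#' @export
read_cohort <- function(manifest_path) {
  if (!file.exists(manifest_path)) {
    abort(paste0("manifest not found: ", manifest_path))
  }
  man <- readr::read_csv(manifest_path, show_col_types = FALSE)
  need <- c("patient_id", "slice_id", "score", "image_path")
  if (!all(need %in% names(man))) {
    abort(paste("manifest is missing columns:",
                paste(setdiff(need, names(man)), collapse = ", ")))
  }
  base <- dirname(manifest_path)
  resolve <- function(p) ifelse(file.exists(p), p, file.path(base, basename(p)))
  images <- purrr::map2(man$image_path, man$slice_id, function(p, sid) {
    p <- resolve(p)
    if (!file.exists(p)) {
      abort(paste0("slice ", sid, ": image file not found (", p, ")"))
    }
    read_slice(p)
  })
  masks <- if ("mask_path" %in% names(man)) {
    purrr::pmap(list(man$mask_path, man$slice_id, images),
                function(p, sid, img) {
                  if (is.na(p) || p == "") return(NULL)
                  p <- resolve(p)
                  if (!file.exists(p)) {
                    abort(paste0("slice ", sid, ": mask file not found (", p, ")"))
                  }
                  load_mask(p, reference = img)
                })
  } else {
    rep(list(NULL), nrow(man))
  }
  out <- tibble::tibble(patient_id = man$patient_id, slice_id = man$slice_id,
                        score = as.integer(man$score),
                        image = images, mask = masks)
  class(out) <- c("heq_cohort", class(out))
  out
}

#' Run the full quantification and prediction pipeline
#'
#' Orchestrates segment (for slices without a mask) -> quantify -> features
#' -> leave-one-patient-out grid search -> evaluation statistics, writing
#' every artifact plus the archived run configuration into `output_dir`.
#' Reruns with the same inputs and seed reproduce identical outputs.
#'
#' @param cohort An `heq_cohort` tibble, or a manifest CSV path for
#'   [read_cohort()].
#' @param output_dir Run directory, created if needed.
#' @param grid A [threshold_grid()].
#' @param kind `"heq"` or `"laa"`.
#' @param configs Hyperparameter grid from [rf_grid()].
#' @param seed Integer seed.
#' @param quiet Suppress per-stage progress messages.
#' @return A list with `curves`, `features`, `search` (the grid search),
#'   `stats` and `output_dir`, invisibly.
#' @export
run_pipeline <- function(cohort, output_dir, grid = threshold_grid(),
                         kind = c("heq", "laa"), configs = rf_grid(),
                         seed = 1L, quiet = FALSE) {
  kind <- match.arg(kind)
  say <- function(stage, ...) {
    if (!quiet) message(sprintf("[%s] ", stage), sprintf(...))
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("pipeline stage '", name, "' failed: ", conditionMessage(e)))
    })
  }
  if (is.character(cohort)) {
    cohort <- stage("load", read_cohort(cohort))
  }
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)

  say("segment", "segmenting %d slices without masks",
      sum(purrr::map_lgl(cohort$mask, is.null)))
  cohort$mask <- stage("segment", purrr::map2(cohort$mask, cohort$image, function(m, img) {
    if (is.null(m)) segment_lungs(img) else m
  }))

  say("quantify", "sweeping %d thresholds over %d slices",
      n_levels(grid), nrow(cohort))
  curves <- stage("quantify", quantify_cohort(cohort, grid))
  write_curves(curves, file.path(output_dir, "curves.csv"))

  say("features", "building %s feature vectors", kind)
  features <- stage("features", build_features(curves, grid, kind))
  readr::write_csv(features, file.path(output_dir, "features.csv"))

  say("cv", "grid search over %d configurations", nrow(configs))
  search <- stage("cv", grid_search(features, configs, seed = seed))
  best <- search$best
  jsonlite::write_json(
    list(best_config = best$config,
         accuracy = best$accuracy,
         configs = dplyr::select(search$results, -dplyr::all_of("cv")),
         predictions = best$predictions),
    file.path(output_dir, "cv.json"), auto_unbox = TRUE, digits = NA)

  say("stats", "evaluating the best configuration")
  tab <- stage("stats", contingency_table(best))
  stats <- list(accuracy = accuracy(tab),
                weighted_kappa = weighted_kappa(tab),
                contingency = tab)
  jsonlite::write_json(list(accuracy = stats$accuracy,
                            weighted_kappa = stats$weighted_kappa,
                            contingency = tab),
                       file.path(output_dir, "stats.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(
    list(grid = unclass(grid), kind = kind, seed = seed,
         configs = configs, n_slices = nrow(cohort)),
    file.path(output_dir, "config.json"), auto_unbox = TRUE, digits = NA)

  say("done", "artifacts in %s", output_dir)
  invisible(list(curves = curves, features = features, search = search,
                 stats = stats, output_dir = output_dir))
}
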