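#' Binarize a masked slice at an HU threshold
#'
#' Partitions the lung into low-attenuation (LAA) and normal-lung pixels at
#' a threshold: a lung pixel is LAA iff its HU is *strictly* below
#' `threshold_hu`. Non-lung pixels belong to neither set.
#'
#' @param image Integer HU matrix.
#' @param mask Logical lung mask congruent with `image`.
#' @param threshold_hu Integer threshold in `[-1024, 500]`.
#' @return A list of class `heq_binarized` with logical matrices `laa` and
#'   `normal_lung`, and `threshold_hu`.
#' @export
binarize <- function(image, mask, threshold_hu) {
  check_hu_matrix(image)
  check_mask(mask, image)
  if (threshold_hu < -1024 || threshold_hu > 500) {
    abort("threshold_hu outside the plausible HU range [-1024, 500]")
  }
  laa <- mask & (image < threshold_hu)
  structure(list(laa = laa, normal_lung = mask & !laa,
                 threshold_hu = as.integer(threshold_hu)),
            class = "heq_binarized")
}

#' Betti numbers of a binary 2-D image
#'
#' For the low-attenuation set of a slice, `b0` counts its connected regions
#' and `b1` counts the normal-lung islands those regions fully enclose. The
#' standard dual connectivity pairing is used: the foreground is 8-connected
#' and its complement 4-connected, and a complement component is a hole iff
#' it contains no image-border pixel. On lung slices all non-lung tissue and
#' outside air are border-connected, so the enclosed complement components
#' are exactly the surrounded normal-lung regions.
#'
#' @param laa Logical matrix (the low-attenuation set).
#' @return Named integer vector `c(b0, b1)`. An empty set gives `c(0, 0)`.
#' @examples
#' m <- matrix(FALSE, 5, 5); m[2:4, 2:4] <- TRUE; m[3, 3] <- FALSE
#' betti_numbers(m)  # an annulus: one component, one hole
#' @export
betti_numbers <- function(laa) {
  check_mask(laa)
  b <- betti_cpp(laa)
  c(b0 = b[1], b1 = b[2])
}

#' Euler characteristic of a binary image as a cubical set
#'
#' Treats each foreground pixel as a closed unit square and returns
#' chi = vertices - edges + faces of the union. Under the 8/4 connectivity
#' pairing of [betti_numbers()], `chi == b0 - b1` for every binary image,
#' which makes this an independent cross-check of the Betti computation.
#'
#' @param laa Logical matrix.
#' @return Integer Euler characteristic.
#' @export
euler_characteristic <- function(laa) {
  check_mask(laa)
  nr <- nrow(laa); nc <- ncol(laa)
  a <- matrix(FALSE, nr + 2L, nc + 2L)
  a[2:(nr + 1L), 2:(nc + 1L)] <- laa
  faces <- sum(laa)
  # horizontal edge slots: between vertically adjacent pixel rows (incl. borders)
  eh <- sum(a[1:(nr + 1L), 2:(nc + 1L)] | a[2:(nr + 2L), 2:(nc + 1L)])
  # vertical edge slots: between horizontally adjacent pixel columns
  ev <- sum(a[2:(nr + 1L), 1:(nc + 1L)] | a[2:(nr + 1L), 2:(nc + 2L)])
  verts <- sum(a[1:(nr + 1L), 1:(nc + 1L)] | a[1:(nr + 1L), 2:(nc + 2L)] |
                 a[2:(nr + 2L), 1:(nc + 1L)] | a[2:(nr + 2L), 2:(nc + 2L)])
  as.integer(verts - (eh + ev) + faces)
}

#' Quantify emphysema on one slice across a threshold filtration
#'
#' Sweeps the threshold grid and, at each level, computes the percentage of
#' low-attenuation lung area (LAA%), the Betti numbers `b0`/`b1` of the
#' low-attenuation set, and their area-normalized forms `nb0`/`nb1`
#' (divided by the total lung pixel count). Because the low-attenuation
#' sets are nested along the filtration, LAA% is monotone nondecreasing in
#' the threshold.
#'
#' @param image Integer HU matrix.
#' @param mask Logical lung mask with at least one lung pixel.
#' @param grid A [threshold_grid()]; default spans -1000 to -700 HU in
#'   5 HU steps (60 levels).
#' @param slice_id,patient_id Optional identifiers carried into the result.
#' @return A tibble of class `heq_curves`, one row per threshold, with
#'   columns `threshold_hu`, `laa_pct`, `b0`, `b1`, `nb0`, `nb1`,
#'   `lung_pixels` (plus identifiers when given).
#' @examples
#' ph <- make_phantom(phantom_spec(image_size = 96, lesion_count = 2))
#' quantify_slice(ph$image, ph$mask, threshold_grid(-1000, -900))
#' @export
quantify_slice <- function(image, mask, grid = threshold_grid(),
                           slice_id = NULL, patient_id = NULL) {
  check_hu_matrix(image)
  check_mask(mask, image)
  lung_pixels <- sum(mask)
  if (lung_pixels == 0L) abort("mask contains no lung pixels")
  out <- purrr::map(thresholds(grid), function(t) {
    bin <- binarize(image, mask, t)
    b <- betti_cpp(bin$laa)
    tibble::tibble(threshold_hu = as.integer(t),
                   laa_pct = 100 * sum(bin$laa) / lung_pixels,
                   b0 = b[1], b1 = b[2],
                   nb0 = b[1] / lung_pixels, nb1 = b[2] / lung_pixels,
                   lung_pixels = lung_pixels)
  })
  out <- dplyr::bind_rows(out)
  if (!is.null(slice_id)) out$slice_id <- slice_id
  if (!is.null(patient_id)) out$patient_id <- patient_id
  class(out) <- c("heq_curves", class(out))
  out
}

#' Quantify every slice of a cohort
#'
#' Applies [quantify_slice()] to each row of a cohort tibble, carrying
#' patient, slice and score metadata through.
#'
#' @param cohort A tibble with columns `patient_id`, `slice_id`, `score`,
#'   and list-columns `image` and `mask` (see [make_cohort()]).
#' @param grid A [threshold_grid()].
#' @return A long tibble of class `heq_curves`: one row per slice x
#'   threshold.
#' @export
quantify_cohort <- function(cohort, grid = threshold_grid()) {
  need <- c("patient_id", "slice_id", "score", "image", "mask")
  if (!all(need %in% names(cohort))) {
    abort(paste("cohort is missing columns:",
                paste(setdiff(need, names(cohort)), collapse = ", ")))
  }
  out <- purrr::pmap(
    list(cohort$image, cohort$mask, cohort$slice_id, cohort$patient_id,
         cohort$score),
    function(img, msk, sid, pid, sc) {
      cv <- quantify_slice(img, msk, grid, slice_id = sid, patient_id = pid)
      cv$score <- sc
      cv
    })
  out <- dplyr::bind_rows(out)
  class(out) <- c("heq_curves", class(out))
  out
}
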