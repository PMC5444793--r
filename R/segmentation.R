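#' Segment the lungs from an HU slice
#'
#' Lung segmentation by attenuation thresholding with border-component
#' removal: candidate pixels are those strictly below `threshold_hu`
#' (default -500 HU, well above lung tissue but below soft tissue), grouped
#' into 8-connected components. Components touching the image border are
#' outside-patient air and are excluded; remaining components smaller than
#' `min_area` pixels are dropped as airway or noise. The mask is the union of
#' the surviving components. The procedure is deterministic and idempotent.
#'
#' @param image Integer matrix of Hounsfield units, at least 16 x 16.
#' @param threshold_hu Segmentation threshold; pixels with HU strictly below
#'   it are lung candidates.
#' @param min_area Minimum component area in pixels (default 50).
#' @return A logical matrix congruent with `image` (`TRUE` = lung pixel).
#' @examples
#' ph <- make_phantom(phantom_spec(image_size = 96))
#' mask <- segment_lungs(ph$image)
#' sum(mask & ph$mask) / sum(mask | ph$mask)
#' @export
segment_lungs <- function(image, threshold_hu = -500L, min_area = 50L) {
  check_hu_matrix(image)
  if (nrow(image) < 16 || ncol(image) < 16) {
    abort("image must be at least 16 x 16 pixels")
  }
  cand <- image < threshold_hu
  lab <- label_components_cpp(cand, 8L)
  if (lab$n == 0L) abort("no lung found: no pixels below segmentation threshold")
  labels <- lab$labels
  border <- unique(c(labels[1, ], labels[nrow(labels), ],
                     labels[, 1], labels[, ncol(labels)]))
  sizes <- tabulate(labels, nbins = lab$n)
  keep <- setdiff(which(sizes >= min_area), border)
  if (length(keep) == 0L) {
    abort("no lung found: every candidate component is border-connected or too small")
  }
  matrix(labels %in% keep, nrow(image), ncol(image))
}

check_hu_matrix <- function(image) {
  if (!is.matrix(image) || !is.numeric(image) || length(image) == 0) {
    abort("expected a non-empty numeric matrix of Hounsfield units")
  }
  if (any(!is.finite(image))) abort("HU values must be finite")
  invisible(image)
}

check_mask <- function(mask, image = NULL) {
  if (!is.matrix(mask) || !is.logical(mask)) {
    abort("mask must be a logical matrix")
  }
  if (!is.null(image) && !identical(dim(mask), dim(image))) {
    abort("mask dimensions do not match the slice")
  }
  invisible(mask)
}

#' Read or write a lung mask as NIfTI
#'
#' Masks are stored as uint8 NIfTI volumes with values 0/1; any other value
#' is rejected on load. If `reference` is supplied, the mask must be
#' congruent with it.
#'
#' @param path File path (`.nii` or `.nii.gz`).
#' @param reference Optional HU matrix the mask will be paired with.
#' @return `load_mask()`: a logical matrix. `write_mask()`: `path`, invisibly.
#' @export
load_mask <- function(path, reference = NULL) {
  arr <- drop(as.array(RNifti::readNifti(path)))
  if (!is.matrix(arr)) abort("mask file must hold a single 2-D slice")
  if (!all(arr %in% c(0, 1))) {
    abort("mask contains values other than 0/1")
  }
  mask <- arr == 1
  if (!is.null(reference)) check_mask(mask, reference)
  mask
}

#' @rdname load_mask
#' @param mask Logical matrix to write.
#' @export
write_mask <- function(mask, path) {
  check_mask(mask)
  RNifti::writeNifti(RNifti::asNifti(mask * 1L, datatype = "uint8"), path)
  invisible(path)
}
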