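#' Specify a synthetic chest phantom
#'
#' Describes a single 2-D CT-like slice: an air background, an elliptical
#' body, two elliptical lung fields, and low-attenuation lesions of known
#' topology placed inside the lungs. Solid disk lesions each contribute one
#' connected low-attenuation component; annular ("ring") lesions each
#' contribute one component *and* one enclosed island of normal lung, so the
#' phantom's Betti numbers are known exactly by construction.
#'
#' @param image_size Pixels per side of the square slice.
#' @param body_hu,lung_hu,lesion_hu,air_hu Hounsfield units of body tissue,
#'   normal lung, lesion interior and outside-body air. Must satisfy
#'   `lesion_hu < lung_hu < body_hu`.
#' @param lesion_count Number of solid disk lesions (>= 0).
#' @param lesion_radius_px Disk radius in pixels (>= 1), at `image_size` 256;
#'   scaled proportionally for other sizes.
#' @param ring_count Number of annular lesions enclosing normal lung (>= 0).
#' @param ring_outer_px,ring_inner_px Outer and inner radii of annuli in
#'   pixels at `image_size` 256.
#' @param noise_sd Standard deviation (HU) of additive Gaussian noise,
#'   rounded back to integer HU; 0 gives a piecewise-constant slice.
#' @param seed Integer seed for lesion placement (and noise).
#'
#' @return An object of class `phantom_spec`.
#' @seealso [make_phantom()]
#' @export
phantom_spec <- function(image_size = 256L,
                         body_hu = 40L, lung_hu = -780L,
                         lesion_hu = -980L, air_hu = -1000L,
                         lesion_count = 0L, lesion_radius_px = 6,
                         ring_count = 0L, ring_outer_px = 10, ring_inner_px = 5,
                         noise_sd = 0, seed = 1L) {
  if (!(lesion_hu < lung_hu && lung_hu < body_hu)) {
    abort("phantom_spec requires lesion_hu < lung_hu < body_hu")
  }
  if (image_size < 32) abort("image_size must be at least 32")
  if (lesion_count < 0 || ring_count < 0) abort("lesion/ring counts must be >= 0")
  if (lesion_radius_px < 1) abort("lesion_radius_px must be >= 1")
  if (ring_inner_px < 1 || ring_outer_px <= ring_inner_px) {
    abort("need ring_outer_px > ring_inner_px >= 1")
  }
  if (noise_sd < 0) abort("noise_sd must be >= 0")
  structure(
    list(image_size = as.integer(image_size),
         body_hu = as.integer(body_hu), lung_hu = as.integer(lung_hu),
         lesion_hu = as.integer(lesion_hu), air_hu = as.integer(air_hu),
         lesion_count = as.integer(lesion_count),
         lesion_radius_px = lesion_radius_px,
         ring_count = as.integer(ring_count),
         ring_outer_px = ring_outer_px, ring_inner_px = ring_inner_px,
         noise_sd = noise_sd, seed = as.integer(seed)),
    class = "phantom_spec")
}

# elliptical body and lung fields, scaled to the image size
phantom_geometry <- function(s) {
  rr <- matrix(seq_len(s), s, s)
  cc <- matrix(seq_len(s), s, s, byrow = TRUE)
  ctr <- (s + 1) / 2
  ell <- function(cr, cv, ar, ac) ((rr - cr) / ar)^2 + ((cc - cv) / ac)^2 <= 1
  body <- ell(ctr, ctr, 0.45 * s, 0.42 * s)
  lungs <- list(
    list(cr = ctr, cv = 0.30 * s, ar = 0.30 * s, ac = 0.15 * s),
    list(cr = ctr, cv = 0.70 * s, ar = 0.30 * s, ac = 0.15 * s))
  lung_mask <- ell(lungs[[1]]$cr, lungs[[1]]$cv, lungs[[1]]$ar, lungs[[1]]$ac) |
    ell(lungs[[2]]$cr, lungs[[2]]$cv, lungs[[2]]$ar, lungs[[2]]$ac)
  list(body = body, lung_mask = lung_mask, lungs = lungs)
}

# sample a centre so a disk of radius rad (+margin to the lung border)
# lies inside one of the lung ellipses; rejection with a fixed attempt cap
place_disks <- function(lungs, radii, margin = 2, max_attempts = 1000) {
  placed <- list()
  for (rad in radii) {
    ok <- FALSE
    for (attempt in seq_len(max_attempts)) {
      lg <- lungs[[sample.int(2L, 1L)]]
      ar <- lg$ar - rad - margin
      ac <- lg$ac - rad - margin
      if (ar <= 0 || ac <= 0) next
      u <- stats::runif(1); v <- stats::runif(1)
      r <- sqrt(u)
      th <- 2 * pi * v
      cr <- lg$cr + ar * r * cos(th)
      cv <- lg$cv + ac * r * sin(th)
      clear <- all(vapply(placed, function(p) {
        sqrt((p$cr - cr)^2 + (p$cv - cv)^2) > p$rad + rad + 2
      }, logical(1)))
      if (clear) {
        placed[[length(placed) + 1L]] <- list(cr = cr, cv = cv, rad = rad)
        ok <- TRUE
        break
      }
    }
    if (!ok) {
      abort("could not place all lesions without overlap; reduce count or radius")
    }
  }
  placed
}

#' Generate a synthetic phantom slice with ground-truth topology
#'
#' Renders the slice described by a [phantom_spec()], returning the HU grid,
#' the exact lung mask, and the ground-truth low-attenuation topology. For a
#' noise-free phantom the ground truth holds at any threshold `t` with
#' `lesion_hu < t <= lung_hu`: the low-attenuation set is exactly the lesion
#' pixels, with `b0 = lesion_count + ring_count` connected components and
#' `b1 = ring_count` enclosed normal-lung islands.
#'
#' @param spec A [phantom_spec()].
#' @return A list of class `heq_phantom` with elements `image` (integer HU
#'   matrix), `mask` (logical lung mask), `truth` (list with `laa_pixels`,
#'   `b0`, `b1`, `lung_pixels`) and `spec`.
#' @examples
#' ph <- make_phantom(phantom_spec(image_size = 96, lesion_count = 3))
#' ph$truth$b0
#' @export
make_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  s <- spec$image_size
  scale <- s / 256
  set.seed(spec$seed)

  geo <- phantom_geometry(s)
  img <- matrix(spec$air_hu, s, s)
  img[geo$body] <- spec$body_hu
  img[geo$lung_mask] <- spec$lung_hu

  r_les <- max(1, spec$lesion_radius_px * scale)
  r_out <- max(2, spec$ring_outer_px * scale)
  r_in <- max(1, spec$ring_inner_px * scale)
  radii <- c(rep(r_out, spec$ring_count), rep(r_les, spec$lesion_count))
  placed <- place_disks(geo$lungs, radii)

  rr <- matrix(seq_len(s), s, s)
  cc <- matrix(seq_len(s), s, s, byrow = TRUE)
  for (i in seq_along(placed)) {
    p <- placed[[i]]
    d2 <- (rr - p$cr)^2 + (cc - p$cv)^2
    if (i <= spec$ring_count) {
      img[d2 <= p$rad^2 & d2 > r_in^2] <- spec$lesion_hu
    } else {
      img[d2 <= p$rad^2] <- spec$lesion_hu
    }
  }

  truth <- list(
    laa_pixels = sum(img == spec$lesion_hu),
    b0 = spec$lesion_count + spec$ring_count,
    b1 = spec$ring_count,
    lung_pixels = sum(geo$lung_mask))

  if (spec$noise_sd > 0) {
    img <- img + round_half_up(matrix(rnorm(s * s, sd = spec$noise_sd), s, s))
  }
  storage.mode(img) <- "integer"

  structure(list(image = img, mask = geo$lung_mask, truth = truth, spec = spec),
            class = "heq_phantom")
}

# lesion burden per visual score: solid-disk and ring counts. Bands are
# disjoint even under the per-slice +/-1 jitter, so burden is monotone in score.
score_lesion_counts <- c(0L, 3L, 7L, 12L, 18L, 25L)
score_ring_counts <- c(0L, 0L, 1L, 2L, 3L, 4L)

#' Specify a synthetic cohort of scored phantom slices
#'
#' Describes a cohort of patients with a fixed number of slices each. Every
#' patient draws one ordinal emphysema visual score (0 = none ... 5 = very
#' severe) from `score_distribution`; each of the patient's slices then
#' renders a phantom whose lesion burden is the score's base burden plus a
#' per-slice jitter of one lesion, so slices of one patient are similar but
#' not identical and patient grouping matters in leave-one-patient-out CV.
#'
#' @param n_patients Number of patients (>= 2).
#' @param slices_per_patient Slices per patient (>= 1).
#' @param score_distribution Probability weights over scores 0-5. The default
#'   is the skewed distribution typical of screening cohorts, with most
#'   slices at scores 0-1 and very few severe cases
#'   (61, 26, 11, 12, 3, 2 out of 115).
#' @param lesion_counts,ring_counts Monotone nondecreasing integer vectors of
#'   length 6: disk and ring lesion counts for scores 0-5.
#' @param seed Integer seed; cohorts are a pure function of this seed.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_patients = 39L, slices_per_patient = 3L,
                        score_distribution = c(61, 26, 11, 12, 3, 2) / 115,
                        lesion_counts = score_lesion_counts,
                        ring_counts = score_ring_counts,
                        seed = 1L) {
  if (n_patients < 2) abort("n_patients must be >= 2")
  if (slices_per_patient < 1) abort("slices_per_patient must be >= 1")
  if (length(score_distribution) != 6 || any(score_distribution < 0)) {
    abort("score_distribution must be 6 nonnegative weights (scores 0-5)")
  }
  if (length(lesion_counts) != 6 || is.unsorted(lesion_counts)) {
    abort("lesion_counts must be nondecreasing, length 6")
  }
  if (length(ring_counts) != 6 || is.unsorted(ring_counts)) {
    abort("ring_counts must be nondecreasing, length 6")
  }
  structure(
    list(n_patients = as.integer(n_patients),
         slices_per_patient = as.integer(slices_per_patient),
         score_distribution = score_distribution / sum(score_distribution),
         lesion_counts = as.integer(lesion_counts),
         ring_counts = as.integer(ring_counts),
         seed = as.integer(seed)),
    class = "cohort_spec")
}

#' Generate a synthetic cohort of phantom slices
#'
#' @param spec A [cohort_spec()].
#' @param template A [phantom_spec()] supplying the per-slice rendering
#'   parameters (HU values, lesion radii, noise); its `lesion_count`,
#'   `ring_count` and `seed` fields are overridden per slice. The default
#'   adds 15 HU of Gaussian noise so downstream segmentation is exercised.
#' @return A tibble of class `heq_cohort`, one row per slice, with columns
#'   `patient_id`, `slice_id`, `score`, `image` and `mask` (list-columns of
#'   matrices), `lesion_fraction` (ground-truth LAA fraction of lung area),
#'   `truth_b0` and `truth_b1`.
#' @examples
#' co <- make_cohort(cohort_spec(n_patients = 3, slices_per_patient = 2),
#'                   phantom_spec(image_size = 96))
#' dplyr::count(co, score)
#' @export
make_cohort <- function(spec, template = phantom_spec(noise_sd = 15)) {
  stopifnot(inherits(spec, "cohort_spec"), inherits(template, "phantom_spec"))
  set.seed(spec$seed)
  scores <- sample(0:5, spec$n_patients, replace = TRUE,
                   prob = spec$score_distribution)
  jitters <- matrix(sample(-1:1, spec$n_patients * spec$slices_per_patient,
                           replace = TRUE),
                    spec$n_patients, spec$slices_per_patient)
  slice_seeds <- matrix(sample.int(.Machine$integer.max - 1L,
                                   spec$n_patients * spec$slices_per_patient),
                        spec$n_patients, spec$slices_per_patient)

  rows <- purrr::map(seq_len(spec$n_patients), function(p) {
    sc <- scores[p]
    purrr::map(seq_len(spec$slices_per_patient), function(k) {
      n_les <- spec$lesion_counts[sc + 1L]
      if (sc > 0) n_les <- max(1L, n_les + jitters[p, k])
      ps <- modifyList(template, list(lesion_count = n_les,
                                      ring_count = spec$ring_counts[sc + 1L],
                                      seed = slice_seeds[p, k]))
      class(ps) <- "phantom_spec"
      ph <- make_phantom(ps)
      tibble::tibble(
        patient_id = sprintf("P%03d", p),
        slice_id = sprintf("P%03d_S%d", p, k),
        score = sc,
        image = list(ph$image),
        mask = list(ph$mask),
        lesion_fraction = ph$truth$laa_pixels / ph$truth$lung_pixels,
        truth_b0 = ph$truth$b0,
        truth_b1 = ph$truth$b1)
    })
  })
  out <- dplyr::bind_rows(purrr::flatten(rows))
  class(out) <- c("heq_cohort", class(out))
  out
}
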