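# Shared fixtures, built in code at load time.

# printed 6x6 contingency tables used as reference inputs for the
# evaluation statistics (rows = visual score 0-5, columns = prediction)
reference_table_laa <- matrix(c(
  48, 11, 1, 1, 0, 0,
  15,  8, 0, 3, 0, 0,
   4,  1, 5, 1, 0, 0,
   1,  3, 2, 3, 2, 1,
   0,  0, 0, 2, 0, 1,
   0,  0, 0, 2, 0, 0), 6, 6, byrow = TRUE,
  dimnames = list(true = 0:5, predicted = 0:5))

reference_table_heq <- matrix(c(
  52,  6, 3, 0, 0, 0,
   6, 17, 3, 0, 0, 0,
   5,  2, 2, 2, 0, 0,
   3,  1, 2, 5, 0, 1,
   0,  0, 0, 2, 0, 1,
   0,  0, 0, 2, 0, 0), 6, 6, byrow = TRUE,
  dimnames = list(true = 0:5, predicted = 0:5))

# small noise-free phantom with known topology: 3 disks + 1 ring
tiny_phantom <- function(seed = 11) {
  make_phantom(phantom_spec(image_size = 96, lesion_count = 3L,
                            ring_count = 1L, lesion_radius_px = 6,
                            noise_sd = 0, seed = seed))
}

# hand-built feature tibble whose first feature encodes the score exactly,
# plus pure-noise features; wraps it with the heq_features attributes.
# Scores cycle 0..5 across patients, so with >= 12 patients every score is
# seen in at least two patients and leave-one-patient-out folds can learn it.
toy_features <- function(n_patients = 12, slices_per_patient = 1,
                         n_noise = 9, seed = 42, scores = NULL) {
  set.seed(seed)
  n <- n_patients * slices_per_patient
  patient_id <- rep(sprintf("P%02d", seq_len(n_patients)),
                    each = slices_per_patient)
  if (is.null(scores)) {
    scores <- rep(rep_len(0:5, n_patients), each = slices_per_patient)
  }
  vals <- cbind(scores + stats::rnorm(n, sd = 0.01),
                matrix(stats::rnorm(n * n_noise), n))
  quantities <- c("signal", paste0("noise", seq_len(n_noise)))
  colnames(vals) <- paste0(quantities, "_", seq_len(ncol(vals)))
  out <- tibble::tibble(patient_id = patient_id,
                        slice_id = sprintf("%s_S%d", patient_id,
                                           rep(seq_len(slices_per_patient),
                                               n_patients)),
                        score = scores)
  out <- dplyr::bind_cols(out, tibble::as_tibble(vals))
  schema <- tibble::tibble(quantity = quantities,
                           threshold_hu = seq_len(ncol(vals)))
  structure(out, schema = schema, kind = "toy",
            class = c("heq_features", class(out)))
}

# minimal heq_cv object from explicit per-slice records
cv_from_records <- function(true, predicted,
                            patient_id = sprintf("P%02d", seq_along(true))) {
  structure(
    list(predictions = tibble::tibble(
           patient_id = patient_id,
           slice_id = sprintf("S%03d", seq_along(true)),
           true_score = as.integer(true),
           predicted_score = as.integer(predicted)),
         accuracy = mean(true == predicted),
         config = list(n_trees = 0L, feature_fraction = 0,
                       keep_fraction = 1, seed = 0L)),
    class = "heq_cv")
}
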