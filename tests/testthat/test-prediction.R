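test_that("a feature that encodes the score is predicted perfectly", {
  f <- toy_features(n_patients = 18, slices_per_patient = 4)
  cv <- lopo_cv(f, n_trees = 100, feature_fraction = 0.9, seed = 1)
  expect_equal(cv$accuracy, 1.0)
  expect_equal(nrow(cv$predictions), 72)
  expect_setequal(cv$predictions$slice_id, f$slice_id)
})

test_that("cross-validation is reproducible and refuses a single patient", {
  f <- toy_features(n_patients = 5, slices_per_patient = 2, n_noise = 19)
  a <- lopo_cv(f, n_trees = 50, feature_fraction = 0.3, seed = 3)
  b <- lopo_cv(f, n_trees = 50, feature_fraction = 0.3, seed = 3)
  expect_identical(a$predictions, b$predictions)
  single <- dplyr::filter(f, patient_id == "P01")
  expect_error(lopo_cv(single, 10, 0.5), "at least 2 patients")
})

test_that("single-class training folds predict that class", {
  f <- toy_features(n_patients = 3, slices_per_patient = 2,
                    scores = rep(2L, 6))
  cv <- lopo_cv(f, n_trees = 10, feature_fraction = 0.5, seed = 1)
  expect_true(all(cv$predictions$predicted_score == 2L))
  expect_equal(cv$accuracy, 1.0)
})

test_that("grid search picks the argmax and breaks ties toward the simpler forest", {
  f <- toy_features(n_patients = 18, slices_per_patient = 4)
  # separable problem: every config reaches 1.0, so the tie rule decides
  gs <- grid_search(f, rf_grid(n_trees = c(1000L, 10L),
                               feature_fraction = c(1.0, 0.9)), seed = 2)
  expect_equal(gs$best$accuracy, 1.0)
  expect_equal(gs$best$config$n_trees, 10L)
  expect_equal(gs$best$config$feature_fraction, 0.9)
  expect_equal(nrow(gs$results), 4)

  single <- grid_search(f, rf_grid(100L, 0.3), seed = 2)
  expect_equal(single$best$config$n_trees, 100L)
})

test_that("best-of-grid accuracy dominates every member", {
  f <- toy_features(n_patients = 5, slices_per_patient = 2, n_noise = 30,
                    seed = 8)
  gs <- grid_search(f, rf_grid(n_trees = c(10L, 50L),
                               feature_fraction = c(0.1, 0.9)), seed = 4)
  expect_true(all(gs$best$accuracy >= gs$results$accuracy))
})

test_that("feature selection keeps the requested count and keep_fraction = 1 is a no-op", {
  set.seed(5)
  x <- matrix(stats::rnorm(200), 20, 10,
              dimnames = list(NULL, letters[1:10]))
  y <- rep(0:1, each = 10)
  kept <- select_features(x, y, n_trees = 50, keep_fraction = 0.5)
  expect_length(kept, 5)
  expect_identical(select_features(x, y, keep_fraction = 1), 1:10)
  expect_error(select_features(x, y, keep_fraction = 0), "\\(0, 1\\]")
  expect_error(select_features(x, y, keep_fraction = 1.2), "\\(0, 1\\]")

  f <- toy_features(n_patients = 5, slices_per_patient = 2)
  a <- lopo_cv(f, n_trees = 50, feature_fraction = 0.5, keep_fraction = 1,
               seed = 6)
  b <- lopo_cv(f, n_trees = 50, feature_fraction = 0.5, seed = 6)
  expect_identical(a$predictions, b$predictions)
})

test_that("informative features are retained more often than noise", {
  # 5 informative + 55 noise features; retention across folds and seeds
  inform_rate <- noise_rate <- c()
  for (seed in 1:10) {
    set.seed(seed)
    n <- 24
    y <- rep(rep_len(0:5, 12), each = 2)
    x <- cbind(matrix(rep(y, 5), n) + matrix(stats::rnorm(n * 5, sd = 0.3), n),
               matrix(stats::rnorm(n * 55), n))
    colnames(x) <- paste0("f", 1:60)
    kept <- select_features(x, y, n_trees = 100, keep_fraction = 0.5)
    inform_rate <- c(inform_rate, mean(1:5 %in% kept))
    noise_rate <- c(noise_rate, mean(6:60 %in% kept))
  }
  expect_gt(mean(inform_rate), mean(noise_rate))
})

test_that("the range sweep tabulates all 21 cells and is consistent with lopo_cv", {
  co <- make_cohort(cohort_spec(n_patients = 4, slices_per_patient = 2,
                                score_distribution = rep(1, 6), seed = 3),
                    phantom_spec(image_size = 128, noise_sd = 10))
  curves <- quantify_cohort(co, threshold_grid(-1000, -700))
  sweep <- range_sweep(curves, "heq", configs = rf_grid(10L, 0.3), seed = 9)
  expect_equal(nrow(sweep), 21)
  expect_true(all(!is.na(sweep$accuracy)))
  full_cell <- dplyr::filter(sweep, lower_hu == -1000, upper_hu == -700)
  direct <- lopo_cv(build_features(curves, threshold_grid(-1000, -700), "heq"),
                    n_trees = 10L, feature_fraction = 0.3, seed = 9)
  expect_equal(full_cell$accuracy, direct$accuracy)
})
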