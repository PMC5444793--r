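test_that("spearman handles monotone, antitone and tied data", {
  expect_equal(spearman(c(1, 2, 3), c(10, 20, 30)), 1.0)
  expect_equal(spearman(c(1, 2, 3), c(3, 2, 1)), -1.0)
  # mid-rank hand computation: ranks (1, 2.5, 2.5, 4) vs (2, 1, 3, 4)
  expect_equal(spearman(c(1, 2, 2, 4), c(2, 1, 3, 4)), 0.6325, tolerance = 1e-4)
  expect_warning(rho <- spearman(c(1, 1, 1), c(1, 2, 3)), "zero rank variance")
  expect_true(is.na(rho))
  expect_error(spearman(1:3, 1:4), "equal length")
  expect_error(spearman(1:2, 1:2), "at least 3")
})

test_that("accuracy reproduces the printed reference tables", {
  expect_equal(accuracy(reference_table_laa), 64 / 115)
  expect_equal(round(100 * accuracy(reference_table_laa), 1), 55.7)
  expect_equal(accuracy(reference_table_heq), 76 / 115)
  expect_equal(round(100 * accuracy(reference_table_heq), 1), 66.1)
  expect_equal(accuracy(diag(3) * 5), 1.0)
  expect_error(accuracy(matrix(0, 6, 6)), "empty")
})

test_that("quadratic-weighted kappa matches hand-derived and reference values", {
  expect_equal(weighted_kappa(diag(6) * 3), 1.0)
  # 2x2 over categories {0, 1}: kappa = 1 - 2/3
  two <- matrix(c(2, 1, 1, 2), 2, 2)
  expect_equal(weighted_kappa(two), 1 / 3, tolerance = 1e-12)
  # on 2x2 tables weighted and unweighted kappa coincide
  po <- sum(diag(two)) / sum(two)
  pe <- sum(rowSums(two) * colSums(two)) / sum(two)^2
  expect_equal(weighted_kappa(two), (po - pe) / (1 - pe))
  expect_equal(round(weighted_kappa(reference_table_laa), 3), 0.688)
  expect_equal(round(weighted_kappa(reference_table_heq), 3), 0.697)
  # consistent relabelling (transposition) leaves kappa unchanged
  expect_equal(weighted_kappa(t(reference_table_heq)),
               weighted_kappa(reference_table_heq))
  expect_warning(k <- weighted_kappa(diag(c(7, 0, 0))), "degenerate")
  expect_true(is.na(k))
})

test_that("exact McNemar matches the binomial tail and the enumeration oracle", {
  expect_equal(mcnemar_exact(4, 4), 1.0)
  expect_equal(mcnemar_exact(3, 9), 2 * 299 / 4096)
  expect_equal(mcnemar_exact(0, 8), 2 / 256)
  expect_warning(p0 <- mcnemar_exact(0, 0), "no discordant")
  expect_equal(p0, 1)
  expect_error(mcnemar_exact(-1, 2), "nonnegative")
  for (b in 0:8) {
    for (c in 0:(8 - b)) {
      if (b + c == 0) next
      expect_equal(mcnemar_exact(b, c), enum_mcnemar(b, c),
                   info = sprintf("b=%d c=%d", b, c))
    }
  }
})

test_that("paired outcomes count discordant slices correctly", {
  a <- cv_from_records(true = rep(0:4, 2), predicted = rep(0:4, 2))
  expect_equal(paired_outcomes(a, a)$b, 0)
  expect_equal(paired_outcomes(a, a)$c, 0)

  b_wrong <- cv_from_records(true = rep(0:4, 2),
                             predicted = rep(0:4, 2) + 1L)
  po <- paired_outcomes(a, b_wrong)
  expect_equal(po$b, 10)
  expect_equal(po$c, 0)
  expect_equal(po$p_value, 2 / 1024)

  set.seed(31)
  true <- sample(0:5, 40, replace = TRUE)
  pa <- cv_from_records(true, sample(0:5, 40, replace = TRUE))
  pb <- cv_from_records(true, sample(0:5, 40, replace = TRUE))
  po2 <- paired_outcomes(pa, pb)
  one_correct <- sum(xor(pa$predictions$true_score == pa$predictions$predicted_score,
                         pb$predictions$true_score == pb$predictions$predicted_score))
  expect_equal(po2$b + po2$c, one_correct)

  mismatched <- cv_from_records(true = 0:3, predicted = 0:3)
  expect_error(paired_outcomes(a, mismatched), "identical slice set")
})

test_that("contingency tables always span the full ordinal scale", {
  tab <- contingency_table(c(0, 0, 1), c(0, 1, 1))
  expect_equal(dim(tab), c(6, 6))
  expect_equal(sum(tab), 3)
  expect_equal(tab["0", "1"], 1L)
  expect_error(contingency_table(c(0, 7), c(0, 1)), "0..5")
})
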