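#' Spearman rank correlation
#'
#' Pearson correlation of mid-ranks (ties receive average ranks). Used to
#' relate per-slice emphysema quantification to the ordinal visual score.
#'
#' @param x,y Numeric vectors of equal length, at least 3.
#' @return Correlation coefficient in `[-1, 1]`, or `NA` (with a warning)
#'   when either variable has zero rank variance.
#' @export
spearman <- function(x, y) {
  if (length(x) != length(y)) abort("x and y must have equal length")
  if (length(x) < 3) abort("need at least 3 observations")
  if (anyNA(x) || anyNA(y)) abort("missing values are not supported")
  if (stats::sd(rank(x)) == 0 || stats::sd(rank(y)) == 0) {
    warn("zero rank variance: Spearman correlation undefined")
    return(NA_real_)
  }
  cor(x, y, method = "spearman")
}

#' Contingency table of visual score against prediction
#'
#' A 6 x 6 count table, rows = true visual score 0-5, columns = predicted
#' score 0-5; the full ordinal scale is always represented even when some
#' scores are absent from a sample.
#'
#' @param true_score,predicted_score Integer vectors with values in 0..5,
#'   or an `heq_cv` object in place of `true_score`.
#' @return A 6 x 6 integer matrix with score dimnames.
#' @export
contingency_table <- function(true_score, predicted_score = NULL) {
  if (inherits(true_score, "heq_cv")) {
    cv <- true_score$predictions
    true_score <- cv$true_score
    predicted_score <- cv$predicted_score
  }
  if (length(true_score) != length(predicted_score)) {
    abort("true and predicted scores must have equal length")
  }
  if (!all(true_score %in% 0:5) || !all(predicted_score %in% 0:5)) {
    abort("scores must lie in 0..5")
  }
  tab <- table(factor(true_score, levels = 0:5),
               factor(predicted_score, levels = 0:5))
  m <- matrix(as.integer(tab), 6, 6,
              dimnames = list(true = 0:5, predicted = 0:5))
  m
}

check_table <- function(counts) {
  if (!is.matrix(counts) || nrow(counts) != ncol(counts)) {
    abort("expected a square count matrix")
  }
  if (any(counts < 0) || any(counts != round(counts))) {
    abort("counts must be nonnegative integers")
  }
  if (sum(counts) == 0) abort("empty contingency table")
  invisible(counts)
}

#' Classification accuracy from a contingency table
#'
#' Sum of the main diagonal divided by the total count — the multi-class
#' generalization of (TP + TN) / (TP + TN + FP + FN).
#'
#' @param counts Square count matrix (true x predicted).
#' @return Accuracy in `[0, 1]`.
#' @export
accuracy <- function(counts) {
  check_table(counts)
  sum(diag(counts)) / sum(counts)
}

#' Quadratic-weighted Cohen's kappa
#'
#' Chance-corrected agreement for ordinal categories with squared-distance
#' disagreement weights:
#' `kappa = 1 - sum((i-j)^2 O_ij) / sum((i-j)^2 E_ij)`, where `E` is the
#' product of the row and column marginals scaled to the total count. On a
#' 2 x 2 table this coincides with unweighted kappa.
#'
#' @param counts Square count matrix over ordered categories (true x
#'   predicted).
#' @return Weighted kappa, or `NA` (with a warning) for degenerate
#'   marginals.
#' @export
weighted_kappa <- function(counts) {
  check_table(counts)
  k <- nrow(counts)
  n <- sum(counts)
  w <- outer(seq_len(k), seq_len(k), function(i, j) (i - j)^2)
  expected <- outer(rowSums(counts), colSums(counts)) / n
  denom <- sum(w * expected)
  if (denom == 0) {
    warn("degenerate marginals: weighted kappa undefined")
    return(NA_real_)
  }
  1 - sum(w * counts) / denom
}

#' Exact McNemar test on discordant pairs
#'
#' Central two-sided exact binomial p-value for comparing two classifiers
#' evaluated on the same slices: with `b` slices correct only under A and
#' `c` correct only under B, `p = min(1, 2 P(X <= min(b, c)))` for
#' `X ~ Binomial(b + c, 1/2)`.
#'
#' @param b,c Nonnegative discordant counts.
#' @return Exact p-value; `b + c = 0` returns 1 with a warning.
#' @export
mcnemar_exact <- function(b, c) {
  if (b < 0 || c < 0 || b != round(b) || c != round(c)) {
    abort("b and c must be nonnegative integers")
  }
  if (b + c == 0) {
    warn("no discordant pairs: McNemar p-value set to 1")
    return(1)
  }
  min(1, 2 * pbinom(min(b, c), b + c, 0.5))
}

#' Pair two cross-validation results for McNemar's test
#'
#' Matches the per-slice predictions of two classifiers evaluated on the
#' identical slice set and counts the discordant slices: `b` where only A
#' is correct and `c` where only B is correct.
#'
#' @param result_a,result_b `heq_cv` objects over the same slices.
#' @return A list of class `heq_paired` with elements `b`, `c`, `n`,
#'   `p_value` (from [mcnemar_exact()]) and the per-slice `outcomes` tibble.
#' @export
paired_outcomes <- function(result_a, result_b) {
  a <- dplyr::arrange(result_a$predictions, .data$slice_id)
  b <- dplyr::arrange(result_b$predictions, .data$slice_id)
  if (!identical(a$slice_id, b$slice_id) ||
      !identical(a$true_score, b$true_score)) {
    abort("the two results do not cover the identical slice set")
  }
  outcomes <- tibble::tibble(
    slice_id = a$slice_id,
    a_correct = a$true_score == a$predicted_score,
    b_correct = b$true_score == b$predicted_score)
  nb <- sum(outcomes$a_correct & !outcomes$b_correct)
  nc <- sum(!outcomes$a_correct & outcomes$b_correct)
  structure(list(b = nb, c = nc, n = nrow(outcomes),
                 p_value = suppressWarnings(mcnemar_exact(nb, nc)),
                 outcomes = outcomes),
            class = "heq_paired")
}

#' @export
print.heq_paired <- function(x, ...) {
  cat(sprintf(
    "Paired comparison on %d slices: b = %d, c = %d, exact McNemar p = %.4f\n",
    x$n, x$b, x$c, x$p_value))
  invisible(x)
}
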