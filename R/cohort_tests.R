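#' Expected counts under independence
#'
#' E_ij = row_i * col_j / total.
#'
#' @param table A `contingency_table` (or plain count matrix) with at least
#'   2 rows and 2 columns and positive margins.
#' @return Numeric matrix of expected counts.
#' @export
expected_counts <- function(table) {
  m <- unclass(as.matrix(table))
  if (nrow(m) < 2 || ncol(m) < 2)
    stop("need at least a 2x2 table")
  if (sum(m) <= 0) stop("empty table")
  if (any(rowSums(m) == 0) || any(colSums(m) == 0))
    stop("zero row or column margin")
  outer(rowSums(m), colSums(m)) / sum(m)
}

new_test_result <- function(method, statistic, df, p_value, expected,
                            selection_reason = NA_character_) {
  structure(list(method = method, statistic = statistic, df = df,
                 p_value = p_value, expected = expected,
                 selection_reason = selection_reason),
            class = "cohort_test")
}

#' @export
print.cohort_test <- function(x, ...) {
  if (x$method == "pearson_chisq")
    cat(sprintf("Pearson chi-square: X2 = %s, df = %d, p = %.4g\n",
                signif(x$statistic, 3), x$df, x$p_value))
  else
    cat(sprintf("Fisher exact (two-tailed): p = %.4g\n", x$p_value))
  if (!is.na(x$selection_reason))
    cat("  selected because:", x$selection_reason, "\n")
  invisible(x)
}

#' Pearson chi-square test on a contingency table
#'
#' Uncorrected (no Yates continuity correction): X2 = sum (O-E)^2/E with
#' df = (r-1)(c-1) and the p-value from the upper chi-square tail.
#'
#' @param table A `contingency_table` or count matrix.
#' @return A `cohort_test` result.
#' @export
pearson_chisq <- function(table) {
  m <- unclass(as.matrix(table))
  E <- expected_counts(m)      # validates margins
  ct <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
  new_test_result("pearson_chisq", unname(ct$statistic),
                  unname(ct$parameter), ct$p.value, E)
}

#' Two-tailed Fisher exact test on a 2x2 table
#'
#' The two-tailed p sums, over all tables with the observed margins, the
#' hypergeometric probabilities no larger than that of the observed table
#' (the SPSS/R convention; float ties are resolved within a relative
#' tolerance of 1e-7).
#'
#' @param table A 2x2 `contingency_table` or count matrix.
#' @return A `cohort_test` result.
#' @export
fisher_exact_2x2 <- function(table) {
  m <- unclass(as.matrix(table))
  if (nrow(m) != 2 || ncol(m) != 2)
    stop("Fisher exact implemented for 2x2 tables; use pearson_chisq ",
         "(or a Monte-Carlo approximation) for larger tables")
  if (any(rowSums(m) == 0) || any(colSums(m) == 0))
    stop("zero row or column margin")
  ft <- stats::fisher.test(m)
  new_test_result("fisher_exact", NA_real_, NA_integer_, ft$p.value,
                  expected_counts(m))
}

#' Select and run the appropriate frequency test
#'
#' Applies the small-expected-count rule: when 20% or more of the cells
#' have expected counts below 5 and the table is 2x2, the two-tailed Fisher
#' exact test is used; otherwise the Pearson chi-square.  For larger tables
#' with small expected counts the chi-square is still run, with a caveat
#' recorded in `selection_reason`.
#'
#' @param table A `contingency_table` or count matrix.
#' @return A `cohort_test` result with `selection_reason` filled in.
#' @export
select_test <- function(table) {
  m <- unclass(as.matrix(table))
  E <- expected_counts(m)
  frac_small <- mean(E < 5)
  small <- frac_small >= 0.2
  if (small && nrow(m) == 2 && ncol(m) == 2) {
    res <- fisher_exact_2x2(m)
    res$selection_reason <- sprintf(
      "%.0f%% of cells have expected counts < 5; 2x2 -> Fisher exact",
      100 * frac_small)
  } else {
    res <- pearson_chisq(m)
    res$selection_reason <- if (small)
      sprintf("%.0f%% of cells have expected counts < 5 but table is %dx%d; chi-square reported with caveat",
              100 * frac_small, nrow(m), ncol(m))
    else "expected counts adequate -> Pearson chi-square"
  }
  res
}

#' Write a test result to TSV
#' @param result A `cohort_test`.
#' @param path Output path.
#' @export
write_test_result <- function(result, path) {
  d <- data.frame(method = result$method,
                  statistic = result$statistic, df = result$df,
                  p_value = result$p_value,
                  selection_reason = result$selection_reason)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
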