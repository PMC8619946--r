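#' Root mean square error between paired method outputs
#'
#' `RMSE = sqrt(sum((P_i - O_i)^2) / N)` over paired predicted/test values
#' `P` and observed/reference values `O`.
#'
#' @param P Predicted (test) values.
#' @param O Observed (reference) values, same length.
#' @return RMSE in the units of the inputs.
#' @examples
#' rmse(c(1, 2, 3), c(2, 2, 2))  # sqrt(2/3)
#' @export
rmse <- function(P, O) {
  if (length(P) != length(O)) {
    stop("'P' and 'O' must have equal length (", length(P), " vs ",
         length(O), ")", call. = FALSE)
  }
  if (length(P) < 1L) stop("need at least one pair", call. = FALSE)
  sqrt(mean((P - O)^2))
}

#' Normalized root mean square error
#'
#' `NRMSE = RMSE / mean(O)`: the RMSE normalized by the mean of the
#' reference values, so comparisons are dimensionless. Not symmetric in its
#' arguments -- the normalizer is always the reference mean.
#'
#' @inheritParams rmse
#' @return Dimensionless NRMSE.
#' @export
nrmse <- function(P, O) {
  r <- rmse(P, O)
  m <- mean(O)
  if (m == 0) stop("mean of reference values is zero; NRMSE undefined",
                   call. = FALSE)
  r / m
}

#' Squared Pearson correlation between paired method outputs
#'
#' The R^2 of the correlation diagram: the square of the Pearson correlation
#' coefficient between the two value sequences. Symmetric and invariant to
#' affine rescaling of either sequence.
#'
#' @inheritParams rmse
#' @return R^2 in `[0, 1]`.
#' @export
r_squared <- function(P, O) {
  if (length(P) != length(O)) {
    stop("'P' and 'O' must have equal length", call. = FALSE)
  }
  if (length(P) < 2L) stop("need at least two pairs", call. = FALSE)
  if (stats::sd(P) == 0 || stats::sd(O) == 0) {
    stop("correlation undefined for a constant sequence", call. = FALSE)
  }
  stats::cor(P, O)^2
}

#' Cross-method agreement statistics
#'
#' Joins two per-formulation value tables on their labels and reports the
#' three agreement statistics used to compare an in silico method against an
#' in vitro reference (or any two methods): R^2, RMSE, NRMSE.
#'
#' @param test Data.frame with columns `formulation`, `value` (predicted).
#' @param reference Data.frame with columns `formulation`, `value`
#'   (observed).
#' @param test_label,reference_label Labels recorded in the result.
#' @return A `comparison_result` list with `r_squared`, `rmse`, `nrmse`,
#'   `n`, `test_label`, `reference_label`.
#' @export
compare_methods <- function(test, reference,
                            test_label = "test",
                            reference_label = "reference") {
  need <- c("formulation", "value")
  if (!all(need %in% names(test)) || !all(need %in% names(reference))) {
    stop("both tables need columns 'formulation' and 'value'", call. = FALSE)
  }
  missing_in_ref <- setdiff(test$formulation, reference$formulation)
  missing_in_test <- setdiff(reference$formulation, test$formulation)
  if (length(missing_in_ref) || length(missing_in_test)) {
    stop("formulation sets do not match; missing in reference: [",
         paste(missing_in_ref, collapse = ", "), "], missing in test: [",
         paste(missing_in_test, collapse = ", "), "]", call. = FALSE)
  }
  m <- merge(test, reference, by = "formulation",
             suffixes = c("_test", "_ref"))
  out <- list(r_squared = r_squared(m$value_test, m$value_ref),
              rmse = rmse(m$value_test, m$value_ref),
              nrmse = nrmse(m$value_test, m$value_ref),
              n = nrow(m),
              test_label = test_label,
              reference_label = reference_label)
  class(out) <- "comparison_result"
  out
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("Method comparison: %s vs %s (n = %d)\n",
              x$test_label, x$reference_label, x$n))
  cat(sprintf("  R^2 = %.4f | RMSE = %.4g | NRMSE = %.4g\n",
              x$r_squared, x$rmse, x$nrmse))
  invisible(x)
}
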