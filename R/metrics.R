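#' Coefficient of determination
#'
#' `1 - sum((y - y_hat)^2) / sum((y - mean(y))^2)`. For a least-squares
#' predictor evaluated on its own calibration data this lies in [0, 1]; on
#' held-out data it can be negative for models worse than the mean
#' predictor, and such values are returned as-is.
#'
#' @param y numeric vector of reference values (not constant, length >= 2).
#' @param y_hat numeric vector of predictions, same length.
#' @return scalar R-squared.
#' @examples
#' r_squared(c(1, 2, 3), c(1.1, 2.0, 2.9))  # 0.99
#' @export
r_squared <- function(y, y_hat) {
  check_paired(y, y_hat, min_len = 2)
  sst <- sum((y - mean(y))^2)
  if (sst < 1e-24) stop("R-squared undefined for constant y")
  1 - sum((y - y_hat)^2) / sst
}

#' Root mean squared error
#'
#' @inheritParams r_squared
#' @return scalar RMSE in the units of `y`; 0 iff the vectors are identical.
#' @export
rmse <- function(y, y_hat) {
  check_paired(y, y_hat, min_len = 1)
  sqrt(mean((y - y_hat)^2))
}

#' Root mean squared percentage error
#'
#' `100 * sqrt(mean(((y - y_hat) / y)^2))`. Used here channel-wise within a
#' spectrum to score autoencoder reconstruction fidelity, which requires
#' every reference value to be nonzero.
#'
#' @inheritParams r_squared
#' @return scalar RMSPE in percent.
#' @examples
#' rmspe(c(10, 10), c(9, 11))  # 10
#' @export
rmspe <- function(y, y_hat) {
  check_paired(y, y_hat, min_len = 1)
  if (any(y == 0)) stop("RMSPE undefined: y contains zero entries")
  100 * sqrt(mean(((y - y_hat) / y)^2))
}

check_paired <- function(y, y_hat, min_len) {
  if (length(y) != length(y_hat))
    stop("length mismatch: ", length(y), " vs ", length(y_hat))
  if (length(y) < min_len) stop("need at least ", min_len, " observations")
  if (!all(is.finite(y)) || !all(is.finite(y_hat)))
    stop("non-finite values in inputs")
  invisible(TRUE)
}

#' Per-spectrum reconstruction RMSPE and its summary
#'
#' `rmspe_by_sample` scores each row of a reconstructed matrix against the
#' original; `rmspe_summary` reduces those per-sample values to the
#' min/max/mean/std layout conventional for reconstruction-quality tables.
#'
#' @param original,reconstructed matrices of identical shape, samples in rows.
#' @return `rmspe_by_sample`: numeric vector, one RMSPE (percent) per sample.
#' @export
rmspe_by_sample <- function(original, reconstructed) {
  stopifnot(all(dim(original) == dim(reconstructed)))
  vapply(seq_len(nrow(original)),
         function(i) rmspe(original[i, ], reconstructed[i, ]), numeric(1))
}

#' @rdname rmspe_by_sample
#' @param values numeric vector of per-sample RMSPE values.
#' @param set partition label stored in the summary row.
#' @export
rmspe_summary <- function(values, set = "calibration") {
  data.frame(set = set, min = min(values), max = max(values),
             mean = mean(values), std = stats::sd(values))
}

#' Evaluate one fitted model on calibration and prediction sets
#'
#' Computes the paired (R-squared, RMSE) entries of a benchmark report row
#' from one prediction vector per set.
#'
#' @param y_cal,yhat_cal reference and predicted values, calibration set.
#' @param y_pred,yhat_pred reference and predicted values, prediction set.
#' @return one-row `data.frame` with `r2_cal`, `r2_pred`, `rmse_cal`,
#'   `rmse_pred`.
#' @export
evaluate_predictions <- function(y_cal, yhat_cal, y_pred, yhat_pred) {
  data.frame(r2_cal = r_squared(y_cal, yhat_cal),
             r2_pred = r_squared(y_pred, yhat_pred),
             rmse_cal = rmse(y_cal, yhat_cal),
             rmse_pred = rmse(y_pred, yhat_pred))
}
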