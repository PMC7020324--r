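## Calibration-assessment formulas: RMSE (CV / external prediction flavours
## differ only in which sample set supplies the divisor), the coefficient of
## determination, the residual predictive deviation and its interpretation
## bands.

#' Root-mean-square error
#'
#' `sqrt(sum((predicted - measured)^2) / n)` where n is the size of the set
#' the residuals come from -- the cross-validation set for RMSECV, the
#' external test set for RMSEP.
#'
#' @param predicted,measured Numeric vectors of equal length >= 1.
#' @return Scalar RMSE.
#' @export
rmse <- function(predicted, measured) {
  if (length(predicted) != length(measured)) {
    stop("predicted and measured differ in length", call. = FALSE)
  }
  sqrt(mean((as.numeric(predicted) - as.numeric(measured))^2))
}

#' Coefficient of determination
#'
#' The standard form `1 - sum((yhat - y)^2) / sum((y - ybar)^2)`. (Printed
#' variants that divide by `sum((yhat - ybar)^2)` are occasionally seen in
#' the applied literature but head towards 0, not 1, for good fits; this
#' implementation uses the standard definition.)
#'
#' @param predicted,measured Numeric vectors; `measured` must have positive
#'   variance.
#' @return R-squared (at most 1; can be negative for models worse than the
#'   mean).
#' @export
r_squared <- function(predicted, measured) {
  if (length(predicted) != length(measured)) {
    stop("predicted and measured differ in length", call. = FALSE)
  }
  measured <- as.numeric(measured); predicted <- as.numeric(predicted)
  ss_tot <- sum((measured - mean(measured))^2)
  if (ss_tot <= 0) {
    stop("measured values have zero variance; R2 is undefined",
         call. = FALSE)
  }
  1 - sum((predicted - measured)^2) / ss_tot
}

#' Residual predictive deviation
#'
#' Sample standard deviation (n - 1 divisor) of the measured test-set
#' values divided by the RMSEP.
#'
#' @param measured_test Measured reference values of the test set (>= 2).
#' @param rmsep External-prediction RMSE, > 0.
#' @return Scalar RPD.
#' @export
rpd <- function(measured_test, rmsep) {
  if (length(measured_test) < 2L) {
    stop("RPD needs at least 2 measured test values", call. = FALSE)
  }
  if (!is.finite(rmsep) || rmsep <= 0) {
    stop("RMSEP must be positive (zero RMSEP gives infinite RPD)",
         call. = FALSE)
  }
  stats::sd(measured_test) / rmsep
}

#' RPD interpretation band
#'
#' Half-open, exhaustive bands: below 1.5 the model is insufficient; 1.5 up
#' to 2 it can discriminate low from high contents; 2 up to 2.5 it predicts
#' roughly; 2.5 and above it has excellent predictive power.
#'
#' @param rpd_value Positive RPD.
#' @return One of `"insufficient"`, `"low_high_discrimination"`,
#'   `"rough_prediction"`, `"excellent"`.
#' @export
rpd_band <- function(rpd_value) {
  if (!is.finite(rpd_value) || rpd_value <= 0) {
    stop("RPD must be positive", call. = FALSE)
  }
  if (rpd_value < 1.5) "insufficient"
  else if (rpd_value < 2) "low_high_discrimination"
  else if (rpd_value < 2.5) "rough_prediction"
  else "excellent"
}

#' Assemble a regression assessment report
#'
#' @param measured_cv,predicted_cv Cross-validation measured/predicted
#'   values (training set).
#' @param measured_test,predicted_test External-prediction values (test
#'   set).
#' @return List of class `regression_report` with `r2_cv`, `rmsecv`,
#'   `r2_pred`, `rmsep`, `rpd` and `rpd_band`.
#' @export
regression_report <- function(measured_cv, predicted_cv,
                              measured_test, predicted_test) {
  rmsep_ <- rmse(predicted_test, measured_test)
  rpd_ <- rpd(measured_test, rmsep_)
  structure(list(r2_cv = r_squared(predicted_cv, measured_cv),
                 rmsecv = rmse(predicted_cv, measured_cv),
                 r2_pred = r_squared(predicted_test, measured_test),
                 rmsep = rmsep_, rpd = rpd_, rpd_band = rpd_band(rpd_)),
            class = "regression_report")
}

#' @export
print.regression_report <- function(x, ...) {
  cat(sprintf("CV:   R2 = %.3f, RMSECV = %.3f\n", x$r2_cv, x$rmsecv))
  cat(sprintf("Test: R2 = %.3f, RMSEP = %.3f, RPD = %.2f (%s)\n",
              x$r2_pred, x$rmsep, x$rpd, x$rpd_band))
  invisible(x)
}
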