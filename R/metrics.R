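#' Root-mean-square error
#'
#' @param y True values.
#' @param yhat Predicted values (same length, non-empty).
#' @return Non-negative scalar.
#' @export
rmse <- function(y, yhat) {
  if (length(y) == 0L || length(y) != length(yhat))
    stopf("y and yhat must be non-empty vectors of equal length")
  sqrt(mean((y - yhat)^2))
}

#' Mean absolute error
#'
#' @inheritParams rmse
#' @return Non-negative scalar.
#' @export
mae <- function(y, yhat) {
  if (length(y) == 0L || length(y) != length(yhat))
    stopf("y and yhat must be non-empty vectors of equal length")
  mean(abs(y - yhat))
}

#' Relative error reduction in percent
#'
#' `100 * (baseline - improved) / baseline`: by how many percent the
#' improved error undercuts the baseline error.
#'
#' @param baseline Baseline error (> 0).
#' @param improved Improved error.
#' @return Percent reduction (negative if `improved` is worse).
#' @export
relative_reduction <- function(baseline, improved) {
  assert_scalar_num(baseline, "baseline", lower = 0, strict_lower = TRUE)
  100 * (baseline - improved) / baseline
}

#' Per-subject evaluation report
#'
#' Assembles the standard result-table shape: one row per subject with
#' RMSE and MAE, plus a final `"Avg"` row holding the arithmetic mean of
#' the per-subject values.
#'
#' @param subject_ids Vector of subject identifiers.
#' @param rmse_values,mae_values Per-subject metric vectors.
#' @return An `eval_report` data.frame with columns `subject`, `rmse`,
#'   `mae`.
#' @export
eval_report <- function(subject_ids, rmse_values, mae_values) {
  stopifnot(length(subject_ids) == length(rmse_values),
            length(subject_ids) == length(mae_values))
  if (any(rmse_values < mae_values - 1e-12))
    stopf("RMSE < MAE in a report row: metrics are inconsistent")
  df <- data.frame(subject = c(as.character(subject_ids), "Avg"),
                   rmse = c(rmse_values, mean(rmse_values)),
                   mae = c(mae_values, mean(mae_values)),
                   stringsAsFactors = FALSE)
  class(df) <- c("eval_report", "data.frame")
  df
}

#' @export
print.eval_report <- function(x, digits = 4, ...) {
  y <- as.data.frame(x)
  y$rmse <- round(y$rmse, digits)
  y$mae <- round(y$mae, digits)
  print(y, row.names = FALSE)
  invisible(x)
}

#' Average row value of an evaluation report
#'
#' @param report An [eval_report()].
#' @param metric `"rmse"` or `"mae"`.
#' @return The Avg-row value.
#' @export
report_avg <- function(report, metric = "rmse") {
  report[[metric]][report$subject == "Avg"]
}
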