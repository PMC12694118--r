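#' Published SEED-VIG benchmark reference metrics
#'
#' Per-subject RMSE/MAE tables reported for next-step PERCLOS forecasting
#' on the 23-subject SEED-VIG benchmark, bundled as plain text. Conditions
#' cover the LOOCV paradigm (LSTM with DE+PERCLOS vs PERCLOS-only input;
#' the full hybrid model with each of the four EEG feature sets) and the
#' pretrain-finetune paradigm (the hybrid model with each feature set).
#' Each condition has 23 subject rows plus the reported `"Avg"` row.
#'
#' @return data.frame with columns `paradigm`, `model`, `feature`,
#'   `subject`, `rmse`, `mae`.
#' @export
reference_metrics <- function() {
  path <- system.file("extdata", "seedvig_reference_metrics.csv",
                      package = "fatiguecast", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE,
                  colClasses = c(subject = "character"))
}

#' Check reported averages against per-subject values
#'
#' For each condition in [reference_metrics()], recomputes the mean of the
#' 23 per-subject values and compares it (rounded to 4 decimals, the
#' table printing convention) with the reported `"Avg"` row.
#'
#' @param metrics Optionally, a data.frame shaped like
#'   [reference_metrics()].
#' @return data.frame with one row per condition and metric: recomputed
#'   mean, reported average, and whether they agree at 4 d.p.
#' @export
check_reference_averages <- function(metrics = reference_metrics()) {
  keys <- unique(metrics[c("paradigm", "model", "feature")])
  out <- do.call(rbind, lapply(seq_len(nrow(keys)), function(i) {
    sel <- metrics$paradigm == keys$paradigm[i] &
      metrics$model == keys$model[i] & metrics$feature == keys$feature[i]
    per <- metrics[sel & metrics$subject != "Avg", ]
    avg <- metrics[sel & metrics$subject == "Avg", ]
    do.call(rbind, lapply(c("rmse", "mae"), function(m)
      data.frame(keys[i, ], metric = m,
                 mean_of_subjects = mean(per[[m]]),
                 reported_avg = avg[[m]],
                 consistent = round(mean(per[[m]]), 4) == avg[[m]],
                 row.names = NULL)))
  }))
  rownames(out) <- NULL
  out
}

#' Reference average for one benchmark condition
#'
#' Mean of the 23 per-subject values (not the reported rounded average).
#'
#' @param paradigm `"loocv"` or `"finetune"`.
#' @param model `"lstm"` or `"ctl_resfnet"`.
#' @param feature Condition feature name (e.g. `"de_perclos"`,
#'   `"perclos_only"`, `"alpha_beta"`, `"de"`).
#' @param metric `"rmse"` or `"mae"`.
#' @return Scalar mean.
#' @export
reference_average <- function(paradigm, model, feature, metric = "rmse") {
  m <- reference_metrics()
  sel <- m$paradigm == paradigm & m$model == model & m$feature == feature &
    m$subject != "Avg"
  if (!any(sel)) stopf("no such condition: %s/%s/%s", paradigm, model, feature)
  mean(m[[metric]][sel])
}
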