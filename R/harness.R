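# Evaluation harnesses: leave-one-subject-out cross-validation and
# cross-subject pretraining with within-subject fine-tuning.

cohort_designs <- function(cohort, feature_kind, window_s = 8) {
  lapply(cohort, function(s) design_matrix(s$session, feature_kind,
                                           window_s = window_s))
}

#' Leave-one-subject-out cross-validation
#'
#' Each subject serves once as the held-out test set while all remaining
#' subjects form the training pool. Per fold, z-score statistics are fit on
#' the pooled training subjects only (no leakage from the held-out
#' subject), the model is trained for a fixed number of epochs without
#' early stopping, and the final-epoch model is evaluated on the whole
#' held-out subject.
#'
#' @param cohort List of `list(profile, session)` from [generate_cohort()].
#' @param feature_kind One of `"de"`, `"abr"`, `"we"`, `"hurst"`,
#'   `"perclos_only"`.
#' @param variant Architecture variant name (see [build_variant()]).
#' @param cfg A [train_config()]; default [loocv_train_config()].
#' @param L Sliding-window length in timesteps (default 3).
#' @param designs Optional precomputed list of design matrices (one per
#'   subject), to avoid re-extracting features across repeated runs.
#' @return An [eval_report()] with one row per subject plus `"Avg"`.
#' @export
run_loocv <- function(cohort, feature_kind = "de", variant = "FULL",
                      cfg = loocv_train_config(), L = 3L, designs = NULL) {
  if (length(cohort) < 2L) stopf("LOOCV needs at least 2 subjects")
  designs <- designs %||% cohort_designs(cohort, feature_kind)
  datasets <- lapply(designs, make_windows, L = L)
  d_in <- dim(datasets[[1]]$X)[3]
  spec <- build_variant(variant, input_dim = d_in)
  ids <- vapply(cohort, function(s) s$profile$subject_id, 0L)

  r_vec <- numeric(length(cohort)); m_vec <- numeric(length(cohort))
  for (k in seq_along(cohort)) {
    train_pool <- pool_datasets(datasets[-k])
    stats <- zscore_fit(train_pool)
    fold_cfg <- cfg
    fold_cfg$seed <- derive_seed(cfg$seed, k)
    fit <- train_model(spec, zscore_apply(train_pool, stats),
                       cfg = fold_cfg)
    test <- zscore_apply(datasets[[k]], stats)
    yh <- nn_predict(fit$params, spec, test)
    r_vec[k] <- rmse(test$y, yh)
    m_vec[k] <- mae(test$y, yh)
  }
  eval_report(ids, r_vec, m_vec)
}

#' Cross-subject pretraining with within-subject fine-tuning
#'
#' Stage 1 splits every subject's series chronologically 8:1:1, pools all
#' training segments into one pretraining set, and trains with early
#' stopping monitored on the pooled validation segments. Stage 2 clones
#' the pretrained weights for each subject, fine-tunes on that subject's
#' training segment with early stopping on its own validation segment, and
#' evaluates on its test segment. Normalization statistics come from the
#' pooled training segments and are reused throughout, keeping the input
#' scale consistent with the transferred weights.
#'
#' @inheritParams run_loocv
#' @param cfg_pre Pretraining config (default [pretrain_train_config()]).
#' @param cfg_ft Fine-tuning config (default [finetune_train_config()]);
#'   `max_epochs = 0` evaluates the pretrained model directly.
#' @return An [eval_report()]; attribute `"run_meta"` records both configs.
#' @export
run_pretrain_finetune <- function(cohort, feature_kind = "de",
                                  variant = "FULL",
                                  cfg_pre = pretrain_train_config(),
                                  cfg_ft = finetune_train_config(),
                                  L = 3L, designs = NULL) {
  if (length(cohort) < 1L) stopf("empty cohort")
  designs <- designs %||% cohort_designs(cohort, feature_kind)
  datasets <- lapply(designs, make_windows, L = L)
  splits <- lapply(datasets, chronological_split)
  d_in <- dim(datasets[[1]]$X)[3]
  spec <- build_variant(variant, input_dim = d_in)
  ids <- vapply(cohort, function(s) s$profile$subject_id, 0L)

  pool_train <- pool_datasets(lapply(splits, `[[`, "train"))
  pool_val <- pool_datasets(lapply(splits, `[[`, "val"))
  stats <- zscore_fit(pool_train)
  pre <- train_model(spec, zscore_apply(pool_train, stats),
                     val = zscore_apply(pool_val, stats), cfg = cfg_pre)

  r_vec <- numeric(length(cohort)); m_vec <- numeric(length(cohort))
  for (k in seq_along(cohort)) {
    ft_cfg <- cfg_ft
    ft_cfg$seed <- derive_seed(cfg_ft$seed, k)
    fit <- if (ft_cfg$max_epochs == 0L) pre
           else train_model(spec, zscore_apply(splits[[k]]$train, stats),
                            val = zscore_apply(splits[[k]]$val, stats),
                            cfg = ft_cfg, init = pre$params)
    test <- zscore_apply(splits[[k]]$test, stats)
    yh <- nn_predict(fit$params, spec, test)
    r_vec[k] <- rmse(test$y, yh)
    m_vec[k] <- mae(test$y, yh)
  }
  rep <- eval_report(ids, r_vec, m_vec)
  attr(rep, "run_meta") <- list(pretrain = unclass(cfg_pre),
                                finetune = unclass(cfg_ft),
                                variant = variant,
                                feature_kind = feature_kind, L = L)
  rep
}

#' Sweep the sliding-window length
#'
#' Repeats [run_loocv()] for each window length and collects the average
#' RMSE/MAE per length.
#'
#' @inheritParams run_loocv
#' @param lengths Integer vector of window lengths to try (default 1:5).
#' @return data.frame with columns `L`, `avg_rmse`, `avg_mae`, and the
#'   per-length reports as attribute `"reports"`.
#' @export
window_length_sweep <- function(cohort, lengths = 1:5, feature_kind = "de",
                                variant = "FULL",
                                cfg = loocv_train_config(),
                                designs = NULL) {
  if (any(lengths < 1)) stopf("window lengths must be >= 1")
  designs <- designs %||% cohort_designs(cohort, feature_kind)
  reports <- lapply(lengths, function(L)
    run_loocv(cohort, feature_kind, variant, cfg, L = L, designs = designs))
  out <- data.frame(L = lengths,
                    avg_rmse = vapply(reports, report_avg, 0),
                    avg_mae = vapply(reports, report_avg, 0,
                                     metric = "mae"))
  attr(out, "reports") <- reports
  out
}

#' Write an evaluation report as CSV and JSON
#'
#' @param report An [eval_report()].
#' @param path_prefix Output path without extension.
#' @param meta Optional metadata list stored in the JSON sidecar.
#' @return Invisibly, the two file paths.
#' @export
write_report <- function(report, path_prefix, meta = NULL) {
  csv <- paste0(path_prefix, ".csv")
  js <- paste0(path_prefix, ".json")
  utils::write.csv(as.data.frame(report), csv, row.names = FALSE)
  jsonlite::write_json(list(report = as.data.frame(report),
                            meta = meta %||% attr(report, "run_meta")),
                       js, auto_unbox = TRUE, digits = NA)
  invisible(c(csv = csv, json = js))
}
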