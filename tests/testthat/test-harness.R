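test_that("rmse and mae follow their definitions", {
  expect_equal(rmse(c(1, 2), c(1, 2)), 0)
  expect_equal(mae(c(1, 2), c(1, 2)), 0)
  expect_equal(rmse(c(0, 1), c(1, 0)), 1)
  expect_equal(mae(c(0, 1), c(1, 0)), 1)
  expect_equal(rmse(c(0, 0), c(3, 4)), sqrt(12.5))
  expect_error(rmse(numeric(0), numeric(0)), "non-empty")
  expect_error(mae(1:3, 1:2), "equal length")
})

test_that("relative reduction is the percent improvement over baseline", {
  expect_equal(relative_reduction(1, 0.5), 50)
  expect_equal(relative_reduction(0.37, 0.37), 0)
  expect_equal(relative_reduction(0.0683, 0.0598), 12.4, tolerance = 0.005)
  expect_error(relative_reduction(0, 1), "baseline")
})

test_that("evaluation reports aggregate exactly and enforce RMSE >= MAE", {
  r <- eval_report(1:3, c(0.2, 0.4, 0.6), c(0.1, 0.3, 0.5))
  expect_equal(nrow(r), 4)
  expect_equal(r$rmse[4], mean(c(0.2, 0.4, 0.6)), tolerance = 1e-12)
  expect_equal(r$mae[4], mean(c(0.1, 0.3, 0.5)), tolerance = 1e-12)
  expect_equal(report_avg(r), 0.4)
  expect_error(eval_report(1:2, c(0.1, 0.1), c(0.2, 0.05)), "inconsistent")
})

test_that("training is seeded-deterministic and early stopping restores the best epoch", {
  ds <- random_dataset()
  spec <- build_variant("LSTM_ONLY", input_dim = 10)
  cfg <- train_config(max_epochs = 15, seed = 3)
  f1 <- train_model(spec, ds, cfg = cfg)
  f2 <- train_model(spec, ds, cfg = cfg)
  expect_identical(f1$params, f2$params)
  expect_identical(f1$history$train_loss, f2$history$train_loss)
  expect_lt(f1$history$train_loss[15], f1$history$train_loss[1])

  val <- random_dataset(n = 16, seed = 9)
  cfg_es <- train_config(max_epochs = 100, early_stop_patience = 5,
                         lr_halving_patience = 3, seed = 4)
  fes <- train_model(spec, ds, val = val, cfg = cfg_es)
  n_ep <- nrow(fes$history)
  expect_lte(n_ep - fes$best_epoch, 5)    # halts within patience of best
  # restored parameters reproduce the best validation loss
  expect_equal(fatiguecast:::dataset_loss(fes$params, spec, val),
               min(fes$history$val_loss))
  # learning rate was halved at least once on this plateau-prone run
  expect_lt(min(fes$history$lr), cfg_es$lr)

  expect_error(train_model(spec, ds, cfg = train_config(
    early_stop_patience = 3)), "validation")
})

test_that("LOOCV partitions subjects correctly and aggregates per fold", {
  coh <- coupled_cohort()
  rep <- run_loocv(coh, "perclos_only", variant = "LSTM_ONLY",
                   cfg = loocv_train_config(seed = 2, max_epochs = 5))
  expect_s3_class(rep, "eval_report")
  expect_equal(rep$subject, c("1", "2", "3", "Avg"))
  expect_equal(rep$rmse[4], mean(rep$rmse[1:3]), tolerance = 1e-12)
  expect_true(all(rep$rmse >= rep$mae))
  expect_error(run_loocv(coh[1], "perclos_only"), "at least 2")
})

test_that("per-fold normalization ignores the held-out subject entirely", {
  coh <- coupled_cohort()
  designs <- coupled_designs("abr")
  datasets <- lapply(designs, make_windows, L = 3L)
  stats <- zscore_fit(fatiguecast:::pool_datasets(datasets[-1]))
  corrupted <- datasets
  corrupted[[1]]$X[] <- 1e9
  stats_c <- zscore_fit(fatiguecast:::pool_datasets(corrupted[-1]))
  expect_identical(stats, stats_c)
})

test_that("pretrain-finetune shares pretrained weights and records its schedule", {
  coh <- coupled_cohort()
  designs <- coupled_designs("abr")
  cfg_pre <- pretrain_train_config(seed = 5, max_epochs = 12)
  cfg_ft <- finetune_train_config(seed = 5, max_epochs = 6)
  rep <- run_pretrain_finetune(coh, "abr", "LSTM_ONLY", cfg_pre, cfg_ft,
                               designs = designs)
  expect_equal(rep$subject, c("1", "2", "3", "Avg"))
  meta <- attr(rep, "run_meta")
  expect_equal(meta$finetune$lr, 1e-4)
  expect_equal(meta$finetune$max_epochs, 6L)
  expect_equal(meta$pretrain$lr, 1e-3)

  # zero fine-tuning epochs = direct evaluation of the pretrained model
  cfg0 <- cfg_ft; cfg0$max_epochs <- 0L
  rep0a <- run_pretrain_finetune(coh, "abr", "LSTM_ONLY", cfg_pre, cfg0,
                                 designs = designs)
  rep0b <- run_pretrain_finetune(coh, "abr", "LSTM_ONLY", cfg_pre, cfg0,
                                 designs = designs)
  expect_identical(as.data.frame(rep0a), as.data.frame(rep0b))
})

test_that("default schedules encode the two training protocols", {
  lo <- loocv_train_config()
  expect_equal(lo$lr, 1e-3); expect_equal(lo$batch_size, 64L)
  expect_equal(lo$max_epochs, 20L); expect_null(lo$early_stop_patience)
  pre <- pretrain_train_config()
  expect_equal(pre$max_epochs, 150L)
  expect_equal(pre$early_stop_patience, 10L)
  expect_equal(pre$lr_halving_patience, 5L)
  ft <- finetune_train_config()
  expect_equal(ft$lr, 1e-4); expect_equal(ft$max_epochs, 50L)
})

test_that("window-length sweep is structurally sound and deterministic", {
  coh <- coupled_cohort()
  designs <- coupled_designs("perclos_only")
  tab <- window_length_sweep(coh, lengths = 1:3, "perclos_only",
                             "LSTM_ONLY",
                             cfg = loocv_train_config(seed = 6,
                                                      max_epochs = 4),
                             designs = designs)
  expect_equal(tab$L, 1:3)
  expect_true(all(is.finite(tab$avg_rmse) & tab$avg_rmse > 0))
  expect_true(all(is.finite(tab$avg_mae) & tab$avg_mae > 0))
  tab2 <- window_length_sweep(coh, lengths = 1:3, "perclos_only",
                              "LSTM_ONLY",
                              cfg = loocv_train_config(seed = 6,
                                                       max_epochs = 4),
                              designs = designs)
  expect_identical(tab$avg_rmse, tab2$avg_rmse)
})

test_that("published benchmark tables agree with their own averages where asserted", {
  chk <- check_reference_averages()
  named <- chk[(chk$feature == "de_perclos" | chk$feature == "perclos_only") &
                 chk$metric == "rmse" |
               (chk$paradigm == "loocv" & chk$feature == "alpha_beta" &
                  chk$metric == "rmse") |
               (chk$paradigm == "finetune" & chk$feature == "de" &
                  chk$metric == "rmse"), ]
  expect_true(all(named$consistent))
})
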