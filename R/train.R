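#' Training configuration
#'
#' MSE loss with the Adam optimizer throughout. Three preset schedules
#' mirror the two evaluation paradigms:
#' \describe{
#'   \item{[loocv_train_config()]}{lr 0.001, batch 64, fixed 20 epochs, no
#'     early stopping.}
#'   \item{[pretrain_train_config()]}{lr 0.001, batch 64, up to 150 epochs,
#'     early stopping patience 10, learning-rate halving patience 5.}
#'   \item{[finetune_train_config()]}{lr 0.0001, up to 50 epochs, otherwise
#'     as pretraining.}
#' }
#'
#' @param lr Initial learning rate.
#' @param batch_size Minibatch size.
#' @param max_epochs Number of epochs (upper bound when early stopping).
#' @param early_stop_patience Epochs without validation improvement before
#'   stopping (NULL disables early stopping).
#' @param lr_halving_patience Epochs without validation improvement before
#'   halving the learning rate (NULL disables).
#' @param seed Integer seed covering initialization and batch shuffling.
#' @return A `train_config` object.
#' @export
train_config <- function(lr = 1e-3, batch_size = 64L, max_epochs = 20L,
                         early_stop_patience = NULL,
                         lr_halving_patience = NULL, seed = 1L) {
  structure(list(lr = lr, batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 early_stop_patience = early_stop_patience,
                 lr_halving_patience = lr_halving_patience,
                 seed = as.integer(seed)),
            class = "train_config")
}

#' @rdname train_config
#' @export
loocv_train_config <- function(seed = 1L, max_epochs = 20L)
  train_config(lr = 1e-3, batch_size = 64L, max_epochs = max_epochs,
               seed = seed)

#' @rdname train_config
#' @export
pretrain_train_config <- function(seed = 1L, max_epochs = 150L)
  train_config(lr = 1e-3, batch_size = 64L, max_epochs = max_epochs,
               early_stop_patience = 10L, lr_halving_patience = 5L,
               seed = seed)

#' @rdname train_config
#' @export
finetune_train_config <- function(seed = 1L, max_epochs = 50L)
  train_config(lr = 1e-4, batch_size = 64L, max_epochs = max_epochs,
               early_stop_patience = 10L, lr_halving_patience = 5L,
               seed = seed)

mse <- function(a, b) mean((a - b)^2)

dataset_loss <- function(params, spec, ds) mse(nn_predict(params, spec, ds), ds$y)

#' Train a model with Adam on MSE loss
#'
#' Minibatch Adam with per-epoch shuffling of sample order (the timestep
#' order inside each sample is never permuted). With a validation set and
#' `early_stop_patience`, training stops after that many epochs without
#' validation improvement and the parameters from the best validation
#' epoch are restored; `lr_halving_patience` halves the learning rate on
#' plateau. Fully deterministic given `cfg$seed`.
#'
#' @param spec A [model_spec()].
#' @param train A `supervised_dataset` (standardized inputs).
#' @param val Optional validation `supervised_dataset`.
#' @param cfg A [train_config()].
#' @param init Optional parameter list to start from (e.g. pretrained
#'   weights); defaults to a fresh seeded initialization.
#' @return List with `params`, `spec`, `history` (per-epoch train/val loss
#'   and learning rate), and `best_epoch`.
#' @export
train_model <- function(spec, train, val = NULL, cfg = train_config(),
                        init = NULL) {
  stopifnot(inherits(spec, "model_spec"), inherits(train, "supervised_dataset"))
  if (!is.null(cfg$early_stop_patience) && is.null(val))
    stopf("early stopping requires a validation set")
  set.seed(cfg$seed)
  params <- init %||% init_model(spec, seed = derive_seed(cfg$seed, 1L))
  N <- length(train$y)
  if (N < 1L) stopf("empty training set")

  adam_m <- lapply(params, function(p) p * 0)
  adam_v <- lapply(params, function(p) p * 0)
  adam_t <- 0L
  lr <- cfg$lr
  beta1 <- 0.9; beta2 <- 0.999; adam_eps <- 1e-8

  best_val <- Inf; best_params <- params; best_epoch <- 0L
  stall <- 0L; lr_stall <- 0L
  hist <- data.frame(epoch = integer(), train_loss = numeric(),
                     val_loss = numeric(), lr = numeric())

  if (cfg$max_epochs == 0L)
    return(list(params = params, spec = spec, history = hist,
                best_epoch = 0L))

  for (epoch in seq_len(cfg$max_epochs)) {
    ord <- sample.int(N)
    ep_loss <- 0; nb <- 0L
    for (start in seq(1L, N, by = cfg$batch_size)) {
      idx <- ord[start:min(start + cfg$batch_size - 1L, N)]
      Xb <- train$X[idx, , , drop = FALSE]
      yb <- train$y[idx]
      fw <- nn_forward(params, spec, Xb, keep_cache = TRUE)
      loss <- mse(fw$yhat, yb)
      if (!is.finite(loss))
        stopf("training diverged (non-finite loss at epoch %d)", epoch)
      dy <- 2 * (fw$yhat - yb) / length(yb)
      g <- nn_backward(params, spec, fw$cache, dy)
      adam_t <- adam_t + 1L
      bc1 <- 1 - beta1^adam_t; bc2 <- 1 - beta2^adam_t
      for (nm in names(params)) {
        adam_m[[nm]] <- beta1 * adam_m[[nm]] + (1 - beta1) * g[[nm]]
        adam_v[[nm]] <- beta2 * adam_v[[nm]] + (1 - beta2) * g[[nm]]^2
        params[[nm]] <- params[[nm]] -
          lr * (adam_m[[nm]] / bc1) / (sqrt(adam_v[[nm]] / bc2) + adam_eps)
      }
      ep_loss <- ep_loss + loss; nb <- nb + 1L
    }
    vl <- if (!is.null(val)) dataset_loss(params, spec, val) else NA_real_
    hist <- rbind(hist, data.frame(epoch = epoch, train_loss = ep_loss / nb,
                                   val_loss = vl, lr = lr))
    if (!is.null(val)) {
      if (vl < best_val - 1e-12) {
        best_val <- vl; best_params <- params; best_epoch <- epoch
        stall <- 0L; lr_stall <- 0L
      } else {
        stall <- stall + 1L; lr_stall <- lr_stall + 1L
      }
      if (!is.null(cfg$lr_halving_patience) &&
          lr_stall >= cfg$lr_halving_patience) {
        lr <- lr / 2; lr_stall <- 0L
      }
      if (!is.null(cfg$early_stop_patience) &&
          stall >= cfg$early_stop_patience) break
    }
  }
  if (!is.null(val) && !is.null(cfg$early_stop_patience)) {
    params <- best_params
  } else {
    best_epoch <- nrow(hist)
  }
  list(params = params, spec = spec, history = hist, best_epoch = best_epoch)
}
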