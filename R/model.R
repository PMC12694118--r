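model_variants <- function() {
  c("FULL", "NO_CNN", "NO_TRANSFORMER", "NO_LSTM", "NO_RESIDUAL",
    "CNN_ONLY", "TRANSFORMER_ONLY", "LSTM_ONLY", "CNN_TRANSFORMER")
}

#' Architecture specification of the fatigue-forecasting network
#'
#' The full network is: sinusoidal positional encoding on the raw input
#' (dimension `input_dim`, 86 for differential entropy + PERCLOS), a
#' width-1 1-D convolution mapping `input_dim` to 64 channels (sequence
#' length preserved), one transformer encoder layer (4-head self-attention,
#' feed-forward width 64, post-norm residual sublayers), an outer residual
#' skip from the convolution output to the encoder output, a 2-layer LSTM
#' with hidden size 32, and an affine 32 to 1 head with sigmoid activation
#' so predictions stay in (0, 1).
#'
#' @param input_dim Width of each timestep's input vector.
#' @param conv_out Convolution output channels / encoder model width.
#' @param n_heads Attention heads (must divide `conv_out`).
#' @param ff_dim Feed-forward inner width.
#' @param n_encoder_layers Encoder layers (1 in this architecture).
#' @param lstm_hidden LSTM hidden size.
#' @param lstm_layers Number of stacked LSTM layers.
#' @param variant One of the names listed by `model_variants()`; see
#'   [build_variant()].
#'
#' @return A `model_spec` object.
#' @export
model_spec <- function(input_dim = 86, conv_out = 64, n_heads = 4,
                       ff_dim = 64, n_encoder_layers = 1, lstm_hidden = 32,
                       lstm_layers = 2, variant = "FULL") {
  if (!variant %in% model_variants())
    stopf("unknown variant '%s'; valid names: %s", variant,
          paste(model_variants(), collapse = ", "))
  if (conv_out %% n_heads != 0)
    stopf("conv_out (%d) must be divisible by n_heads (%d)",
          conv_out, n_heads)
  if (n_encoder_layers != 1)
    stopf("only a single encoder layer is supported")
  flags <- variant_flags(variant)
  lstm_in <- if (is.na(flags$frontend)) input_dim else conv_out
  head_in <- if (flags$use_lstm) lstm_hidden
             else if (!is.na(flags$frontend)) conv_out
             else input_dim
  structure(c(list(input_dim = as.integer(input_dim),
                   conv_out = as.integer(conv_out),
                   n_heads = as.integer(n_heads),
                   ff_dim = as.integer(ff_dim),
                   n_encoder_layers = as.integer(n_encoder_layers),
                   lstm_hidden = as.integer(lstm_hidden),
                   lstm_layers = as.integer(lstm_layers),
                   variant = variant,
                   lstm_in = as.integer(lstm_in),
                   head_in = as.integer(head_in)),
              flags),
            class = "model_spec")
}

# Which blocks each variant keeps. frontend: "conv" (Kaiming-uniform init),
# "adapter" (same affine map, Xavier-uniform init, used where the
# convolution was ablated but the encoder width must still be reached), or
# NA (sequence fed onward at its raw width).
variant_flags <- function(variant) {
  switch(variant,
    FULL            = list(frontend = "conv", use_pe = TRUE,
                           use_encoder = TRUE, use_outer_residual = TRUE,
                           use_lstm = TRUE),
    NO_CNN          = list(frontend = "adapter", use_pe = TRUE,
                           use_encoder = TRUE, use_outer_residual = TRUE,
                           use_lstm = TRUE),
    NO_TRANSFORMER  = list(frontend = "conv", use_pe = FALSE,
                           use_encoder = FALSE, use_outer_residual = FALSE,
                           use_lstm = TRUE),
    NO_LSTM         = list(frontend = "conv", use_pe = TRUE,
                           use_encoder = TRUE, use_outer_residual = TRUE,
                           use_lstm = FALSE),
    NO_RESIDUAL     = list(frontend = "conv", use_pe = TRUE,
                           use_encoder = TRUE, use_outer_residual = FALSE,
                           use_lstm = TRUE),
    CNN_ONLY        = list(frontend = "conv", use_pe = FALSE,
                           use_encoder = FALSE, use_outer_residual = FALSE,
                           use_lstm = FALSE),
    TRANSFORMER_ONLY = list(frontend = "adapter", use_pe = TRUE,
                           use_encoder = TRUE, use_outer_residual = FALSE,
                           use_lstm = FALSE),
    LSTM_ONLY       = list(frontend = NA_character_, use_pe = FALSE,
                           use_encoder = FALSE, use_outer_residual = FALSE,
                           use_lstm = TRUE),
    CNN_TRANSFORMER = list(frontend = "conv", use_pe = TRUE,
                           use_encoder = TRUE, use_outer_residual = FALSE,
                           use_lstm = FALSE))
}

#' Build a named architecture variant
#'
#' `"FULL"` is the complete hybrid network. Ablations remove one block:
#' `"NO_CNN"` replaces the width-1 convolution with an equal-shape affine
#' width adapter (the encoder width must still be reached), `"NO_TRANSFORMER"`
#' drops the encoder (and the positional encoding that serves it),
#' `"NO_LSTM"` feeds the head from the last-position encoder output, and
#' `"NO_RESIDUAL"` disables the outer convolution-to-encoder-output skip
#' while keeping the encoder's internal (definitional) residual sublayers.
#' The baselines `"CNN_ONLY"`, `"TRANSFORMER_ONLY"`, `"LSTM_ONLY"` and
#' `"CNN_TRANSFORMER"` are the single/dual-block models trained under the
#' identical protocol.
#'
#' @param variant Variant name.
#' @param input_dim Input width per timestep.
#' @param ... Passed to [model_spec()].
#' @return A `model_spec`.
#' @export
build_variant <- function(variant, input_dim = 86, ...) {
  model_spec(input_dim = input_dim, variant = variant, ...)
}

#' @export
print.model_spec <- function(x, ...) {
  blocks <- c(if (x$use_pe) sprintf("PE(d=%d)", x$input_dim),
              if (!is.na(x$frontend))
                sprintf("%s(%d->%d)", x$frontend, x$input_dim, x$conv_out),
              if (x$use_encoder)
                sprintf("encoder(d=%d,h=%d,ff=%d)", x$conv_out, x$n_heads,
                        x$ff_dim),
              if (x$use_outer_residual) "outer-skip",
              if (x$use_lstm)
                sprintf("lstm(%d->%d x%d)", x$lstm_in, x$lstm_hidden,
                        x$lstm_layers),
              sprintf("fc(%d->1)+sigmoid", x$head_in))
  cat(sprintf("<model_spec> %s: %s\n", x$variant,
              paste(blocks, collapse = " -> ")))
  invisible(x)
}

runif_mat <- function(nr, nc, bound) matrix(runif(nr * nc, -bound, bound), nr, nc)

xavier_uniform <- function(nr, nc) runif_mat(nr, nc, sqrt(6 / (nr + nc)))

# PyTorch-style defaults: Kaiming-uniform (a = sqrt(5)) for convolutions
# collapses to U(+-1/sqrt(fan_in)); LSTM weights U(+-1/sqrt(hidden)).
kaiming_conv <- function(nr, nc) runif_mat(nr, nc, 1 / sqrt(nr))

#' Initialize model parameters
#'
#' Deterministic given `seed`: convolution weights Kaiming-uniform, affine
#' (adapter, attention, feed-forward, head) weights Xavier-uniform with
#' zero biases, LSTM weights uniform in +-1/sqrt(hidden), layer-norm gains
#' 1 and shifts 0.
#'
#' @param spec A [model_spec()].
#' @param seed Integer seed.
#' @return Named list of parameter matrices/vectors.
#' @export
init_model <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "model_spec"))
  set.seed(seed)
  p <- list()
  d <- spec$input_dim; cw <- spec$conv_out
  if (!is.na(spec$frontend)) {
    if (spec$frontend == "conv") {
      p$W_in <- kaiming_conv(d, cw)
      p$b_in <- runif(cw, -1 / sqrt(d), 1 / sqrt(d))
    } else {
      p$W_in <- xavier_uniform(d, cw)
      p$b_in <- numeric(cw)
    }
  }
  if (spec$use_encoder) {
    for (nm in c("W_q", "W_k", "W_v", "W_ao")) p[[nm]] <- xavier_uniform(cw, cw)
    for (nm in c("b_q", "b_k", "b_v", "b_ao")) p[[nm]] <- numeric(cw)
    p$ln1_g <- rep(1, cw); p$ln1_b <- numeric(cw)
    p$W_f1 <- xavier_uniform(cw, spec$ff_dim); p$b_f1 <- numeric(spec$ff_dim)
    p$W_f2 <- xavier_uniform(spec$ff_dim, cw); p$b_f2 <- numeric(cw)
    p$ln2_g <- rep(1, cw); p$ln2_b <- numeric(cw)
  }
  if (spec$use_lstm) {
    h <- spec$lstm_hidden
    bnd <- 1 / sqrt(h)
    ins <- c(spec$lstm_in, rep(h, spec$lstm_layers - 1L))
    for (l in seq_len(spec$lstm_layers)) {
      p[[sprintf("lstm%d_Wx", l)]] <- runif_mat(ins[l], 4L * h, bnd)
      p[[sprintf("lstm%d_Wh", l)]] <- runif_mat(h, 4L * h, bnd)
      p[[sprintf("lstm%d_b", l)]] <- runif(4L * h, -bnd, bnd)
    }
  }
  p$W_head <- xavier_uniform(spec$head_in, 1L)
  p$b_head <- 0
  p
}

#' Total parameter count of a model
#'
#' @param params Parameter list from [init_model()].
#' @return Integer count.
#' @export
n_parameters <- function(params) sum(vapply(params, length, 0L))
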