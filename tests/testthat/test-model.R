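test_that("positional encoding follows the sinusoidal definition", {
  pe <- positional_encoding(4, 6)
  expect_equal(pe[1, c(1, 3, 5)], rep(0, 3))   # sin(0)
  expect_equal(pe[1, c(2, 4, 6)], rep(1, 3))   # cos(0)
  expect_true(all(pe >= -1 & pe <= 1))
  expect_equal(pe[, 1], sin(0:3))              # column 0: sin(pos)
  expect_equal(pe[2, 3], sin(1 / 10000^(2 / 6)))
})

test_that("the FULL spec reproduces the published layer dimensions", {
  spec <- build_variant("FULL")
  expect_equal(spec$input_dim, 86)
  expect_equal(spec$conv_out, 64)
  expect_equal(spec$n_heads, 4)
  expect_equal(spec$ff_dim, 64)
  expect_equal(spec$n_encoder_layers, 1)
  expect_equal(spec$lstm_hidden, 32)
  expect_equal(spec$lstm_layers, 2)
  expect_equal(spec$head_in, 32)
  p <- init_model(spec, 1)
  expect_equal(dim(p$W_in), c(86, 64))
  expect_equal(dim(p$W_q), c(64, 64))
  expect_equal(dim(p$W_f1), c(64, 64))
  expect_equal(dim(p$lstm1_Wx), c(64, 128))
  expect_equal(dim(p$lstm2_Wx), c(32, 128))
  expect_equal(dim(p$W_head), c(32, 1))
})

test_that("variants assemble the right blocks", {
  no_lstm <- build_variant("NO_LSTM")
  expect_false(no_lstm$use_lstm)
  expect_equal(no_lstm$head_in, 64)   # head fed by last-position encoder out
  expect_true(no_lstm$use_encoder)

  no_res <- build_variant("NO_RESIDUAL")
  expect_false(no_res$use_outer_residual)
  # same parameter shapes as FULL, skip path disabled
  p_full <- init_model(build_variant("FULL"), 1)
  p_nores <- init_model(no_res, 1)
  expect_identical(lapply(p_full, dim), lapply(p_nores, dim))

  lstm_only <- build_variant("LSTM_ONLY", input_dim = 18)
  expect_true(is.na(lstm_only$frontend))
  expect_equal(lstm_only$lstm_in, 18)

  expect_error(build_variant("BOGUS"), "FULL.*LSTM_ONLY")
  expect_error(model_spec(conv_out = 62), "divisible")
})

test_that("two builds of one spec have identical shapes and counts", {
  spec <- build_variant("FULL")
  p1 <- init_model(spec, 1); p2 <- init_model(spec, 2)
  expect_identical(names(p1), names(p2))
  expect_identical(lapply(p1, dim), lapply(p2, dim))
  expect_identical(n_parameters(p1), n_parameters(p2))
  expect_identical(init_model(spec, 7), init_model(spec, 7))
})

test_that("forward pass is bounded, batch-equivariant, and centred at a zeroed head", {
  spec <- build_variant("FULL")
  params <- init_model(spec, 3)
  set.seed(4)
  X <- array(rnorm(5 * 3 * 86), c(5, 3, 86))
  y <- nn_forward(params, spec, X)$yhat
  expect_length(y, 5)
  expect_true(all(y > 0 & y < 1))

  pz <- params; pz$W_head[] <- 0; pz$b_head <- 0
  expect_equal(nn_forward(pz, spec, X)$yhat, rep(0.5, 5))

  perm <- c(3, 1, 5, 2, 4)
  expect_equal(nn_forward(params, spec, X[perm, , , drop = FALSE])$yhat,
               y[perm])

  Xex <- X; Xex[1, , ] <- 1e6; Xex[2, , ] <- -1e6
  yex <- nn_forward(params, spec, Xex)$yhat
  expect_true(all(yex > 0 & yex < 1))
  expect_error(nn_forward(params, spec, array(0, c(2, 3, 10))), "N x L x 86")
})

test_that("attention weights are a proper distribution per query", {
  spec <- build_variant("FULL", input_dim = 12, conv_out = 8, n_heads = 2,
                        ff_dim = 8, lstm_hidden = 4)
  params <- init_model(spec, 5)
  set.seed(6)
  X <- array(rnorm(7 * 3 * 12), c(7, 3, 12))
  cache <- nn_forward(params, spec, X, keep_cache = TRUE)$cache
  A <- cache$att$A                       # n x L x L x heads
  sums <- apply(A, c(1, 2, 4), sum)
  expect_lt(max(abs(sums - 1)), 1e-6)
  expect_true(all(A >= 0))
})

test_that("analytic gradients agree with finite differences in every variant", {
  for (variant in c("FULL", "NO_TRANSFORMER", "NO_LSTM", "LSTM_ONLY")) {
    spec <- model_spec(input_dim = 7, conv_out = 8, n_heads = 2, ff_dim = 6,
                       lstm_hidden = 5, variant = variant)
    set.seed(11)
    n <- 4
    X <- array(rnorm(n * 3 * 7), c(n, 3, 7))
    y <- runif(n)
    params <- init_model(spec, 12)
    loss_fn <- function(p) mean((nn_forward(p, spec, X)$yhat - y)^2)
    fw <- nn_forward(params, spec, X, keep_cache = TRUE)
    g <- nn_backward(params, spec, fw$cache, 2 * (fw$yhat - y) / n)
    for (nm in names(params)) {
      ii <- sort(sample(length(params[[nm]]), min(4, length(params[[nm]]))))
      for (i in ii) {
        eps <- 1e-5
        p_up <- params; p_up[[nm]][i] <- p_up[[nm]][i] + eps
        p_dn <- params; p_dn[[nm]][i] <- p_dn[[nm]][i] - eps
        num <- (loss_fn(p_up) - loss_fn(p_dn)) / (2 * eps)
        expect_lt(abs(num - g[[nm]][i]) /
                    max(1e-6, abs(num) + abs(g[[nm]][i])), 1e-3)
      }
    }
  }
})
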