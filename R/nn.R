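# Forward and backward passes of the sequence-regression network, written
# directly in base R matrix algebra. Batch activations for a sequence
# block are stored as N x L x d arrays; flattening to (N*L) x d matrices
# (samples vary fastest) turns every per-timestep affine map into a single
# matrix product.

#' Sinusoidal positional encoding
#'
#' `PE[pos, 2i] = sin(pos / 10000^(2i/d))` and
#' `PE[pos, 2i+1] = cos(pos / 10000^(2i/d))` with 0-based `pos` and `i`,
#' added elementwise to the input sequence.
#'
#' @param T_len Sequence length.
#' @param d Feature dimension (>= 2).
#' @return A `T_len` x `d` matrix with entries in `[-1, 1]`.
#' @export
positional_encoding <- function(T_len, d) {
  stopifnot(T_len >= 1, d >= 2)
  pe <- matrix(0, T_len, d)
  pos <- 0:(T_len - 1)
  for (j in 0:(d - 1)) {
    i <- j %/% 2
    arg <- pos / 10000^(2 * i / d)
    pe[, j + 1] <- if (j %% 2 == 0) sin(arg) else cos(arg)
  }
  pe
}

flat <- function(X3) {
  d <- dim(X3)
  matrix(X3, d[1] * d[2], d[3])
}

unflat <- function(M, n, L) array(M, c(n, L, ncol(M)))

seq_linear <- function(X3, W, b) {
  d <- dim(X3)
  unflat(sweep(flat(X3) %*% W, 2L, b, `+`), d[1], d[2])
}

# returns list(dX, dW, db) for Y = X W + b applied per timestep
seq_linear_bwd <- function(X3, W, dY3) {
  Xm <- flat(X3); dYm <- flat(dY3)
  list(dX = unflat(dYm %*% t(W), dim(X3)[1], dim(X3)[2]),
       dW = crossprod(Xm, dYm),
       db = colSums(dYm))
}

layernorm_fwd <- function(X3, g, b, eps = 1e-5) {
  d <- dim(X3)
  m <- flat(X3)
  mu <- rowMeans(m)
  xc <- m - mu
  v <- rowMeans(xc^2)
  inv <- 1 / sqrt(v + eps)
  xhat <- xc * inv
  y <- sweep(sweep(xhat, 2L, g, `*`), 2L, b, `+`)
  list(Y = unflat(y, d[1], d[2]), xhat = xhat, inv = inv)
}

layernorm_bwd <- function(cache, g, dY3) {
  dy <- flat(dY3)
  dg <- colSums(dy * cache$xhat)
  db <- colSums(dy)
  dxh <- sweep(dy, 2L, g, `*`)
  dx <- (dxh - rowMeans(dxh) - cache$xhat * rowMeans(dxh * cache$xhat)) *
    cache$inv
  d <- dim(dY3)
  list(dX = unflat(dx, d[1], d[2]), dg = dg, db = db)
}

# Multi-head scaled dot-product self-attention over an N x L x dm block.
attention_fwd <- function(Z, params, n_heads) {
  dm <- dim(Z)[3]; n <- dim(Z)[1]; L <- dim(Z)[2]
  dk <- dm %/% n_heads
  Q <- seq_linear(Z, params$W_q, params$b_q)
  K <- seq_linear(Z, params$W_k, params$b_k)
  V <- seq_linear(Z, params$W_v, params$b_v)
  A <- array(0, c(n, L, L, n_heads))
  H <- array(0, c(n, L, dm))
  for (hh in seq_len(n_heads)) {
    cols <- ((hh - 1L) * dk + 1L):(hh * dk)
    S <- array(0, c(n, L, L))
    for (t1 in seq_len(L)) for (t2 in seq_len(L))
      S[, t1, t2] <- rowSums(Q[, t1, cols, drop = FALSE] *
                             K[, t2, cols, drop = FALSE]) / sqrt(dk)
    for (t1 in seq_len(L)) {
      s <- matrix(S[, t1, ], n, L)
      s <- exp(s - apply(s, 1L, max))
      A[, t1, , hh] <- s / rowSums(s)
    }
    for (t1 in seq_len(L)) {
      acc <- matrix(0, n, dk)
      for (t2 in seq_len(L))
        acc <- acc + A[, t1, t2, hh] * matrix(V[, t2, cols], n, dk)
      H[, t1, cols] <- acc
    }
  }
  out <- seq_linear(H, params$W_ao, params$b_ao)
  list(out = out, Q = Q, K = K, V = V, A = A, H = H, Z = Z)
}

attention_bwd <- function(cache, params, n_heads, dOut) {
  Z <- cache$Z
  n <- dim(Z)[1]; L <- dim(Z)[2]; dm <- dim(Z)[3]
  dk <- dm %/% n_heads
  lo <- seq_linear_bwd(cache$H, params$W_ao, dOut)
  dH <- lo$dX
  dQ <- array(0, dim(Z)); dK <- array(0, dim(Z)); dV <- array(0, dim(Z))
  for (hh in seq_len(n_heads)) {
    cols <- ((hh - 1L) * dk + 1L):(hh * dk)
    dA <- array(0, c(n, L, L))
    for (t1 in seq_len(L)) for (t2 in seq_len(L)) {
      dV[, t2, cols] <- matrix(dV[, t2, cols], n, dk) +
        cache$A[, t1, t2, hh] * matrix(dH[, t1, cols], n, dk)
      dA[, t1, t2] <- rowSums(matrix(dH[, t1, cols], n, dk) *
                              matrix(cache$V[, t2, cols], n, dk))
    }
    for (t1 in seq_len(L)) {
      a <- matrix(cache$A[, t1, , hh], n, L)
      da <- matrix(dA[, t1, ], n, L)
      ds <- a * (da - rowSums(da * a)) / sqrt(dk)
      for (t2 in seq_len(L)) {
        dQ[, t1, cols] <- matrix(dQ[, t1, cols], n, dk) +
          ds[, t2] * matrix(cache$K[, t2, cols], n, dk)
        dK[, t2, cols] <- matrix(dK[, t2, cols], n, dk) +
          ds[, t2] * matrix(cache$Q[, t1, cols], n, dk)
      }
    }
  }
  bq <- seq_linear_bwd(Z, params$W_q, dQ)
  bk <- seq_linear_bwd(Z, params$W_k, dK)
  bv <- seq_linear_bwd(Z, params$W_v, dV)
  list(dZ = bq$dX + bk$dX + bv$dX,
       grads = list(W_q = bq$dW, b_q = bq$db, W_k = bk$dW, b_k = bk$db,
                    W_v = bv$dW, b_v = bv$db, W_ao = lo$dW, b_ao = lo$db))
}

sigm <- function(x) 1 / (1 + exp(-x))

# One LSTM layer over an N x L x din block (gate order i, f, g, o).
lstm_fwd <- function(X3, Wx, Wh, b) {
  n <- dim(X3)[1]; L <- dim(X3)[2]
  h <- nrow(Wh)
  H <- array(0, c(n, L, h))
  hp <- matrix(0, n, h); cp <- matrix(0, n, h)
  steps <- vector("list", L)
  for (t in seq_len(L)) {
    xt <- matrix(X3[, t, ], n)
    z <- sweep(xt %*% Wx + hp %*% Wh, 2L, b, `+`)
    i_g <- sigm(z[, 1:h, drop = FALSE])
    f_g <- sigm(z[, (h + 1):(2 * h), drop = FALSE])
    g_g <- tanh(z[, (2 * h + 1):(3 * h), drop = FALSE])
    o_g <- sigm(z[, (3 * h + 1):(4 * h), drop = FALSE])
    ct <- f_g * cp + i_g * g_g
    tc <- tanh(ct)
    ht <- o_g * tc
    steps[[t]] <- list(xt = xt, hp = hp, cp = cp, i = i_g, f = f_g,
                       g = g_g, o = o_g, c = ct, tc = tc)
    hp <- ht; cp <- ct
    H[, t, ] <- ht
  }
  list(H = H, steps = steps)
}

lstm_bwd <- function(cache, Wx, Wh, dH3) {
  L <- dim(dH3)[2]; n <- dim(dH3)[1]
  h <- nrow(Wh)
  dWx <- matrix(0, nrow(Wx), 4L * h); dWh <- matrix(0, h, 4L * h)
  db <- numeric(4L * h)
  dX <- array(0, c(n, L, nrow(Wx)))
  dh_next <- matrix(0, n, h); dc_next <- matrix(0, n, h)
  for (t in rev(seq_len(L))) {
    st <- cache$steps[[t]]
    dh <- matrix(dH3[, t, ], n, h) + dh_next
    dc <- dc_next + dh * st$o * (1 - st$tc^2)
    do_ <- dh * st$tc
    di <- dc * st$g
    df <- dc * st$cp
    dg <- dc * st$i
    dz <- cbind(di * st$i * (1 - st$i),
                df * st$f * (1 - st$f),
                dg * (1 - st$g^2),
                do_ * st$o * (1 - st$o))
    dWx <- dWx + crossprod(st$xt, dz)
    dWh <- dWh + crossprod(st$hp, dz)
    db <- db + colSums(dz)
    dX[, t, ] <- dz %*% t(Wx)
    dh_next <- dz %*% t(Wh)
    dc_next <- dc * st$f
  }
  list(dX = dX, dWx = dWx, dWh = dWh, db = db)
}

#' Forward pass of the network
#'
#' @param params Parameter list from [init_model()].
#' @param spec The [model_spec()].
#' @param X N x L x input_dim input array (already standardized).
#' @param keep_cache Keep intermediate activations (for the backward pass).
#' @return List with `yhat` (N predictions, all strictly in (0, 1)) and,
#'   when requested, `cache`.
#' @export
nn_forward <- function(params, spec, X, keep_cache = FALSE) {
  if (length(dim(X)) != 3L || dim(X)[3] != spec$input_dim)
    stopf("input must be an N x L x %d array", spec$input_dim)
  n <- dim(X)[1]; L <- dim(X)[2]
  cache <- list(X = X, n = n, L = L)
  h <- X
  if (spec$use_pe) {
    pe <- positional_encoding(L, spec$input_dim)
    for (t in seq_len(L)) h[, t, ] <- sweep(matrix(h[, t, ], n), 2L, pe[t, ], `+`)
  }
  Z0 <- if (!is.na(spec$frontend)) seq_linear(h, params$W_in, params$b_in)
        else h
  cache$h_in <- h; cache$Z0 <- Z0
  if (spec$use_encoder) {
    att <- attention_fwd(Z0, params, spec$n_heads)
    S1 <- Z0 + att$out
    ln1 <- layernorm_fwd(S1, params$ln1_g, params$ln1_b)
    Z1 <- ln1$Y
    F1pre <- seq_linear(Z1, params$W_f1, params$b_f1)
    F1 <- pmax(F1pre, 0)
    F2 <- seq_linear(F1, params$W_f2, params$b_f2)
    S2 <- Z1 + F2
    ln2 <- layernorm_fwd(S2, params$ln2_g, params$ln2_b)
    Z2 <- ln2$Y
    cache <- c(cache, list(att = att, ln1 = ln1, Z1 = Z1, F1pre = F1pre,
                           F1 = F1, ln2 = ln2))
  } else Z2 <- Z0
  Z3 <- if (spec$use_outer_residual) Z2 + Z0 else Z2
  cache$Z3 <- Z3
  if (spec$use_lstm) {
    inp <- Z3
    lstm_caches <- vector("list", spec$lstm_layers)
    for (l in seq_len(spec$lstm_layers)) {
      lc <- lstm_fwd(inp, params[[sprintf("lstm%d_Wx", l)]],
                     params[[sprintf("lstm%d_Wh", l)]],
                     params[[sprintf("lstm%d_b", l)]])
      lstm_caches[[l]] <- lc
      inp <- lc$H
    }
    feat <- matrix(inp[, L, ], n)
    cache$lstm <- lstm_caches
  } else {
    feat <- matrix(Z3[, L, ], n)
  }
  cache$feat <- feat
  u <- as.numeric(feat %*% params$W_head + params$b_head)
  yhat <- sigm(u)
  cache$yhat <- yhat
  list(yhat = yhat, cache = if (keep_cache) cache else NULL)
}

#' Backward pass: gradients of the loss w.r.t. all parameters
#'
#' @param params Parameter list.
#' @param spec The `model_spec`.
#' @param cache Cache from [nn_forward()] with `keep_cache = TRUE`.
#' @param dyhat Gradient of the loss w.r.t. each prediction (length N).
#' @return Named list of gradients matching `params`.
#' @export
nn_backward <- function(params, spec, cache, dyhat) {
  n <- cache$n; L <- cache$L
  g <- list()
  du <- dyhat * cache$yhat * (1 - cache$yhat)
  g$W_head <- crossprod(cache$feat, du)
  g$b_head <- sum(du)
  dfeat <- matrix(du, ncol = 1) %*% t(params$W_head)

  if (spec$use_lstm) {
    dH <- array(0, dim(cache$lstm[[spec$lstm_layers]]$H))
    dH[, L, ] <- dfeat
    for (l in rev(seq_len(spec$lstm_layers))) {
      lb <- lstm_bwd(cache$lstm[[l]], params[[sprintf("lstm%d_Wx", l)]],
                     params[[sprintf("lstm%d_Wh", l)]], dH)
      g[[sprintf("lstm%d_Wx", l)]] <- lb$dWx
      g[[sprintf("lstm%d_Wh", l)]] <- lb$dWh
      g[[sprintf("lstm%d_b", l)]] <- lb$db
      dH <- lb$dX
    }
    dZ3 <- dH
  } else {
    dZ3 <- array(0, dim(cache$Z3))
    dZ3[, L, ] <- dfeat
  }

  dZ0 <- if (spec$use_outer_residual) dZ3 else array(0, dim(cache$Z0))
  if (spec$use_encoder) {
    l2 <- layernorm_bwd(cache$ln2, params$ln2_g, dZ3)
    g$ln2_g <- l2$dg; g$ln2_b <- l2$db
    dS2 <- l2$dX
    f2 <- seq_linear_bwd(cache$F1, params$W_f2, dS2)
    g$W_f2 <- f2$dW; g$b_f2 <- f2$db
    dF1 <- f2$dX * (cache$F1pre > 0)
    f1 <- seq_linear_bwd(cache$Z1, params$W_f1, dF1)
    g$W_f1 <- f1$dW; g$b_f1 <- f1$db
    dZ1 <- dS2 + f1$dX
    l1 <- layernorm_bwd(cache$ln1, params$ln1_g, dZ1)
    g$ln1_g <- l1$dg; g$ln1_b <- l1$db
    dS1 <- l1$dX
    ab <- attention_bwd(cache$att, params, spec$n_heads, dS1)
    g <- c(g, ab$grads)
    dZ0 <- dZ0 + dS1 + ab$dZ
  } else {
    dZ0 <- dZ0 + dZ3
  }

  if (!is.na(spec$frontend)) {
    fi <- seq_linear_bwd(cache$h_in, params$W_in, dZ0)
    g$W_in <- fi$dW; g$b_in <- fi$db
  }
  g
}

#' Predict PERCLOS for a supervised dataset
#'
#' @param params,spec Model parameters and spec.
#' @param ds A `supervised_dataset` (inputs already standardized).
#' @param batch_size Forward batch size.
#' @return Numeric vector of predictions in (0, 1).
#' @export
nn_predict <- function(params, spec, ds, batch_size = 512L) {
  N <- length(ds$y)
  out <- numeric(N)
  at <- 1L
  while (at <= N) {
    idx <- at:min(at + batch_size - 1L, N)
    out[idx] <- nn_forward(params, spec,
                           ds$X[idx, , , drop = FALSE])$yhat
    at <- at + batch_size
  }
  out
}
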