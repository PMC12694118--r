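#' PERCLOS from eyelid-closure time
#'
#' Fraction of an observation window during which the eyelids cover the
#' pupils: `closure_s / total_s`, stored as a fraction in `[0, 1]`.
#'
#' @param closure_s Eyelid-closure duration(s) in seconds (vectorized).
#' @param total_s Total window length in seconds.
#' @return Numeric vector of fractions in `[0, 1]`.
#' @export
perclos <- function(closure_s, total_s) {
  assert_scalar_num(total_s, "total_s", lower = 0, strict_lower = TRUE)
  if (any(closure_s < 0) || any(closure_s > total_s))
    stopf("closure_s must lie in [0, total_s]")
  closure_s / total_s
}

#' Per-window PERCLOS series of a session
#'
#' @param session A `fatigue_session`.
#' @return Numeric vector of per-window PERCLOS fractions.
#' @export
perclos_series <- function(session) {
  stopifnot(inherits(session, "fatigue_session"))
  perclos(session$eyelid_closure_s, session$window_s)
}

#' Concatenate windowed features with the PERCLOS series
#'
#' Builds the timesteps x (F+1) design matrix with PERCLOS as the last
#' column, the layout used for sliding-window supervision (85 differential
#' entropy columns + PERCLOS gives the 86-column matrix).
#'
#' @param features A `windowed_features` matrix (timesteps x F).
#' @param perclos Numeric vector of per-window PERCLOS values in `[0, 1]`,
#'   same length as `nrow(features)`.
#' @return A numeric matrix with `ncol(features) + 1` columns; the last
#'   column is named `"PERCLOS"`.
#' @export
concatenate_features <- function(features, perclos) {
  if (nrow(features) != length(perclos))
    stopf("timestep mismatch: %d feature rows vs %d PERCLOS values",
          nrow(features), length(perclos))
  if (any(perclos < 0 | perclos > 1))
    stopf("PERCLOS values must lie in [0, 1]")
  D <- cbind(unclass(features), PERCLOS = as.numeric(perclos))
  attr(D, "window_s") <- attr(features, "window_s")
  D
}

#' Sliding-window supervised dataset
#'
#' For each valid start index i, the input is L consecutive rows of `D` and
#' the target is the PERCLOS entry (last column) of the following row:
#' `X[i] = D[i..i+L-1, ]`, `y[i] = D[i+L, F+1]`. Yields `N = timesteps - L`
#' samples.
#'
#' @param D Timesteps x (F+1) matrix from [concatenate_features()] (or any
#'   numeric matrix whose last column is the target series).
#' @param L Window length in timesteps (default 3).
#' @return A `supervised_dataset`: list with `X` (N x L x (F+1) array),
#'   `y` (length-N vector), `L`, and `feature_names`.
#' @export
make_windows <- function(D, L = 3L) {
  D <- as.matrix(D)
  n_t <- nrow(D); p <- ncol(D)
  if (n_t <= L)
    stopf("need more than L = %d timesteps to form any sample (got %d)",
          L, n_t)
  N <- n_t - L
  X <- array(NA_real_, c(N, L, p))
  for (l in seq_len(L)) X[, l, ] <- D[l:(l + N - 1L), ]
  y <- D[(L + 1L):n_t, p]
  structure(list(X = X, y = y, L = as.integer(L),
                 feature_names = colnames(D)),
            class = "supervised_dataset")
}

#' @export
print.supervised_dataset <- function(x, ...) {
  cat(sprintf("<supervised_dataset> N=%d samples, L=%d steps, %d columns\n",
              length(x$y), x$L, dim(x$X)[3]))
  invisible(x)
}

subset_dataset <- function(ds, idx) {
  structure(list(X = ds$X[idx, , , drop = FALSE], y = ds$y[idx],
                 L = ds$L, feature_names = ds$feature_names),
            class = "supervised_dataset")
}

# Pool several supervised datasets (same L and width) into one.
pool_datasets <- function(ds_list) {
  stopifnot(length(ds_list) >= 1)
  X <- do.call(abind_first, lapply(ds_list, `[[`, "X"))
  structure(list(X = X, y = unlist(lapply(ds_list, `[[`, "y")),
                 L = ds_list[[1]]$L,
                 feature_names = ds_list[[1]]$feature_names),
            class = "supervised_dataset")
}

abind_first <- function(...) {
  parts <- list(...)
  d <- dim(parts[[1]])
  out <- array(NA_real_, c(sum(vapply(parts, function(p) dim(p)[1], 0)),
                           d[2], d[3]))
  at <- 0L
  for (p in parts) {
    out[at + seq_len(dim(p)[1]), , ] <- p
    at <- at + dim(p)[1]
  }
  out
}

#' Chronological train/validation/test split
#'
#' Splits samples into contiguous, temporally ordered segments (default
#' 8:1:1) with floor arithmetic; the remainder goes to the test segment.
#' No shuffling, no overlap.
#'
#' @param ds A `supervised_dataset`.
#' @param fractions Length-3 non-negative fractions summing to 1.
#' @return List with `train`, `val`, `test` (`supervised_dataset`s) and
#'   `indices` (the three index ranges).
#' @export
chronological_split <- function(ds, fractions = c(0.8, 0.1, 0.1)) {
  stopifnot(inherits(ds, "supervised_dataset"))
  if (length(fractions) != 3L || any(fractions < 0) ||
      abs(sum(fractions) - 1) > 1e-9)
    stopf("fractions must be three non-negative numbers summing to 1")
  N <- length(ds$y)
  n1 <- floor(fractions[1] * N)
  n2 <- floor((fractions[1] + fractions[2]) * N) - n1
  if (n1 < 1L || n2 < 1L || N - n1 - n2 < 1L)
    stopf("N = %d is too small for non-empty splits", N)
  idx <- list(train = seq_len(n1),
              val = n1 + seq_len(n2),
              test = (n1 + n2 + 1L):N)
  list(train = subset_dataset(ds, idx$train),
       val = subset_dataset(ds, idx$val),
       test = subset_dataset(ds, idx$test),
       indices = idx)
}

#' Fit z-score normalization statistics on a training set
#'
#' Per-feature mean and standard deviation over all samples and timesteps
#' of the training inputs only. Targets are never standardized: the model
#' head is a sigmoid with outputs in (0,1), so PERCLOS targets stay on
#' their natural scale (the past-PERCLOS input column is standardized like
#' any other input).
#'
#' @param train A `supervised_dataset` (training portion only).
#' @param eps Guard for zero-variance columns: their sigma is replaced by
#'   `eps` and recorded in `flagged`.
#' @return A `norm_stats` object: list with `mu`, `sigma`, `flagged`.
#' @export
zscore_fit <- function(train, eps = 1e-8) {
  stopifnot(inherits(train, "supervised_dataset"))
  p <- dim(train$X)[3]
  m <- matrix(train$X, ncol = p)   # (N*L) x p
  mu <- colMeans(m)
  sigma <- sqrt(colMeans(m^2) - mu^2)
  flagged <- sigma <= eps | !is.finite(sigma)
  sigma[flagged] <- eps
  structure(list(mu = mu, sigma = sigma, flagged = flagged,
                 feature_names = train$feature_names),
            class = "norm_stats")
}

#' Apply (or invert) z-score normalization
#'
#' @param ds A `supervised_dataset`.
#' @param stats A `norm_stats` from [zscore_fit()].
#' @param invert If TRUE, undo the transformation.
#' @return The transformed dataset (targets untouched).
#' @export
zscore_apply <- function(ds, stats, invert = FALSE) {
  stopifnot(inherits(ds, "supervised_dataset"), inherits(stats, "norm_stats"))
  p <- dim(ds$X)[3]
  out <- ds
  for (j in seq_len(p)) {
    out$X[, , j] <- if (invert) ds$X[, , j] * stats$sigma[j] + stats$mu[j]
                    else (ds$X[, , j] - stats$mu[j]) / stats$sigma[j]
  }
  out
}

#' Build a subject's concatenated design matrix for a given feature kind
#'
#' Convenience wrapper: extracts the requested windowed EEG features from a
#' session and concatenates the PERCLOS column. `kind = "perclos_only"`
#' yields the univariate design (a single PERCLOS column).
#'
#' @param session A `fatigue_session`.
#' @param kind One of `"de"`, `"abr"`, `"we"`, `"hurst"`, `"perclos_only"`.
#' @param window_s Window length in seconds.
#' @return Timesteps x (F+1) matrix (F = 0 for `perclos_only`).
#' @export
design_matrix <- function(session, kind = "de", window_s = 8) {
  pc <- perclos_series(session)
  if (kind == "perclos_only") {
    D <- cbind(PERCLOS = pc)
    attr(D, "window_s") <- session$window_s
    return(D)
  }
  feats <- extract_features(session, kind, window_s = window_s)
  concatenate_features(feats, pc)
}
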