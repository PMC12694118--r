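# Periodized discrete wavelet transform with the Daubechies-4 (8-tap)
# filter pair.  Periodization keeps the transform orthogonal: coefficient
# energies sum to the signal energy and reconstruction is exact, which the
# band-reconstruction step of the Hurst feature relies on.

# db4 scaling (low-pass) decomposition filter, full precision.
DB4_DEC_LO <- c(-0.010597401785069032, 0.032883011666885197,
                0.030841381835560764, -0.18703481171909309,
                -0.027983769416859854, 0.63088076792985892,
                0.71484657055291567, 0.23037781330889651)
# Quadrature mirror high-pass: g[k] = (-1)^k h[L-1-k]
DB4_DEC_HI <- rev(DB4_DEC_LO) * c(-1, 1, -1, 1, -1, 1, -1, 1) * -1

dwt_step_per <- function(x, f) {
  # circular convolution y[n] = sum_m f[m+1] * x[n-m], then keep odd phase
  n <- length(x)
  L <- length(f)
  idx <- outer(seq_len(n), 0:(L - 1L), function(i, m) ((i - 1L - m) %% n) + 1L)
  y <- as.numeric(matrix(x[idx], n, L) %*% f)
  y[seq(2L, n, by = 2L)]
}

idwt_step_per <- function(a, d) {
  # adjoint (= inverse, by orthogonality) of the analysis step: upsample
  # onto the kept phase, then circular correlation with the same filters
  n2 <- 2L * length(a)
  up <- function(c) { z <- numeric(n2); z[seq(2L, n2, by = 2L)] <- c; z }
  ua <- up(a); ud <- up(d)
  L <- length(DB4_DEC_LO)
  idx <- outer(seq_len(n2), 0:(L - 1L), function(i, m) ((i - 1L + m) %% n2) + 1L)
  as.numeric(matrix(ua[idx], n2, L) %*% DB4_DEC_LO +
             matrix(ud[idx], n2, L) %*% DB4_DEC_HI)
}

#' Multilevel periodized db4 wavelet decomposition
#'
#' Decomposes a single-channel window into `level` detail scales plus the
#' final approximation, using the 8-tap Daubechies-4 filter pair with
#' periodic boundary handling. At a 200 Hz sampling rate the five scales
#' D2..D5 and A5 approximate the canonical EEG bands:
#' D2 gamma (25-50 Hz), D3 beta (12.5-25), D4 alpha (6.25-12.5),
#' D5 theta (3.125-6.25), A5 delta (0-3.125).
#'
#' @param x Numeric vector, length divisible by `2^level` (a 1600-sample
#'   8-s window at 200 Hz satisfies this).
#' @param level Number of decomposition levels (default 5).
#'
#' @return A list with `coefficients` (named list `A<level>`, `D<level>`,
#'   ..., `D1`), per-scale `energies`, and `rel_energies`: relative energies
#'   of the five band-mapped scales (gamma..delta), normalized to sum to 1.
#' @export
wavelet_decomposition <- function(x, level = 5L) {
  if (length(x) < 2^level)
    stopf("window too short for a %d-level decomposition (%d < %d samples)",
          level, length(x), 2^level)
  if (length(x) %% 2^level != 0L)
    stopf("window length (%d) must be divisible by 2^level = %d",
          length(x), 2^level)
  a <- x
  details <- vector("list", level)
  for (j in seq_len(level)) {
    details[[j]] <- dwt_step_per(a, DB4_DEC_HI)
    a <- dwt_step_per(a, DB4_DEC_LO)
  }
  coefs <- c(list(a), rev(details))
  names(coefs) <- c(sprintf("A%d", level), sprintf("D%d", level:1))
  energies <- vapply(coefs, function(c) sum(c^2), numeric(1))
  # five canonical bands from D2..D5 + A-level (D1 carries >50 Hz content);
  # for shallower decompositions fall back to all scales
  if (level >= 5L) {
    band_scales <- c(gamma = "D2", beta = "D3", alpha = "D4",
                     theta = "D5", delta = sprintf("A%d", level))
    eb <- energies[band_scales]
    names(eb) <- names(band_scales)
  } else {
    eb <- energies
  }
  tot <- sum(eb)
  rel <- if (tot > 0) eb / tot else rep(0, length(eb))
  list(coefficients = coefs, energies = energies, rel_energies = rel)
}

# Reconstruct the signal keeping only the named scales' coefficients.
wavelet_band_reconstruct <- function(x, keep, level = 5L) {
  dec <- wavelet_decomposition(x, level)$coefficients
  for (nm in names(dec)) if (!nm %in% keep) dec[[nm]] <- dec[[nm]] * 0
  a <- dec[[sprintf("A%d", level)]]
  for (j in level:1)
    a <- idwt_step_per(a, dec[[sprintf("D%d", j)]])
  a
}
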