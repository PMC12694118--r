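#' Canonical EEG frequency bands
#'
#' The five-band partition used throughout vigilance EEG work:
#' delta 1-4 Hz, theta 4-8 Hz, alpha 8-14 Hz, beta 14-31 Hz,
#' gamma 31-50 Hz. Band membership of a PSD bin is half-open,
#' `low <= f < high`, so adjacent bands never double-count an edge bin.
#'
#' @return data.frame with columns `name`, `low`, `high`.
#' @export
eeg_bands <- function() {
  data.frame(name = c("delta", "theta", "alpha", "beta", "gamma"),
             low  = c(1, 4, 8, 14, 31),
             high = c(4, 8, 14, 31, 50),
             stringsAsFactors = FALSE)
}

band_edges <- function(band) {
  if (is.character(band)) {
    b <- eeg_bands()
    i <- match(band, b$name)
    if (is.na(i)) stopf("unknown band '%s'; use one of %s", band,
                        paste(b$name, collapse = ", "))
    c(b$low[i], b$high[i])
  } else if (is.numeric(band) && length(band) == 2L && band[1] < band[2]) {
    band
  } else stopf("`band` must be a band name or c(low, high)")
}

#' Welch power spectral density of a single window
#'
#' Hann-tapered Welch estimate with `seg_s`-second segments at 50% overlap
#' (defaults: 2-s segments inside an 8-s window). One-sided density in
#' units of microvolt^2 per Hz.
#'
#' @param x Numeric sample vector.
#' @param rate Sampling rate in Hz.
#' @param seg_s Segment length in seconds.
#' @param overlap Fractional overlap between segments.
#'
#' @return List with `freq` (Hz) and `psd`.
#' @export
welch_psd <- function(x, rate, seg_s = 2, overlap = 0.5) {
  n <- length(x)
  if (n < 2L) stopf("window is empty or too short for a PSD")
  nseg <- min(n, round(seg_s * rate))
  step <- max(1L, round(nseg * (1 - overlap)))
  starts <- seq(1L, n - nseg + 1L, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq(0, nseg - 1) / nseg)  # periodic Hann
  scale <- rate * sum(w^2)
  nf <- nseg %/% 2L + 1L
  acc <- numeric(nf)
  for (s in starts) {
    seg <- x[s:(s + nseg - 1L)] * w
    sp <- abs(fft(seg)[seq_len(nf)])^2 / scale
    acc <- acc + sp
  }
  psd <- acc / length(starts)
  # fold two-sided density into one-sided (DC and Nyquist unique)
  dbl <- 2:(nf - if (nseg %% 2L == 0L) 1L else 0L)
  psd[dbl] <- 2 * psd[dbl]
  list(freq = (seq_len(nf) - 1L) * rate / nseg, psd = psd)
}

# Welch PSD of every non-overlapping `wlen`-sample window of a channel at
# once (one mvfft call), returning an nf x n_windows matrix. Same estimator
# as welch_psd(), vectorized across windows.
welch_psd_windows <- function(x, rate, wlen, seg_s = 2, overlap = 0.5) {
  n_win <- length(x) %/% wlen
  nseg <- min(wlen, round(seg_s * rate))
  step <- max(1L, round(nseg * (1 - overlap)))
  starts <- seq(1L, wlen - nseg + 1L, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq(0, nseg - 1) / nseg)
  scale <- rate * sum(w^2)
  nf <- nseg %/% 2L + 1L
  idx <- as.vector(outer(seq_len(nseg) - 1L,
                         as.vector(outer(starts, (seq_len(n_win) - 1L) * wlen, `+`)),
                         `+`))
  segs <- matrix(x[idx], nseg) * w
  sp <- abs(stats::mvfft(segs)[seq_len(nf), , drop = FALSE])^2 / scale
  # average segments within each window
  g <- rep(seq_len(n_win), each = length(starts))
  psd <- t(rowsum(t(sp), g)) / length(starts)
  dbl <- 2:(nf - if (nseg %% 2L == 0L) 1L else 0L)
  psd[dbl, ] <- 2 * psd[dbl, ]
  list(freq = (seq_len(nf) - 1L) * rate / nseg, psd = psd)
}

# Per-window band power for every window of a channel.
band_power_windows <- function(x, rate, wlen, band, seg_s = 2) {
  edges <- band_edges(band)
  p <- welch_psd_windows(x, rate, wlen, seg_s = seg_s)
  sel <- p$freq >= edges[1] & p$freq < edges[2]
  colSums(p$psd[sel, , drop = FALSE])
}

#' Band power of a single-channel window
#'
#' Sum of Welch PSD bins falling in `low <= f < high`, following the
#' discrete band-power convention of STFT-based vigilance pipelines.
#'
#' @param window Numeric sample vector.
#' @param rate Sampling rate in Hz.
#' @param band Band name ("alpha", ...) or numeric `c(low, high)` in Hz.
#' @param seg_s Welch segment length in seconds.
#'
#' @return Non-negative scalar power.
#' @export
band_power <- function(window, rate, band, seg_s = 2) {
  if (length(window) == 0L) stopf("empty window")
  edges <- band_edges(band)
  if (edges[2] > rate / 2)
    stopf("band upper edge %g Hz exceeds Nyquist (%g Hz)", edges[2], rate / 2)
  p <- welch_psd(window, rate, seg_s = seg_s)
  sel <- p$freq >= edges[1] & p$freq < edges[2]
  sum(p$psd[sel])
}

#' Alpha/beta band-power ratio
#'
#' Ratio of 8-14 Hz to 14-31 Hz power; rises with relaxation and fatigue.
#' A vanishing beta power is epsilon-guarded (`eps = 1e-12`) and flagged via
#' the `"degenerate"` attribute.
#'
#' @inheritParams band_power
#' @return Positive scalar, possibly with attribute `degenerate = TRUE`.
#' @export
alpha_beta_ratio <- function(window, rate, seg_s = 2) {
  pa <- band_power(window, rate, "alpha", seg_s)
  pb <- band_power(window, rate, "beta", seg_s)
  eps <- 1e-12
  if (pb <= eps) {
    r <- pa / eps
    attr(r, "degenerate") <- TRUE
    return(r)
  }
  pa / pb
}

# Zero-phase Butterworth-magnitude bandpass applied spectrally: the
# amplitude response equals that of forward-backward (filtfilt) order-m
# Butterworth high-pass + low-pass cascades, with exactly zero phase and
# O(n log n) cost. Used for band isolation inside feature extraction and
# for synthesizing band-limited noise.
fft_bandpass <- function(x, rate, low, high, order = 2L) {
  n <- length(x)
  f <- (0:(n - 1)) * rate / n
  f <- pmin(f, rate - f)  # fold to two-sided symmetric magnitudes
  A <- rep(1, n)
  if (low > 0) {
    r <- ifelse(f == 0, Inf, low / f)
    A <- A / (1 + r^(2 * order))
  }
  if (is.finite(high) && high < rate / 2)
    A <- A / (1 + (f / high)^(2 * order))
  Re(fft(fft(x) * A, inverse = TRUE)) / n
}

# Fraction of unit-variance white noise power passed by fft_bandpass:
# the mean squared amplitude response over frequencies.
band_gain_sq <- function(rate, low, high, order = 2L, n = 4096L) {
  f <- (0:(n - 1)) * rate / n
  f <- pmin(f, rate - f)
  A <- rep(1, n)
  if (low > 0) {
    r <- ifelse(f == 0, Inf, low / f)
    A <- A / (1 + r^(2 * order))
  }
  if (is.finite(high) && high < rate / 2)
    A <- A / (1 + (f / high)^(2 * order))
  mean(A^2)
}

# Band-isolate a signal (zero-phase, order-2 Butterworth magnitude).
band_filter <- function(x, rate, band, order = 2L) {
  edges <- band_edges(band)
  fft_bandpass(x, rate, edges[1], edges[2], order = order)
}

#' Differential entropy of a band-filtered window
#'
#' Continuous (differential) entropy under the Gaussian assumption standard
#' for vigilance EEG: `DE = 0.5 * log(2 * pi * e * sigma2)` in nats, where
#' `sigma2` is the variance of the window after isolating `band` with a
#' zero-phase Butterworth filter. A zero-variance window is epsilon-guarded
#' (`sigma2 = 1e-12`) and flagged with attribute `degenerate`.
#'
#' @inheritParams band_power
#' @return Scalar DE in nats.
#' @export
differential_entropy <- function(window, rate, band) {
  if (length(window) == 0L) stopf("empty window")
  y <- band_filter(window, rate, band)
  s2 <- mean((y - mean(y))^2)
  if (s2 <= 1e-12) {
    de <- 0.5 * log(2 * pi * exp(1) * 1e-12)
    attr(de, "degenerate") <- TRUE
    return(de)
  }
  0.5 * log(2 * pi * exp(1) * s2)
}

shannon_entropy <- function(p) {
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Wavelet entropy of a window
#'
#' Shannon entropy (natural log) of the five relative band energies from a
#' 5-level periodized db4 decomposition (scales D2..D5 and A5, mapped to
#' gamma..delta at a 200 Hz sampling rate). Ranges from 0 (all energy in
#' one band) to `log(5)` (equal energies).
#'
#' @param window Numeric sample vector (length a multiple of 32).
#' @param rate Sampling rate in Hz; the scale-to-band mapping matches the
#'   canonical bands at 200 Hz and is approximate elsewhere.
#'
#' @return Scalar in `[0, log(5)]`; an all-zero window returns 0 with
#'   attribute `degenerate = TRUE`.
#' @export
wavelet_entropy <- function(window, rate = 200) {
  dec <- wavelet_decomposition(window, level = 5L)
  if (sum(dec$rel_energies) == 0) {
    w <- 0
    attr(w, "degenerate") <- TRUE
    return(w)
  }
  shannon_entropy(dec$rel_energies)
}

# Mean rescaled range R/S over non-overlapping segments of size n.
rs_statistic <- function(x, n) {
  k <- length(x) %/% n
  vals <- numeric(0)
  for (i in seq_len(k)) {
    seg <- x[((i - 1) * n + 1):(i * n)]
    s <- sd(seg)
    if (!is.finite(s) || s == 0) next
    z <- cumsum(seg - mean(seg))
    vals <- c(vals, (max(z) - min(z)) / s)
  }
  if (length(vals) == 0) NA_real_ else mean(vals)
}

#' Hurst exponent by rescaled-range analysis
#'
#' Slope of `log(R/S)` against `log(n)` over a dyadic grid of segment sizes
#' (8, 16, ... up to half the series length), estimated by ordinary least
#' squares. Roughly 0.5 for uncorrelated noise and above 0.5 for
#' persistent (long-range dependent) signals. The raw estimate is clipped
#' to `[0, 1]`; when clipping occurred the result carries attribute
#' `clipped = TRUE`. A constant series (S = 0 everywhere) is degenerate and
#' reported as `H = 1` with attribute `degenerate = TRUE`.
#'
#' @param x Numeric series (length >= 64 after any band reconstruction).
#' @param rate Sampling rate in Hz; only needed when `band` is given.
#' @param band Optional band name; if supplied, `x` is first reduced to
#'   that band by keeping the matching scale of a 5-level db4
#'   decomposition and inverting.
#'
#' @return Scalar H in `[0, 1]`.
#' @export
hurst_exponent <- function(x, rate = NULL, band = NULL) {
  if (!is.null(band)) {
    scale_of <- c(gamma = "D2", beta = "D3", alpha = "D4",
                  theta = "D5", delta = "A5")
    sc <- scale_of[[band]]
    if (is.null(sc)) stopf("unknown band '%s'", band)
    x <- wavelet_band_reconstruct(x, sc, level = 5L)
  }
  if (length(x) < 64L)
    stopf("series too short for R/S analysis (%d < 64 points)", length(x))
  if (sd(x) == 0) {
    h <- 1
    attr(h, "degenerate") <- TRUE
    return(h)
  }
  sizes <- 2^(3:floor(log2(length(x) / 2)))
  rs <- vapply(sizes, function(n) rs_statistic(x, n), numeric(1))
  ok <- is.finite(rs) & rs > 0
  h_raw <- unname(lm.fit(cbind(1, log(sizes[ok])), log(rs[ok]))$coefficients[2])
  h <- clip(h_raw, 0, 1)
  if (h != h_raw) attr(h, "clipped") <- TRUE
  h
}

feature_kinds <- function() c("de", "abr", "we", "hurst")

#' Windowed feature extraction over a session
#'
#' Splits each channel of a session's EEG into non-overlapping `window_s`
#' second windows and computes one feature row per window:
#' \describe{
#'   \item{de}{differential entropy per channel and band (channels x 5
#'     columns; 85 for the 17-channel montage)}
#'   \item{abr}{alpha/beta band-power ratio per channel (channels columns)}
#'   \item{we}{wavelet entropy per channel (channels columns)}
#'   \item{hurst}{per-band Hurst exponent of the wavelet-reconstructed band
#'     signals (channels x 5 columns)}
#' }
#' Column names are deterministic: `<channel>_<band>` (or `<channel>` for
#' single-valued kinds), bands ordered delta..gamma within channel.
#'
#' @param session A `fatigue_session` from [generate_session()], or an
#'   [eeg_recording()].
#' @param kind One of `"de"`, `"abr"`, `"we"`, `"hurst"`.
#' @param window_s Window length in seconds (default 8).
#'
#' @return A `windowed_features` object: a timesteps x features matrix with
#'   attributes `window_s` and `kind`.
#' @export
extract_features <- function(session, kind = c("de", "abr", "we", "hurst"),
                             window_s = 8) {
  kind <- match.arg(kind)
  rec <- if (inherits(session, "fatigue_session")) session$eeg else session
  stopifnot(inherits(rec, "eeg_recording"))
  rate <- rec$rate
  wlen <- round(window_s * rate)
  n_win <- ncol(rec$data) %/% wlen
  if (n_win < 1L)
    stopf("session (%.1f s) is shorter than one %g-s window",
          ncol(rec$data) / rate, window_s)
  bands <- eeg_bands()$name
  per_band <- kind %in% c("de", "hurst")
  ch <- rec$channel_labels
  cols <- if (per_band) as.vector(t(outer(ch, bands, paste, sep = "_")))
          else ch
  out <- matrix(NA_real_, n_win, length(cols), dimnames = list(NULL, cols))

  for (c_i in seq_along(ch)) {
    x <- rec$data[c_i, seq_len(n_win * wlen)]
    if (kind == "de") {
      # filter the full channel once per band, then take window variances
      for (b_i in seq_along(bands)) {
        y <- band_filter(x, rate, bands[b_i])
        segs <- matrix(y, wlen, n_win)
        s2 <- pmax(colMeans(segs^2) - colMeans(segs)^2, 0)
        flag <- s2 <= 1e-12
        s2[flag] <- 1e-12
        out[, (c_i - 1L) * 5L + b_i] <- 0.5 * log(2 * pi * exp(1) * s2)
      }
    } else if (kind == "abr") {
      pa <- band_power_windows(x, rate, wlen, "alpha")
      pb <- pmax(band_power_windows(x, rate, wlen, "beta"), 1e-12)
      out[, c_i] <- pa / pb
    } else {
      segs <- matrix(x, wlen, n_win)
      for (k in seq_len(n_win)) {
        w <- segs[, k]
        out[k, if (per_band) ((c_i - 1L) * 5L + 1L):(c_i * 5L) else c_i] <-
          switch(kind,
            we = as.numeric(wavelet_entropy(w, rate)),
            hurst = vapply(bands, function(b)
              as.numeric(hurst_exponent(w, rate, band = b)), numeric(1)))
      }
    }
  }
  structure(out, window_s = window_s, kind = kind,
            class = c("windowed_features", "matrix", "array"))
}

#' @export
print.windowed_features <- function(x, ...) {
  cat(sprintf("<windowed_features> kind=%s, %d timesteps x %d features (%gs windows)\n",
              attr(x, "kind"), nrow(x), ncol(x), attr(x, "window_s")))
  invisible(x)
}
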