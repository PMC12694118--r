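#' Standard 17-channel montage used for vigilance EEG
#'
#' Channel labels of the 17-electrode posterior montage (temporal through
#' occipital sites, referenced to CPZ) used by the SEED-VIG vigilance
#' recordings that this package emulates.
#'
#' @return Character vector of 17 channel labels.
#' @export
seedvig_channels <- function() {
  c("FT7", "FT8", "T7", "T8", "TP7", "TP8", "CP1", "CP2", "P1", "PZ",
    "P2", "PO3", "POZ", "PO4", "O1", "OZ", "O2")
}

#' Construct a multichannel EEG recording
#'
#' @param data Numeric matrix, channels x samples, in microvolts.
#' @param rate Sampling rate in Hz.
#' @param channel_labels Character vector, one label per row of `data`.
#'
#' @return An object of class `eeg_recording`: a list with elements
#'   `data`, `rate` and `channel_labels`.
#' @export
eeg_recording <- function(data, rate,
                          channel_labels = seedvig_channels()[seq_len(nrow(data))]) {
  if (!is.matrix(data) || !is.numeric(data))
    stopf("`data` must be a numeric channels x samples matrix")
  if (!all(is.finite(data)))
    stopf("EEG samples must all be finite")
  assert_scalar_num(rate, "rate", lower = 0, strict_lower = TRUE)
  if (length(channel_labels) != nrow(data))
    stopf("need one channel label per data row (%d != %d)",
          length(channel_labels), nrow(data))
  structure(list(data = data, rate = rate,
                 channel_labels = as.character(channel_labels)),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$data), ncol(x$data), x$rate, ncol(x$data) / x$rate))
  cat("channels:", paste(x$channel_labels, collapse = " "), "\n")
  invisible(x)
}

n_samples <- function(rec) ncol(rec$data)
n_channels <- function(rec) nrow(rec$data)
duration_s <- function(rec) ncol(rec$data) / rec$rate

#' Zero-phase bandpass filter an EEG recording
#'
#' Applies an exactly zero-phase Butterworth-magnitude bandpass (order
#' `order` per edge, squared as in a forward-backward pass) to every
#' channel, realized spectrally so there are no startup transients or time
#' shifts. The preprocessing protocol this mirrors uses a 1-75 Hz passband
#' on the raw recordings.
#'
#' @param rec An [eeg_recording()].
#' @param low,high Band edges in Hz, `0 < low < high < rate/2`.
#' @param order Filter order per edge (default 4).
#'
#' @return A filtered `eeg_recording` with identical shape and labels.
#' @export
bandpass <- function(rec, low = 1, high = 75, order = 4L) {
  stopifnot(inherits(rec, "eeg_recording"))
  assert_scalar_num(low, "low", lower = 0, strict_lower = TRUE)
  assert_scalar_num(high, "high", lower = 0, strict_lower = TRUE)
  if (low >= high) stopf("need low < high (got %g >= %g)", low, high)
  if (high >= rec$rate / 2)
    stopf("`high` (%g Hz) must be below the Nyquist frequency (%g Hz)",
          high, rec$rate / 2)
  out <- rec
  out$data <- t(apply(rec$data, 1L, fft_bandpass,
                      rate = rec$rate, low = low, high = high, order = order))
  out
}

#' Downsample an EEG recording by polyphase rational resampling
#'
#' @param rec An [eeg_recording()], assumed already lowpass-filtered below
#'   `target_rate / 2`.
#' @param target_rate Target sampling rate in Hz (must not exceed the
#'   current rate; no upsampling).
#'
#' @return An `eeg_recording` at `target_rate`.
#' @export
resample_eeg <- function(rec, target_rate) {
  stopifnot(inherits(rec, "eeg_recording"))
  assert_scalar_num(target_rate, "target_rate", lower = 0, strict_lower = TRUE)
  if (target_rate > rec$rate)
    stopf("no upsampling: target_rate (%g) exceeds rate (%g)",
          target_rate, rec$rate)
  if (target_rate == rec$rate) return(rec)
  frac <- rational_ratio(target_rate, rec$rate)
  out <- rec
  out$data <- t(apply(rec$data, 1L, function(ch)
    as.numeric(signal::resample(ch, frac[1L], frac[2L]))))
  out$rate <- target_rate
  out
}

# Reduce p/q = a/b to smallest integers (rates scaled to integers first).
rational_ratio <- function(a, b) {
  scale <- 1e6
  p <- round(a * scale); q <- round(b * scale)
  g <- gcd_int(p, q)
  c(p / g, q / g)
}

gcd_int <- function(a, b) {
  while (b != 0) { t <- b; b <- a %% b; a <- t }
  a
}
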