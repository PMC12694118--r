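#' Subject profile for the synthetic fatigue cohort
#'
#' Describes one simulated driver: baseline alpha/beta band powers, the
#' speed of the latent fatigue drift, broadband sensor noise, and how
#' strongly the EEG band structure is coupled to the latent fatigue
#' process.
#'
#' @param subject_id Small integer identifier.
#' @param baseline_alpha_power Baseline alpha (8-14 Hz) power, microvolt^2.
#' @param baseline_beta_power Baseline beta (14-31 Hz) power, microvolt^2.
#' @param fatigue_drift_rate Drift of the latent fatigue process on the
#'   logit scale, per second. The default traverses alert to drowsy over a
#'   118-minute session.
#' @param noise_sd Standard deviation of additive white sensor noise in
#'   microvolts (0 allowed for noise-free simulations).
#' @param coupling_strength In `[0, 1]`: 0 decouples band powers from
#'   fatigue entirely, 1 is deterministic coupling.
#' @param seed Integer seed; identical profile + seed gives a bit-identical
#'   session.
#'
#' @return A `subject_profile` object.
#' @export
subject_profile <- function(subject_id, baseline_alpha_power = 20,
                            baseline_beta_power = 10,
                            fatigue_drift_rate = 8.5e-4,
                            noise_sd = 2, coupling_strength = 0.8,
                            seed = 1L) {
  assert_scalar_num(baseline_alpha_power, "baseline_alpha_power",
                    lower = 0, strict_lower = TRUE)
  assert_scalar_num(baseline_beta_power, "baseline_beta_power",
                    lower = 0, strict_lower = TRUE)
  assert_scalar_num(noise_sd, "noise_sd", lower = 0)
  assert_scalar_num(coupling_strength, "coupling_strength",
                    lower = 0, upper = 1)
  assert_scalar_num(fatigue_drift_rate, "fatigue_drift_rate")
  structure(list(subject_id = as.integer(subject_id),
                 baseline_alpha_power = baseline_alpha_power,
                 baseline_beta_power = baseline_beta_power,
                 fatigue_drift_rate = fatigue_drift_rate,
                 noise_sd = noise_sd,
                 coupling_strength = coupling_strength,
                 seed = as.integer(seed)),
            class = "subject_profile")
}

#' @export
print.subject_profile <- function(x, ...) {
  cat(sprintf(
    "<subject_profile> id=%d alpha=%.1f beta=%.1f drift=%.2e noise=%.2f coupling=%.2f seed=%d\n",
    x$subject_id, x$baseline_alpha_power, x$baseline_beta_power,
    x$fatigue_drift_rate, x$noise_sd, x$coupling_strength, x$seed))
  invisible(x)
}

# Gaussian noise whose spectrum occupies [low + margin, high - margin]:
# band-limited, noise-like (not sinusoidal), and spectrally disjoint from
# the neighbouring canonical bands.
band_noise <- function(n, rate, low, high, margin_hz = 1) {
  # the guard must exceed the Welch estimator's spectral main-lobe width
  # (2 bins = 1 Hz for 2-s Hann segments) or carriers bleed across bands
  m <- min(margin_hz, 0.3 * (high - low))
  f <- (0:(n - 1)) * rate / n
  f <- pmin(f, rate - f)
  mask <- as.numeric(f >= low + m & f <= high - m)
  Re(fft(fft(rnorm(n)) * mask, inverse = TRUE)) / n
}

# Per-band power targets as a function of latent fatigue F in [0,1].
# Alpha and theta rise with fatigue, beta falls; delta and gamma are flat.
# Multipliers keep every power strictly positive at F = 1.
band_power_targets <- function(profile, F) {
  c_ <- profile$coupling_strength
  a <- profile$baseline_alpha_power
  b <- profile$baseline_beta_power
  list(delta = rep(1.5 * a, length(F)),
       theta = 0.75 * a * (1 + 1.0 * c_ * F),
       alpha = a * (1 + 1.5 * c_ * F),
       beta  = b * (1 - 0.75 * c_ * F),
       gamma = rep(0.3 * b, length(F)))
}

#' Generate one synthetic fatigue-driving session
#'
#' Simulates a latent fatigue process (logistic drift from an alert start
#' plus a bounded Gaussian random walk on the logit scale, mapped to
#' `[0, 1]`), an EEG recording whose per-window band powers track the
#' latent fatigue (alpha and theta rise, beta falls, scaled by the
#' profile's coupling strength), and a per-window eyelid-closure duration
#' `window_s * clip(fatigue + noise, 0, 1)`.
#'
#' Each band is synthesized as Butterworth band-limited Gaussian noise,
#' rescaled within every window to hit that window's target band power
#' exactly, so the coupling is deterministic at `coupling_strength = 1`.
#'
#' @param profile A [subject_profile()].
#' @param duration_s Session length in seconds (default 7080 = 118 min).
#' @param rate Sampling rate in Hz (>= 100 so the gamma band is
#'   representable; default 200).
#' @param window_s Window length in seconds (default 8).
#' @param n_channels Number of EEG channels (default 17).
#' @param closure_noise_sd Noise added to latent fatigue before computing
#'   eyelid closure, on the PERCLOS scale.
#'
#' @return A `fatigue_session`: list with `eeg` ([eeg_recording()]),
#'   `eyelid_closure_s`, `latent_fatigue` (ground truth, for tests),
#'   `window_s` and the generating `profile`.
#' @export
generate_session <- function(profile, duration_s = 7080, rate = 200,
                             window_s = 8, n_channels = 17,
                             closure_noise_sd = 0.05) {
  stopifnot(inherits(profile, "subject_profile"))
  assert_scalar_num(duration_s, "duration_s", lower = 0, strict_lower = TRUE)
  assert_scalar_num(rate, "rate", lower = 100)
  assert_scalar_num(window_s, "window_s", lower = 0, strict_lower = TRUE)
  if (duration_s < window_s)
    stopf("duration_s (%g) must be at least one window (%g s)",
          duration_s, window_s)
  wlen <- round(window_s * rate)
  n_win <- floor(duration_s / window_s)
  n <- n_win * wlen

  set.seed(profile$seed)

  # latent fatigue: logistic drift + bounded random walk on the logit scale
  t_mid <- window_s * (seq_len(n_win) - 0.5)
  rw <- clip(cumsum(rnorm(n_win, 0, 0.05)), -1.5, 1.5)
  logit_f <- -3 + profile$fatigue_drift_rate * t_mid + rw
  latent <- clip(plogis(logit_f), 0, 1)

  closure <- window_s * clip(latent + rnorm(n_win, 0, closure_noise_sd), 0, 1)

  targets <- band_power_targets(profile, latent)
  bands <- eeg_bands()
  labels <- seedvig_channels()
  if (n_channels > length(labels))
    labels <- c(labels, sprintf("CH%02d", seq_len(n_channels - length(labels))))
  labels <- labels[seq_len(n_channels)]

  eeg <- matrix(0, n_channels, n)
  for (ch in seq_len(n_channels)) {
    chan_gain <- exp(rnorm(1, 0, 0.1))  # mild per-channel power variation
    x <- numeric(n)
    for (b in seq_len(nrow(bands))) {
      # spectrally disjoint band-limited noise: a hard spectral mask with a
      # small guard margin inside each canonical band, so neighbouring
      # carriers do not leak into each other's measurement bands
      carrier <- band_noise(n, rate, bands$low[b], bands$high[b])
      # calibrate each window against the same Welch estimator the feature
      # extractor uses, so per-window measured band power hits its target
      u <- band_power_windows(carrier, rate, wlen,
                              c(bands$low[b], bands$high[b]))
      pow <- chan_gain * targets[[bands$name[b]]]
      seg <- matrix(carrier, wlen, n_win)
      seg <- sweep(seg, 2L, sqrt(pow / pmax(u, 1e-300)), `*`)
      x <- x + as.numeric(seg)
    }
    if (profile$noise_sd > 0) x <- x + rnorm(n, 0, profile$noise_sd)
    eeg[ch, ] <- x
  }

  structure(list(eeg = eeg_recording(eeg, rate, labels),
                 eyelid_closure_s = closure,
                 latent_fatigue = latent,
                 window_s = window_s,
                 profile = profile),
            class = "fatigue_session")
}

#' @export
print.fatigue_session <- function(x, ...) {
  cat(sprintf("<fatigue_session> subject %d: %d windows of %g s, %d channels @ %g Hz\n",
              x$profile$subject_id, length(x$eyelid_closure_s), x$window_s,
              nrow(x$eeg$data), x$eeg$rate))
  invisible(x)
}

#' Generate a seeded synthetic cohort
#'
#' Draws per-subject profiles (baseline powers and drift rates log-normally
#' dispersed around the [subject_profile()] defaults, each subject with a
#' sub-seed derived from `base_seed`) and simulates one session per
#' subject.
#'
#' @param n_subjects Number of subjects (>= 1).
#' @param base_seed Integer seed for the whole cohort.
#' @param duration_s Session length in seconds.
#' @param coupling_strength Coupling passed to every profile.
#' @param noise_sd Sensor noise passed to every profile.
#' @param ... Further arguments forwarded to [generate_session()].
#'
#' @return List of `n_subjects` elements, each
#'   `list(profile = <subject_profile>, session = <fatigue_session>)`.
#' @export
generate_cohort <- function(n_subjects = 23, base_seed = 1L,
                            duration_s = 7080, coupling_strength = 0.8,
                            noise_sd = 2, ...) {
  if (!is.numeric(n_subjects) || n_subjects < 1)
    stopf("n_subjects must be >= 1")
  # the latent drift is calibrated so a session traverses alert -> drowsy
  # whatever its length (prolonged simulated driving induces fatigue by
  # design); the per-second rate therefore scales inversely with duration
  drift0 <- 8.5e-4 * 7080 / duration_s
  lapply(seq_len(n_subjects), function(i) {
    set.seed(derive_seed(base_seed, i))
    prof <- subject_profile(
      subject_id = i,
      baseline_alpha_power = 20 * exp(rnorm(1, 0, 0.2)),
      baseline_beta_power = 10 * exp(rnorm(1, 0, 0.2)),
      fatigue_drift_rate = drift0 * exp(rnorm(1, 0, 0.2)),
      noise_sd = noise_sd,
      coupling_strength = coupling_strength,
      seed = derive_seed(base_seed, 1000L + i))
    list(profile = prof,
         session = generate_session(prof, duration_s = duration_s, ...))
  })
}

#' Export a session as delimited text plus manifest
#'
#' Writes `<prefix>_eeg.tsv` (one column per channel, microvolts),
#' `<prefix>_windows.tsv` (window_index, eyelid_closure_s, latent_fatigue)
#' and `<prefix>_manifest.json` (profile, rate, window length).
#'
#' @param session A `fatigue_session`.
#' @param prefix Output path prefix.
#' @return Invisibly, the three file paths.
#' @export
write_session <- function(session, prefix) {
  stopifnot(inherits(session, "fatigue_session"))
  eeg_path <- paste0(prefix, "_eeg.tsv")
  win_path <- paste0(prefix, "_windows.tsv")
  man_path <- paste0(prefix, "_manifest.json")
  eeg <- as.data.frame(t(session$eeg$data))
  names(eeg) <- session$eeg$channel_labels
  utils::write.table(format(eeg, digits = 8, trim = TRUE), eeg_path,
                     sep = "\t", row.names = FALSE, quote = FALSE)
  win <- data.frame(window_index = seq_along(session$eyelid_closure_s),
                    eyelid_closure_s = session$eyelid_closure_s,
                    latent_fatigue = session$latent_fatigue)
  utils::write.table(win, win_path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  jsonlite::write_json(
    list(profile = unclass(session$profile), rate = session$eeg$rate,
         window_s = session$window_s,
         n_windows = length(session$eyelid_closure_s),
         channels = session$eeg$channel_labels),
    man_path, auto_unbox = TRUE, digits = NA)
  invisible(c(eeg = eeg_path, windows = win_path, manifest = man_path))
}

#' Read a session written by [write_session()]
#'
#' @param prefix Path prefix used when writing.
#' @return A `fatigue_session` (with `latent_fatigue` if present).
#' @export
read_session <- function(prefix) {
  man <- jsonlite::read_json(paste0(prefix, "_manifest.json"),
                             simplifyVector = TRUE)
  eeg <- as.matrix(utils::read.table(paste0(prefix, "_eeg.tsv"),
                                     header = TRUE, sep = "\t"))
  win <- utils::read.table(paste0(prefix, "_windows.tsv"), header = TRUE,
                           sep = "\t")
  prof <- do.call(subject_profile, man$profile)
  structure(list(eeg = eeg_recording(t(eeg), man$rate, man$channels),
                 eyelid_closure_s = win$eyelid_closure_s,
                 latent_fatigue = win$latent_fatigue,
                 window_s = man$window_s,
                 profile = prof),
            class = "fatigue_session")
}
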