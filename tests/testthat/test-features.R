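rate <- 200
t8 <- seq(0, 8 - 1 / rate, by = 1 / rate)

test_that("default band edges follow the canonical five-band partition", {
  b <- eeg_bands()
  expect_equal(b$name, c("delta", "theta", "alpha", "beta", "gamma"))
  expect_equal(b$low, c(1, 4, 8, 14, 31))
  expect_equal(b$high, c(4, 8, 14, 31, 50))
})

test_that("band power localizes tones and handles degenerate input", {
  tone <- sin(2 * pi * 10 * t8)
  expect_gt(band_power(tone, rate, "alpha"),
            100 * band_power(tone, rate, "beta"))
  expect_equal(band_power(numeric(1600) , rate, "alpha"), 0)
  expect_error(band_power(numeric(0), rate, "alpha"), "empty")
  expect_error(band_power(tone, rate, c(10, 150)), "Nyquist")
})

test_that("white-noise band power matches the flat-spectrum level", {
  # unit-variance white noise: one-sided PSD level 1/(rate/2); a band sums
  # (bandwidth / bin width) bins of that level
  set.seed(41)
  bp_a <- replicate(100, band_power(rnorm(1600), rate, "alpha"))
  bp_b <- replicate(100, band_power(rnorm(1600), rate, "beta"))
  lev <- 1 / (rate / 2)
  exp_a <- (14 - 8) / 0.5 * lev
  exp_b <- (31 - 14) / 0.5 * lev
  expect_lt(abs(mean(bp_a) / exp_a - 1), 1)   # within a factor of 2
  expect_lt(abs(mean(bp_b) / exp_b - 1), 1)
  expect_lt(abs(mean(bp_a) / exp_a - 1), 0.1) # and in fact much closer
  expect_lt(abs(mean(bp_b) / exp_b - 1), 0.1)
})

test_that("alpha/beta ratio separates tones and is scale invariant", {
  expect_gt(alpha_beta_ratio(sin(2 * pi * 10 * t8), rate), 100)
  expect_lt(alpha_beta_ratio(sin(2 * pi * 20 * t8), rate), 0.01)
  mix <- sin(2 * pi * 10 * t8) + sin(2 * pi * 20 * t8)
  r <- alpha_beta_ratio(mix, rate)
  expect_gt(r, 0.8); expect_lt(r, 1.25)

  set.seed(1)
  w <- rnorm(1600)
  for (c_ in c(1e-3, 1, 250))
    expect_equal(alpha_beta_ratio(c_ * w, rate), alpha_beta_ratio(w, rate),
                 tolerance = 1e-9)
})

test_that("differential entropy satisfies its Gaussian closed form", {
  set.seed(7)
  w <- rnorm(1600)
  de <- differential_entropy(w, rate, "alpha")
  y <- fatiguecast:::band_filter(w, rate, "alpha")
  s2 <- mean((y - mean(y))^2)
  expect_lt(abs(de - 0.5 * log(2 * pi * exp(1) * s2)), 1e-6)
  # closed-form anchor values
  expect_equal(0.5 * log(2 * pi * exp(1)), 1.4189, tolerance = 1e-4)
  # scaling the window by 2 raises DE by ln 2
  expect_equal(differential_entropy(2 * w, rate, "alpha") - de, log(2),
               tolerance = 1e-9)
  # zero-variance guard
  de0 <- differential_entropy(numeric(1600), rate, "alpha")
  expect_true(isTRUE(attr(de0, "degenerate")))
})

test_that("mean DE over seeds tracks the theoretical band variance within 5%", {
  gain <- fatiguecast:::band_gain_sq(rate, 8, 14)
  theory <- 0.5 * log(2 * pi * exp(1) * gain)
  set.seed(13)
  des <- replicate(60, as.numeric(differential_entropy(rnorm(1600), rate,
                                                       "alpha")))
  expect_lt(abs(mean(des) - theory) / abs(theory), 0.05)
})

test_that("wavelet decomposition is orthogonal and invertible", {
  set.seed(3)
  x <- rnorm(1600)
  d <- wavelet_decomposition(x)
  expect_equal(sum(d$energies), sum(x^2), tolerance = 1e-9)
  expect_equal(sum(d$rel_energies), 1, tolerance = 1e-9)
  expect_true(all(d$rel_energies >= 0))
  xr <- fatiguecast:::wavelet_band_reconstruct(
    x, c("A5", paste0("D", 1:5)), 5)
  expect_equal(xr, x, tolerance = 1e-10)
  expect_error(wavelet_decomposition(rnorm(16)), "too short")
  expect_error(wavelet_decomposition(rnorm(100)), "divisible")
})

test_that("db4 scale energies of a 10 Hz tone match the reference decomposition", {
  # frozen from an independent PyWavelets periodized db4 decomposition of
  # sin(2*pi*10*t), 1600 samples at 200 Hz
  x <- sin(2 * pi * 10 * t8)
  e <- wavelet_decomposition(x)$energies
  expect_equal(unname(e["D4"]), 643.046377084394, tolerance = 1e-8)
  expect_equal(unname(e["D3"]), 153.62915443552072, tolerance = 1e-8)
  expect_equal(unname(e["A5"]), 1.1944140233850262, tolerance = 1e-8)
})

test_that("wavelet entropy spans [0, ln 5] with the right extremes", {
  # equal energies are the exact maximum-entropy case
  expect_equal(fatiguecast:::shannon_entropy(rep(0.2, 5)), log(5))
  expect_equal(fatiguecast:::shannon_entropy(c(1, 0, 0, 0, 0)), 0)

  # a pure 10 Hz tone concentrates in the alpha scale (derived value
  # 0.5189; db4 leaks ~20% of the tone into the neighbouring scale)
  we_tone <- wavelet_entropy(sin(2 * pi * 10 * t8))
  expect_equal(as.numeric(we_tone), 0.5189, tolerance = 1e-3)
  expect_lt(we_tone, 0.4 * log(5))

  # white noise: theoretical WE is 1.2997 (band widths are dyadic, so
  # p = (0.5, 0.25, 0.125, 0.0625, 0.0625)), inside 20% of ln 5
  set.seed(17)
  wes <- replicate(100, as.numeric(wavelet_entropy(rnorm(1600))))
  p_theory <- c(0.5, 0.25, 0.125, 0.0625, 0.0625)
  expect_lt(abs(mean(wes) - log(5)) / log(5), 0.2)
  expect_lt(abs(mean(wes) - fatiguecast:::shannon_entropy(p_theory)), 0.03)
  expect_true(all(wes >= 0 & wes <= log(5) + 1e-12))

  z <- wavelet_entropy(numeric(1600))
  expect_equal(as.numeric(z), 0)
  expect_true(isTRUE(attr(z, "degenerate")))
})

test_that("Hurst estimates recover known long-range dependence", {
  set.seed(42)
  h_wn <- replicate(50, hurst_exponent(rnorm(4096)))
  expect_lt(abs(mean(h_wn) - 0.5), 0.1)

  set.seed(43)
  h_08 <- replicate(50, hurst_exponent(fgn(4096, 0.8)))
  expect_lt(abs(mean(h_08) - 0.8), 0.1)

  expect_error(hurst_exponent(rnorm(32)), "too short")
  hc <- hurst_exponent(rep(2, 128))
  expect_equal(as.numeric(hc), 1)
  expect_true(isTRUE(attr(hc, "degenerate")))
})

test_that("Hurst output is always clipped to [0, 1]", {
  set.seed(9)
  for (i in 1:20) {
    x <- switch(1 + i %% 4,
                rnorm(128), cumsum(rnorm(256)),
                sin(2 * pi * 10 * t8), rnorm(1600) + 100)
    h <- hurst_exponent(x)
    expect_gte(as.numeric(h), 0)
    expect_lte(as.numeric(h), 1)
  }
})

test_that("feature extraction yields the documented shapes and is deterministic", {
  prof <- subject_profile(2, seed = 55)
  s <- generate_session(prof, duration_s = 40, n_channels = 4)
  de <- extract_features(s, "de")
  expect_equal(dim(de), c(5, 20))            # 5 windows x (4 channels x 5)
  expect_equal(colnames(de)[1:5],
               paste0(s$eeg$channel_labels[1], "_",
                      c("delta", "theta", "alpha", "beta", "gamma")))
  abr <- extract_features(s, "abr")
  expect_equal(dim(abr), c(5, 4))
  we <- extract_features(s, "we")
  expect_equal(dim(we), c(5, 4))
  hu <- extract_features(s, "hurst")
  expect_equal(dim(hu), c(5, 20))
  expect_true(all(hu >= 0 & hu <= 1))

  # single-window boundary: an 8-s session gives exactly one row
  s1 <- generate_session(prof, duration_s = 8, n_channels = 2)
  expect_equal(nrow(extract_features(s1, "de")), 1)

  expect_identical(extract_features(s, "de"), de)  # bit-identical rerun
  expect_error(extract_features(
    generate_session(prof, duration_s = 8, n_channels = 2), "de",
    window_s = 16), "shorter than one")
})
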