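# Shared fixtures, built once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- force(expr)
  .fixtures[[key]]
}

# Strongly coupled 3-subject cohort: the study conditions for the
# direction checks (coupling 1, low sensor noise, 60 windows/subject).
coupled_cohort <- function() {
  cached("coupled_cohort",
         generate_cohort(3, base_seed = 11, duration_s = 480,
                         coupling_strength = 1, noise_sd = 0.5))
}

coupled_designs <- function(kind) {
  cached(paste0("designs_", kind),
         lapply(coupled_cohort(),
                function(s) design_matrix(s$session, kind)))
}

# Noise-free, fully coupled single subject whose latent fatigue traverses
# the whole range within a short session.
deterministic_session <- function() {
  cached("det_session", {
    prof <- subject_profile(1, fatigue_drift_rate = 8.5e-4 * 7080 / 480,
                            coupling_strength = 1, noise_sd = 0, seed = 7)
    generate_session(prof, duration_s = 480)
  })
}

# Fractional Gaussian noise by Davies-Harte circulant embedding: the
# independent oracle for Hurst-exponent recovery.
fgn <- function(n, H) {
  k <- 0:(n - 1)
  r <- 0.5 * (abs(k + 1)^(2 * H) - 2 * abs(k)^(2 * H) + abs(k - 1)^(2 * H))
  circ <- c(r, 0, rev(r[-1]))
  lam <- pmax(Re(fft(circ)), 0)
  m <- length(circ)
  z <- complex(real = rnorm(m), imaginary = rnorm(m))
  Re(fft(sqrt(lam / (2 * m)) * z))[1:n]
}

# Tiny random supervised dataset for optimizer tests.
random_dataset <- function(n = 32, L = 3, d = 10, seed = 5) {
  set.seed(seed)
  structure(list(X = array(rnorm(n * L * d), c(n, L, d)), y = runif(n),
                 L = L, feature_names = NULL),
            class = "supervised_dataset")
}
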