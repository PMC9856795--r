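# Shared fixtures. Expensive synthetic cohorts are generated once per test
# run and cached, so module tests and the acceptance checks reuse them.

.fixture_cache <- new.env(parent = emptyenv())

cached_fixture <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# Strong-signal cohort at the recovery-study size: full asymmetry effect.
strong_study_42 <- function() {
  cached_fixture("strong42",
    synth_study(synth_params(n_patients = 42, effect_delta = 1, seed = 101),
                ids = 1, band_hjorth = FALSE))
}

# Balanced medium cohort for calibration studies.
balanced_study_14 <- function(delta = 0, seed = 301) {
  cached_fixture(paste0("bal14_", delta, "_", seed),
    synth_study(synth_params(n_patients = 14, sf_fraction = 0.5,
                             effect_delta = delta, seed = seed),
                ids = 1, band_hjorth = FALSE))
}

# One small synthetic patient with both segments, full montage.
small_recording <- function(seed = 5) {
  cached_fixture(paste0("rec_", seed), {
    gen <- generate_cohort(synth_params(n_patients = 2, seed = seed))
    gen$recordings[[1]]
  })
}

# A sinusoid sampled at fs.
sinusoid <- function(freq_hz, n = 1280, fs = 256, amplitude = 1, phase = 0) {
  amplitude * sin(2 * pi * freq_hz * (0:(n - 1)) / fs + phase)
}

# Independent spectral oracle: direct DFT-bin summation (no fft), same
# symmetric Hann taper and one-sided scaling as the estimator under test.
naive_band_power <- function(x, fs, lo, hi) {
  n <- length(x)
  w <- 0.5 * (1 - cos(2 * pi * (0:(n - 1)) / (n - 1)))
  xw <- x * w
  ks <- 0:(n %/% 2)
  f <- ks * fs / n
  X <- vapply(ks, function(k)
    sum(xw * exp(-2i * pi * k * (0:(n - 1)) / n)), complex(1))
  p <- Mod(X)^2 / (fs * sum(w^2))
  sc <- rep(2, length(ks))
  sc[1] <- 1
  if (n %% 2 == 0) sc[length(ks)] <- 1
  sel <- f >= lo & f < hi
  sum(p[sel] * sc[sel]) * fs / n
}
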