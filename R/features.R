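# Per-window EEG features: six band-power PSD features (delta, theta, alpha,
# beta, gamma, total) and the three Hjorth parameters (activity, mobility,
# complexity). Nine features x 16 lateral electrodes = 144 values per window.

#' Canonical frequency bands
#'
#' Clinical EEG bands tiling the 0.5-45 Hz acquisition band without overlap:
#' delta 0.5-4, theta 4-8, alpha 8-13, beta 13-30, gamma 30-45, plus the
#' total band 0.5-45 Hz. Band membership of a spectral bin is half-open,
#' `lo <= f < hi`, so the five narrow-band powers sum exactly to the
#' total-band power of the same spectral estimate.
#'
#' @param include_total include the `total` row.
#' @return data.frame with columns `name`, `lo_hz`, `hi_hz`.
#' @export
eeg_bands <- function(include_total = TRUE) {
  b <- data.frame(
    name  = c("delta", "theta", "alpha", "beta", "gamma", "total"),
    lo_hz = c(0.5, 4, 8, 13, 30, 0.5),
    hi_hz = c(4, 8, 13, 30, 45, 45),
    stringsAsFactors = FALSE)
  if (include_total) b else b[b$name != "total", ]
}

#' Canonical per-electrode feature names
#'
#' The nine features of the core set, in canonical order: the six band
#' powers, then Hjorth activity, mobility, complexity.
#'
#' @return character vector of length 9.
#' @export
feature_names <- function() {
  c(paste0("psd_", eeg_bands()$name), "activity", "mobility", "complexity")
}

#' Band powers from a modified periodogram
#'
#' One-sided PSD estimate of a single 5-s window via a Hann-tapered modified
#' periodogram (frequency resolution fs/n, 0.2 Hz for 1280 samples at
#' 256 Hz), integrated over each band with half-open `[lo, hi)` bin
#' assignment. Units: signal-units squared (microvolt^2 for EEG).
#'
#' @param x numeric sample vector (one channel, one window).
#' @param fs sampling frequency, Hz.
#' @param bands data.frame as from [eeg_bands()].
#' @return named numeric vector of band powers.
#' @export
psd_band_powers <- function(x, fs, bands = eeg_bands()) {
  n <- length(x)
  stopifnot(n >= 2)
  if (any(bands$hi_hz > fs / 2))
    stop("band edge beyond the Nyquist frequency ", fs / 2, " Hz")
  # symmetric Hann: reversal-symmetric, so features are invariant under
  # time reversal of the window
  w <- 0.5 * (1 - cos(2 * pi * (0:(n - 1)) / (n - 1)))
  X <- stats::fft(x * w)
  nk <- n %/% 2 + 1
  psd <- Mod(X[seq_len(nk)])^2 / (fs * sum(w^2))
  scale2 <- rep(2, nk)
  scale2[1] <- 1
  if (n %% 2 == 0) scale2[nk] <- 1
  psd <- psd * scale2
  f <- (seq_len(nk) - 1) * fs / n
  df <- fs / n
  out <- vapply(seq_len(nrow(bands)), function(i) {
    sum(psd[f >= bands$lo_hz[i] & f < bands$hi_hz[i]]) * df
  }, 0)
  names(out) <- bands$name
  out
}

#' Hjorth parameters
#'
#' Time-domain descriptors of one window:
#' * activity — population variance of the signal (microvolt^2);
#' * mobility — `sqrt(var(diff(x)) / var(x))`, the RMS of the normalized
#'   first difference (dimensionless, per-sample convention: no sampling
#'   interval scaling);
#' * complexity — mobility of the first difference divided by mobility of
#'   the signal (dimensionless, 1 for a pure sinusoid).
#'
#' Degenerate inputs (zero variance, zero mobility) return 0 by convention
#' with a warning rather than propagating NaN.
#'
#' @param x numeric sample vector.
#' @return scalar.
#' @export
hjorth_activity <- function(x) {
  stopifnot(length(x) >= 2)
  m <- mean(x)
  mean((x - m)^2)
}

#' @rdname hjorth_activity
#' @export
hjorth_mobility <- function(x) {
  a <- hjorth_activity(x)
  if (a == 0) {
    warning("zero-variance window: mobility set to 0 by convention")
    return(0)
  }
  sqrt(hjorth_activity(diff(x)) / a)
}

#' @rdname hjorth_activity
#' @export
hjorth_complexity <- function(x) {
  m <- hjorth_mobility(x)
  if (m == 0) {
    warning("zero-mobility window: complexity set to 0 by convention")
    return(0)
  }
  hjorth_mobility(diff(x)) / m
}

# All three Hjorth parameters without double-computing; silent 0 convention
# for degenerate windows (the extractor warns once per window set).
hjorth_all <- function(x) {
  a <- hjorth_activity(x)
  if (a == 0) return(c(activity = 0, mobility = 0, complexity = 0))
  d1 <- diff(x)
  a1 <- hjorth_activity(d1)
  mob <- sqrt(a1 / a)
  if (a1 == 0) return(c(activity = a, mobility = 0, complexity = 0))
  mob1 <- sqrt(hjorth_activity(diff(d1)) / a1)
  c(activity = a, mobility = mob, complexity = mob1 / mob)
}

#' Extract the nine features for every channel of a window
#'
#' @param window channels x samples numeric matrix (the 16 lateral
#'   electrodes for the study pipeline).
#' @param fs sampling frequency, Hz.
#' @param bands data.frame as from [eeg_bands()].
#' @return channels x 9 numeric matrix; columns in [feature_names()] order.
#' @export
extract_window_features <- function(window, fs, bands = eeg_bands()) {
  stopifnot(is.matrix(window))
  out <- t(apply(window, 1, function(x)
    c(psd_band_powers(x, fs, bands), hjorth_all(x))))
  colnames(out) <- feature_names()
  rownames(out) <- rownames(window)
  out
}
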