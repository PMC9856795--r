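# Band-pass filtering (Butterworth) and segmentation into 5-s windows.
# The whole recording is filtered before segment extraction so that window
# edges are interior samples of the filtered signal.

#' Band-pass filter specification
#'
#' @param low_hz,high_hz passband corner frequencies in Hz. Defaults are the
#'   study's acquisition band, 0.5-45 Hz.
#' @param order Butterworth prototype order (4). In `zero_phase` mode the
#'   forward-backward pass squares the magnitude response, i.e. doubles the
#'   effective magnitude order.
#' @param mode `"zero_phase"` (default; forward-backward, no phase
#'   distortion) or `"single_pass"`.
#' @return list of class `filter_spec`.
#' @export
filter_spec <- function(low_hz = 0.5, high_hz = 45, order = 4,
                        mode = c("zero_phase", "single_pass")) {
  mode <- match.arg(mode)
  stopifnot(low_hz > 0, high_hz > low_hz)
  structure(list(low_hz = low_hz, high_hz = high_hz, order = order,
                 family = "butterworth", mode = mode),
            class = "filter_spec")
}

# Digital Butterworth band-pass as second-order sections (stable at the
# 0.5 Hz corner / 256 Hz regime where the order-2N transfer-function form is
# badly conditioned). Analog prototype poles -> band-pass transform ->
# bilinear transform with prewarped corners; each conjugate pole pair forms
# one biquad with zeros at z = +1 and z = -1; gain normalized to unity at
# the geometric center frequency. Errors if fs can't support the band or
# the discretized design is unstable.
design_bandpass <- function(spec, fs) {
  if (fs / 2 <= spec$high_hz)
    stop("Nyquist frequency ", fs / 2, " Hz does not exceed the upper corner ",
         spec$high_hz, " Hz")
  n <- spec$order
  W1 <- 2 * fs * tan(pi * spec$low_hz / fs)   # prewarped analog corners
  W2 <- 2 * fs * tan(pi * spec$high_hz / fs)
  w0 <- sqrt(W1 * W2)
  B <- W2 - W1
  k <- seq_len(n)
  proto <- exp(1i * pi * (2 * k + n - 1) / (2 * n))  # left-half-plane circle
  half <- B * proto / 2
  s_poles <- c(half + sqrt(half^2 - w0^2), half - sqrt(half^2 - w0^2))
  z_poles <- (2 * fs + s_poles) / (2 * fs - s_poles)
  if (any(Mod(z_poles) >= 1))
    stop("unstable Butterworth design at fs = ", fs,
         " Hz (pole radius ", format(max(Mod(z_poles))), ")")
  up <- z_poles[Im(z_poles) > 0]
  up <- up[order(Mod(up))]            # least selective sections first
  if (length(up) != n)
    stop("degenerate Butterworth design: poles are not conjugate pairs")
  sos <- lapply(up, function(p)
    list(b = c(1, 0, -1), a = c(1, -2 * Re(p), Mod(p)^2)))
  obj <- structure(list(sos = sos, gain = 1, fs = fs, spec = spec),
                   class = "bandpass_sos")
  wc <- 2 * pi * sqrt(spec$low_hz * spec$high_hz) / fs
  obj$gain <- 1 / Mod(sos_response(obj, wc))
  obj
}

# Complex response of the section cascade at normalized angular frequency w.
sos_response <- function(filt, w) {
  z1 <- exp(-1i * w)
  H <- rep(filt$gain + 0i, length(w))
  for (s in filt$sos)
    H <- H * (s$b[1] + s$b[2] * z1 + s$b[3] * z1^2) /
      (s$a[1] + s$a[2] * z1 + s$a[3] * z1^2)
  H
}

# Complex frequency response H(f) of the designed filter, accounting for the
# squared magnitude of zero-phase mode. Used as the analytic oracle for
# attenuation checks.
#' Magnitude response of a band-pass specification
#'
#' @param spec a [filter_spec()].
#' @param fs sampling frequency, Hz.
#' @param freqs_hz frequencies at which to evaluate, Hz.
#' @return numeric vector of magnitude gains.
#' @export
filter_gain <- function(spec, fs, freqs_hz) {
  filt <- design_bandpass(spec, fs)
  g <- Mod(sos_response(filt, 2 * pi * freqs_hz / fs))
  if (spec$mode == "zero_phase") g^2 else g
}

#' Band-pass filter a signal or recording
#'
#' Filters each channel independently with a Butterworth band-pass
#' ([filter_spec()]), zero-phase (forward-backward) by default.
#'
#' @param x numeric vector, channels x samples matrix, or `eeg_recording`.
#' @param spec a [filter_spec()].
#' @param fs sampling frequency in Hz (taken from the recording when `x` is
#'   one).
#' @return filtered object of the same shape/class.
#' @export
bandpass <- function(x, spec = filter_spec(), fs = NULL) {
  UseMethod("bandpass")
}

#' @export
bandpass.numeric <- function(x, spec = filter_spec(), fs = NULL) {
  stopifnot(!is.null(fs))
  drop(bandpass(matrix(x, nrow = 1), spec, fs = fs))
}

#' @export
bandpass.matrix <- function(x, spec = filter_spec(), fs = NULL) {
  stopifnot(!is.null(fs))
  filt <- design_bandpass(spec, fs)  # design once, apply to all channels
  filt_channels(filt, x, zero_phase = spec$mode == "zero_phase")
}

# Apply the section cascade to every row of X. Each biquad runs through
# stats::filter on the whole multivariate series (C level), so all channels
# are processed per call. Zero-phase mode filters forward and backward over
# an odd-reflection padded extension (pad long enough for the slowest pole
# transient to die off), matching textbook filtfilt in the signal interior.
filt_channels <- function(filt, X, zero_phase = TRUE) {
  one_pass <- function(M) {           # columns = time, rows = channels
    Mt <- t(M) * filt$gain
    for (s in filt$sos) {
      # 3-tap MA with leading zeros so no NAs enter the recursion
      Z <- rbind(matrix(0, 2, ncol(Mt)), Mt)
      v <- stats::filter(Z, s$b, method = "convolution", sides = 1)
      v <- v[3:nrow(Z), , drop = FALSE]
      v <- stats::filter(v, -s$a[-1], method = "recursive")
      Mt <- matrix(as.numeric(v), nrow(Mt), ncol(Mt))
    }
    t(Mt)
  }
  if (!zero_phase) return(one_pass(X))
  n <- ncol(X)
  pad <- min(n - 1L, 1024L)
  left  <- 2 * X[, 1] - X[, pad + 1 - seq_len(pad) + 1, drop = FALSE]
  right <- 2 * X[, n] - X[, n - seq_len(pad), drop = FALSE]
  Xe <- cbind(left, X, right)
  y <- one_pass(Xe)
  y <- y[, rev(seq_len(ncol(y))), drop = FALSE]
  y <- one_pass(y)
  y <- y[, rev(seq_len(ncol(y))), drop = FALSE]
  out <- y[, pad + seq_len(n), drop = FALSE]
  dimnames(out) <- dimnames(X)
  out
}

#' @export
bandpass.eeg_recording <- function(x, spec = filter_spec(), fs = NULL) {
  x$data <- bandpass(x$data, spec, fs = x$fs)
  x
}

#' Cut an annotated segment into non-overlapping windows
#'
#' Splits a segment into contiguous, non-overlapping, full-length windows
#' (default 5 s, the study's analysis unit); a trailing partial window is
#' dropped. A 60-s segment yields 12 windows.
#'
#' @param recording an `eeg_recording` (already filtered, normally).
#' @param segment a [segment_annotation()]; by default each annotated segment
#'   of the recording is used via [extract_all_windows()].
#' @param window_len_s window length in seconds.
#' @return object of class `window_set`: list with `patient_id`, `state`,
#'   `fs`, `channels`, `window_len_s` and `windows` (list of channels x
#'   samples matrices).
#' @export
extract_windows <- function(recording, segment, window_len_s = 5) {
  fs <- recording$fs
  wlen <- window_len_s * fs
  if (wlen != round(wlen))
    stop("window length times sampling rate must be an integer sample count")
  wlen <- as.integer(round(wlen))
  seg_n <- as.integer(round(segment$duration * fs))
  if (seg_n < wlen)
    stop("segment (", segment$duration, " s) shorter than one window (",
         window_len_s, " s)")
  start <- as.integer(round(segment$start * fs))
  if (start + seg_n > ncol(recording$data))
    stop("segment extends beyond the recording")
  n_win <- seg_n %/% wlen
  windows <- lapply(seq_len(n_win) - 1L, function(k) {
    idx <- start + k * wlen + seq_len(wlen)
    recording$data[, idx, drop = FALSE]
  })
  structure(list(patient_id = recording$patient_id, state = segment$state,
                 fs = fs, channels = recording$channels,
                 window_len_s = window_len_s, windows = windows),
            class = "window_set")
}

#' @rdname extract_windows
#' @export
extract_all_windows <- function(recording, window_len_s = 5) {
  lapply(recording$segments, function(seg)
    extract_windows(recording, seg, window_len_s))
}
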