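# Synthetic EEG cohort generator. Emulates the statistical structure the
# analysis assumes: band-limited oscillatory scalp EEG on the 10-20 montage
# (state-dependent spectral profiles: posterior-dominant alpha in wake,
# delta/theta-dominant sleep), 1/f-shaped background noise, a lateralized
# spectral perturbation on the pathological hemisphere (focal slowing +
# alpha suppression), and a binary SF/NSF outcome whose separability is
# governed by an interhemispheric-asymmetry effect size: NSF patients
# express a *reduced* asymmetry (the pathological rhythm couples to the
# contralateral hemisphere, i.e. higher interhemispheric connectivity),
# encoding the working hypothesis that preserved interhemispheric coupling
# predicts seizure recurrence. A modeling choice, not a finding.

#' Parameters of the synthetic EEG cohort
#'
#' Defaults encode the study conditions: 21 patients with a 15/6 SF/NSF
#' split, 256 Hz, one 60-s wake and one 60-s sleep segment each.
#'
#' @param n_patients cohort size.
#' @param sf_fraction fraction of seizure-free patients (class counts by
#'   largest-remainder rounding).
#' @param fs sampling frequency, Hz.
#' @param segment_len_s length of each state segment, seconds.
#' @param effect_delta interhemispheric-asymmetry effect size in `[0, 1]`:
#'   SF patients express the full pathology asymmetry; NSF patients'
#'   asymmetry factors are shrunk toward 1 by `delta`
#'   (`f_NSF = 1 + (f - 1)(1 - delta)`). 0 makes the classes statistically
#'   identical; 1 makes NSF hemispherically symmetric. Default 0.5: partially
#'   overlapping classes, the regime a moderately accurate classifier
#'   implies.
#' @param noise_sd RMS amplitude (microvolt) of the 1/f^0.7-shaped
#'   background noise.
#' @param osc_per_band random-phase sinusoids per band.
#' @param amp_jitter_sdlog per-patient/state/band lognormal amplitude
#'   jitter (sdlog).
#' @param chan_jitter_sdlog per-channel lognormal amplitude jitter (sdlog).
#' @param state_profiles per-state band RMS amplitudes (microvolt).
#' @param pathology per-band multiplicative amplitude factors applied to
#'   pathological-hemisphere channels (slowing: delta/theta up; alpha
#'   suppressed).
#' @param seed cohort RNG seed.
#' @return list of class `synth_params`.
#' @export
synth_params <- function(n_patients = 21, sf_fraction = 15 / 21, fs = 256,
                         segment_len_s = 60, effect_delta = 0.5,
                         noise_sd = 2, osc_per_band = 5,
                         amp_jitter_sdlog = 0.2, chan_jitter_sdlog = 0.1,
                         state_profiles = list(
                           wake  = c(delta = 3, theta = 3, alpha = 6,
                                     beta = 2, gamma = 0.8),
                           sleep = c(delta = 8, theta = 5, alpha = 2,
                                     beta = 1.5, gamma = 0.6)),
                         pathology = c(delta = 1.5, theta = 1.3,
                                       alpha = 0.6, beta = 0.8, gamma = 1.0),
                         seed = 1) {
  stopifnot(sf_fraction >= 0, sf_fraction <= 1, effect_delta >= 0,
            effect_delta <= 1, n_patients >= 2)
  structure(as.list(environment()), class = "synth_params")
}

# Posterior-dominant alpha topography in wakefulness.
.alpha_topography <- c(
  Fp1 = 0.6, Fp2 = 0.6, F3 = 0.6, F4 = 0.6, F7 = 0.6, F8 = 0.6,
  C3 = 1.0, C4 = 1.0, T3 = 1.0, T4 = 1.0, Fz = 1.0, Cz = 1.0,
  T5 = 1.6, T6 = 1.6, P3 = 1.6, P4 = 1.6, O1 = 1.6, O2 = 1.6, Pz = 1.3)

# White noise shaped to a 1/f^exponent power spectrum, RMS = sd.
colored_noise <- function(n, sd, exponent = 0.7) {
  if (sd == 0) return(numeric(n))
  X <- stats::fft(stats::rnorm(n))
  k <- c(1, seq_len(n - 1))             # DC treated like the first bin
  shape <- k^(-exponent / 2)
  x <- Re(stats::fft(X * shape, inverse = TRUE)) / n
  sd * x / sqrt(mean(x^2))
}

# Sum of random-phase sinusoid banks with the given per-band RMS amplitudes.
# Oscillator frequencies are drawn 0.5 Hz inside the band edges so their
# spectral mass stays within the nominal band (no edge leakage) and inside
# the flat passband of the acquisition filter.
synth_oscillations <- function(n, fs, band_rms, osc_per_band) {
  bands <- eeg_bands(include_total = FALSE)
  t <- (seq_len(n) - 1) / fs
  x <- numeric(n)
  for (i in seq_len(nrow(bands))) {
    rms <- band_rms[[bands$name[i]]]
    if (is.null(rms) || rms == 0) next
    margin <- min(0.5, (bands$hi_hz[i] - bands$lo_hz[i]) / 4)
    f <- stats::runif(osc_per_band, bands$lo_hz[i] + margin,
                      bands$hi_hz[i] - margin)
    phi <- stats::runif(osc_per_band, 0, 2 * pi)
    A <- rms * sqrt(2 / osc_per_band)
    for (k in seq_len(osc_per_band))
      x <- x + A * sin(2 * pi * f[k] * t + phi[k])
  }
  x
}

#' Generate one channel of one state segment
#'
#' Band-limited oscillations with the state's spectral profile (posterior
#' alpha emphasis in wake) plus 1/f-shaped noise; pathological-hemisphere
#' channels have their band amplitudes scaled by the pathology factors.
#' Uses the current RNG state; set a seed for reproducibility.
#'
#' @param state `"wake"` or `"sleep"`.
#' @param electrode 10-20 label.
#' @param params [synth_params()].
#' @param pathological does this channel lie on the pathological hemisphere?
#' @param asym_factors per-band asymmetry factors to use for a pathological
#'   channel (defaults to `params$pathology`; the cohort generator passes
#'   the class- and patient-specific realization).
#' @return numeric vector of `segment_len_s * fs` samples (microvolt).
#' @export
generate_channel <- function(state, electrode, params,
                             pathological = FALSE,
                             asym_factors = params$pathology) {
  state <- match.arg(state, c("wake", "sleep"))
  n <- as.integer(round(params$segment_len_s * params$fs))
  amps <- params$state_profiles[[state]]
  if (!length(amps))
    return(colored_noise(n, params$noise_sd))
  if (state == "wake")
    amps["alpha"] <- amps["alpha"] * .alpha_topography[[electrode]]
  if (pathological)
    amps <- amps * asym_factors[names(amps)]
  synth_oscillations(n, params$fs, as.list(amps), params$osc_per_band) +
    colored_noise(n, params$noise_sd)
}

#' Generate a synthetic cohort of annotated recordings
#'
#' Produces `n_patients` two-segment (wake + sleep) 19-channel recordings
#' with ground truth. Class counts follow `sf_fraction` by largest-remainder
#' rounding; the pathological side is assigned uniformly at random. Per
#' patient, band amplitudes receive lognormal jitter (per state x band, and
#' per channel), and NSF patients' asymmetry factors are shrunk toward
#' symmetry by `effect_delta`.
#'
#' @param params a [synth_params()].
#' @param out_dir if non-`NULL`, write per-patient EDF + JSON sidecars, a
#'   `cohort.csv` and a `ground_truth.json` there.
#' @return list with `recordings` (list of `eeg_recording`), `cohort`
#'   (data.frame in the cohort-table schema, with `label`), and
#'   `ground_truth` (data.frame: patient, label, side, realized per-band
#'   asymmetry factors).
#' @export
generate_cohort <- function(params = synth_params(), out_dir = NULL) {
  set.seed(params$seed)
  n <- params$n_patients
  n_sf <- apportion(n, c(params$sf_fraction, 1 - params$sf_fraction))[1]
  labels <- sample(rep(c("SF", "NSF"), c(n_sf, n - n_sf)))
  sides <- sample(c("left", "right"), n, replace = TRUE)
  ids <- sprintf("S%02d", seq_len(n))
  channels <- ten_twenty_labels()
  left_set <- .pair_table$left

  recordings <- vector("list", n)
  gt_rows <- vector("list", n)
  for (i in seq_len(n)) {
    shrink <- if (labels[i] == "NSF") 1 - params$effect_delta else 1
    asym <- 1 + (params$pathology - 1) * shrink
    nseg <- as.integer(round(params$segment_len_s * params$fs))
    data <- matrix(0, length(channels), 2L * nseg)
    for (st_i in 1:2) {
      state <- c("wake", "sleep")[st_i]
      jit <- stats::rlnorm(length(params$state_profiles[[state]]),
                           sdlog = params$amp_jitter_sdlog)
      p_i <- params
      p_i$state_profiles[[state]] <- params$state_profiles[[state]] * jit
      for (ch in seq_along(channels)) {
        lab <- channels[ch]
        is_patho <- if (sides[i] == "left") lab %in% left_set
                    else lab %in% .pair_table$right
        cj <- stats::rlnorm(1, sdlog = params$chan_jitter_sdlog)
        p_c <- p_i
        p_c$state_profiles[[state]] <- p_i$state_profiles[[state]] * cj
        data[ch, (st_i - 1L) * nseg + seq_len(nseg)] <-
          generate_channel(state, lab, p_c, pathological = is_patho,
                           asym_factors = asym)
      }
    }
    segs <- list(segment_annotation("wake", 0, params$segment_len_s),
                 segment_annotation("sleep", params$segment_len_s,
                                    params$segment_len_s))
    recordings[[i]] <- new_recording(ids[i], params$fs, channels, data,
                                     pathological_side = sides[i],
                                     segments = segs)
    gt_rows[[i]] <- data.frame(patient_id = ids[i], label = labels[i],
                               pathological_side = sides[i],
                               t(asym), stringsAsFactors = FALSE)
  }

  cohort <- data.frame(
    patient_id = ids,
    age_at_surgery = round(stats::runif(n, 0.2, 18), 1),
    etiology = "synthetic",
    histology = "synthetic",
    engel_outcome = ifelse(labels == "SF", "IA",
                           sample(c("ID", "II", "III", "IV"), n, TRUE)),
    followup_years = round(stats::runif(n, 2, 13), 1),
    stringsAsFactors = FALSE)
  cohort$label <- factor(labels, c("SF", "NSF"))
  ground_truth <- do.call(rbind, gt_rows)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (r in recordings)
      write_recording(r, file.path(out_dir, paste0(r$patient_id, ".edf")))
    utils::write.csv(cohort[, names(cohort) != "label"],
                     file.path(out_dir, "cohort.csv"), row.names = FALSE)
    jsonlite::write_json(ground_truth,
                         file.path(out_dir, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(recordings = recordings, cohort = cohort, ground_truth = ground_truth)
}
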