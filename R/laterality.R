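# From windows to the ANN design matrix: per-electrode means over the 12
# windows of each segment, pathological-minus-healthy differences over the 8
# homologous pairs, and the four feature-subset datasets.

#' Extended per-electrode feature names
#'
#' The nine core features ([feature_names()]) plus the Hjorth parameters
#' recomputed on each narrow band-filtered signal (`activity_delta`, ...,
#' `complexity_gamma`). The core `activity`/`mobility`/`complexity` are the
#' total-band (0.5-45 Hz) Hjorth values, since the signal is broadband
#' filtered before feature extraction.
#'
#' @return character vector of length 24.
#' @export
ext_feature_names <- function() {
  nb <- eeg_bands(include_total = FALSE)$name
  c(feature_names(),
    as.vector(t(outer(c("activity", "mobility", "complexity"), nb, paste,
                      sep = "_"))))
}

#' Per-window feature table for one recording
#'
#' Runs the preprocessing + feature stack for one patient: broadband
#' band-pass of the full recording, extraction of each annotated segment
#' into 5-s windows over the 16 lateral electrodes, and computation of the
#' nine core features per window. With `band_hjorth = TRUE` (needed for
#' feature dataset 4) the Hjorth parameters are additionally computed on the
#' signal band-filtered into each narrow band (full recording filtered per
#' band before windowing, so window edges are interior samples).
#'
#' @param recording an `eeg_recording` with wake/sleep segment annotations.
#' @param bands data.frame from [eeg_bands()].
#' @param spec broadband [filter_spec()].
#' @param window_len_s window length, seconds.
#' @param band_hjorth compute per-band Hjorth features as well.
#' @return long data.frame: `patient_id`, `state`, `window_idx`,
#'   `electrode`, `feature`, `value`.
#' @export
patient_feature_windows <- function(recording, bands = eeg_bands(),
                                    spec = filter_spec(),
                                    window_len_s = 5, band_hjorth = TRUE) {
  arrs <- patient_feature_arrays(recording, bands, spec, window_len_s,
                                 band_hjorth)
  chunks <- lapply(names(arrs), function(state) {
    tab <- as.data.frame.table(arrs[[state]], stringsAsFactors = FALSE)
    names(tab) <- c("electrode", "feature", "window_idx", "value")
    tab$window_idx <- as.integer(tab$window_idx)
    tab$patient_id <- recording$patient_id
    tab$state <- state
    tab[, c("patient_id", "state", "window_idx", "electrode", "feature",
            "value")]
  })
  do.call(rbind, chunks)
}

#' Per-patient feature tensor (window means)
#'
#' Same computation as [patient_feature_windows()] followed by
#' [aggregate_electrode_means()], fused for speed: the mean of each feature
#' over a segment's windows, per electrode and state.
#'
#' @inheritParams patient_feature_windows
#' @return long data.frame: `patient_id`, `state`, `electrode`, `feature`,
#'   `value`.
#' @export
patient_feature_tensor <- function(recording, bands = eeg_bands(),
                                   spec = filter_spec(),
                                   window_len_s = 5, band_hjorth = TRUE) {
  arrs <- patient_feature_arrays(recording, bands, spec, window_len_s,
                                 band_hjorth)
  chunks <- lapply(names(arrs), function(state) {
    m <- apply(arrs[[state]], c(1, 2), mean)
    tab <- as.data.frame.table(m, stringsAsFactors = FALSE)
    names(tab) <- c("electrode", "feature", "value")
    tab$patient_id <- recording$patient_id
    tab$state <- state
    tab[, c("patient_id", "state", "electrode", "feature", "value")]
  })
  do.call(rbind, chunks)
}

# electrode x feature x window arrays per state: broadband filter the full
# recording, window each annotated segment, compute the 9 core features per
# window; per-band Hjorth columns come from re-filtering the full recording
# into each narrow band before windowing.
patient_feature_arrays <- function(recording, bands = eeg_bands(),
                                   spec = filter_spec(),
                                   window_len_s = 5, band_hjorth = TRUE) {
  lateral <- ten_twenty_labels(lateral_only = TRUE)
  missing <- setdiff(lateral, recording$channels)
  if (length(missing))
    stop("channel ", paste(missing, collapse = ", "), " absent")
  if (!length(recording$segments)) stop("recording has no annotated segments")

  lat_rec <- recording
  lat_rec$data <- recording$data[lateral, , drop = FALSE]
  lat_rec$channels <- lateral

  broad <- lat_rec
  broad$data <- bandpass(lat_rec$data, spec, fs = recording$fs)

  narrow <- bands[bands$name != "total", , drop = FALSE]
  band_recs <- list()
  if (band_hjorth) {
    for (i in seq_len(nrow(narrow))) {
      bspec <- filter_spec(narrow$lo_hz[i], narrow$hi_hz[i],
                           order = spec$order, mode = spec$mode)
      br <- lat_rec
      br$data <- bandpass(lat_rec$data, bspec, fs = recording$fs)
      band_recs[[narrow$name[i]]] <- br
    }
  }

  feats <- if (band_hjorth) ext_feature_names() else feature_names()
  out <- list()
  for (seg in recording$segments) {
    ws <- extract_windows(broad, seg, window_len_s)
    n_win <- length(ws$windows)
    arr <- array(NA_real_,
                 dim = c(length(lateral), length(feats), n_win),
                 dimnames = list(lateral, feats, NULL))
    for (k in seq_len(n_win))
      arr[, feature_names(), k] <-
        extract_window_features(ws$windows[[k]], recording$fs, bands)
    if (band_hjorth) {
      for (bn in names(band_recs)) {
        wsb <- extract_windows(band_recs[[bn]], seg, window_len_s)
        cols <- paste(c("activity", "mobility", "complexity"), bn, sep = "_")
        for (k in seq_len(n_win))
          arr[, cols, k] <- t(apply(wsb$windows[[k]], 1, hjorth_all))
      }
    }
    out[[seg$state]] <- arr
  }
  out
}

#' Average window features per electrode
#'
#' Arithmetic mean of each feature across a segment's windows, per patient,
#' state and electrode — the per-patient feature tensor (9 core features x
#' 16 electrodes x 2 states = 288 core values per patient). Patients lacking
#' a wake or sleep segment are excluded with a message.
#'
#' @param window_table long data.frame from [patient_feature_windows()]
#'   (possibly several patients row-bound).
#' @return long data.frame: `patient_id`, `state`, `electrode`, `feature`,
#'   `value`.
#' @export
aggregate_electrode_means <- function(window_table) {
  states <- tapply(window_table$state, window_table$patient_id,
                   function(s) length(unique(s)))
  incomplete <- names(states)[states < 2]
  if (length(incomplete)) {
    message("excluding patient(s) without both wake and sleep segments: ",
            paste(incomplete, collapse = ", "))
    window_table <- window_table[!window_table$patient_id %in% incomplete, ,
                                 drop = FALSE]
  }
  if (!nrow(window_table)) stop("no complete patients to aggregate")
  agg <- stats::aggregate(
    value ~ patient_id + state + electrode + feature,
    data = window_table, FUN = mean)
  agg[order(agg$patient_id, agg$state, agg$electrode, agg$feature), ,
      drop = FALSE]
}

#' Pathological-minus-healthy interhemispheric differences
#'
#' For each homologous electrode pair, state and feature, the value at the
#' pathological-hemisphere electrode minus the value at its healthy-side
#' homolog. The sign convention is fixed: pathological - healthy.
#'
#' @param tensor long data.frame from [aggregate_electrode_means()].
#' @param montage a [build_montage_map()].
#' @param sides pathological side per patient: named character vector
#'   (`"left"`/`"right"`, names = patient ids) or a single value recycled.
#' @return long data.frame: `patient_id`, `state`, `pair`, `feature`,
#'   `value`.
#' @export
interhemispheric_difference <- function(tensor, montage, sides) {
  patients <- unique(tensor$patient_id)
  if (is.null(names(sides))) {
    if (length(sides) == 1) sides <- stats::setNames(rep(sides, length(patients)), patients)
    else stop("'sides' must be named by patient id (or length 1)")
  }
  missing <- setdiff(patients, names(sides))
  if (length(missing))
    stop("pathological side unknown for patient(s): ",
         paste(missing, collapse = ", "))
  if (!all(sides[patients] %in% c("left", "right")))
    stop("pathological side must be 'left' or 'right'")

  key <- function(p, s, e, f) paste(p, s, e, f, sep = "\r")
  val <- stats::setNames(tensor$value,
                         key(tensor$patient_id, tensor$state,
                             tensor$electrode, tensor$feature))
  grid <- expand.grid(feature = unique(tensor$feature),
                      pair = montage$pairs$pair,
                      state = unique(tensor$state),
                      patient_id = patients,
                      stringsAsFactors = FALSE)
  pl <- montage$pairs$left[match(grid$pair, montage$pairs$pair)]
  pr <- montage$pairs$right[match(grid$pair, montage$pairs$pair)]
  side <- sides[grid$patient_id]
  patho  <- ifelse(side == "left", pl, pr)
  healthy <- ifelse(side == "left", pr, pl)
  v_p <- val[key(grid$patient_id, grid$state, patho, grid$feature)]
  v_h <- val[key(grid$patient_id, grid$state, healthy, grid$feature)]
  if (anyNA(v_p) || anyNA(v_h))
    stop("feature tensor is incomplete for some (patient, state, electrode)")
  out <- grid[, c("patient_id", "state", "pair", "feature")]
  out$value <- unname(v_p - v_h)
  rownames(out) <- NULL
  out
}

# Column selectors for the four feature datasets.
dataset_features <- function(id) {
  nb <- eeg_bands(include_total = FALSE)$name
  hj <- c("activity", "mobility", "complexity")
  switch(as.character(id),
    "1" = feature_names(),
    "2" = c("psd_total", hj),
    "3" = paste0("psd_", eeg_bands()$name),
    "4" = c(hj, as.vector(t(outer(hj, nb, paste, sep = "_")))),
    stop("unknown dataset id: ", id, " (must be 1, 2, 3 or 4)"))
}

#' Assemble a feature dataset for classification
#'
#' Pivots lateralized features into a patients x columns design matrix and
#' selects the feature subset of one of the four study datasets:
#' 1. all nine core features (144 columns: 9 x 8 pairs x 2 states);
#' 2. features of the total band only — total-band power + broadband Hjorth
#'    (64 columns);
#' 3. frequency-domain (PSD) features for every band (96 columns);
#' 4. time-domain (Hjorth) features for every band, computed on
#'    band-filtered signal (288 columns; requires `band_hjorth` features).
#'
#' @param lateralized long data.frame from [interhemispheric_difference()].
#' @param id dataset id, 1-4.
#' @return list of class `feature_dataset`: `id`, `x` (numeric matrix,
#'   rownames = patient ids, colnames `state.pair.feature`), `selector`.
#' @export
build_dataset <- function(lateralized, id = 1) {
  feats <- dataset_features(id)
  missing <- setdiff(feats, unique(lateralized$feature))
  if (length(missing))
    stop("lateralized features lack column(s) needed by dataset ", id, ": ",
         paste(missing, collapse = ", "),
         " (run the pipeline with band_hjorth = TRUE)")
  d <- lateralized[lateralized$feature %in% feats, , drop = FALSE]
  patients <- unique(d$patient_id)
  states <- sort(unique(d$state))
  pairs <- unique(d$pair)
  cols <- as.vector(outer(feats, outer(pairs, states, function(p, s)
    paste(s, p, sep = ".")), function(f, sp) paste(sp, f, sep = ".")))
  cn <- paste(d$state, d$pair, d$feature, sep = ".")
  x <- matrix(NA_real_, nrow = length(patients), ncol = length(cols),
              dimnames = list(patients, cols))
  x[cbind(match(d$patient_id, patients), match(cn, cols))] <- d$value
  if (anyNA(x)) stop("incomplete lateralized features for dataset ", id)
  structure(list(id = id, x = x,
                 selector = paste0("dataset ", id, ": ",
                                   paste(feats, collapse = ", "))),
            class = "feature_dataset")
}

#' Alternative classifier input matrices
#'
#' The default analysis feeds the classifier per-pair
#' pathological-minus-healthy differences ([interhemispheric_difference()]
#' + [build_dataset()]). Two alternative readings of "mean values per
#' electrode, divided by hemisphere" are available for sensitivity
#' analyses:
#' * `hemisphere_mean` — average each feature over all 8 electrodes of a
#'   hemisphere first, then take the pathological-minus-healthy difference
#'   (9 features x 2 states = 18 inputs per patient);
#' * `raw` — no differencing: the full per-electrode tensor as columns
#'   (9 x 16 x 2 = 288 inputs per patient).
#'
#' @param tensor long data.frame from [aggregate_electrode_means()] /
#'   [cohort_feature_tensor()] (core features).
#' @param montage a [build_montage_map()].
#' @param sides named pathological-side vector as in
#'   [interhemispheric_difference()] (ignored for `raw`).
#' @param mode input construction mode.
#' @return numeric matrix, rownames = patient ids.
#' @export
build_input_matrix <- function(tensor, montage, sides,
                               mode = c("pair_difference", "hemisphere_mean",
                                        "raw")) {
  mode <- match.arg(mode)
  tensor <- tensor[tensor$feature %in% feature_names(), , drop = FALSE]
  if (mode == "pair_difference") {
    return(build_dataset(interhemispheric_difference(tensor, montage, sides),
                         1)$x)
  }
  patients <- unique(tensor$patient_id)
  if (mode == "raw") {
    cn <- paste(tensor$state, tensor$electrode, tensor$feature, sep = ".")
    cols <- sort(unique(cn))
    x <- matrix(NA_real_, length(patients), length(cols),
                dimnames = list(patients, cols))
    x[cbind(match(tensor$patient_id, patients), match(cn, cols))] <-
      tensor$value
    return(x)
  }
  # hemisphere_mean: average over each hemisphere's 8 lateral electrodes
  if (is.null(names(sides)) && length(sides) == 1)
    sides <- stats::setNames(rep(sides, length(patients)), patients)
  hemi <- ifelse(tensor$electrode %in% montage$pairs$left, "left", "right")
  key <- paste(tensor$patient_id, tensor$state, hemi, tensor$feature,
               sep = ".")
  means <- tapply(tensor$value, key, mean)
  grid <- expand.grid(feature = unique(tensor$feature),
                      state = unique(tensor$state),
                      patient_id = patients, stringsAsFactors = FALSE)
  side <- sides[grid$patient_id]
  v_p <- means[paste(grid$patient_id, grid$state, side, grid$feature,
                     sep = ".")]
  v_h <- means[paste(grid$patient_id, grid$state,
                     ifelse(side == "left", "right", "left"), grid$feature,
                     sep = ".")]
  cn <- paste(grid$state, "hemisphere", grid$feature, sep = ".")
  cols <- unique(cn)
  x <- matrix(NA_real_, length(patients), length(cols),
              dimnames = list(patients, cols))
  x[cbind(match(grid$patient_id, patients), match(cn, cols))] <-
    unname(v_p - v_h)
  x
}

#' Z-score columns using training-fold statistics
#'
#' Standardizes every column by the mean and standard deviation computed on
#' the training rows only (no leakage from validation/test rows).
#' Zero-variance columns are centered and left at zero.
#'
#' @param x numeric matrix (patients x features).
#' @param train_idx integer indices of the training rows.
#' @return matrix of the same shape.
#' @export
standardize <- function(x, train_idx) {
  stopifnot(length(train_idx) >= 1)
  mu <- colMeans(x[train_idx, , drop = FALSE])
  sd <- apply(x[train_idx, , drop = FALSE], 2, stats::sd)
  sd[!is.finite(sd) | sd == 0] <- 1
  sweep(sweep(x, 2, mu, "-"), 2, sd, "/")
}
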