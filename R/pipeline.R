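# End-to-end conveniences tying the modules together: cohort-level feature
# extraction, lateralization, dataset assembly and the architecture grid
# evaluation. These are what the analysis scripts and the acceptance checks
# drive.

#' Feature tensor for a whole cohort
#'
#' Applies [patient_feature_tensor()] to each recording and row-binds the
#' results.
#'
#' @param recordings list of `eeg_recording` objects.
#' @param ... passed to [patient_feature_tensor()] (`bands`, `spec`,
#'   `window_len_s`, `band_hjorth`).
#' @return long data.frame: `patient_id`, `state`, `electrode`, `feature`,
#'   `value`.
#' @export
cohort_feature_tensor <- function(recordings, ...) {
  do.call(rbind, lapply(recordings, patient_feature_tensor, ...))
}

#' Lateralize a cohort tensor using each recording's annotated side
#'
#' @param tensor from [cohort_feature_tensor()].
#' @param recordings the same recordings (for their `pathological_side`).
#' @return long data.frame from [interhemispheric_difference()].
#' @export
cohort_lateralized <- function(tensor, recordings) {
  sides <- vapply(recordings, function(r) r$pathological_side, "")
  names(sides) <- vapply(recordings, function(r) r$patient_id, "")
  montage <- build_montage_map(ten_twenty_labels())
  interhemispheric_difference(tensor, montage, sides)
}

#' Build the four feature datasets for a cohort
#'
#' @param lateralized from [cohort_lateralized()].
#' @param ids which dataset ids to build.
#' @return named list of [build_dataset()] objects (`"1"`..`"4"`).
#' @export
cohort_datasets <- function(lateralized, ids = 1:4) {
  stats::setNames(lapply(ids, function(i) build_dataset(lateralized, i)),
                  as.character(ids))
}

#' Run a synthetic cohort through the full pipeline
#'
#' Generation -> filtering/windowing -> features -> lateralization ->
#' datasets. The work-horse behind the calibration and recovery studies.
#'
#' @param params a [synth_params()].
#' @param ids dataset ids to assemble.
#' @param band_hjorth compute per-band Hjorth features (needed for dataset
#'   4; skipping them roughly halves the filtering work).
#' @return list: `datasets` (named list), `labels` (factor SF/NSF in
#'   dataset row order), `cohort`, `ground_truth`.
#' @export
synth_study <- function(params = synth_params(), ids = 1:4,
                        band_hjorth = TRUE) {
  gen <- generate_cohort(params)
  tensor <- cohort_feature_tensor(gen$recordings, band_hjorth = band_hjorth)
  lat <- cohort_lateralized(tensor, gen$recordings)
  datasets <- cohort_datasets(lat, ids)
  labels <- gen$cohort$label[match(rownames(datasets[[1]]$x),
                                   gen$cohort$patient_id)]
  list(datasets = datasets, labels = labels, cohort = gen$cohort,
       ground_truth = gen$ground_truth, lateralized = lat)
}

#' Evaluate the nine-architecture grid on one dataset
#'
#' @param x patients x features matrix.
#' @param labels SF/NSF labels.
#' @param n_iter holdout iterations per architecture.
#' @param seed split-plan seed.
#' @param arch_ids which architectures to run.
#' @param ... passed to [evaluate()].
#' @return list: `results` (per-architecture [evaluate()] outputs), `table`
#'   (data.frame in the performance-table layout), `best` (selected
#'   architecture result).
#' @export
run_grid <- function(x, labels, n_iter = 20, seed = 1,
                     arch_ids = names(architectures()), ...) {
  splits <- make_splits(nrow(x), labels, n_iter = n_iter, seed = seed)
  results <- lapply(arch_ids, function(a) {
    set.seed(seed + match(a, names(architectures())))
    evaluate(x, labels, arch = a, splits = splits, ...)
  })
  names(results) <- arch_ids
  tab <- data.frame(
    architecture = arch_ids,
    hidden = vapply(results, function(r) paste(r$hidden, collapse = "+"), ""),
    P = vapply(results, `[[`, 0, "P"),
    P_sd = vapply(results, `[[`, 0, "P_sd"),
    sensitivity = vapply(results, `[[`, 0, "sensitivity"),
    sensitivity_sd = vapply(results, `[[`, 0, "sensitivity_sd"),
    specificity = vapply(results, `[[`, 0, "specificity"),
    specificity_sd = vapply(results, `[[`, 0, "specificity_sd"),
    mse_pct = vapply(results, `[[`, 0, "mse_pct"),
    row.names = NULL)
  list(results = results, table = tab,
       best = select_architecture(results, n_inputs = ncol(x)))
}
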