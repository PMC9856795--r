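#!/usr/bin/env Rscript
# Step 3 — preprocessing and feature extraction.
# Reads the synthetic cohort back from EDF, band-pass filters 0.5-45 Hz
# (4th-order Butterworth, zero-phase), cuts each annotated 60-s segment
# into 12 non-overlapping 5-s windows, computes the 9 features per lateral
# electrode (6 band powers + 3 Hjorth parameters; 144 per EEG, 288 per
# patient), averages windows per electrode, and forms the
# pathological-minus-healthy differences over the 8 homologous pairs.
# Writes results/feature_tensor.csv and results/lateralized_features.csv.

suppressMessages(library(hemiconn))

edf_dir <- "results/synthetic_cohort"
paths <- list.files(edf_dir, pattern = "\\.edf$", full.names = TRUE)
if (!length(paths))
  stop("no EDFs found under ", edf_dir, "; run 02_simulate_cohort.R first")

recordings <- lapply(paths, read_recording)
cat("Read", length(recordings), "recordings from EDF\n")

tensor <- cohort_feature_tensor(recordings, band_hjorth = TRUE)
core <- tensor[tensor$feature %in% feature_names(), ]
cat("Feature tensor:", nrow(core) / length(recordings),
    "core values per patient (9 features x 16 electrodes x 2 states)\n")
write.csv(tensor, "results/feature_tensor.csv", row.names = FALSE)

lat <- cohort_lateralized(tensor, recordings)
cat("Lateralized features:",
    nrow(lat[lat$feature %in% feature_names(), ]) / length(recordings),
    "pathological-minus-healthy differences per patient (9 x 8 pairs x 2 states)\n")
write.csv(lat, "results/lateralized_features.csv", row.names = FALSE)
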