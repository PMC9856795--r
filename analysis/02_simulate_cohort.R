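#!/usr/bin/env Rscript
# Step 2 — synthetic EEG cohort.
# No patient recordings are publicly deposited, so the analysis runs on a
# synthetic cohort that mirrors the study conditions: 21 patients (15 SF /
# 6 NSF), 19-channel 10-20 EEG at 256 Hz, one 60-s wake and one 60-s
# sleep segment each, a lateralized spectral perturbation (slowing + alpha
# suppression) on the pathological hemisphere, and an SF/NSF separation
# controlled by the interhemispheric-asymmetry effect size (default 0.5).
# Writes EDF + JSON sidecars, cohort.csv and ground_truth.json under
# results/synthetic_cohort/.

suppressMessages(library(hemiconn))

seed <- 20260928L
out <- "results/synthetic_cohort"
params <- synth_params(seed = seed)          # study-condition defaults
gen <- generate_cohort(params, out_dir = out)

cat("Generated", length(gen$recordings), "patients into", out, "\n")
print(table(gen$cohort$label))
cat("Pathological side:", table(gen$ground_truth$pathological_side), "\n")
cat("Asymmetry effect size delta =", params$effect_delta, "\n")
cat("Per-band pathological amplitude factors (SF patients):\n")
print(params$pathology)
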