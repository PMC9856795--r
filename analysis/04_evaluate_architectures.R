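#!/usr/bin/env Rscript
# Step 4 — feature-subset selection and the nine-architecture grid.
# Builds the four feature datasets from the lateralized features (1: all
# features; 2: total-band only; 3: per-band PSD; 4: per-band Hjorth),
# compares them by held-out output MSE, then evaluates the nine network
# topologies on the winning dataset under the 20x random 70/15/15 protocol.
# Writes results/dataset_mse.csv, results/architecture_performance.csv and
# results/best_confusion_matrix.csv.

suppressMessages(library(hemiconn))

seed <- 20260928L
lat <- read.csv("results/lateralized_features.csv", stringsAsFactors = FALSE)
cohort <- read.csv("results/synthetic_cohort/cohort.csv",
                   stringsAsFactors = FALSE)
labels_by_id <- factor(ifelse(cohort$engel_outcome == "IA", "SF", "NSF"),
                       c("SF", "NSF"))
names(labels_by_id) <- cohort$patient_id

datasets <- cohort_datasets(lat, 1:4)
labels <- labels_by_id[rownames(datasets[["1"]]$x)]
n <- length(labels)

## Feature-subset selection by held-out MSE
splits <- make_splits(n, labels, n_iter = 20, seed = seed)
set.seed(seed)
dm <- dataset_mse(datasets, labels, splits, arch = "II")
cat("Held-out output MSE per feature dataset (%):\n")
print(round(dm$mse, 2))
cat("Selected dataset:", dm$best, "\n\n")
write.csv(data.frame(dataset = names(dm$mse), mse_pct = unname(dm$mse),
                     selected = names(dm$mse) == dm$best),
          "results/dataset_mse.csv", row.names = FALSE)

## Nine-architecture grid on the selected dataset
grid <- run_grid(datasets[[dm$best]]$x, labels, n_iter = 20, seed = seed)
cat("Architecture grid (20 iterations each):\n")
print(cbind(grid$table[, c("architecture", "hidden")],
            round(grid$table[, c("P", "P_sd", "sensitivity",
                                 "specificity", "mse_pct")], 1)))
write.csv(grid$table, "results/architecture_performance.csv",
          row.names = FALSE)

best <- grid$best
cat("\nSelected architecture:", best$arch,
    sprintf("(P = %.1f%% +/- %.1f)\n", best$P, best$P_sd))
cat("Mean confusion matrix (column-normalized %, columns = true class):\n")
print(round(best$mean_cm, 1))
cm <- as.data.frame(best$mean_cm)
cm <- cbind(predicted = rownames(best$mean_cm), cm)
write.csv(cm, "results/best_confusion_matrix.csv", row.names = FALSE)
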