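# The nine-architecture grid and the repeated 70/15/15 holdout protocol with
# averaged confusion matrices and the P / sensitivity / specificity / MSE
# selection metrics.

#' The nine network topologies of the architecture grid
#'
#' One or two hidden layers; when two, both have the same width; widths
#' 8, 5, 4, 3, 2: I `[8]`, II `[8,8]`, III `[5]`, IV `[5,5]`, V `[4]`,
#' VI `[4,4]`, VII `[3]`, VIII `[3,3]`, IX `[2]`.
#'
#' @return named list of integer vectors (hidden-layer widths), names
#'   `"I"`..`"IX"`.
#' @export
architectures <- function() {
  list(I = 8L, II = c(8L, 8L), III = 5L, IV = c(5L, 5L), V = 4L,
       VI = c(4L, 4L), VII = 3L, VIII = c(3L, 3L), IX = 2L)
}

# Largest-remainder apportionment of n into fractions (sums exactly to n).
apportion <- function(n, fractions) {
  raw <- n * fractions
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    order_rem <- order(raw - base, decreasing = TRUE)
    base[order_rem[seq_len(rem)]] <- base[order_rem[seq_len(rem)]] + 1
  }
  as.integer(base)
}

#' Random 70/15/15 patient-level split plans
#'
#' Generates the repeated-holdout plans: each iteration assigns every
#' patient to exactly one of train/validation/test, with fold sizes from
#' largest-remainder rounding of the fractions (n = 21 resolves to 15/3/3).
#' By default splits are stratified by class label, so the training fold
#' always carries both classes where the class sizes permit; `stratify =
#' FALSE` gives the fully random protocol.
#'
#' @param n_patients cohort size (>= 7 so each fold is nonempty).
#' @param labels factor/character of class labels, length `n_patients`
#'   (needed for stratification).
#' @param n_iter number of iterations (20 in the study protocol).
#' @param fractions train/validation/test fractions.
#' @param seed RNG seed making the plans reproducible.
#' @param stratify stratify fold assignment by label.
#' @return list of `n_iter` plans, each a list with integer index vectors
#'   `train`, `val`, `test` and the iteration number.
#' @export
make_splits <- function(n_patients, labels = NULL, n_iter = 20,
                        fractions = c(0.70, 0.15, 0.15), seed = 1,
                        stratify = TRUE) {
  stopifnot(abs(sum(fractions) - 1) < 1e-9)
  if (n_patients < 7)
    stop("cohort of ", n_patients, " is too small for a 70/15/15 protocol ",
         "(need at least 7 patients)")
  sizes <- apportion(n_patients, fractions)
  if (any(sizes == 0))
    stop("cohort of ", n_patients, " is too small: a fold would be empty")
  if (stratify && is.null(labels))
    stop("labels are required for stratified splits")
  set.seed(seed)
  lapply(seq_len(n_iter), function(it) {
    fold <- integer(n_patients)
    if (stratify) {
      # per-class largest-remainder allocation, then greedy repair so the
      # fold totals match exactly
      alloc <- t(vapply(split(seq_len(n_patients), labels),
                        function(idx) apportion(length(idx), fractions),
                        integer(3)))
      for (f in 1:3) {
        while (sum(alloc[, f]) > sizes[f]) {
          g <- which.max(alloc[, f])
          alloc[g, f] <- alloc[g, f] - 1L
          tgt <- which.min(colSums(alloc) - c(sizes))[1]
          alloc[g, tgt] <- alloc[g, tgt] + 1L
        }
      }
      for (cls in rownames(alloc)) {
        idx <- sample(which(labels == cls))
        cuts <- cumsum(c(0, alloc[cls, ]))
        for (f in 1:3)
          fold[idx[(cuts[f] + 1):cuts[f + 1]]] <- f
      }
    } else {
      idx <- sample(n_patients)
      cuts <- cumsum(c(0, sizes))
      for (f in 1:3) fold[idx[(cuts[f] + 1):cuts[f + 1]]] <- f
    }
    list(iteration = it, train = which(fold == 1), val = which(fold == 2),
         test = which(fold == 3))
  })
}

# 2x2 confusion counts; columns = true class, rows = predicted class,
# class order SF then NSF.
confusion_counts <- function(pred, truth) {
  lv <- c("SF", "NSF")
  m <- table(factor(pred, lv), factor(truth, lv))
  matrix(as.numeric(m), 2, 2, dimnames = list(predicted = lv, true = lv))
}

# Column-normalize to percentages per true class; all-zero columns -> NA.
normalize_cm <- function(cm) {
  tot <- colSums(cm)
  out <- sweep(cm, 2, ifelse(tot == 0, NA, tot), "/") * 100
  out
}

#' Evaluate one architecture under the repeated-holdout protocol
#'
#' For each split plan: standardize by training-fold statistics, train the
#' network (early stopping on the validation fold), classify the held-out
#' test patients at the 0.5 output threshold, and tally the 2x2 confusion
#' matrix. Reports the mean of the per-iteration column-normalized confusion
#' matrices, P = mean overall test accuracy (%), the diagonal-mean of the
#' average confusion matrix (balanced accuracy) as a secondary metric, SF
#' recall ("sensitivity") and NSF recall ("specificity") with SDs over
#' iterations, the mean squared output error on test patients (in %), and
#' the test misclassification rate.
#'
#' @param x patients x features matrix (unstandardized; standardization is
#'   done per split inside).
#' @param labels factor/character SF/NSF per patient.
#' @param arch architecture id (`"I"`..`"IX"`) or an integer vector of
#'   hidden widths.
#' @param splits plans from [make_splits()].
#' @param threshold decision threshold on the sigmoid output.
#' @param ... passed to [mlp_train()] (`max_epochs`, `lr`, `patience`).
#' @return list of class `eval_result`.
#' @export
evaluate <- function(x, labels, arch = "II", splits, threshold = 0.5, ...) {
  stopifnot(length(splits) >= 1)
  hidden <- if (is.character(arch)) architectures()[[arch]] else arch
  if (is.null(hidden)) stop("unknown architecture id: ", arch)
  labels <- factor(as.character(labels), c("SF", "NSF"))
  y <- as.numeric(labels == "SF")

  iters <- lapply(splits, function(sp) {
    xs <- standardize(x, sp$train)
    fit <- mlp_train(xs[sp$train, , drop = FALSE], y[sp$train],
                     hidden = hidden,
                     x_val = xs[sp$val, , drop = FALSE], y_val = y[sp$val],
                     ...)
    p <- mlp_predict(fit, xs[sp$test, , drop = FALSE])
    pred <- ifelse(p > threshold, "SF", "NSF")
    truth <- as.character(labels[sp$test])
    cm <- confusion_counts(pred, truth)
    list(cm = cm, ncm = normalize_cm(cm),
         accuracy = 100 * mean(pred == truth),
         mse_pct = 100 * mean((p - y[sp$test])^2),
         sf_recall = if (any(truth == "SF"))
           100 * mean(pred[truth == "SF"] == "SF") else NA_real_,
         nsf_recall = if (any(truth == "NSF"))
           100 * mean(pred[truth == "NSF"] == "NSF") else NA_real_)
  })
  acc <- vapply(iters, `[[`, 0, "accuracy")
  sfr <- vapply(iters, `[[`, 0, "sf_recall")
  nsr <- vapply(iters, `[[`, 0, "nsf_recall")
  ncms <- simplify2array(lapply(iters, `[[`, "ncm"))
  mean_cm <- apply(ncms, c(1, 2), mean, na.rm = TRUE)
  structure(list(
    arch = if (is.character(arch)) arch else paste(hidden, collapse = "+"),
    hidden = hidden,
    n_iter = length(splits),
    mean_cm = mean_cm,
    P = mean(acc), P_sd = stats::sd(acc),
    diag_mean = mean(diag(mean_cm)),
    sensitivity = mean(sfr, na.rm = TRUE),
    sensitivity_sd = stats::sd(sfr, na.rm = TRUE),
    specificity = mean(nsr, na.rm = TRUE),
    specificity_sd = stats::sd(nsr, na.rm = TRUE),
    mse_pct = mean(vapply(iters, `[[`, 0, "mse_pct")),
    misclass_pct = 100 - mean(acc),
    iterations = iters), class = "eval_result")
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf("Architecture %s (%s): P = %.1f%% +/- %.1f (n_iter = %d)\n",
              x$arch, paste(x$hidden, collapse = "+"), x$P, x$P_sd, x$n_iter))
  cat(sprintf("  SF recall %.1f%% +/- %.1f | NSF recall %.1f%% +/- %.1f | test MSE %.2f%%\n",
              x$sensitivity, x$sensitivity_sd, x$specificity,
              x$specificity_sd, x$mse_pct))
  cat("  mean confusion matrix (column-normalized %, columns = true class):\n")
  print(round(x$mean_cm, 1))
  invisible(x)
}

#' Per-dataset test MSE for feature-subset selection
#'
#' Trains the given architecture on each of the four feature datasets under
#' the same split plans and reports the mean squared deviation of the
#' network output from the 0/1 target on held-out patients, averaged over
#' iterations and expressed in percent. The dataset with the lowest MSE is
#' the selected feature subset.
#'
#' @param datasets named list of [build_dataset()] objects (or plain
#'   matrices).
#' @param labels SF/NSF labels.
#' @param splits plans from [make_splits()].
#' @param arch architecture used for the comparison.
#' @param ... passed to [evaluate()].
#' @return list with `mse` (named numeric, %) and `best` (name of the
#'   argmin dataset).
#' @export
dataset_mse <- function(datasets, labels, splits, arch = "II", ...) {
  mse <- vapply(datasets, function(d) {
    x <- if (inherits(d, "feature_dataset")) d$x else d
    evaluate(x, labels, arch = arch, splits = splits, ...)$mse_pct
  }, 0)
  list(mse = mse, best = names(mse)[which.min(mse)])
}

#' Select the best architecture
#'
#' Argmax of P; ties broken by lower SD of P, then by fewer trainable
#' parameters (the smaller net trains faster).
#'
#' @param results list of [evaluate()] results.
#' @param n_inputs input dimensionality used for the parameter-count
#'   tie-break (defaults to 144, the all-features dataset width).
#' @return the winning element of `results`.
#' @export
select_architecture <- function(results, n_inputs = 144) {
  stopifnot(length(results) >= 1)
  P <- vapply(results, `[[`, 0, "P")
  sd <- vapply(results, `[[`, 0, "P_sd")
  np <- vapply(results, function(r) mlp_n_params(r$hidden, n_inputs), 0)
  ord <- order(-P, sd, np)
  results[[ord[1]]]
}
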