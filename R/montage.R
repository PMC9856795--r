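#' @keywords internal
"_PACKAGE"

# Canonical 10-20 vocabulary (legacy naming, as used clinically with T3/T4/T5/T6).
# Pair order is fixed frontal -> occipital; left column before right everywhere.
.pair_table <- data.frame(
  pair  = c("Fp1_Fp2", "F3_F4", "F7_F8", "C3_C4", "T3_T4", "T5_T6", "P3_P4", "O1_O2"),
  left  = c("Fp1", "F3", "F7", "C3", "T3", "T5", "P3", "O1"),
  right = c("Fp2", "F4", "F8", "C4", "T4", "T6", "P4", "O2"),
  stringsAsFactors = FALSE
)

.midline_labels <- c("Fz", "Cz", "Pz")

# Modern equivalents mapped onto the legacy names on read.
.label_aliases <- c(T7 = "T3", T8 = "T4", P7 = "T5", P8 = "T6")

#' Standard 10-20 scalp electrode labels
#'
#' The 19 scalp electrodes of the international 10-20 system in canonical
#' order: the 8 homologous lateral pairs frontal to occipital (left before
#' right), followed by the 3 midline electrodes.
#'
#' @param lateral_only if `TRUE`, return only the 16 lateral electrodes.
#' @return character vector of electrode labels.
#' @export
ten_twenty_labels <- function(lateral_only = FALSE) {
  lat <- as.vector(t(as.matrix(.pair_table[, c("left", "right")])))
  if (lateral_only) lat else c(lat, .midline_labels)
}

#' Canonicalize electrode labels
#'
#' Case-insensitive matching against the 10-20 vocabulary, with modern
#' temporal-chain names (T7/T8/P7/P8) resolved to their legacy equivalents
#' (T3/T4/T5/T6).
#'
#' @param labels character vector of raw channel labels.
#' @return character vector of canonical labels.
#' @export
canonical_labels <- function(labels) {
  vocab <- c(ten_twenty_labels(), names(.label_aliases))
  idx <- match(toupper(trimws(labels)), toupper(vocab))
  if (anyNA(idx)) {
    stop("unrecognized electrode label(s): ",
         paste(labels[is.na(idx)], collapse = ", "))
  }
  out <- vocab[idx]
  ali <- out %in% names(.label_aliases)
  out[ali] <- .label_aliases[out[ali]]
  out
}

#' Resolve a channel set into homologous pairs and midline electrodes
#'
#' Partitions 10-20 labels into left/right homologous pairs (canonical
#' frontal-to-occipital order) and midline electrodes. Midline electrodes are
#' excluded from lateralized feature extraction; every lateral electrode must
#' have its homolog present.
#'
#' @param channels character vector of channel labels (10-20 vocabulary).
#' @return object of class `montage_map`: list with `pairs` (data.frame with
#'   columns `pair`, `left`, `right`) and `midline` (character).
#' @export
build_montage_map <- function(channels) {
  labs <- canonical_labels(channels)
  if (anyDuplicated(labs)) {
    stop("duplicate electrode label(s): ",
         paste(unique(labs[duplicated(labs)]), collapse = ", "))
  }
  midline <- .midline_labels[.midline_labels %in% labs]
  keep <- .pair_table$left %in% labs | .pair_table$right %in% labs
  pairs <- .pair_table[keep, , drop = FALSE]
  half <- xor(pairs$left %in% labs, pairs$right %in% labs)
  if (any(half)) {
    missing_side <- ifelse(pairs$left[half] %in% labs, pairs$right[half],
                           pairs$left[half])
    stop("unpaired lateral electrode(s); missing homolog(s): ",
         paste(missing_side, collapse = ", "))
  }
  rownames(pairs) <- NULL
  structure(list(pairs = pairs, midline = midline), class = "montage_map")
}

#' @export
print.montage_map <- function(x, ...) {
  cat("<montage_map> ", nrow(x$pairs), " homologous pairs, ",
      length(x$midline), " midline\n", sep = "")
  cat("  pairs:  ", paste(x$pairs$pair, collapse = " "), "\n", sep = "")
  if (length(x$midline))
    cat("  midline:", paste(x$midline, collapse = " "), "\n")
  invisible(x)
}
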