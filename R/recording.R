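#' Construct an EEG recording object
#'
#' In-memory container for a multichannel scalp EEG: a channels x samples
#' matrix in microvolts with montage labels, sampling rate, the annotated
#' wake/sleep segments and the pathological hemisphere.
#'
#' @param patient_id character scalar.
#' @param fs sampling frequency in Hz (the study recordings are 256 Hz).
#' @param channels character vector of 10-20 electrode labels, one per row of
#'   `data`.
#' @param data numeric matrix, channels x samples, in microvolts.
#' @param pathological_side `"left"` or `"right"`, or `NA` if not yet known.
#' @param segments list of segment annotations as returned by
#'   [segment_annotation()].
#' @param reference_label recording reference electrode label (monopolar
#'   recordings referenced to G2 in the study setting).
#' @return object of class `eeg_recording`.
#' @export
new_recording <- function(patient_id, fs, channels, data,
                          pathological_side = NA_character_,
                          segments = list(), reference_label = "G2") {
  stopifnot(is.matrix(data), is.numeric(data), fs > 0)
  channels <- canonical_labels(channels)
  if (anyDuplicated(channels)) stop("channel labels must be unique")
  if (nrow(data) != length(channels))
    stop("data has ", nrow(data), " rows but ", length(channels), " channel labels")
  if (!is.na(pathological_side))
    pathological_side <- match.arg(pathological_side, c("left", "right"))
  n <- ncol(data)
  for (seg in segments) {
    if ((seg$start + seg$duration) * fs > n + 1e-9)
      stop("segment '", seg$state, "' extends beyond the recording")
  }
  rownames(data) <- channels
  structure(
    list(patient_id = patient_id, fs = fs, channels = channels, data = data,
         reference_label = reference_label,
         pathological_side = pathological_side, segments = segments),
    class = "eeg_recording")
}

#' Annotate a wake or sleep segment
#'
#' @param state `"wake"` or `"sleep"` (sleep = stage II in the study protocol).
#' @param start segment onset in seconds from recording start.
#' @param duration segment length in seconds (60 in the study protocol).
#' @return list with class `segment_annotation`.
#' @export
segment_annotation <- function(state, start, duration = 60) {
  state <- match.arg(state, c("wake", "sleep"))
  stopifnot(start >= 0, duration > 0)
  structure(list(state = state, start = start, duration = duration),
            class = "segment_annotation")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat("<eeg_recording> patient ", x$patient_id, ": ", length(x$channels),
      " channels x ", ncol(x$data), " samples @ ", x$fs, " Hz\n", sep = "")
  cat("  pathological side: ", x$pathological_side, "; segments: ",
      paste(vapply(x$segments, function(s)
        sprintf("%s[%gs+%gs]", s$state, s$start, s$duration), ""),
        collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Re-reference a recording to the common average
#'
#' Signals are analyzed against the recording reference by default (the
#' study montage is monopolar against G2). For sensitivity analyses this
#' subtracts the instantaneous mean over all channels from every channel.
#'
#' @param recording an `eeg_recording`.
#' @return the re-referenced recording (`reference_label` set to `"CAR"`).
#' @export
rereference_car <- function(recording) {
  recording$data <- sweep(recording$data, 2, colMeans(recording$data), "-")
  recording$reference_label <- "CAR"
  recording
}

# Retrieve the annotation for one state, or NULL.
find_segment <- function(recording, state) {
  for (seg in recording$segments) if (seg$state == state) return(seg)
  NULL
}
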