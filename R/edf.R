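# Minimal EDF (European Data Format, 16-bit) reader/writer.
# Covers plain EDF only (no EDF+ annotations channel); segment annotations and
# the pathological side travel in a JSON sidecar (see read_annotations()).

.edf_field <- function(x, width) {
  s <- as.character(x)
  if (nchar(s) > width) stop("EDF header field too wide: '", s, "'")
  formatC(s, width = width, flag = "-")
}

.edf_num <- function(x, width = 8) {
  for (digits in c(6, 5, 4, 3, 2)) {
    s <- formatC(x, digits = digits, format = "g", flag = "-")
    if (nchar(s) <= width) return(.edf_field(s, width))
  }
  stop("cannot format ", x, " in ", width, " chars")
}

#' Write a recording to an EDF file
#'
#' Plain EDF, 16-bit samples, one-second data records. Each channel gets a
#' symmetric physical range covering its data, so quantization error is at
#' most range/65534 per sample. The number of samples must be a whole number
#' of seconds.
#'
#' @param recording an [new_recording()] object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(recording, path) {
  data <- recording$data
  fs <- recording$fs
  if (fs != round(fs)) stop("write_edf requires an integer sampling rate")
  n <- ncol(data)
  if (n %% fs != 0) stop("recording length must be a whole number of seconds")
  n_rec <- n %/% fs
  ns <- nrow(data)

  phys_max <- apply(abs(data), 1, max)
  phys_max[phys_max == 0] <- 1
  # 0.1% headroom so the value carried by the 8-char ASCII field (<= 6
  # significant digits) still covers the data after rounding
  phys_str <- vapply(phys_max * 1.001, .edf_num, "")
  phys_max <- as.numeric(phys_str)
  dig_max <- 32767L
  dig_min <- -32767L

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    .edf_field("0", 8),
    .edf_field(recording$patient_id, 80),
    .edf_field(paste0("ref ", recording$reference_label), 80),
    .edf_field("01.01.20", 8), .edf_field("00.00.00", 8),
    .edf_field(256 * (ns + 1), 8),
    .edf_field("", 44),
    .edf_field(n_rec, 8),
    .edf_field(1, 8),
    .edf_field(ns, 4),
    paste(vapply(recording$channels, .edf_field, "", width = 16), collapse = ""),
    paste(rep(.edf_field("", 80), ns), collapse = ""),
    paste(rep(.edf_field("uV", 8), ns), collapse = ""),
    paste(vapply(-phys_max, .edf_num, ""), collapse = ""),
    paste(phys_str, collapse = ""),
    paste(rep(.edf_field(dig_min, 8), ns), collapse = ""),
    paste(rep(.edf_field(dig_max, 8), ns), collapse = ""),
    paste(rep(.edf_field("BP 0.5-45Hz", 80), ns), collapse = ""),
    paste(rep(.edf_field(fs, 8), ns), collapse = ""),
    paste(rep(.edf_field("", 32), ns), collapse = ""))
  writeChar(hdr, con, eos = NULL)

  scale <- (dig_max - dig_min) / (2 * phys_max)
  dig <- round((data + phys_max) * scale) + dig_min
  dig <- pmin(pmax(dig, dig_min), dig_max)
  # interleave: per record, all samples of ch1, then ch2, ...
  arr <- array(t(dig), dim = c(fs, n_rec, ns))          # sample x record x ch
  out <- as.integer(aperm(arr, c(1, 3, 2)))             # sample, ch, record
  writeBin(out, con, size = 2, endian = "little")
  invisible(path)
}

read_edf_header <- function(con) {
  rd <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  h <- list(version = rd(8), patient = rd(80), recording = rd(80),
            date = rd(8), time = rd(8), header_bytes = as.integer(rd(8)))
  rd(44)
  h$n_records <- as.integer(rd(8))
  h$record_duration <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  h$ns <- ns
  fld <- function(w) vapply(seq_len(ns), function(i) rd(w), "")
  h$labels <- fld(16); fld(80); h$dim <- fld(8)
  h$phys_min <- as.numeric(fld(8)); h$phys_max <- as.numeric(fld(8))
  h$dig_min <- as.integer(fld(8)); h$dig_max <- as.integer(fld(8))
  fld(80)
  h$samples_per_record <- as.integer(fld(8))
  fld(32)
  h
}

#' Read an EDF recording with its JSON annotation sidecar
#'
#' Parses a plain 16-bit EDF file, maps channel labels onto the canonical
#' legacy 10-20 vocabulary (modern T7/T8/P7/P8 resolved to T3/T4/T5/T6),
#' verifies that every lateral 10-20 electrode referenced by the montage has
#' its homolog, and attaches wake/sleep segment annotations and the
#' pathological side from the sidecar.
#'
#' @param path EDF file path.
#' @param annotations path to the JSON sidecar (default: `path` with
#'   extension `.json`); `NULL` to skip.
#' @param require_channels channels that must be present (default: the 16
#'   lateral 10-20 electrodes). A missing one is an error naming the channel.
#' @return an `eeg_recording`.
#' @export
read_recording <- function(path, annotations = NULL,
                           require_channels = ten_twenty_labels(lateral_only = TRUE)) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  h <- read_edf_header(con)
  if (length(unique(h$samples_per_record)) != 1)
    stop("mixed per-channel sampling rates are not supported")
  spr <- h$samples_per_record[1]
  fs <- spr / h$record_duration
  raw <- readBin(con, integer(), n = h$n_records * h$ns * spr, size = 2,
                 endian = "little")
  arr <- array(raw, dim = c(spr, h$ns, h$n_records))
  dig <- matrix(aperm(arr, c(1, 3, 2)), nrow = spr * h$n_records, ncol = h$ns)
  gain <- (h$phys_max - h$phys_min) / (h$dig_max - h$dig_min)
  data <- t(dig) * gain + (h$phys_min - h$dig_min * gain)

  channels <- canonical_labels(h$labels)
  missing <- setdiff(require_channels, channels)
  if (length(missing))
    stop("channel ", paste(missing, collapse = ", "), " absent")
  if (fs != 256)
    warning("sampling frequency is ", fs, " Hz, not the expected 256 Hz; ",
            "windowing adapts to the actual rate")

  side <- NA_character_
  segments <- list()
  if (is.null(annotations)) {
    cand <- sub("\\.edf$", ".json", path, ignore.case = TRUE)
    if (file.exists(cand)) annotations <- cand
  }
  if (!is.null(annotations)) {
    ann <- read_annotations(annotations)
    side <- ann$pathological_side
    segments <- ann$segments
  }
  new_recording(patient_id = h$patient, fs = fs, channels = channels,
                data = data, pathological_side = side, segments = segments)
}

#' Write a recording's EDF file plus JSON annotation sidecar
#'
#' @inheritParams write_edf
#' @return `path`, invisibly.
#' @export
write_recording <- function(recording, path) {
  write_edf(recording, path)
  write_annotations(recording, sub("\\.edf$", ".json", path, ignore.case = TRUE))
  invisible(path)
}

#' Read or write the JSON annotation sidecar
#'
#' The sidecar holds the pathological hemisphere and the expert-selected
#' wake/sleep segment bounds:
#' `{"pathological_side": "left", "segments": [{"state": "wake",
#' "start_s": 0, "duration_s": 60}, ...]}`.
#'
#' @param path JSON file path.
#' @return for `read_annotations`, a list with `pathological_side` and a list
#'   of [segment_annotation()]s.
#' @export
read_annotations <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = FALSE)
  segs <- lapply(j$segments, function(s)
    segment_annotation(s$state, s$start_s, s$duration_s))
  list(pathological_side = j$pathological_side %||% NA_character_,
       segments = segs)
}

#' @rdname read_annotations
#' @param recording an `eeg_recording` whose annotations are to be written.
#' @export
write_annotations <- function(recording, path) {
  j <- list(
    pathological_side = recording$pathological_side,
    segments = lapply(recording$segments, function(s)
      list(state = s$state, start_s = s$start, duration_s = s$duration)))
  jsonlite::write_json(j, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
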