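# Minimal European Data Format (EDF) I/O: fixed 256-byte main header,
# 256 bytes per signal, then data records of little-endian 16-bit integers
# scaled linearly between digital and physical ranges. Covers the continuous
# single-rate layout used by CHB-MIT; EDF+ annotation channels are not
# interpreted.

.edf_pad <- function(s, width) {
  s <- substr(as.character(s), 1L, width)
  formatC(s, width = width, flag = "-")
}

.edf_num <- function(x, width) {
  s <- formatC(x, format = "g", digits = 7, width = 1)
  if (nchar(s) > width) s <- substr(s, 1L, width)
  .edf_pad(s, width)
}

#' Write a recording as an EDF file
#'
#' Amplitudes are quantized to 16-bit integers over a symmetric physical
#' range covering the data, one-second data records. The duration is
#' truncated to whole seconds. Seizure annotations are not stored in the EDF
#' itself; write them with [write_annotations_csv()].
#'
#' @param rec An [eeg_recording()] with integer sampling rate.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  fs <- rec$sampling_rate
  if (fs != round(fs)) stop("EDF writer requires an integer sampling rate",
                            call. = FALSE)
  n_sig <- nrow(rec$samples)
  n_rec <- floor(ncol(rec$samples) / fs)
  if (n_rec < 1) stop("recording shorter than one data record", call. = FALSE)
  x <- rec$samples[, seq_len(n_rec * fs), drop = FALSE]

  pmaxv <- max(1e-6, max(abs(x)))
  phys_min <- -pmaxv
  phys_max <- pmaxv
  dig_min <- -32767L
  dig_max <- 32767L
  scale <- (dig_max - dig_min) / (phys_max - phys_min)
  digital <- round((x - phys_min) * scale) + dig_min

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    .edf_pad("0", 8), .edf_pad(rec$source_id, 80),
    .edf_pad("seizecast synthetic recording", 80),
    .edf_pad("01.01.00", 8), .edf_pad("00.00.00", 8),
    .edf_pad(256L * (1L + n_sig), 8), .edf_pad("", 44),
    .edf_pad(n_rec, 8), .edf_pad(1, 8), .edf_pad(n_sig, 4))
  writeChar(hdr, con, eos = NULL)
  field <- function(vals, width) {
    writeChar(paste0(vapply(vals, .edf_pad, "", width = width),
                     collapse = ""), con, eos = NULL)
  }
  field(rec$channel_names, 16)
  field(rep("", n_sig), 80)                       # transducer
  field(rep("uV", n_sig), 8)                      # physical dimension
  field(vapply(rep(phys_min, n_sig), .edf_num, "", width = 8), 8)
  field(vapply(rep(phys_max, n_sig), .edf_num, "", width = 8), 8)
  field(rep(dig_min, n_sig), 8)
  field(rep(dig_max, n_sig), 8)
  field(rep("", n_sig), 80)                       # prefiltering
  field(rep(fs, n_sig), 8)
  field(rep("", n_sig), 32)
  for (r in seq_len(n_rec)) {
    cols <- ((r - 1L) * fs + 1L):(r * fs)
    block <- t(digital[, cols, drop = FALSE])     # per-signal contiguous
    writeBin(as.integer(block), con, size = 2L, endian = "little")
  }
  invisible(path)
}

#' Read an EDF file
#'
#' All signals must share one sampling rate (true of CHB-MIT recordings).
#'
#' @param path EDF file path.
#' @param source_id Case identifier; defaults to the file name without
#'   extension.
#' @return An [eeg_recording()] without seizure annotations (attach them via
#'   [read_recording()]).
#' @export
read_edf <- function(path, source_id = NULL) {
  if (!file.exists(path)) stop("EDF file not found: ", path, call. = FALSE)
  if (is.null(source_id)) {
    source_id <- sub("\\.[^.]*$", "", basename(path))
  }
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(width) trimws(readChar(con, width, useBytes = TRUE))
  version <- rd(8)
  patient <- rd(80); recording <- rd(80)
  rd(8); rd(8)                                    # start date/time
  header_bytes <- as.integer(rd(8)); rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  n_sig <- as.integer(rd(4))
  if (is.na(n_sig) || n_sig < 1) stop("corrupt EDF header in ", path,
                                      call. = FALSE)
  rdv <- function(width) vapply(seq_len(n_sig), function(i) rd(width), "")
  labels <- rdv(16); rdv(80); rdv(8)
  phys_min <- as.numeric(rdv(8)); phys_max <- as.numeric(rdv(8))
  dig_min <- as.numeric(rdv(8)); dig_max <- as.numeric(rdv(8))
  rdv(80)
  spr <- as.integer(rdv(8)); rdv(32)
  if (length(unique(spr)) != 1L) {
    stop("multi-rate EDF not supported (", path, ")", call. = FALSE)
  }
  seek(con, header_bytes)
  raw16 <- readBin(con, integer(), n = n_rec * sum(spr), size = 2L,
                   signed = TRUE, endian = "little")
  if (length(raw16) < n_rec * sum(spr)) {
    stop("truncated EDF data in ", path, call. = FALSE)
  }
  fs <- spr[1] / rec_dur
  samples <- matrix(0, nrow = n_sig, ncol = n_rec * spr[1])
  scale <- (phys_max - phys_min) / (dig_max - dig_min)
  pos <- 0L
  for (r in seq_len(n_rec)) {
    for (s in seq_len(n_sig)) {
      vals <- raw16[(pos + 1L):(pos + spr[s])]
      pos <- pos + spr[s]
      samples[s, ((r - 1L) * spr[s] + 1L):(r * spr[s])] <-
        (vals - dig_min[s]) * scale[s] + phys_min[s]
    }
  }
  eeg_recording(samples, fs, labels, source_id = source_id)
}

#' Read seizure annotations
#'
#' Accepts either a CSV with header `case,onset_s,offset_s` or a CHB-MIT
#' style summary text file (line-oriented, tolerant: blocks introduced by
#' `File Name:` with `Seizure ... Start Time: <n> seconds` /
#' `Seizure ... End Time: <n> seconds` lines).
#'
#' @param path Annotation file path.
#' @return Data frame with columns `case`, `onset_s`, `offset_s`.
#' @export
read_seizure_annotations <- function(path) {
  if (!file.exists(path)) stop("annotation file not found: ", path,
                               call. = FALSE)
  first <- readLines(path, n = 1L, warn = FALSE)
  if (grepl("onset_s", first, ignore.case = TRUE)) {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    names(df) <- tolower(trimws(names(df)))
    return(df[, c("case", "onset_s", "offset_s")])
  }
  lines <- readLines(path, warn = FALSE)
  case <- NA_character_
  out <- data.frame(case = character(0), onset_s = numeric(0),
                    offset_s = numeric(0), stringsAsFactors = FALSE)
  pending_onset <- NULL
  for (ln in lines) {
    if (grepl("file\\s*name\\s*:", ln, ignore.case = TRUE)) {
      fn <- trimws(sub(".*[Ff]ile\\s*[Nn]ame\\s*:", "", ln))
      case <- sub("\\.[^.]*$", "", fn)
      pending_onset <- NULL
    } else if (grepl("seizure.*start\\s*time\\s*:", ln, ignore.case = TRUE)) {
      pending_onset <- as.numeric(sub(".*:\\s*([0-9.]+).*", "\\1", ln))
    } else if (grepl("seizure.*end\\s*time\\s*:", ln, ignore.case = TRUE)) {
      off <- as.numeric(sub(".*:\\s*([0-9.]+).*", "\\1", ln))
      if (!is.null(pending_onset)) {
        out <- rbind(out, data.frame(case = case, onset_s = pending_onset,
                                     offset_s = off,
                                     stringsAsFactors = FALSE))
        pending_onset <- NULL
      }
    }
  }
  out
}

#' Write annotations as CSV
#'
#' @param ann Data frame with columns `case`, `onset_s`, `offset_s`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotations_csv <- function(ann, path) {
  utils::write.csv(ann[, c("case", "onset_s", "offset_s")], path,
                   row.names = FALSE)
  invisible(path)
}

#' Read an annotated EEG recording
#'
#' Reads the EDF signals and attaches seizure onset/offset annotations whose
#' `case` matches the EDF file name (all rows are used if the annotation
#' file carries no matching case, e.g. a single-recording CSV).
#'
#' @param path EDF file path.
#' @param annotation_path Annotation file (CSV or summary text), or `NULL`
#'   for an unannotated recording.
#' @return An [eeg_recording()] with annotations attached.
#' @export
read_recording <- function(path, annotation_path = NULL) {
  rec <- read_edf(path)
  if (is.null(annotation_path)) return(rec)
  ann <- read_seizure_annotations(annotation_path)
  sel <- ann[ann$case == rec$source_id, , drop = FALSE]
  if (nrow(sel) == 0 && length(unique(ann$case)) <= 1L) sel <- ann
  if (nrow(sel) > 0) {
    sel <- sel[order(sel$onset_s), , drop = FALSE]
    if (any(sel$onset_s >= rec$duration) || any(sel$offset_s > rec$duration)) {
      stop("annotation beyond recording duration (", rec$duration,
           " s) for case ", rec$source_id, call. = FALSE)
    }
    rec <- eeg_recording(rec$samples, rec$sampling_rate, rec$channel_names,
                         sel$onset_s, sel$offset_s, rec$source_id)
  }
  rec
}
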