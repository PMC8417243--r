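# Recording container, channel selection, pre-ictal/inter-ictal labeling and
# fixed-length windowing. Time convention: seconds from recording start,
# intervals half-open [start, end).

#' Default CHB-MIT bipolar longitudinal montage (18 channels)
#'
#' The standard 18-channel bipolar derivation list used for scalp EEG in the
#' CHB-MIT corpus; the channel-graph machinery defaults to graphs of this
#' size.
#'
#' @return Character vector of 18 channel labels.
#' @export
chbmit_montage <- function() {
  c("FP1-F7", "F7-T7", "T7-P7", "P7-O1",
    "FP1-F3", "F3-C3", "C3-P3", "P3-O1",
    "FP2-F4", "F4-C4", "C4-P4", "P4-O2",
    "FP2-F8", "F8-T8", "T8-P8", "P8-O2",
    "FZ-CZ", "CZ-PZ")
}

#' Construct an annotated multichannel EEG recording
#'
#' @param samples Numeric matrix, channels x time, amplitudes in microvolts.
#' @param sampling_rate Samples per second (Hz).
#' @param channel_names Character vector, one label per row of `samples`.
#' @param seizure_onsets,seizure_offsets Numeric vectors of seizure onset and
#'   offset times in seconds from recording start (equal lengths, onsets
#'   strictly increasing, each onset before its offset).
#' @param source_id Case identifier attached to segments cut from this
#'   recording.
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(samples, sampling_rate, channel_names,
                          seizure_onsets = numeric(0),
                          seizure_offsets = numeric(0),
                          source_id = "case") {
  samples <- as.matrix(samples)
  if (!is.numeric(samples)) stop("samples must be numeric", call. = FALSE)
  if (sampling_rate <= 0) stop("sampling_rate must be > 0", call. = FALSE)
  if (length(channel_names) != nrow(samples)) {
    stop("channel_names length must equal the channel (row) count",
         call. = FALSE)
  }
  duration <- ncol(samples) / sampling_rate
  if (length(seizure_onsets) != length(seizure_offsets)) {
    stop("seizure_onsets and seizure_offsets must have equal length",
         call. = FALSE)
  }
  if (length(seizure_onsets) > 1 && any(diff(seizure_onsets) <= 0)) {
    stop("seizure onsets must be strictly increasing", call. = FALSE)
  }
  if (any(seizure_offsets <= seizure_onsets)) {
    stop("each seizure offset must exceed its onset", call. = FALSE)
  }
  if (any(seizure_onsets >= duration) || any(seizure_offsets > duration)) {
    stop("seizure annotation beyond recording duration (",
         duration, " s)", call. = FALSE)
  }
  if (any(seizure_onsets < 0)) stop("negative onset time", call. = FALSE)
  rownames(samples) <- channel_names
  structure(
    list(samples = samples, sampling_rate = sampling_rate,
         channel_names = as.character(channel_names),
         seizure_onsets = as.numeric(seizure_onsets),
         seizure_offsets = as.numeric(seizure_offsets),
         duration = duration, source_id = source_id),
    class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording '%s': %d channels, %.1f s @ %g Hz, %d seizure(s)>\n",
              x$source_id, nrow(x$samples), x$duration, x$sampling_rate,
              length(x$seizure_onsets)))
  invisible(x)
}

#' Select and reorder montage channels
#'
#' Matching is case-insensitive after whitespace stripping; the result's
#' rows follow the order of `wanted`.
#'
#' @param rec An [eeg_recording()].
#' @param wanted Ordered character vector of channel labels to keep
#'   (default: the 18-channel [chbmit_montage()]).
#' @return An `eeg_recording` restricted to (and ordered as) `wanted`.
#' @export
select_channels <- function(rec, wanted = chbmit_montage()) {
  stopifnot(inherits(rec, "eeg_recording"))
  norm <- function(s) toupper(gsub("\\s+", "", s))
  have <- norm(rec$channel_names)
  idx <- match(norm(wanted), have)
  if (anyNA(idx)) {
    missing <- wanted[is.na(idx)]
    stop("channel(s) not found: ", paste(missing, collapse = ", "),
         "; available: ", paste(rec$channel_names, collapse = ", "),
         call. = FALSE)
  }
  out <- rec
  out$samples <- rec$samples[idx, , drop = FALSE]
  out$channel_names <- as.character(wanted)
  rownames(out$samples) <- out$channel_names
  out
}

.interval <- function(start, end, label) {
  data.frame(start = start, end = end, label = label,
             stringsAsFactors = FALSE)
}

# complement of a union of intervals within [0, dur)
.complement_intervals <- function(iv, dur) {
  if (nrow(iv) == 0) return(.interval(0, dur, NA_character_)[, 1:2])
  iv <- iv[order(iv$start), , drop = FALSE]
  merged <- list()
  cur <- c(iv$start[1], iv$end[1])
  for (k in seq_len(nrow(iv))[-1]) {
    if (iv$start[k] <= cur[2]) {
      cur[2] <- max(cur[2], iv$end[k])
    } else {
      merged[[length(merged) + 1]] <- cur
      cur <- c(iv$start[k], iv$end[k])
    }
  }
  merged[[length(merged) + 1]] <- cur
  gaps <- list()
  prev_end <- 0
  for (m in merged) {
    if (m[1] > prev_end) gaps[[length(gaps) + 1]] <- c(prev_end, m[1])
    prev_end <- max(prev_end, m[2])
  }
  if (prev_end < dur) gaps[[length(gaps) + 1]] <- c(prev_end, dur)
  if (length(gaps) == 0) return(.interval(numeric(0), numeric(0), character(0))[, 1:2])
  do.call(rbind, lapply(gaps, function(g) data.frame(start = g[1], end = g[2])))
}

#' Label pre-ictal and inter-ictal intervals
#'
#' For each seizure onset `t`, the pre-ictal interval is
#' `[max(0, t - pre_start_offset), t - pre_end_offset)` — by default the span
#' from 1 h to 5 min before onset — truncated at the recording start and at
#' the end of any earlier seizure. Inter-ictal intervals are all stretches at
#' least `inter_guard` away from every seizure (guard before onset and after
#' offset). Ictal spans belong to neither class. Pre-ictal intervals that
#' collapse to zero length (onset too close to the recording start) are
#' skipped with a warning.
#'
#' @param rec An [eeg_recording()].
#' @param pre_start_offset,pre_end_offset Pre-ictal window bounds in seconds
#'   before onset (defaults 3600 and 300).
#' @param inter_guard Minimum distance (s) from any seizure for inter-ictal
#'   data (default 4 h).
#' @return Data frame with columns `start`, `end`, `label`
#'   (`"pre_ictal"`/`"inter_ictal"`), sorted by `start`, intervals disjoint.
#' @export
label_intervals <- function(rec, pre_start_offset = 3600,
                            pre_end_offset = 300, inter_guard = 14400) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (pre_start_offset <= 0 || pre_end_offset <= 0) {
    stop("offsets must be positive", call. = FALSE)
  }
  if (pre_start_offset <= pre_end_offset) {
    stop("pre_start_offset must exceed pre_end_offset", call. = FALSE)
  }
  onsets <- rec$seizure_onsets
  offsets <- rec$seizure_offsets
  dur <- rec$duration

  pre <- .interval(numeric(0), numeric(0), character(0))
  for (i in seq_along(onsets)) {
    s <- max(0, onsets[i] - pre_start_offset)
    if (i > 1) s <- max(s, max(offsets[seq_len(i - 1)]))
    e <- onsets[i] - pre_end_offset
    if (e <= s) {
      warning("pre-ictal interval for onset at ", onsets[i],
              " s is empty; skipped", call. = FALSE)
      next
    }
    pre <- rbind(pre, .interval(s, e, "pre_ictal"))
  }

  if (length(onsets) > 0) {
    guarded <- .interval(pmax(0, onsets - inter_guard),
                         pmin(dur, offsets + inter_guard), "x")
    excl <- rbind(guarded[, 1:2], pre[, 1:2])
  } else {
    excl <- pre[, 1:2]
  }
  inter <- .complement_intervals(excl, dur)
  out <- pre
  if (nrow(inter) > 0) {
    out <- rbind(out, .interval(inter$start, inter$end, "inter_ictal"))
  }
  out <- out[out$end > out$start, , drop = FALSE]
  out[order(out$start), , drop = FALSE]
}

#' Cut one labeled interval into fixed-length windows
#'
#' Windows start at `iv$start + k * stride` with
#' `stride = window_seconds * (1 - overlap_fraction)`; an interval shorter
#' than one window yields an empty list (not an error).
#'
#' @param rec An [eeg_recording()].
#' @param iv One-row data frame (or list) with `start`, `end`, `label`.
#' @param window_seconds Window length in seconds (default 5).
#' @param overlap_fraction Fraction of window shared by consecutive windows,
#'   in `[0, 1)`.
#' @return List of `eeg_segment` objects (fields `samples`, `label`,
#'   `start_time`, `source_id`, `sampling_rate`).
#' @export
segment_interval <- function(rec, iv, window_seconds = 5,
                             overlap_fraction = 0) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (overlap_fraction < 0 || overlap_fraction >= 1) {
    stop("overlap_fraction must be in [0, 1)", call. = FALSE)
  }
  len <- iv$end - iv$start
  if (len < window_seconds) return(list())
  stride <- window_seconds * (1 - overlap_fraction)
  n_win <- floor((len - window_seconds) / stride) + 1
  wsamp <- round(window_seconds * rec$sampling_rate)
  starts <- iv$start + (seq_len(n_win) - 1) * stride
  lapply(starts, function(s0) {
    i0 <- round(s0 * rec$sampling_rate) + 1L
    seg <- rec$samples[, i0:(i0 + wsamp - 1L), drop = FALSE]
    structure(list(samples = seg, label = iv$label, start_time = s0,
                   source_id = rec$source_id,
                   sampling_rate = rec$sampling_rate),
              class = "eeg_segment")
  })
}

#' @export
print.eeg_segment <- function(x, ...) {
  cat(sprintf("<eeg_segment '%s' @ %.1f s: %d x %d, %s>\n", x$source_id,
              x$start_time, nrow(x$samples), ncol(x$samples), x$label))
  invisible(x)
}

#' Label and segment a whole recording
#'
#' Applies [label_intervals()] and then [segment_interval()] to every
#' labeled interval, using 50 % window overlap for pre-ictal intervals and
#' no overlap for inter-ictal ones by default — the overlap imbalance is the
#' device that roughly equalizes the two class counts, since inter-ictal
#' time dominates.
#'
#' @inheritParams label_intervals
#' @inheritParams segment_interval
#' @param pre_overlap,inter_overlap Overlap fractions per class
#'   (defaults 0.5 and 0).
#' @return List of `eeg_segment` objects.
#' @export
segment_recording <- function(rec, window_seconds = 5, pre_overlap = 0.5,
                              inter_overlap = 0, pre_start_offset = 3600,
                              pre_end_offset = 300, inter_guard = 14400) {
  ivs <- label_intervals(rec, pre_start_offset, pre_end_offset, inter_guard)
  segs <- list()
  for (k in seq_len(nrow(ivs))) {
    ov <- if (ivs$label[k] == "pre_ictal") pre_overlap else inter_overlap
    segs <- c(segs, segment_interval(rec, ivs[k, ], window_seconds, ov))
  }
  segs
}

#' Write a segment manifest
#'
#' @param segments List of `eeg_segment` objects.
#' @param path Output CSV path (columns `source_id,start_time,label`).
#' @return `path`, invisibly.
#' @export
write_segment_manifest <- function(segments, path) {
  df <- data.frame(
    source_id = vapply(segments, `[[`, "", "source_id"),
    start_time = vapply(segments, `[[`, 0, "start_time"),
    label = vapply(segments, `[[`, "", "label"))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
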