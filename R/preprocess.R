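#' Cut a record into fixed-length synchronous segments
#'
#' Non-overlapping consecutive windows of exactly `length_s * fs` samples,
#' cut synchronously across the ECG, PPG and ABP channels; a trailing
#' partial window is discarded. A record shorter than one window yields an
#' empty list.
#'
#' @param record A `bp_record` (see [generate_record()] / [read_record()]).
#' @param length_s Window length in seconds (8 in the full pipeline, giving
#'   1000 samples at 125 Hz).
#' @return List of raw segments: each a list with `ecg`, `ppg`, `abp`, `fs`,
#'   `start` (1-based index of the first sample) and `subject_id`.
#' @export
segment_record <- function(record, length_s = 8) {
  stopifnot(inherits(record, "bp_record"), length_s > 0)
  w <- round(length_s * record$fs)
  n_seg <- floor(length(record$abp) / w)
  if (n_seg == 0) return(list())
  lapply(seq_len(n_seg), function(i) {
    idx <- ((i - 1) * w + 1):(i * w)
    list(ecg = record$ecg[idx], ppg = record$ppg[idx], abp = record$abp[idx],
         fs = record$fs, start = idx[1], subject_id = record$subject_id)
  })
}

# Strict local maxima: x[i] > x[i-1] and x[i] > x[i+1].
.local_maxima <- function(x) {
  n <- length(x)
  if (n < 3) return(integer(0))
  core <- which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] > x[3:n]) + 1L
  core
}

#' Constrained ABP beat detection
#'
#' Finds systolic peaks and diastolic troughs in an arterial pressure trace
#' under the two validity constraints used to clean reference labels:
#'
#' * a peak-to-peak time limit — any candidate peak closer than 0.6 s to a
#'   higher retained peak is suppressed (greedy, highest first), which
#'   rejects dicrotic false peaks;
#' * amplitude limits — peaks must lie in \[80, 180\] mmHg and troughs in
#'   \[60, 130\] mmHg; out-of-range beats are discarded.
#'
#' Each trough is the minimum between two retained consecutive peaks, so
#' peaks and troughs strictly alternate in the result.
#'
#' @param abp Numeric pressure trace in mmHg.
#' @param fs Sampling rate in Hz.
#' @param sbp_limits,dbp_limits Inclusive amplitude windows in mmHg.
#' @param min_spacing_s Minimum peak-to-peak spacing in seconds (exclusive:
#'   retained peaks are strictly further apart than this).
#' @return A `beat_set`: list with 1-based `peak_indices`, `trough_indices`,
#'   `peak_values`, `trough_values`, `fs`, and the bookkeeping counts
#'   `n_candidates` (strict local maxima before any filtering) and
#'   `n_amplitude_rejected` (beats dropped by the amplitude limits). A
#'   constant or feature-free signal gives an empty `beat_set`.
#' @export
detect_abp_beats <- function(abp, fs, sbp_limits = c(80, 180),
                             dbp_limits = c(60, 130), min_spacing_s = 0.6) {
  stopifnot(fs > 0)
  if (any(!is.finite(abp))) stop("'abp' must be finite", call. = FALSE)
  cand <- .local_maxima(abp)
  min_gap <- round(min_spacing_s * fs)

  # Greedy highest-first suppression within the exclusion window.
  keep <- integer(0)
  if (length(cand)) {
    for (i in cand[order(abp[cand], decreasing = TRUE)]) {
      if (!length(keep) || all(abs(keep - i) > min_gap)) keep <- c(keep, i)
    }
    keep <- sort(keep)
  }

  in_amp <- abp[keep] >= sbp_limits[1] & abp[keep] <= sbp_limits[2]
  n_amp_rej <- sum(!in_amp)
  peaks <- keep[in_amp]

  troughs <- integer(0)
  repeat {
    troughs <- integer(0)
    bad <- 0L
    if (length(peaks) >= 2) {
      for (j in seq_len(length(peaks) - 1)) {
        span <- (peaks[j] + 1L):(peaks[j + 1] - 1L)
        tr <- span[which.min(abp[span])]
        if (abp[tr] < dbp_limits[1] || abp[tr] > dbp_limits[2]) {
          bad <- j + 1L # drop the later peak of the offending pair
          break
        }
        troughs <- c(troughs, tr)
      }
    }
    if (bad == 0L) break
    peaks <- peaks[-bad]
    n_amp_rej <- n_amp_rej + 1L
  }

  structure(list(
    peak_indices = peaks, trough_indices = troughs,
    peak_values = abp[peaks], trough_values = abp[troughs],
    fs = fs, n_candidates = length(cand), n_amplitude_rejected = n_amp_rej
  ), class = "beat_set")
}

#' @export
print.beat_set <- function(x, ...) {
  cat(sprintf(
    "<beat_set> %d peaks / %d troughs (%d candidates, %d amplitude-rejected)\n",
    length(x$peak_indices), length(x$trough_indices),
    x$n_candidates, x$n_amplitude_rejected
  ))
  invisible(x)
}

#' Reference blood-pressure labels from detected beats
#'
#' Aggregates beat-level systolic peaks and diastolic troughs over a window
#' into a single reference triple. SBP and DBP are the mean (or median) of
#' the retained peak and trough values; the mean arterial pressure follows
#' the standard formula MAP = (SBP + 2 DBP) / 3.
#'
#' @param beats A `beat_set` with at least one peak and one trough.
#' @param aggregate `"mean"` (default) or `"median"`.
#' @return A `bp_labels` list with `sbp`, `dbp`, `map` in mmHg.
#' @examples
#' # single beat: peak 120, trough 60 -> MAP (120 + 2 * 60) / 3 = 80
#' @export
extract_labels <- function(beats, aggregate = c("mean", "median")) {
  stopifnot(inherits(beats, "beat_set"))
  aggregate <- match.arg(aggregate)
  if (!length(beats$peak_values) || !length(beats$trough_values)) {
    stop("empty beat set: no labels can be extracted", call. = FALSE)
  }
  agg <- if (aggregate == "mean") mean else stats::median
  sbp <- agg(beats$peak_values)
  dbp <- agg(beats$trough_values)
  structure(list(sbp = sbp, dbp = dbp, map = (sbp + 2 * dbp) / 3),
            class = "bp_labels")
}

#' Rescale a signal to \[-1, 1\]
#'
#' Per-segment, per-channel amplitude normalization
#' `2 * (x - min) / (max - min) - 1`, so the minimum maps to -1 and the
#' maximum to +1 exactly. A constant channel has no amplitude to normalize
#' and is an error (the pipeline rejects such segments).
#'
#' @param x Numeric vector.
#' @return Normalized vector with `min = -1`, `max = +1`.
#' @examples
#' layer_normalize(c(1, 2, 3))
#' @export
layer_normalize <- function(x) {
  r <- range(x)
  if (!all(is.finite(r))) stop("signal must be finite", call. = FALSE)
  if (r[2] <= r[1]) stop("constant channel cannot be normalized", call. = FALSE)
  2 * (x - r[1]) / (r[2] - r[1]) - 1
}

#' Full preprocessing pipeline: record to model-ready segments
#'
#' Composes [segment_record()], per-segment [detect_abp_beats()] and
#' [extract_labels()] on the raw ABP, [dwt_denoise()] of ECG (7 levels) and
#' PPG (8 levels), and [layer_normalize()]. A segment is dropped when it has
#' no valid beats, when any beat was rejected by the amplitude limits, or
#' when an aggregated label falls outside \[60, 180\] mmHg. The ABP channel
#' is consumed only for labels and never enters the model input.
#'
#' @param record A `bp_record`.
#' @param length_s Segment length in seconds.
#' @param ecg_levels,ppg_levels Wavelet decomposition depths.
#' @param aggregate Label aggregation rule, see [extract_labels()].
#' @param denoise Apply wavelet denoising (disable for already-clean input).
#' @param min_duration_s Record-level gate: records shorter than this are
#'   rejected outright (0 disables; 480 reproduces the 8-min rule used for
#'   whole-record screening of clinical data).
#' @return List of `bp_segment` objects (`x`: 2 x 1000 matrix, rows ECG then
#'   PPG; `labels`: [extract_labels()] triple; `source`: subject and start
#'   index), with an attached `"log"` attribute — one row per candidate
#'   window stating acceptance or the rejection reason.
#' @export
build_segments <- function(record, length_s = 8, ecg_levels = 7,
                           ppg_levels = 8, aggregate = "mean",
                           denoise = TRUE, min_duration_s = 0) {
  stopifnot(inherits(record, "bp_record"))
  log <- data.frame(subject_id = character(0), start = integer(0),
                    accepted = logical(0), reason = character(0))
  if (length(record$abp) / record$fs < min_duration_s) {
    out <- list()
    attr(out, "log") <- data.frame(subject_id = record$subject_id, start = 1L,
                                   accepted = FALSE, reason = "record_too_short")
    return(out)
  }
  raw <- segment_record(record, length_s)
  out <- list()
  for (seg in raw) {
    reason <- "accepted"
    labels <- NULL
    beats <- tryCatch(detect_abp_beats(seg$abp, seg$fs), error = function(e) NULL)
    if (is.null(beats) || !length(beats$peak_indices) ||
        !length(beats$trough_indices)) {
      reason <- "no_beats"
    } else if (beats$n_amplitude_rejected > 0) {
      reason <- "out_of_range_beat"
    } else {
      labels <- extract_labels(beats, aggregate)
      if (any(unlist(labels) < 60) || any(unlist(labels) > 180)) {
        reason <- "label_range"
      }
    }
    if (reason == "accepted") {
      x <- tryCatch({
        ecg <- seg$ecg
        ppg <- seg$ppg
        if (denoise) {
          ecg <- dwt_denoise(ecg, ecg_levels)
          ppg <- dwt_denoise(ppg, ppg_levels)
        }
        rbind(ecg = layer_normalize(ecg), ppg = layer_normalize(ppg))
      }, error = function(e) NULL)
      if (is.null(x)) {
        reason <- "degenerate_channel"
      } else {
        out[[length(out) + 1]] <- structure(
          list(x = x, labels = labels,
               source = list(subject_id = seg$subject_id, start = seg$start)),
          class = "bp_segment"
        )
      }
    }
    log <- rbind(log, data.frame(subject_id = seg$subject_id, start = seg$start,
                                 accepted = reason == "accepted",
                                 reason = reason))
  }
  attr(out, "log") <- log
  out
}
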