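#' Read a record from CSV
#'
#' Expects a header row and columns `t` (seconds, monotone increasing),
#' `ecg`, `ppg`, `abp`. The sampling rate is inferred from the median
#' spacing of `t` unless supplied.
#'
#' @param path CSV file path.
#' @param fs Optional sampling rate in Hz, overriding the inferred value.
#' @param subject_id Identifier; defaults to the file name.
#' @return A `bp_record`.
#' @export
read_record <- function(path, fs = NULL, subject_id = NULL) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  df <- utils::read.csv(path)
  missing_cols <- setdiff(c("t", "ecg", "ppg", "abp"), names(df))
  if (length(missing_cols)) {
    stop(sprintf("record CSV lacks column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  if (nrow(df) >= 2 && any(diff(df$t) <= 0)) {
    stop("time column 't' must be strictly increasing", call. = FALSE)
  }
  if (is.null(fs)) {
    if (nrow(df) < 2) stop("cannot infer fs from fewer than 2 samples", call. = FALSE)
    fs <- 1 / stats::median(diff(df$t))
  }
  structure(list(ecg = df$ecg, ppg = df$ppg, abp = df$abp, fs = fs,
                 subject_id = subject_id %||% basename(path),
                 annotations = NULL),
            class = "bp_record")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a record to CSV
#'
#' Columns `t`, `ecg`, `ppg`, `abp`; a write-then-read round trip agrees to
#' within floating-point printing precision.
#'
#' @param record A `bp_record`.
#' @param path Destination file.
#' @return Invisibly, `path`.
#' @export
write_record <- function(record, path) {
  stopifnot(inherits(record, "bp_record"))
  n <- length(record$abp)
  df <- data.frame(t = (seq_len(n) - 1) / record$fs,
                   ecg = record$ecg, ppg = record$ppg, abp = record$abp)
  utils::write.csv(format(df, digits = 15, trim = TRUE), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write / read preprocessed segments
#'
#' Plain-text layout: `labels.csv` holds one row per segment (id, subject,
#' start index, SBP/DBP/MAP labels); `signals.csv` holds the flattened
#' 2 x L input matrix per row (ECG samples then PPG samples).
#'
#' @param segments List of `bp_segment` objects.
#' @param dir Directory (created if absent).
#' @return `write_segments()`: invisibly, `dir`. `read_segments()`: the
#'   reconstructed list of `bp_segment` objects.
#' @export
write_segments <- function(segments, dir) {
  stopifnot(length(segments) >= 1)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  labels <- data.frame(
    seg_id = seq_along(segments),
    subject_id = vapply(segments, function(s) s$source$subject_id, character(1)),
    start = vapply(segments, function(s) s$source$start, numeric(1)),
    sbp = vapply(segments, function(s) s$labels$sbp, numeric(1)),
    dbp = vapply(segments, function(s) s$labels$dbp, numeric(1)),
    map = vapply(segments, function(s) s$labels$map, numeric(1))
  )
  utils::write.csv(labels, file.path(dir, "labels.csv"), row.names = FALSE)
  sig <- t(vapply(segments, function(s) as.vector(t(s$x)),
                  numeric(length(segments[[1]]$x))))
  utils::write.table(cbind(seg_id = labels$seg_id, signif(sig, 12)),
                     file.path(dir, "signals.csv"),
                     sep = ",", row.names = FALSE, col.names = TRUE)
  invisible(dir)
}

#' @rdname write_segments
#' @export
read_segments <- function(dir) {
  labels <- utils::read.csv(file.path(dir, "labels.csv"))
  sig <- as.matrix(utils::read.csv(file.path(dir, "signals.csv")))
  L <- (ncol(sig) - 1) / 2
  lapply(seq_len(nrow(labels)), function(i) {
    v <- sig[i, -1]
    x <- rbind(ecg = v[1:L], ppg = v[(L + 1):(2 * L)])
    structure(list(
      x = unname(x) * 1, # strip names
      labels = structure(list(sbp = labels$sbp[i], dbp = labels$dbp[i],
                              map = labels$map[i]), class = "bp_labels"),
      source = list(subject_id = labels$subject_id[i], start = labels$start[i])
    ), class = "bp_segment")
  })
}

#' Run-configuration round trip
#'
#' Serializes the nested run configuration (paths, model and training
#' hyperparameters, preprocessing toggles, seed) as plain-text `key: value`
#' YAML; `read_run_config(write_run_config(cfg, path))` returns `cfg`.
#'
#' @param config Named list (nesting allowed; scalar and vector leaves).
#' @param path File path.
#' @return `write_run_config()`: invisibly `path`; `read_run_config()`: the
#'   configuration list.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such config: %s", path), call. = FALSE)
  yaml::read_yaml(path)
}

#' Adapter for a locally supplied clinical waveform extract (stub)
#'
#' Optional entry point for the public cuff-less blood-pressure extract
#' (PPG/ABP/ECG channel order, 125 Hz). The data are **not** bundled; the
#' caller must supply a local CSV with columns `ppg`, `abp`, `ecg` (or three
#' unnamed columns in that order). A plausibility check on the ABP channel
#' (median within 40--250 mmHg) catches channel-order misdeclarations.
#' Never exercised by the automated tests except through tiny synthetic
#' fixtures.
#'
#' @param path Local CSV file.
#' @param fs Sampling rate (125 Hz for the published extract).
#' @return List with one `bp_record`.
#' @export
read_uci_extract <- function(path, fs = 125) {
  if (!file.exists(path)) {
    stop("external data not bundled: supply a local copy of the extract",
         call. = FALSE)
  }
  df <- utils::read.csv(path)
  if (!all(c("ppg", "abp", "ecg") %in% names(df))) {
    if (ncol(df) != 3) {
      stop("expected columns ppg, abp, ecg (or exactly three unnamed columns)",
           call. = FALSE)
    }
    names(df) <- c("ppg", "abp", "ecg")
  }
  med <- stats::median(df$abp)
  if (!is.finite(med) || med < 40 || med > 250) {
    stop(sprintf(
      "ABP channel median %.3g outside the plausible 40-250 mmHg window; check the channel order",
      med
    ), call. = FALSE)
  }
  list(structure(list(ecg = df$ecg, ppg = df$ppg, abp = df$abp, fs = fs,
                      subject_id = basename(path), annotations = NULL),
                 class = "bp_record"))
}
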