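#' Parameters of the synthetic physiological record generator
#'
#' Bundles and validates every knob of [generate_record()]. The generator
#' emulates the signal properties the preprocessing pipeline assumes:
#' periodic arterial pressure beats with controllable per-beat systolic and
#' diastolic values, a dicrotic wave after each systolic peak (the source of
#' false peaks in real ABP), an ECG R-wave preceding each ABP peak by a pulse
#' transit delay, and a PPG formed as a smoothed, delayed copy of the pulse
#' train. Baseline drift (below 0.5 Hz) and a high-frequency tone (above
#' 31 Hz) can be injected into the bands targeted by the wavelet denoiser.
#'
#' @param sampling_rate Sampling rate in Hz (125 for the full pipeline).
#' @param duration Record duration in seconds.
#' @param heart_rate Beats per minute; the beat period must exceed
#'   `dicrotic_delay`.
#' @param sbp_series Per-beat systolic targets in mmHg; a scalar is recycled
#'   over all beats.
#' @param dbp_series Per-beat diastolic targets in mmHg; scalar recycled.
#' @param dicrotic_rel_amp Dicrotic bump amplitude as a fraction in \[0, 1)
#'   of the pulse amplitude; at the default 0.1 the bump is a shoulder on
#'   the diastolic decay, while values above roughly 0.2 turn it into a
#'   local maximum (a detectable false peak).
#' @param dicrotic_delay Seconds between the systolic peak and the bump
#'   centre.
#' @param ptt_delay Seconds between the ECG R-wave and the ABP systolic peak.
#' @param drift_amp,drift_freq Baseline-wander sinusoid amplitude (mmHg on
#'   ABP, a.u. on ECG/PPG) and frequency in Hz (must stay below 0.5 Hz).
#' @param hf_noise_sd,hf_noise_band High-frequency tone amplitude and its
#'   frequency in Hz (must lie above 31 Hz and below Nyquist).
#' @param seed Integer seed controlling the random phases; records are
#'   bit-identical under the same seed.
#' @return A validated `physio_params` list.
#' @export
physio_params <- function(sampling_rate = 125, duration = 60, heart_rate = 75,
                          sbp_series = 120, dbp_series = 80,
                          dicrotic_rel_amp = 0.1, dicrotic_delay = 0.25,
                          ptt_delay = 0.2,
                          drift_amp = 0, drift_freq = 0.1,
                          hf_noise_sd = 0, hf_noise_band = 40,
                          seed = 1L) {
  stopifnot(sampling_rate > 0, duration > 0, heart_rate > 0)
  if (60 / heart_rate <= dicrotic_delay) {
    stop("beat period must exceed 'dicrotic_delay'", call. = FALSE)
  }
  if (dicrotic_rel_amp < 0 || dicrotic_rel_amp >= 1) {
    stop("'dicrotic_rel_amp' must lie in [0, 1)", call. = FALSE)
  }
  n_beats <- floor(duration * heart_rate / 60)
  if (n_beats < 1) stop("duration too short for a single beat", call. = FALSE)
  for (nm in c("sbp_series", "dbp_series")) {
    v <- get(nm)
    if (!length(v) %in% c(1L, n_beats)) {
      stop(sprintf("'%s' must have length 1 or %d (the beat count)", nm, n_beats),
           call. = FALSE)
    }
  }
  sbp_series <- rep_len(sbp_series, n_beats)
  dbp_series <- rep_len(dbp_series, n_beats)
  if (any(sbp_series <= dbp_series)) {
    stop("every per-beat SBP must exceed the matching DBP", call. = FALSE)
  }
  if (drift_amp > 0 && drift_freq >= sampling_rate / 2) {
    stop("'drift_freq' must lie below the Nyquist frequency", call. = FALSE)
  }
  structure(list(
    sampling_rate = sampling_rate, duration = duration,
    heart_rate = heart_rate, n_beats = n_beats,
    sbp_series = sbp_series, dbp_series = dbp_series,
    dicrotic_rel_amp = dicrotic_rel_amp, dicrotic_delay = dicrotic_delay,
    ptt_delay = ptt_delay,
    drift_amp = drift_amp, drift_freq = drift_freq,
    hf_noise_sd = hf_noise_sd, hf_noise_band = hf_noise_band,
    seed = as.integer(seed)
  ), class = "physio_params")
}

# Raised-cosine systolic upstroke and diastolic decay plus a Gaussian
# dicrotic bump, rescaled per beat so the requested SBP/DBP are exact.
.beat_shape <- function(m, fs, period_s, dicrotic_rel_amp, dicrotic_delay,
                        sigma_s = 0.05) {
  t <- (seq_len(m) - 1) / fs
  t_peak <- min(0.15, 0.3 * period_s)
  b <- ifelse(
    t <= t_peak,
    0.5 - 0.5 * cos(pi * t / t_peak),
    0.5 + 0.5 * cos(pi * (t - t_peak) / (period_s - t_peak))
  )
  centre <- t_peak + dicrotic_delay
  g <- dicrotic_rel_amp * exp(-0.5 * ((t - centre) / sigma_s)^2)
  s <- b + g
  list(shape = (s - min(s)) / (max(s) - min(s)),
       dicrotic_index = which.min(abs(t - centre)))
}

#' Generate a synchronized synthetic ECG/PPG/ABP record
#'
#' Builds a noise-free pulse train whose k-th beat attains exactly
#' `sbp_series[k]` at its systolic peak and `dbp_series[k]` at its onset
#' trough, then adds the configured drift and high-frequency artifacts.
#' Per-beat ground-truth annotations travel with the record so downstream
#' beat detection can be checked exactly: onset, systolic peak index/value,
#' the beat's own trough (its onset, where the requested DBP is exact), the
#' inter-beat trough (the true minimum strictly between consecutive peaks,
#' which under per-beat DBP variation need not be the next onset), the
#' dicrotic bump position, and an in-range flag for the amplitude limits.
#'
#' @param params A [physio_params()] object.
#' @param subject_id Identifier stored on the record.
#' @return A `bp_record`: list with `ecg`, `ppg`, `abp`, `fs`, `subject_id`
#'   and an `annotations` data frame (1-based sample indices).
#' @examples
#' rec <- generate_record(physio_params(duration = 8))
#' nrow(rec$annotations) # 10 beats at 75 bpm
#' @export
generate_record <- function(params, subject_id = "synthetic") {
  stopifnot(inherits(params, "physio_params"))
  p <- params
  fs <- p$sampling_rate
  n <- round(p$duration * fs)
  spp <- fs * 60 / p$heart_rate # samples per beat period (possibly fractional)
  onsets <- floor((seq_len(p$n_beats) - 1) * spp) + 1L

  set.seed(p$seed)
  abp <- numeric(n)
  ann <- data.frame(
    beat = seq_len(p$n_beats), onset = onsets,
    peak_index = NA_integer_, peak_value = NA_real_,
    trough_index = onsets, trough_value = p$dbp_series,
    dicrotic_index = NA_integer_,
    in_range = p$sbp_series >= 80 & p$sbp_series <= 180 &
      p$dbp_series >= 60 & p$dbp_series <= 130
  )
  for (k in seq_len(p$n_beats)) {
    to <- if (k < p$n_beats) onsets[k + 1] - 1L else min(n, floor(k * spp))
    m <- to - onsets[k] + 1L
    bs <- .beat_shape(m, fs, m / fs, p$dicrotic_rel_amp, p$dicrotic_delay)
    abp[onsets[k]:to] <- p$dbp_series[k] +
      (p$sbp_series[k] - p$dbp_series[k]) * bs$shape
    ann$peak_index[k] <- onsets[k] + which.max(bs$shape) - 1L
    ann$peak_value[k] <- p$sbp_series[k]
    ann$dicrotic_index[k] <- onsets[k] + bs$dicrotic_index - 1L
  }
  tail_start <- if (p$n_beats > 0) min(n, floor(p$n_beats * spp)) + 1L else 1L
  if (tail_start <= n) abp[tail_start:n] <- p$dbp_series[p$n_beats]

  # Inter-beat troughs: the true minimum of the constructed signal strictly
  # between consecutive systolic peaks (row k holds the trough after beat k).
  ann$inter_trough_index <- NA_integer_
  ann$inter_trough_value <- NA_real_
  if (p$n_beats >= 2) {
    for (k in seq_len(p$n_beats - 1)) {
      span <- (ann$peak_index[k] + 1L):(ann$peak_index[k + 1] - 1L)
      ann$inter_trough_index[k] <- span[which.min(abp[span])]
      ann$inter_trough_value[k] <- abp[ann$inter_trough_index[k]]
    }
  }

  # ECG: narrow triangular R-spikes preceding each ABP peak, with small
  # Gaussian P and T bumps. Amplitudes in arbitrary units.
  t_axis <- (seq_len(n) - 1) / fs
  ecg <- numeric(n)
  add_gauss <- function(sig, centre_idx, amp, sigma_s) {
    ct <- (centre_idx - 1) / fs
    sig + amp * exp(-0.5 * ((t_axis - ct) / sigma_s)^2)
  }
  r_half <- max(2L, round(0.02 * fs))
  for (k in seq_len(p$n_beats)) {
    r_idx <- ann$peak_index[k] - round(p$ptt_delay * fs)
    if (r_idx - r_half < 1 || r_idx + r_half > n) next
    tri <- 1 - abs(seq(-r_half, r_half)) / r_half
    idx <- (r_idx - r_half):(r_idx + r_half)
    ecg[idx] <- ecg[idx] + tri
    ecg <- add_gauss(ecg, r_idx - round(0.16 * fs), 0.15, 0.03)
    ecg <- add_gauss(ecg, r_idx + round(0.25 * fs), 0.25, 0.05)
  }

  # PPG: low-pass-filtered, delayed, rescaled copy of the pulse train.
  pulse <- (abp - min(abp)) / max(max(abp) - min(abp), .Machine$double.eps)
  bf <- signal::butter(2, min(8 / (fs / 2), 0.99), type = "low")
  ppg <- as.numeric(signal::filtfilt(bf, pulse))
  lag <- round(0.05 * fs)
  ppg <- c(rep(ppg[1], lag), ppg)[seq_len(n)]
  rng <- range(ppg)
  ppg <- (ppg - rng[1]) / max(rng[2] - rng[1], .Machine$double.eps)

  rec <- structure(list(ecg = ecg, ppg = ppg, abp = abp, fs = fs,
                        subject_id = subject_id, annotations = ann,
                        params = p),
                   class = "bp_record")
  if (p$drift_amp > 0 || p$hf_noise_sd > 0) {
    rec <- inject_artifacts(rec,
      drift_amp = p$drift_amp, drift_freq = p$drift_freq,
      hf_noise_sd = p$hf_noise_sd, hf_noise_band = p$hf_noise_band,
      seed = p$seed
    )
  }
  rec
}

#' @export
print.bp_record <- function(x, ...) {
  cat(sprintf(
    "<bp_record> subject %s: %d samples at %g Hz (%.1f s), %d annotated beats\n",
    x$subject_id, length(x$abp), x$fs, length(x$abp) / x$fs,
    if (is.null(x$annotations)) 0L else nrow(x$annotations)
  ))
  invisible(x)
}

#' Inject artifacts into a record
#'
#' Returns a corrupted copy of `record`; the input is untouched. Drift is a
#' sinusoid below 0.5 Hz added to all three channels; high-frequency noise is
#' a tone above 31 Hz; `false_peak_boost` raises the dicrotic bump of every
#' annotated beat by `boost * (SBP - DBP)` so the bumps become local maxima
#' that a naive peak scan counts as extra beats. When only the deterministic
#' bump boost is applied (no drift, no noise) the per-beat peak/trough
#' annotations are recomputed from the corrupted signal, which is still an
#' exact ground truth.
#'
#' @param record A `bp_record`.
#' @param drift_amp,drift_freq Baseline sinusoid amplitude and frequency (Hz,
#'   below 0.5).
#' @param hf_noise_sd,hf_noise_band Tone amplitude and frequency (Hz, above
#'   31 and below Nyquist).
#' @param false_peak_boost Extra dicrotic amplitude as a fraction of the
#'   pulse amplitude.
#' @param seed Seed for the random phases.
#' @return A new `bp_record`.
#' @export
inject_artifacts <- function(record, drift_amp = 0, drift_freq = 0.1,
                             hf_noise_sd = 0, hf_noise_band = 40,
                             false_peak_boost = 0, seed = 1L) {
  stopifnot(inherits(record, "bp_record"))
  fs <- record$fs
  if (drift_amp > 0) {
    if (drift_freq >= fs / 2) stop("'drift_freq' at or above Nyquist", call. = FALSE)
    if (drift_freq >= 0.5) {
      stop("'drift_freq' must lie below 0.5 Hz, the band the denoiser removes",
           call. = FALSE)
    }
  }
  if (hf_noise_sd > 0 && (hf_noise_band <= 31 || hf_noise_band >= fs / 2)) {
    stop("'hf_noise_band' must lie in (31, Nyquist) Hz", call. = FALSE)
  }
  out <- record
  n <- length(record$abp)
  t_axis <- (seq_len(n) - 1) / fs

  if (false_peak_boost > 0 && !is.null(record$annotations)) {
    ann <- record$annotations
    p <- record$params
    for (k in seq_len(nrow(ann))) {
      amp <- false_peak_boost * (p$sbp_series[k] - p$dbp_series[k])
      ct <- (ann$dicrotic_index[k] - 1) / fs
      out$abp <- out$abp + amp * exp(-0.5 * ((t_axis - ct) / 0.05)^2)
    }
    if (drift_amp == 0 && hf_noise_sd == 0) {
      # deterministic corruption: annotations recomputed, still exact
      ends <- c(ann$onset[-1] - 1L, n)
      for (k in seq_len(nrow(ann))) {
        span <- ann$onset[k]:ends[k]
        ann$peak_index[k] <- span[which.max(out$abp[span])]
        ann$peak_value[k] <- out$abp[ann$peak_index[k]]
        ann$trough_index[k] <- span[which.min(out$abp[span])]
        ann$trough_value[k] <- out$abp[ann$trough_index[k]]
      }
      if (nrow(ann) >= 2) {
        for (k in seq_len(nrow(ann) - 1)) {
          span <- (ann$peak_index[k] + 1L):(ann$peak_index[k + 1] - 1L)
          ann$inter_trough_index[k] <- span[which.min(out$abp[span])]
          ann$inter_trough_value[k] <- out$abp[ann$inter_trough_index[k]]
        }
      }
      out$annotations <- ann
    }
  }

  set.seed(as.integer(seed))
  if (drift_amp > 0) {
    phase <- stats::runif(1, 0, 2 * pi)
    drift <- drift_amp * sin(2 * pi * drift_freq * t_axis + phase)
    out$ecg <- out$ecg + drift
    out$ppg <- out$ppg + drift
    out$abp <- out$abp + drift
  }
  if (hf_noise_sd > 0) {
    phase <- stats::runif(1, 0, 2 * pi)
    tone <- hf_noise_sd * sin(2 * pi * hf_noise_band * t_axis + phase)
    out$ecg <- out$ecg + tone
    out$ppg <- out$ppg + tone
    out$abp <- out$abp + tone
  }
  out
}

#' Draw a dataset of synthetic records
#'
#' Samples per-record physiology uniformly from the supplied ranges. The
#' default pressure windows match the label distribution the pipeline
#' accepts: SBP in \[80, 180\] and DBP in \[60, 130\] mmHg. Per-beat values
#' jitter by up to `beat_jitter` mmHg around the record's base pressures
#' while staying inside the windows.
#'
#' @param n_records Number of records (0 gives an empty list).
#' @param param_ranges Named list of `c(min, max)` ranges for `duration`,
#'   `heart_rate`, `sbp`, `dbp`; missing entries use the defaults.
#' @param seed Integer seed; datasets are reproducible under it.
#' @param beat_jitter Per-beat uniform jitter amplitude in mmHg.
#' @return List of `bp_record` objects.
#' @export
make_dataset <- function(n_records, param_ranges = list(), seed = 1L,
                         beat_jitter = 2) {
  stopifnot(n_records >= 0)
  defaults <- list(duration = c(32, 64), heart_rate = c(60, 100),
                   sbp = c(80, 180), dbp = c(60, 130))
  ranges <- utils::modifyList(defaults, param_ranges)
  for (nm in names(defaults)) {
    r <- ranges[[nm]]
    if (length(r) != 2 || r[2] < r[1]) {
      stop(sprintf("range '%s' must be c(min, max) with min <= max", nm),
           call. = FALSE)
    }
  }
  if (n_records == 0) return(list())
  set.seed(as.integer(seed))
  lapply(seq_len(n_records), function(i) {
    dur <- stats::runif(1, ranges$duration[1], ranges$duration[2])
    hr <- stats::runif(1, ranges$heart_rate[1], ranges$heart_rate[2])
    j <- beat_jitter
    sbp_base <- stats::runif(1, ranges$sbp[1] + j, ranges$sbp[2] - j)
    dbp_hi <- min(ranges$dbp[2] - j, sbp_base - 15)
    dbp_base <- stats::runif(1, ranges$dbp[1] + j, max(ranges$dbp[1] + j, dbp_hi))
    n_beats <- floor(dur * hr / 60)
    rec_seed <- sample.int(.Machine$integer.max, 1)
    params <- physio_params(
      duration = dur, heart_rate = hr,
      sbp_series = sbp_base + stats::runif(n_beats, -j, j),
      dbp_series = dbp_base + stats::runif(n_beats, -j, j),
      seed = rec_seed
    )
    generate_record(params, subject_id = sprintf("synthetic-%03d", i))
  })
}
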