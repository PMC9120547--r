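# Shared fixtures and independent oracles used across the suite.

# Strict-local-maxima scan, written independently of the package's detector.
naive_maxima <- function(x) {
  n <- length(x)
  which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] > x[3:n]) + 1L
}

# Spectral power in [lo, hi] Hz via a plain FFT periodogram.
band_power <- function(x, fs, lo, hi) {
  sp <- Mod(stats::fft(x - mean(x)))^2
  f <- (seq_along(x) - 1) * fs / length(x)
  sum(sp[f >= lo & f <= hi & f <= fs / 2])
}

clean_record_8s <- function(seed = 3) {
  generate_record(physio_params(duration = 8, heart_rate = 75, seed = seed))
}

# A tiny architecture used wherever the test only needs a working network.
tiny_config <- function() {
  mstnet_config(input_length = 1000, stem_filters = 4, stem_kernel = 15,
                stream_kernels = c(5, 7, 9), modules_per_stream = 2,
                module_filters = c(4, 8), stream_fc = 8, head_fc = 8)
}

# Reduced-width variant of the full architecture (same depth, narrower).
reduced_config <- function() {
  mstnet_config(stem_filters = 8, module_filters = c(8, 16, 32, 64),
                stream_fc = 64, head_fc = 64)
}

make_segments <- function(n, seed = 11, duration = 32) {
  recs <- make_dataset(ceiling(n / floor(duration / 8)),
                       list(duration = c(duration, duration)), seed = seed)
  segs <- unlist(lapply(recs, build_segments), recursive = FALSE)
  stopifnot(length(segs) >= n)
  segs[seq_len(n)]
}
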