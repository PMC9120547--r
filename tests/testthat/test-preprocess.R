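test_that("segmentation cuts synchronous non-overlapping full windows", {
  rec <- generate_record(physio_params(duration = 80, seed = 2))
  segs <- segment_record(rec)
  expect_length(segs, 10)
  for (i in seq_along(segs)) {
    expect_length(segs[[i]]$abp, 1000)
    expect_identical(segs[[i]]$start, (i - 1L) * 1000L + 1L)
    expect_identical(segs[[i]]$abp, rec$abp[((i - 1) * 1000 + 1):(i * 1000)])
  }
  # partial trailing window discarded; sub-window record gives empty list
  short <- generate_record(physio_params(duration = 8.5, seed = 2))
  expect_length(segment_record(short), 1)
  expect_identical(segment_record(short)[[1]]$start, 1L)
  tiny <- generate_record(physio_params(duration = 7.9, seed = 2))
  expect_length(segment_record(tiny), 0)
})

test_that("beat detection recovers generator annotations exactly on clean records", {
  rec <- clean_record_8s()
  bs <- detect_abp_beats(rec$abp, rec$fs)
  ann <- rec$annotations
  expect_identical(bs$peak_indices, as.integer(ann$peak_index))
  expect_equal(bs$peak_values, ann$peak_value)
  # each trough is the minimum between consecutive peaks; with constant DBP
  # that is the next beat's onset, where the requested DBP is exact
  expect_identical(bs$trough_indices,
                   as.integer(ann$inter_trough_index[-nrow(ann)]))
  expect_identical(bs$trough_indices, as.integer(ann$onset[-1]))
  expect_equal(bs$trough_values, ann$trough_value[-1])
  # alternation and the 0.6-s spacing invariant
  expect_true(all(bs$trough_indices > utils::head(bs$peak_indices, -1) &
                    bs$trough_indices < bs$peak_indices[-1]))
  expect_true(all(diff(bs$peak_indices) > 0.6 * rec$fs))
})

test_that("dicrotic false peaks are suppressed by the peak-to-peak time limit", {
  rec <- clean_record_8s()
  boosted <- inject_artifacts(rec, false_peak_boost = 0.4)
  expect_length(naive_maxima(boosted$abp), 2 * nrow(rec$annotations))
  bs <- detect_abp_beats(boosted$abp, boosted$fs)
  expect_length(bs$peak_indices, nrow(rec$annotations))
  expect_identical(bs$peak_indices, as.integer(boosted$annotations$peak_index))
  expect_identical(bs$n_candidates, 2L * nrow(rec$annotations))
})

test_that("amplitude limits exclude out-of-range beats", {
  p <- physio_params(duration = 8,
                     sbp_series = c(rep(120, 4), 190, rep(120, 5)),
                     dbp_series = 80)
  rec <- generate_record(p)
  bs <- detect_abp_beats(rec$abp, rec$fs)
  expect_length(bs$peak_indices, 9)
  expect_identical(bs$n_amplitude_rejected, 1L)
  expect_true(all(bs$peak_values >= 80 & bs$peak_values <= 180))
  expect_true(all(bs$trough_values >= 60 & bs$trough_values <= 130))

  # a constant trace has no strict maxima at all
  empty <- detect_abp_beats(rep(100, 1000), 125)
  expect_length(empty$peak_indices, 0)
})

test_that("label extraction aggregates beats and applies the MAP formula", {
  mk <- function(pv, tv) {
    structure(list(peak_indices = seq_along(pv) * 100L,
                   trough_indices = seq_along(tv) * 100L + 50L,
                   peak_values = pv, trough_values = tv, fs = 125,
                   n_candidates = length(pv), n_amplitude_rejected = 0L),
              class = "beat_set")
  }
  lab <- extract_labels(mk(120, 60))
  expect_equal(unclass(lab)[c("sbp", "dbp", "map")],
               list(sbp = 120, dbp = 60, map = 80))
  lab2 <- extract_labels(mk(c(110, 130), c(70, 90)))
  expect_equal(lab2$sbp, 120)
  expect_equal(lab2$dbp, 80)
  expect_equal(lab2$map, (120 + 2 * 80) / 3)
  lab3 <- extract_labels(mk(c(100, 100, 160), c(60, 60, 90)),
                         aggregate = "median")
  expect_equal(lab3$sbp, 100)
  expect_error(extract_labels(mk(numeric(0), numeric(0))), "empty")
})

test_that("normalization maps extremes to exactly -1/+1 and is idempotent", {
  expect_equal(layer_normalize(c(1, 2, 3)), c(-1, 0, 1))
  expect_equal(layer_normalize(c(-5, 0, 5))[2], 0)
  expect_error(layer_normalize(c(4, 4, 4)), "constant")
  set.seed(3)
  x <- rnorm(500)
  y <- layer_normalize(x)
  expect_identical(min(y), -1)
  expect_identical(max(y), 1)
  expect_equal(layer_normalize(y), y, tolerance = 1e-14)
})

test_that("build_segments composes the pipeline and drops invalid windows", {
  rec <- generate_record(physio_params(duration = 80, seed = 4),
                         subject_id = "s1")
  segs <- build_segments(rec)
  expect_length(segs, 10)
  log <- attr(segs, "log")
  expect_true(all(log$accepted))
  for (s in segs) {
    expect_identical(dim(s$x), c(2L, 1000L))
    expect_equal(unname(apply(s$x, 1, min)), c(-1, -1))
    expect_equal(unname(apply(s$x, 1, max)), c(1, 1))
    expect_true(all(unlist(s$labels[c("sbp", "dbp", "map")]) >= 60 &
                      unlist(s$labels[c("sbp", "dbp", "map")]) <= 180))
    expect_identical(s$source$subject_id, "s1")
  }
  # labels come from the ABP annotations, not from the model input
  expect_equal(segs[[1]]$labels$sbp, 120, tolerance = 1e-9)
  expect_equal(segs[[1]]$labels$dbp, 80, tolerance = 1e-9)

  # a window with one out-of-range beat is rejected with a logged reason
  sbp <- rep(120, 100)
  sbp[25] <- 190 # falls in the third 8-s window
  rec2 <- generate_record(physio_params(duration = 80, sbp_series = sbp,
                                        dbp_series = 80))
  segs2 <- build_segments(rec2)
  expect_length(segs2, 9)
  log2 <- attr(segs2, "log")
  expect_identical(log2$reason[!log2$accepted], "out_of_range_beat")

  # flat-line ABP yields nothing
  rec3 <- rec
  rec3$abp <- rep(100, length(rec3$abp))
  segs3 <- build_segments(rec3)
  expect_length(segs3, 0)
  expect_true(all(attr(segs3, "log")$reason == "no_beats"))

  # record-level minimum-duration gate
  gated <- build_segments(rec, min_duration_s = 480)
  expect_length(gated, 0)
  expect_identical(attr(gated, "log")$reason, "record_too_short")
})

test_that("the pipeline is a pure function of the record", {
  rec <- generate_record(physio_params(duration = 24, seed = 8))
  s1 <- build_segments(rec)
  s2 <- build_segments(rec)
  expect_identical(s1, s2)
})
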