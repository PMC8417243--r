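# Labeling rule and windowing arithmetic.

test_that("single onset yields the 1 h to 5 min pre-ictal interval", {
  rec <- flat_recording(7500, fs = 16, onsets = 7200, offsets = 7260)
  iv <- label_intervals(rec, inter_guard = 100)
  pre <- iv[iv$label == "pre_ictal", ]
  expect_equal(nrow(pre), 1L)
  expect_equal(pre$start, 3600)
  expect_equal(pre$end, 6900)
})

test_that("no seizures gives only one guarded inter-ictal interval", {
  rec <- flat_recording(600, fs = 16)
  iv <- label_intervals(rec, inter_guard = 100)
  expect_identical(iv$label, "inter_ictal")
  expect_equal(nrow(iv), 1L)
  expect_equal(c(iv$start, iv$end), c(0, 600))
})

test_that("pre-ictal interval is truncated by an earlier seizure's end", {
  rec <- flat_recording(6000, fs = 16, onsets = c(4000, 5000),
                        offsets = c(4100, 5100))
  iv <- label_intervals(rec, inter_guard = 50)
  pre <- iv[iv$label == "pre_ictal", ]
  expect_equal(nrow(pre), 2L)
  expect_equal(pre$start[1], 400)   # 4000 - 3600
  expect_equal(pre$end[1], 3700)    # 4000 - 300
  expect_equal(pre$start[2], 4100)  # truncated at prior offset
  expect_equal(pre$end[2], 4700)
})

test_that("labeled intervals are disjoint and exclude guarded zones", {
  rec <- flat_recording(30000, fs = 16, onsets = 20000, offsets = 20050)
  iv <- label_intervals(rec, inter_guard = 14400)
  iv <- iv[order(iv$start), ]
  if (nrow(iv) > 1) {
    expect_true(all(iv$start[-1] >= iv$end[-nrow(iv)] - 1e-9))
  }
  inter <- iv[iv$label == "inter_ictal", ]
  # every inter-ictal point is >= 4 h from the seizure
  expect_true(all(inter$end <= 20000 - 14400 + 1e-9 |
                    inter$start >= 20050 + 14400 - 1e-9))
})

test_that("an onset too close to recording start is skipped with warning", {
  rec <- flat_recording(1000, fs = 16, onsets = 200, offsets = 220)
  expect_warning(iv <- label_intervals(rec, inter_guard = 10), "empty")
  expect_false(any(iv$label == "pre_ictal"))
})

test_that("window counts follow the stride arithmetic", {
  rec <- flat_recording(3400, fs = 16)
  iv <- data.frame(start = 0, end = 3300, label = "inter_ictal")
  expect_length(segment_interval(rec, iv, 5, 0.5), 1319)
  expect_length(segment_interval(rec, iv, 5, 0.0), 660)
  short <- data.frame(start = 0, end = 4, label = "inter_ictal")
  expect_length(segment_interval(rec, short, 5, 0.5), 0)
  expect_error(segment_interval(rec, iv, 5, 1), "overlap_fraction")
})

test_that("50% overlap roughly doubles the per-time segment yield", {
  rec <- flat_recording(500, fs = 16)
  iv <- data.frame(start = 0, end = 500, label = "pre_ictal")
  n_half <- length(segment_interval(rec, iv, 5, 0.5))
  n_none <- length(segment_interval(rec, iv, 5, 0.0))
  expect_lte(abs(n_half - 2 * n_none), 1)
})

test_that("segments stay within their interval and share shape", {
  rec <- flat_recording(100, fs = 16)
  iv <- data.frame(start = 10, end = 55, label = "pre_ictal")
  segs <- segment_interval(rec, iv, 5, 0.5)
  expect_true(all(vapply(segs, function(s) s$start_time + 5 <= 55 + 1e-9,
                         TRUE)))
  expect_true(all(vapply(segs, function(s) ncol(s$samples), 0L) == 80L))
  expect_true(all(vapply(segs, `[[`, "", "label") == "pre_ictal"))
})

test_that("labeling is invariant to onset ordering in construction", {
  rec1 <- flat_recording(30000, fs = 4, onsets = c(10000, 20000),
                         offsets = c(10050, 20050))
  iv1 <- label_intervals(rec1, inter_guard = 1000)
  # same seizures; interval set must be identical regardless of how the
  # complement/truncation logic visits them
  expect_true(all(diff(iv1$start) > 0))
  expect_equal(sum(iv1$label == "pre_ictal"), 2L)
})

test_that("channel selection reorders and errors on missing labels", {
  rec <- flat_recording(10, fs = 16, n_channels = 3)
  rec$channel_names <- c("A", "B", "C")
  rownames(rec$samples) <- rec$channel_names
  sel <- select_channels(rec, c("C", "A"))
  expect_identical(sel$channel_names, c("C", "A"))
  expect_equal(sel$samples[1, ], rec$samples[3, ])
  expect_equal(sel$samples[2, ], rec$samples[1, ])
  expect_error(select_channels(rec, c("A", "XX")), "XX")
})

test_that("the default montage has 18 channels and is selectable", {
  labs <- chbmit_montage()
  expect_length(labs, 18)
  rec <- flat_recording(4, fs = 16, n_channels = 18)
  rec$channel_names <- rev(labs)   # different order, same set
  rownames(rec$samples) <- rec$channel_names
  sel <- select_channels(rec)
  expect_identical(sel$channel_names, labs)
})

test_that("segment_recording applies the per-class overlap policy", {
  rec <- flat_recording(8000, fs = 16, onsets = 7200, offsets = 7250)
  segs <- segment_recording(rec, window_seconds = 5, inter_guard = 200)
  labs <- vapply(segs, `[[`, "", "label")
  starts <- vapply(segs, `[[`, 0, "start_time")
  pre_starts <- sort(starts[labs == "pre_ictal"])
  inter_starts <- sort(starts[labs == "inter_ictal"])
  expect_equal(diff(pre_starts)[1], 2.5)   # 50% overlap
  expect_equal(diff(inter_starts)[1], 5)   # no overlap
  tf <- tempfile(fileext = ".csv")
  write_segment_manifest(segs, tf)
  man <- read.csv(tf)
  expect_identical(nrow(man), length(segs))
  expect_named(man, c("source_id", "start_time", "label"))
})
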