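test_that("3 s segmentation yields the expected window counts and lengths", {
  # 200 Hz, 60 s: 600-sample windows, floor(12000/600) = 20 of them
  rec200 <- random_recording(n_channels = 2, n_samples = 12000, rate = 200)
  segs <- segment_recording(rec200, window_seconds = 3)
  expect_length(segs, 20)
  expect_true(all(vapply(segs, function(s) ncol(s$data), 0L) == 600L))
  # 128 Hz, 235 s: 384-sample windows, floor(30080/384) = 78
  rec128 <- random_recording(n_channels = 2, n_samples = 30080, rate = 128)
  segs <- segment_recording(rec128, window_seconds = 3)
  expect_length(segs, 78)
  expect_equal(ncol(segs[[1]]$data), 384)
  # recording shorter than one window: empty, not an error
  expect_length(segment_recording(random_recording(n_samples = 100, rate = 50)), 0)
  # non-integer window sample count errors
  expect_error(segment_recording(random_recording(rate = 50), window_seconds = 0.03),
               "whole")
})

test_that("segment count matches floor(n/window) and data reconstructs exactly", {
  set.seed(11)
  for (rep_i in 1:5) {
    n <- sample(50:400, 1)
    rate <- sample(c(10, 20, 50), 1)
    rec <- random_recording(n_channels = 3, n_samples = n, rate = rate,
                            seed = rep_i)
    ws <- 2 * rate
    segs <- segment_recording(rec, window_seconds = 2)
    expect_length(segs, floor(n / ws))
    if (length(segs)) {
      recon <- do.call(cbind, lapply(segs, function(s) s$data))
      expect_identical(recon, rec$data[, seq_len(length(segs) * ws)])
      expect_equal(vapply(segs, function(s) s$window_index, 0L),
                   seq_along(segs) - 1L)
    }
  }
})

test_that("overlapping windows advance by the complementary step", {
  rec <- random_recording(n_channels = 1, n_samples = 100, rate = 10)
  segs <- segment_recording(rec, window_seconds = 2, overlap_fraction = 0.5)
  expect_length(segs, 9)   # starts 0,10,...,80 with 20-sample windows
  expect_identical(segs[[2]]$data[1, 1:10], rec$data[1, 11:20])
})

test_that("rating thresholds follow the strict midpoint rule and are monotone", {
  expect_identical(dimension_label(9), 1L)
  expect_identical(dimension_label(1), 0L)
  expect_identical(dimension_label(5), 0L)      # boundary: strictly greater
  expect_identical(dimension_label(5 + 1e-9), 1L)
  expect_error(dimension_label(0.5), "\\[1, 9\\]")
  ratings <- sort(runif(50, 1, 9))
  expect_true(all(diff(dimension_label(ratings)) >= 0))
})

test_that("quadrant labels cross arousal and valence as documented", {
  expect_identical(quadrant_label(9, 9), 3L)   # HAHV
  expect_identical(quadrant_label(1, 1), 0L)   # LALV
  expect_identical(quadrant_label(9, 1), 1L)   # LAHV: high valence, low arousal
  expect_identical(quadrant_label(1, 9), 2L)   # HALV
})

test_that("assemble_dataset counts segments, maps labels, and validates input", {
  recs <- lapply(1:6, function(i)
    random_recording(n_channels = 4, n_samples = 500, rate = 50, seed = i,
                     trial_id = paste0("t", i),
                     label = c("negative", "neutral", "positive")[(i - 1) %% 3 + 1]))
  ds <- assemble_dataset(recs, task = "pnn")
  expect_s3_class(ds, "segment_dataset")
  expect_equal(n_segments(ds), 6 * 3)          # floor(500/150) = 3 per trial
  expect_equal(ds$n_classes, 3)
  # SEED-style order: negative = 0, neutral = 1, positive = 2
  expect_equal(unique(ds$y[ds$info$trial_id == recs[[1]]$trial_id]), 0L)
  expect_equal(sort(unique(ds$y)), 0:2)

  # dimensional task without ratings errors
  expect_error(assemble_dataset(recs, task = "valence"), "rating")
  # mixed sampling rates error
  recs2 <- c(recs[1], list(random_recording(n_channels = 4, rate = 25, label = "neutral")))
  expect_error(assemble_dataset(recs2, task = "pnn"), "rates")
  # mixed channel counts error
  recs3 <- c(recs[1], list(random_recording(n_channels = 5, rate = 50, label = "neutral")))
  expect_error(assemble_dataset(recs3, task = "pnn"), "channel")
})

test_that("dimensional tasks label segments from ratings", {
  recs <- list(
    random_recording(seed = 1, valence = 2, arousal = 8),
    random_recording(seed = 2, valence = 8, arousal = 2))
  ds <- assemble_dataset(recs, task = "av", window_seconds = 2)
  expect_equal(ds$n_classes, 4)
  expect_setequal(unique(ds$y), c(2L, 1L))     # HALV and LAHV
  dsv <- assemble_dataset(recs, task = "valence", window_seconds = 2)
  expect_setequal(unique(dsv$y), c(0L, 1L))
})
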