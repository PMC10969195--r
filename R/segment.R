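#' Map a 1-9 self-rating to a low/high class
#'
#' Dimensional emotion tasks binarize the continuous valence or arousal
#' self-rating at the scale midpoint: high (1) iff the rating strictly
#' exceeds the threshold, low (0) otherwise.
#'
#' @param rating numeric rating(s) in \[1, 9\].
#' @param threshold split point, default 5 (the scale midpoint).
#' @return integer 0 (low) or 1 (high), vectorized over `rating`.
#' @examples
#' dimension_label(c(1, 5, 5.5, 9))
#' @export
dimension_label <- function(rating, threshold = 5.0) {
  if (any(!is.finite(rating)) || any(rating < 1) || any(rating > 9))
    stopf("ratings must lie in [1, 9]")
  as.integer(rating > threshold)
}

#' Map valence/arousal ratings to a quadrant class
#'
#' The four-class task crosses low/high arousal with low/high valence:
#' 0 = LALV, 1 = LAHV, 2 = HALV, 3 = HAHV.
#'
#' @param valence_rating,arousal_rating ratings in \[1, 9\] (vectorized).
#' @param threshold split point passed to [dimension_label()].
#' @return integer class in 0..3.
#' @examples
#' quadrant_label(9, 1)  # high valence, low arousal -> 1
#' @export
quadrant_label <- function(valence_rating, arousal_rating, threshold = 5.0) {
  2L * dimension_label(arousal_rating, threshold) +
    dimension_label(valence_rating, threshold)
}

seed_class_names <- c("negative", "neutral", "positive")
quadrant_class_names <- c("LALV", "LAHV", "HALV", "HAHV")

task_n_classes <- function(task, n_discrete = 3L) {
  switch(task, pnn = n_discrete, arousal = 2L, valence = 2L, av = 4L)
}

# Resolve one recording's integer class under a task.
recording_class <- function(rec, task, class_names, threshold = 5.0) {
  if (task == "pnn") {
    if (is.null(rec$label)) stopf("recording %s/%s lacks a discrete label",
                                  rec$subject_id, rec$trial_id)
    idx <- match(rec$label, class_names)
    if (is.na(idx)) stopf("label '%s' not among classes: %s", rec$label,
                          paste(class_names, collapse = ", "))
    return(idx - 1L)
  }
  need <- switch(task, arousal = "arousal", valence = "valence", av = c("valence", "arousal"))
  for (f in need) if (is.null(rec[[f]]))
    stopf("recording %s/%s lacks the %s rating required by task '%s'",
          rec$subject_id, rec$trial_id, f, task)
  switch(task,
         arousal = dimension_label(rec$arousal, threshold),
         valence = dimension_label(rec$valence, threshold),
         av = quadrant_label(rec$valence, rec$arousal, threshold))
}

#' Segment a recording into fixed-length windows
#'
#' Slices the recording into consecutive windows of `window_seconds` (3 s by
#' default, i.e. 600 samples at 200 Hz or 384 at 128 Hz). Windows are
#' half-open sample ranges; the trailing partial window is discarded. With
#' `overlap_fraction > 0` consecutive windows share that fraction of samples.
#'
#' @param rec an [eeg_recording].
#' @param window_seconds window length in seconds; `window_seconds *
#'   sampling_rate` must be a whole number of samples.
#' @param overlap_fraction fraction in \[0, 1) of each window shared with its
#'   successor; default 0 (non-overlapping).
#' @return a list of `eeg_segment` objects (empty if the recording is shorter
#'   than one window). Each segment carries its channels x window matrix and
#'   provenance (`subject_id`, `trial_id`, 0-based `window_index`); any label
#'   or ratings on the recording are inherited.
#' @examples
#' rec <- eeg_recording(matrix(rnorm(2 * 1000), 2), sampling_rate = 100)
#' length(segment_recording(rec, window_seconds = 3))  # floor(1000/300) = 3
#' @export
segment_recording <- function(rec, window_seconds = 3.0, overlap_fraction = 0.0) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (overlap_fraction < 0 || overlap_fraction >= 1)
    stopf("`overlap_fraction` must lie in [0, 1)")
  ws <- window_seconds * rec$sampling_rate
  if (abs(ws - round(ws)) > 1e-8 || round(ws) < 1)
    stopf("window of %g s at %d Hz is not a whole positive number of samples",
          window_seconds, rec$sampling_rate)
  ws <- as.integer(round(ws))
  step <- max(1L, as.integer(round(ws * (1 - overlap_fraction))))
  n <- ncol(rec$data)
  if (n < ws) return(list())
  starts <- seq.int(0L, n - ws, by = step)
  lapply(seq_along(starts), function(i) {
    structure(list(
      data = rec$data[, starts[i] + seq_len(ws), drop = FALSE],
      label = rec$label, valence = rec$valence, arousal = rec$arousal,
      subject_id = rec$subject_id, trial_id = rec$trial_id,
      window_index = i - 1L
    ), class = "eeg_segment")
  })
}

#' Assemble recordings into a labeled segment dataset
#'
#' Segments every recording with [segment_recording()] and attaches the
#' integer class each task requires: `"pnn"` maps discrete labels through
#' `class_names` (default negative = 0, neutral = 1, positive = 2),
#' `"arousal"`/`"valence"` binarize the rating at the midpoint, and `"av"`
#' uses the four arousal-valence quadrants.
#'
#' @param recordings list of [eeg_recording] objects sharing channel count
#'   and sampling rate.
#' @param task one of `"pnn"`, `"arousal"`, `"valence"`, `"av"`.
#' @param window_seconds,overlap_fraction passed to [segment_recording()].
#' @param class_names class names for the `"pnn"` task, in index order.
#' @param threshold rating split point for dimensional tasks.
#' @return a `segment_dataset`: list with `x` (array \[n, channels, samples\]),
#'   `y` (0-based integer classes), `n_classes`, `class_names`, `task`,
#'   `sampling_rate`, and a provenance data frame `info`.
#' @export
assemble_dataset <- function(recordings, task = c("pnn", "arousal", "valence", "av"),
                             window_seconds = 3.0, overlap_fraction = 0.0,
                             class_names = seed_class_names, threshold = 5.0) {
  task <- match.arg(task)
  stopifnot(length(recordings) >= 1)
  n_ch <- vapply(recordings, function(r) nrow(r$data), 0L)
  rates <- vapply(recordings, function(r) r$sampling_rate, 0L)
  if (length(unique(n_ch)) != 1)
    stopf("heterogeneous channel counts: %s", paste(unique(n_ch), collapse = ", "))
  if (length(unique(rates)) != 1)
    stopf("heterogeneous sampling rates: %s Hz", paste(unique(rates), collapse = ", "))
  class_names <- switch(task, pnn = class_names,
                        arousal = c("low_arousal", "high_arousal"),
                        valence = c("low_valence", "high_valence"),
                        av = quadrant_class_names)
  n_classes <- length(class_names)
  segs <- list(); ys <- integer(); info <- list()
  for (rec in recordings) {
    y <- recording_class(rec, task, class_names, threshold)
    ss <- segment_recording(rec, window_seconds, overlap_fraction)
    for (s in ss) {
      segs[[length(segs) + 1L]] <- s$data
      ys <- c(ys, y)
      info[[length(info) + 1L]] <- data.frame(
        subject_id = s$subject_id, trial_id = s$trial_id,
        window_index = s$window_index, stringsAsFactors = FALSE)
    }
  }
  if (length(segs) == 0) stopf("no recording is long enough for one window")
  w <- ncol(segs[[1]])
  x <- array(0, c(length(segs), n_ch[1], w))
  for (i in seq_along(segs)) x[i, , ] <- segs[[i]]
  structure(list(x = x, y = as.integer(ys), n_classes = n_classes,
                 class_names = class_names, task = task,
                 sampling_rate = rates[1],
                 info = do.call(rbind, info)),
            class = "segment_dataset")
}

#' @export
print.segment_dataset <- function(x, ...) {
  cat(sprintf("<segment_dataset> %d segments of %d channels x %d samples @ %d Hz\n",
              dim(x$x)[1], dim(x$x)[2], dim(x$x)[3], x$sampling_rate))
  cat(sprintf("  task '%s', %d classes: %s\n", x$task, x$n_classes,
              paste(sprintf("%s=%d", x$class_names, table(factor(x$y, 0:(x$n_classes - 1)))),
                    collapse = ", ")))
  invisible(x)
}

#' Number of segments in a dataset
#' @param x a `segment_dataset`.
#' @return integer count.
#' @export
n_segments <- function(x) dim(x$x)[1]

# Subset a segment_dataset by segment index.
dataset_subset <- function(ds, idx) {
  out <- ds
  out$x <- ds$x[idx, , , drop = FALSE]
  out$y <- ds$y[idx]
  out$info <- ds$info[idx, , drop = FALSE]
  out
}
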