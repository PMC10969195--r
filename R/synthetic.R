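#' Specify a class-conditional synthetic EEG generator
#'
#' Defines a generative model for affective-EEG-like trials in which the
#' class-discriminative signal can be planted independently along two axes:
#'
#' * **spatial**: a class-specific smooth gain topography over channels
#'   modulates a coherent fixed-frequency oscillation, so classes differ in
#'   *where* on the scalp the rhythm sits (and hence in the inter-channel
#'   correlation structure), not in its timing;
#' * **temporal**: a class-specific oscillation frequency drawn from the
#'   canonical EEG bands, applied uniformly over channels, so classes differ
#'   in *when/how fast* the rhythm beats, not in its topography.
#'
#' Setting `spatial_snr = 0` removes all between-class spatial differences;
#' `temporal_snr = 0` likewise for temporal differences; both zero yields
#' class-identical pure background (1/f plus white noise).
#'
#' Defaults emulate a 62-channel, 200 Hz, 3-class recording regime; a
#' 32-channel, 128 Hz spec emulates the dimensional-rating regime.
#'
#' @param n_channels,sampling_rate,trial_seconds geometry of each trial.
#' @param n_classes number of emotion classes (>= 2).
#' @param spatial_snr,temporal_snr amplitude of each planted effect, as a
#'   multiple of the total background noise SD; >= 0.
#' @param spatial_freq carrier frequency (Hz) of the spatially planted
#'   oscillation (class-independent).
#' @param temporal_freqs per-class oscillation frequencies (Hz) for the
#'   temporal effect; recycled over classes. Defaults to theta/alpha/beta/
#'   low-gamma centers (6, 10, 20, 30 Hz).
#' @param spatial_patterns integer vector mapping each class to a topography
#'   id (0-based); classes sharing an id share a topography. The default
#'   `0:(n_classes-1)` gives every class its own topography; assignments
#'   like `c(0, 0, 1, 1)` with `temporal_freqs = c(3, 6, 3, 6)` build a
#'   product code in which the spatial axis and the temporal axis each
#'   carry one independent bit of the class.
#' @param phase_lock phase law of the planted oscillations: `FALSE` (default)
#'   draws fresh uniform phases per trial, so class information lives in
#'   oscillatory power and correlation structure only; `TRUE` locks phases to
#'   a fixed deterministic law (carrier phase 0 at trial onset, temporal
#'   phases staggered linearly over channels), giving every trial of a class
#'   the same underlying waveform template, as in a time-locked evoked
#'   response. With frequencies whose period divides the window length,
#'   locked templates are identical across segmentation windows.
#' @param noise_alpha exponent of the 1/f^alpha background spectrum.
#' @param noise_pink_sd,noise_white_sd SDs (microvolts) of the 1/f and white
#'   background components.
#' @param seed master seed; per-trial streams are derived from it by counter
#'   mixing so trials are independent and reproducible.
#' @return an object of class `synthetic_spec`.
#' @examples
#' spec <- synthetic_spec(n_channels = 8, sampling_rate = 32, trial_seconds = 6)
#' rec <- generate_recording(spec, class_index = 0, trial_seed = 1)
#' dim(rec$data)
#' @export
synthetic_spec <- function(n_channels = 62, sampling_rate = 200,
                           trial_seconds = 60, n_classes = 3,
                           spatial_snr = 1.0, temporal_snr = 1.0,
                           spatial_freq = 8, temporal_freqs = c(6, 10, 20, 30),
                           spatial_patterns = NULL, phase_lock = FALSE,
                           noise_alpha = 1.0, noise_pink_sd = 10,
                           noise_white_sd = 2, seed = 1L) {
  stopifnot(n_classes >= 2, spatial_snr >= 0, temporal_snr >= 0,
            is_count(n_channels), is_count(sampling_rate), trial_seconds > 0)
  if (is.null(spatial_patterns)) spatial_patterns <- 0:(n_classes - 1)
  spatial_patterns <- rep_len(as.integer(spatial_patterns), n_classes)
  structure(list(n_channels = as.integer(n_channels),
                 sampling_rate = as.integer(sampling_rate),
                 trial_seconds = trial_seconds, n_classes = as.integer(n_classes),
                 spatial_snr = spatial_snr, temporal_snr = temporal_snr,
                 spatial_freq = spatial_freq,
                 temporal_freqs = rep_len(temporal_freqs, n_classes),
                 spatial_patterns = spatial_patterns,
                 phase_lock = isTRUE(phase_lock),
                 noise_alpha = noise_alpha, noise_pink_sd = noise_pink_sd,
                 noise_white_sd = noise_white_sd, seed = as.integer(seed)),
            class = "synthetic_spec")
}

# Smooth gain topography: Gaussian bump over channel index whose center is
# set by the pattern id. Peak 1, width 15% of the montage.
pattern_topography <- function(n_channels, pattern_id, n_patterns) {
  centers <- (seq_len(n_patterns) - 0.5) / n_patterns * n_channels
  exp(-0.5 * ((seq_len(n_channels) - centers[pattern_id + 1]) /
                (0.15 * n_channels))^2)
}

# One channel of 1/f^alpha noise, synthesized in the frequency domain with
# random phases, scaled to unit SD.
pink_noise <- function(n, alpha) {
  half <- floor((n - 1) / 2)
  full <- complex(real = numeric(n))
  if (half >= 1) {
    amp <- seq_len(half)^(-alpha / 2)
    phase <- stats::runif(half, 0, 2 * pi)
    spec <- complex(modulus = amp, argument = phase)
    full[1 + seq_len(half)] <- spec
    full[n + 1 - seq_len(half)] <- Conj(spec)
  }
  if (n %% 2 == 0)   # Nyquist bin must be real
    full[n / 2 + 1] <- (n / 2)^(-alpha / 2) * sign(stats::runif(1) - 0.5)
  x <- Re(stats::fft(full, inverse = TRUE)) / n
  s <- stats::sd(x)
  if (s < 1e-12) return(numeric(n))
  x / s
}

#' Generate one synthetic EEG trial
#'
#' Draws background noise (per-channel 1/f^alpha plus white Gaussian) and
#' superimposes the class-conditional spatial and temporal oscillatory
#' effects described in [synthetic_spec()]. Deterministic given
#' `(spec$seed, trial_seed, class_index)`.
#'
#' @param spec a [synthetic_spec()].
#' @param class_index 0-based class.
#' @param trial_seed per-trial counter mixed with the master seed.
#' @param subject_id,trial_id provenance strings stored on the recording.
#' @return an [eeg_recording] whose discrete label is `class<k>` and whose
#'   ratings encode the class (see [generate_dataset()]).
#' @export
generate_recording <- function(spec, class_index, trial_seed,
                               subject_id = "sim01",
                               trial_id = sprintf("c%d_t%d", class_index, trial_seed)) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (class_index < 0 || class_index >= spec$n_classes)
    stopf("class_index %d outside [0, %d)", class_index, spec$n_classes)
  n <- as.integer(round(spec$trial_seconds * spec$sampling_rate))
  C <- spec$n_channels
  noise_sd <- sqrt(spec$noise_pink_sd^2 + spec$noise_white_sd^2)
  with_seed(derive_seed(spec$seed, trial_seed, class_index), {
    tt <- (seq_len(n) - 1) / spec$sampling_rate
    data <- matrix(stats::rnorm(C * n, sd = spec$noise_white_sd), C, n)
    for (c_i in seq_len(C))
      data[c_i, ] <- data[c_i, ] + spec$noise_pink_sd * pink_noise(n, spec$noise_alpha)
    if (spec$spatial_snr > 0) {
      # coherent carrier with a class-specific topography: the signature is
      # the instantaneous cross-channel pattern (where the rhythm sits)
      g <- pattern_topography(C, spec$spatial_patterns[class_index + 1],
                              max(spec$spatial_patterns) + 1L)
      phi <- if (spec$phase_lock) 0 else stats::runif(1, 0, 2 * pi)
      carrier <- sin(2 * pi * spec$spatial_freq * tt + phi)
      data <- data + (spec$spatial_snr * noise_sd * g) %o% carrier
    }
    if (spec$temporal_snr > 0) {
      # class-specific rhythm, flat topography; phases independent per
      # channel, so the signature is each channel's oscillation frequency
      # with no instantaneous cross-channel pattern
      f_k <- spec$temporal_freqs[class_index + 1]
      ph <- if (spec$phase_lock) 2 * pi * (seq_len(C) - 1) / C
            else stats::runif(C, 0, 2 * pi)
      osc <- sin(outer(ph, 2 * pi * f_k * tt, `+`))   # C x n
      data <- data + spec$temporal_snr * noise_sd * osc
    }
    ratings <- class_ratings(spec$n_classes, class_index)
    eeg_recording(data, spec$sampling_rate,
                  subject_id = subject_id, trial_id = trial_id,
                  label = sprintf("class%d", class_index),
                  valence = ratings["valence"], arousal = ratings["arousal"])
  })
}

# Ratings consistent with the class index so dimensional labeling reproduces
# it: 2 classes -> low/high arousal and valence together; 4 classes -> the
# four quadrants; otherwise neutral-ish midpoints (unused for pnn).
class_ratings <- function(n_classes, class_index) {
  lo <- 3; hi <- 7
  if (n_classes == 4) {
    a <- if (class_index >= 2) hi else lo
    v <- if (class_index %% 2 == 1) hi else lo
  } else if (n_classes == 2) {
    a <- if (class_index == 1) hi else lo
    v <- a
  } else {
    a <- lo + (hi - lo) * class_index / max(1, n_classes - 1)
    v <- a
  }
  c(valence = v, arousal = a)
}

#' Generate a balanced labeled segment dataset
#'
#' Simulates `n_trials_per_class` trials per class from `spec`, then segments
#' and labels them via [assemble_dataset()] under the requested task. For
#' dimensional tasks the synthetic ratings encode the generating class, so
#' the rating-threshold labeling path is exercised end to end.
#'
#' @param spec a [synthetic_spec()].
#' @param n_trials_per_class trials per class (>= 1).
#' @param task label mapping, as in [assemble_dataset()]; `"pnn"` requires
#'   nothing extra, `"arousal"`/`"valence"` need `n_classes = 2`, `"av"`
#'   needs `n_classes = 4`.
#' @param window_seconds,overlap_fraction segmentation parameters.
#' @return a `segment_dataset`, exactly balanced across classes.
#' @export
generate_dataset <- function(spec, n_trials_per_class, task = "pnn",
                             window_seconds = 3.0, overlap_fraction = 0.0) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (!is_count(n_trials_per_class))
    stopf("`n_trials_per_class` must be a positive integer")
  recs <- list()
  for (k in 0:(spec$n_classes - 1)) for (tr in seq_len(n_trials_per_class))
    recs[[length(recs) + 1L]] <-
      generate_recording(spec, k, trial_seed = tr)
  assemble_dataset(recs, task = task, window_seconds = window_seconds,
                   overlap_fraction = overlap_fraction,
                   class_names = sprintf("class%d", 0:(spec$n_classes - 1)))
}
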