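# Shared fixtures: every dataset is generated in code at test time.

# Reduced-scale recording regime used throughout the training-dependent
# tests: 8 channels at 32 Hz so a 3 s window is 96 samples.
small_spec <- function(n_classes = 2, spatial_snr = 3, temporal_snr = 3,
                       seed = 1L, trial_seconds = 12) {
  synthetic_spec(n_channels = 8, sampling_rate = 32,
                 trial_seconds = trial_seconds, n_classes = n_classes,
                 spatial_snr = spatial_snr, temporal_snr = temporal_snr,
                 spatial_freq = 8, temporal_freqs = c(3, 6, 12, 15),
                 seed = seed)
}

small_train_cfg <- function(epochs = 12, seed = 1L, k = 4, ...) {
  train_config(k_folds = k, learning_rate = 1e-3, batch_size = 32,
               max_epochs = epochs, seed = seed, ...)
}

small_model_args <- function() list(d_model = 16, h = 4, conv_kernels = 8,
                                    dropout = 0.1)

tiny_cfg <- function(variant = "st-tcnn", n_classes = 3) {
  model_config(variant, n_channels = 5, window_samples = 12,
               n_classes = n_classes, d_model = 8, h = 2, ff_dim = 16,
               dropout = 0, conv_kernels = 3)
}

random_recording <- function(n_channels = 4, n_samples = 200, rate = 50,
                             seed = 7, ...) {
  set.seed(seed)
  eeg_recording(matrix(rnorm(n_channels * n_samples), n_channels), rate, ...)
}

# Independent per-row softmax oracle: explicit exp/normalize loop.
softmax_rows_oracle <- function(S) {
  out <- S
  for (i in seq_len(nrow(S))) {
    e <- exp(S[i, ] - max(S[i, ]))
    out[i, ] <- e / sum(e)
  }
  out
}

# Independent scaled dot-product attention oracle, element by element.
sdpa_oracle <- function(Q, K, V) {
  n <- nrow(Q); m <- nrow(K); dk <- ncol(Q)
  S <- matrix(0, n, m)
  for (i in seq_len(n)) for (j in seq_len(m))
    S[i, j] <- sum(Q[i, ] * K[j, ]) / sqrt(dk)
  A <- softmax_rows_oracle(S)
  out <- matrix(0, n, ncol(V))
  for (i in seq_len(n)) for (c_i in seq_len(ncol(V)))
    out[i, c_i] <- sum(A[i, ] * V[, c_i])
  list(output = out, weights = A)
}
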