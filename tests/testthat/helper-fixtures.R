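# Small in-code fixtures shared across test files.

# A tiny recording built directly from templates and labels, with optional
# noiseless/noisy synthesis at reduced channel count and duration.
small_sim <- function(n_channels = 24, fs = 125, duration_s = 20, K = 4,
                      snr = 4, seed = 11, mean_dwell_ms = 100) {
  cfg <- simulation_config(n_channels = n_channels, fs = fs,
                           duration_s = duration_s, K_true = K,
                           mean_dwell_ms = mean_dwell_ms, snr = snr,
                           seed = seed)
  simulate_recording(cfg)
}

# K exactly-repeated orthogonal maps: clustering must recover them exactly.
orthogonal_peak_set <- function(K = 3, n_channels = 12, reps = 50, seed = 5) {
  maps <- generate_templates(K, n_channels, seed = seed)
  X <- maps[, rep(seq_len(K), each = reps)]
  list(maps = maps, X = X)
}

# Build a microstate_model by hand from given unit-norm centered maps.
model_from_maps <- function(maps) {
  maps <- as.matrix(maps)
  maps <- sweep(maps, 2, colMeans(maps))
  maps <- sweep(maps, 2, sqrt(colSums(maps^2)), "/")
  if (is.null(rownames(maps)))
    rownames(maps) <- sprintf("ch%03d", seq_len(nrow(maps)))
  colnames(maps) <- LETTERS[seq_len(ncol(maps))]
  structure(list(K = ncol(maps), maps = maps,
                 gev_total = NA_real_, gev_per_class = rep(NA_real_, ncol(maps)),
                 labels = integer(0), gev_trace = numeric(0),
                 settings = list()),
            class = "microstate_model")
}

# Recording whose every sample is a scaled (possibly sign-flipped) template.
recording_from_labels <- function(maps, labels, fs = 125, amp = NULL) {
  maps <- as.matrix(maps)
  if (is.null(amp)) amp <- rep(1, length(labels))
  X <- maps[, labels, drop = FALSE] * rep(amp, each = nrow(maps))
  eeg_recording(X, fs, channel_labels = rownames(maps))
}
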