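# Fixtures built in code; no data files.

# analysis-window epoch with a known amplitude spectrum: an impulse of
# height N/2 at sample 1 gives a flat spectrum of amplitude 1 at every
# non-DC bin, and adding a * cos(2*pi*f*t) moves the f bin to |1 + a|
make_flat_epoch <- function(snr_targets = c(), f = 6, fs = 250, dur = 20,
                            subject_id = "s01", sequence_id = 1L) {
  n <- fs * dur
  t <- (seq_len(n) - 1) / fs
  base <- numeric(n)
  base[1] <- n / 2
  labels <- if (length(snr_targets)) names(snr_targets) else "ch1"
  data <- do.call(rbind, lapply(labels, function(ch) {
    a <- if (length(snr_targets)) snr_targets[[ch]] - 1 else 0
    base + a * cos(2 * pi * f * t)
  }))
  rownames(data) <- labels
  new_epoch(data, fs, window = "analysis", subject_id = subject_id,
            sequence_id = sequence_id, channel_labels = labels)
}

# fpvs_spectrum around a hand-chosen amplitude matrix
make_spectrum <- function(amplitudes, bin_resolution = 0.05,
                          channel_labels = rownames(amplitudes)) {
  if (is.null(channel_labels)) {
    channel_labels <- paste0("ch", seq_len(nrow(amplitudes)))
  }
  rownames(amplitudes) <- channel_labels
  structure(
    list(
      amplitudes = amplitudes,
      bin_resolution = bin_resolution,
      channel_labels = channel_labels,
      n_averaged_sequences = 1L,
      montage = NULL,
      subject_id = "s01"
    ),
    class = "fpvs_spectrum"
  )
}

# toy montage: target channel at the vertex, three equidistant neighbours
# around it and one distant channel
toy_montage <- function() {
  tibble::tibble(
    label = c("T0", "N1", "N2", "N3", "FAR"),
    x = c(0, 0.2, -0.1, -0.1, 0.9),
    y = c(0, 0, sqrt(0.03), -sqrt(0.03), 0),
    z = c(1, 0.9798, 0.9798, 0.9798, 0.4359)
  )
}

# small simulation config for fast end-to-end tests
small_sim <- function(seed = 1L, ...) {
  sim_config(n_sequences = 2, seed = seed, ...)
}

brute_force_metric <- function(A, metric = "snr") {
  off <- c(-(11:2), 2:11)
  out <- matrix(NA_real_, nrow(A), ncol(A))
  for (k in seq_len(ncol(A))) {
    if (k - 12 < 0 || k + 11 > ncol(A)) next
    for (ch in seq_len(nrow(A))) {
      nb <- A[ch, k + off]
      out[ch, k] <- if (metric == "snr") {
        A[ch, k] / mean(nb)
      } else {
        (A[ch, k] - mean(nb)) / stats::sd(nb)
      }
    }
  }
  out
}
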