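# Preprocessing chain: FFT band-pass -> Fourier resample -> segmentation ->
# channel interpolation -> common average reference -> analysis-window crop
# -> per-sequence quality control.

# raised-cosine ramp from 0 at `a` to 1 at `b`
rc_ramp <- function(f, a, b) {
  g <- 0.5 * (1 - cos(pi * (f - a) / (b - a)))
  g[f <= a] <- 0
  g[f >= b] <- 1
  g
}

#' FFT band-pass filter
#'
#' Filters every channel in the frequency domain with a band-pass mask:
#' unit gain in the passband, zero outside, joined by raised-cosine
#' transitions (width 0.1 Hz around the low cutoff, 5 Hz around the high
#' cutoff) to avoid the ringing of a brick-wall mask. With `low = 0` the
#' filter is low-pass only. Output length equals input length.
#'
#' @param rec An [eeg_recording()].
#' @param low,high Band edges in Hz; `0 <= low < high < sampling_rate / 2`.
#' @return The filtered recording, with the step appended to its
#'   provenance chain.
#' @export
bandpass_filter <- function(rec, low = 0.1, high = 100) {
  stopifnot(inherits(rec, "fpvs_recording"))
  fs <- rec$sampling_rate
  if (!is_number(low) || !is_number(high) || low < 0 || low >= high ||
      high >= fs / 2) {
    abort_invalid("need 0 <= low < high < sampling_rate / 2")
  }
  n <- n_samples(rec)
  f <- (seq_len(n) - 1) / n * fs
  f <- pmin(f, fs - f) # fold to physical frequency
  gain <- rc_ramp(f, high - 2.5, high + 2.5)
  gain <- 1 - gain
  if (low > 0) gain <- gain * rc_ramp(f, low - 0.05, low + 0.05)
  x <- t(rec$data)
  y <- Re(stats::mvfft(stats::mvfft(x) * gain, inverse = TRUE)) / n
  rec$data <- t(y)
  rownames(rec$data) <- rec$channel_labels
  append_chain(rec, sprintf("bandpass(%g-%g Hz)", low, high))
}

#' Fourier-domain resampling
#'
#' Resamples every channel by truncating its discrete Fourier spectrum at
#' the new Nyquist frequency and inverse-transforming at the new length —
#' exact for band-limited signals, so a bin-aligned sinusoid below the new
#' Nyquist survives with its amplitude intact. The new length
#' `n * target_rate / sampling_rate` must be an integer (whole-second
#' recordings at the rates used here always satisfy this). Trigger indices
#' are rescaled and rounded half away from zero.
#'
#' @param rec An [eeg_recording()].
#' @param target_rate New sampling rate in Hz, below the current rate. The
#'   signal must already be low-passed below `target_rate / 2` (see
#'   [bandpass_filter()]); energy at or above the new Nyquist is discarded.
#' @return The resampled recording.
#' @export
downsample <- function(rec, target_rate = 250) {
  stopifnot(inherits(rec, "fpvs_recording"))
  fs <- rec$sampling_rate
  if (!is_number(target_rate) || target_rate >= fs) {
    abort_invalid("`target_rate` must be below the current sampling rate")
  }
  n <- n_samples(rec)
  m <- n * target_rate / fs
  if (!is_integerish(m, tol = 1e-6)) {
    abort_invalid(
      "recording length does not map to a whole number of samples at `target_rate`"
    )
  }
  m <- round(m)
  x <- stats::mvfft(t(rec$data))
  y <- matrix(0 + 0i, nrow = m, ncol = nrow(rec$data))
  hw <- (m - 1) %/% 2 # positive non-Nyquist frequencies kept
  y[seq_len(hw + 1L), ] <- x[seq_len(hw + 1L), ]
  if (hw > 0) {
    y[(m - hw + 1L):m, ] <- x[(n - hw + 1L):n, ]
  }
  # new Nyquist bin (m even) left at zero: the precondition guarantees the
  # signal carries no energy there
  out <- Re(stats::mvfft(y, inverse = TRUE)) / n
  rec$data <- t(out)
  rownames(rec$data) <- rec$channel_labels
  if (nrow(rec$triggers) > 0) {
    rec$triggers$sample <- as.integer(
      round_half_up(rec$triggers$sample * target_rate / fs)
    )
  }
  rec$sampling_rate <- target_rate
  append_chain(rec, sprintf("downsample(%g Hz)", target_rate))
}

# Band-pass filter and resample in a single FFT round trip. Identical (to
# rounding) to bandpass_filter() followed by downsample() — the inverse and
# forward transforms between the two steps cancel — but with half the
# large-transform work; used by preprocess_subject() on full recordings.
filter_resample <- function(rec, low, high, target_rate) {
  fs <- rec$sampling_rate
  if (!is_number(low) || !is_number(high) || low < 0 || low >= high ||
      high >= fs / 2) {
    abort_invalid("need 0 <= low < high < sampling_rate / 2")
  }
  if (!is_number(target_rate) || target_rate >= fs) {
    abort_invalid("`target_rate` must be below the current sampling rate")
  }
  n <- n_samples(rec)
  m <- n * target_rate / fs
  if (!is_integerish(m, tol = 1e-6)) {
    abort_invalid(
      "recording length does not map to a whole number of samples at `target_rate`"
    )
  }
  m <- round(m)
  f <- (seq_len(n) - 1) / n * fs
  f <- pmin(f, fs - f)
  gain <- 1 - rc_ramp(f, high - 2.5, high + 2.5)
  if (low > 0) gain <- gain * rc_ramp(f, low - 0.05, low + 0.05)
  # pack channel pairs into complex columns: multiplying by the real,
  # frequency-symmetric gain and the symmetric spectrum truncation act
  # channel-wise on the packed transform, so one FFT serves two channels
  nch <- nrow(rec$data)
  half <- (nch + 1L) %/% 2L
  packed <- matrix(0 + 0i, n, half)
  re_idx <- seq_len(half) * 2L - 1L
  im_idx <- pmin(seq_len(half) * 2L, nch)
  packed[] <- t(rec$data[re_idx, , drop = FALSE]) +
    1i * t(rec$data[im_idx, , drop = FALSE])
  x <- stats::mvfft(packed) * gain
  y <- matrix(0 + 0i, nrow = m, ncol = half)
  hw <- (m - 1) %/% 2
  y[seq_len(hw + 1L), ] <- x[seq_len(hw + 1L), ]
  if (hw > 0) y[(m - hw + 1L):m, ] <- x[(n - hw + 1L):n, ]
  y <- stats::mvfft(y, inverse = TRUE) / n
  out <- matrix(0, nch, m)
  out[re_idx, ] <- t(Re(y))
  out[im_idx, ] <- t(Im(y))
  rec$data <- out
  rownames(rec$data) <- rec$channel_labels
  if (nrow(rec$triggers) > 0) {
    rec$triggers$sample <- as.integer(
      round_half_up(rec$triggers$sample * target_rate / fs)
    )
  }
  rec$sampling_rate <- target_rate
  rec <- append_chain(rec, sprintf("bandpass(%g-%g Hz)", low, high))
  append_chain(rec, sprintf("downsample(%g Hz)", target_rate))
}

#' Segment a recording into per-sequence epochs
#'
#' Cuts one epoch per `trial_start` trigger, beginning `pre_baseline`
#' seconds before the trigger and spanning the full sequence (baselines,
#' fades and stimulation; 28 s for the default design). Triggers too close
#' to the recording edges are skipped, with the reason recorded in the
#' `skipped` attribute of the result.
#'
#' @param rec An [eeg_recording()].
#' @param seq The [build_sequence()] design that was presented; provides
#'   the epoch span and baseline offset.
#' @param subject_id Subject identifier attached to each epoch.
#' @return A list of `fpvs_epoch` objects (window `"full"`), with
#'   attribute `skipped` (tibble of dropped triggers and reasons).
#' @export
segment <- function(rec, seq = build_sequence(),
                    subject_id = rec$metadata$subject_id %||% "s01") {
  stopifnot(inherits(rec, "fpvs_recording"), inherits(seq, "fpvs_sequence"))
  fs <- rec$sampling_rate
  starts <- rec$triggers$sample[rec$triggers$code == "trial_start"]
  if (length(starts) == 0L) {
    abort_invalid("no `trial_start` triggers in recording")
  }
  span <- round(seq$total_span * fs)
  pre <- round(seq$pre_baseline * fs)
  epochs <- list()
  skipped <- tibble::tibble(sample = integer(), reason = character())
  for (i in seq_along(starts)) {
    s0 <- starts[i] - pre # 0-based start sample of the epoch
    if (s0 < 0) {
      skipped <- dplyr::bind_rows(skipped, tibble::tibble(
        sample = starts[i], reason = "under 2 s of data before trigger"))
      next
    }
    if (s0 + span > n_samples(rec)) {
      skipped <- dplyr::bind_rows(skipped, tibble::tibble(
        sample = starts[i], reason = "recording ends before epoch end"))
      next
    }
    epochs[[length(epochs) + 1L]] <- new_epoch(
      rec$data[, (s0 + 1L):(s0 + span), drop = FALSE],
      sampling_rate = fs,
      window = "full",
      sequence_id = length(epochs) + 1L,
      subject_id = subject_id,
      channel_labels = rec$channel_labels,
      montage = rec$montage,
      metadata = c(rec$metadata, list(epoch_start_sample = s0))
    )
  }
  attr(epochs, "skipped") <- skipped
  epochs
}

#' Interpolate a bad channel from its nearest neighbours
#'
#' Replaces one channel by the inverse-distance-weighted mean of its
#' `n_neighbors` nearest neighbours (Euclidean distance on the montage
#' positions). Other channels are untouched.
#'
#' @param epoch An `fpvs_epoch` carrying a montage.
#' @param label Channel to replace.
#' @param n_neighbors Number of neighbours (default 3).
#' @return The epoch with the channel replaced.
#' @export
interpolate_channel <- function(epoch, label, n_neighbors = 3) {
  stopifnot(inherits(epoch, "fpvs_epoch"))
  if (is.null(epoch$montage)) {
    abort_invalid("epoch carries no montage positions; cannot interpolate")
  }
  stopifnot_channels(epoch$channel_labels, label)
  others <- setdiff(epoch$channel_labels, label)
  if (length(others) < n_neighbors) {
    abort_invalid(sprintf("need at least %d other channels", n_neighbors))
  }
  pos <- epoch$montage
  stopifnot_channels(pos$label, c(label, others))
  p0 <- unlist(pos[pos$label == label, c("x", "y", "z")])
  d <- vapply(others, function(ch) {
    sqrt(sum((unlist(pos[pos$label == ch, c("x", "y", "z")]) - p0)^2))
  }, 0)
  nb <- others[order(d)][seq_len(n_neighbors)]
  w <- 1 / d[order(d)][seq_len(n_neighbors)]
  w <- w / sum(w)
  epoch$data[label, ] <- as.vector(w %*% epoch$data[nb, , drop = FALSE])
  epoch$metadata$interpolated <- c(epoch$metadata$interpolated, label)
  epoch
}

#' Common average reference
#'
#' Re-expresses every channel relative to the instantaneous mean across all
#' channels, so the channel mean is zero at every sample. Idempotent.
#'
#' @param epoch An `fpvs_epoch` with at least two channels.
#' @return The re-referenced epoch.
#' @export
rereference_common_average <- function(epoch) {
  stopifnot(inherits(epoch, "fpvs_epoch"))
  if (nrow(epoch$data) < 2L) {
    abort_invalid("common average reference needs at least 2 channels")
  }
  epoch$data <- sweep(epoch$data, 2L, colMeans(epoch$data), "-")
  epoch
}

#' Crop an epoch to the full-contrast analysis window
#'
#' Drops the pre-baseline and fade-in (4 s for the default design) and
#' keeps exactly the full-contrast stimulation window (20 s), which spans a
#' whole number of oddball cycles so the tagged frequencies fall exactly on
#' the spectral bin grid.
#'
#' @param epoch A full-window `fpvs_epoch`.
#' @param seq The presented [build_sequence()] design.
#' @return An `fpvs_epoch` with `window = "analysis"`.
#' @export
crop_analysis_window <- function(epoch, seq = build_sequence()) {
  stopifnot(inherits(epoch, "fpvs_epoch"))
  if (epoch$window != "full") {
    abort_invalid("`epoch` must be a full (uncropped) window")
  }
  fs <- epoch$sampling_rate
  from <- round((seq$pre_baseline + seq$fade_in) * fs)
  len <- round(seq$stim_duration * fs)
  if (from + len > ncol(epoch$data)) {
    abort_invalid("epoch too short for the analysis window")
  }
  epoch$data <- epoch$data[, (from + 1L):(from + len), drop = FALSE]
  epoch$window <- "analysis"
  epoch
}

#' Per-sequence quality control
#'
#' Applies the base-rate synchronization criterion: a sequence is rejected
#' when the neighbour-bin SNR at the base stimulation frequency is below
#' `threshold` at *all* of the listed medial-occipital channels (strict
#' inequality; an SNR of exactly 2 keeps the sequence). External exclusion
#' reasons established by inspection (`technical_problem`, `electrode_off`,
#' `no_fixation`) can be passed as annotations and force rejection.
#'
#' @param epoch An analysis-window `fpvs_epoch`.
#' @param base_rate Base stimulation frequency in Hz (default 6).
#' @param threshold SNR threshold (default 2).
#' @param occipital_channels Channels tested (default Oz, O1, O2).
#' @param annotations Character vector of externally supplied exclusion
#'   reasons; non-empty annotations reject the sequence.
#' @return A one-row tibble: `subject_id`, `sequence_id`, `verdict`
#'   (`"keep"`/`"reject"`), `reasons` (comma-separated, `""` if kept), and
#'   one `base_snr_<channel>` column per tested channel.
#' @export
sequence_qc <- function(epoch, base_rate = 6, threshold = 2,
                        occipital_channels = c("Oz", "O1", "O2"),
                        annotations = character()) {
  stopifnot(inherits(epoch, "fpvs_epoch"))
  stopifnot_channels(epoch$channel_labels, occipital_channels)
  # the criterion only looks at the listed channels; restrict the spectrum
  # to them (the neighbour-bin SNR is computed per channel)
  sub <- epoch
  sub$data <- epoch$data[occipital_channels, , drop = FALSE]
  sub$channel_labels <- occipital_channels
  spec <- amplitude_spectrum(sub)
  snr <- snr_spectrum(spec)
  vals <- vapply(occipital_channels, function(ch) {
    value_at(snr, ch, base_rate)
  }, 0)
  reasons <- as.character(annotations)
  # undefined SNR (NA) is not "below threshold"; the inequality is strict,
  # with a 1e-9 guard so a value exactly at threshold is never rejected by
  # floating-point rounding
  if (all(!is.na(vals) & vals < threshold - 1e-9)) {
    reasons <- c(reasons, "low_base_snr")
  }
  out <- tibble::tibble(
    subject_id = epoch$subject_id,
    sequence_id = epoch$sequence_id,
    verdict = if (length(reasons)) "reject" else "keep",
    reasons = paste(reasons, collapse = ",")
  )
  for (i in seq_along(occipital_channels)) {
    out[[paste0("base_snr_", occipital_channels[i])]] <- unname(vals[i])
  }
  out
}

#' Flag noisy sequences by spectrum amplitude
#'
#' Marks sequences whose channel-median amplitude-spectrum RMS exceeds
#' `k` times the cohort median of the same statistic. This is a flag for
#' inspection, mirroring the practice of excluding globally noisy sequences
#' after visual review; flagged sequences are never dropped automatically.
#'
#' @param spectra List of [amplitude_spectrum()] objects (one per sequence).
#' @param k Outlier multiplier (default 3).
#' @return A tibble with `index`, `rms` and `flagged`.
#' @export
flag_noisy_sequences <- function(spectra, k = 3) {
  rms <- vapply(spectra, function(sp) {
    stats::median(sqrt(rowMeans(sp$amplitudes^2)))
  }, 0)
  tibble::tibble(
    index = seq_along(spectra),
    rms = rms,
    flagged = rms > k * stats::median(rms)
  )
}

#' Run the full preprocessing chain on one subject
#'
#' Band-pass filter, downsample, segment, (optionally) interpolate a bad
#' channel, common-average reference, crop to the analysis window and apply
#' per-sequence QC — in that order.
#'
#' @param rec Raw [eeg_recording()].
#' @param seq The presented [build_sequence()] design.
#' @param low,high Band-pass edges in Hz.
#' @param target_rate Analysis sampling rate in Hz.
#' @param qc_threshold,qc_channels Parameters of [sequence_qc()].
#' @param interpolate Optional channel label to interpolate in every epoch.
#' @param annotations Optional named list: external exclusion reasons per
#'   sequence index.
#' @return A list with `epochs` (kept analysis-window epochs), `qc` (QC
#'   tibble over all sequences) and `n_sequences` (number segmented).
#' @export
preprocess_subject <- function(rec, seq = build_sequence(), low = 0.1,
                               high = 100, target_rate = 250,
                               qc_threshold = 2,
                               qc_channels = c("Oz", "O1", "O2"),
                               interpolate = NULL,
                               annotations = list()) {
  rec <- filter_resample(rec, low, high, target_rate)
  epochs <- segment(rec, seq)
  qc <- list()
  kept <- list()
  for (ep in epochs) {
    if (!is.null(interpolate)) ep <- interpolate_channel(ep, interpolate)
    ep <- rereference_common_average(ep)
    ep <- crop_analysis_window(ep, seq)
    ann <- annotations[[as.character(ep$sequence_id)]] %||% character()
    rep_i <- sequence_qc(ep, base_rate = seq$base_rate,
                         threshold = qc_threshold,
                         occipital_channels = qc_channels,
                         annotations = ann)
    qc[[length(qc) + 1L]] <- rep_i
    if (rep_i$verdict == "keep") kept[[length(kept) + 1L]] <- ep
  }
  list(
    epochs = kept,
    qc = dplyr::bind_rows(qc),
    n_sequences = length(epochs)
  )
}
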