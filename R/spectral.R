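# Frequency-domain quantification: amplitude spectra and the neighbour-bin
# SNR / Z-score statistics.

#' Average epochs in the time domain
#'
#' Per-sample, per-channel arithmetic mean across sequences of one subject.
#' Phase-locked (stimulus-driven) activity survives averaging while
#' non-phase-locked background shrinks as 1/sqrt(n).
#'
#' @param epochs Non-empty list of `fpvs_epoch` objects with identical
#'   window type, dimensions, sampling rate and channel set.
#' @return A single `fpvs_epoch`; the number of averaged sequences is
#'   recorded in `metadata$n_averaged`.
#' @export
average_epochs <- function(epochs) {
  if (!is.list(epochs) || length(epochs) == 0L) {
    abort_invalid("`epochs` must be a non-empty list of epochs")
  }
  ref <- epochs[[1L]]
  for (ep in epochs) {
    stopifnot(inherits(ep, "fpvs_epoch"))
    if (!identical(dim(ep$data), dim(ref$data)) ||
        ep$sampling_rate != ref$sampling_rate ||
        !identical(ep$channel_labels, ref$channel_labels) ||
        ep$window != ref$window) {
      abort_invalid("epochs differ in shape, rate, channels or window type")
    }
  }
  out <- ref
  out$data <- Reduce(`+`, lapply(epochs, `[[`, "data")) / length(epochs)
  out$metadata$n_averaged <- length(epochs)
  out
}

#' Amplitude spectrum of an analysis-window epoch
#'
#' Discrete Fourier transform with a rectangular window (no taper, no
#' zero-padding, no detrending): because the analysis window spans an
#' integer number of cycles of every tagged frequency, the target bins are
#' leakage-free by construction and a taper would only smear them.
#' Amplitudes are normalised to sinusoid peak amplitude in microvolts
#' (`2 |X_k| / N`; DC and Nyquist `|X_k| / N`), and the bin spacing is the
#' reciprocal of the window duration (0.05 Hz for 20-s windows).
#'
#' @param epoch An analysis-window `fpvs_epoch` (see
#'   [crop_analysis_window()]).
#' @return An object of class `fpvs_spectrum`: channels x bins amplitude
#'   matrix (bins 0 .. N/2), `bin_resolution` in Hz, channel labels and the
#'   number of time-domain-averaged sequences behind the epoch.
#' @export
amplitude_spectrum <- function(epoch) {
  stopifnot(inherits(epoch, "fpvs_epoch"))
  if (epoch$window != "analysis") {
    abort_invalid("`epoch` must be an analysis-window epoch")
  }
  n <- ncol(epoch$data)
  x <- stats::mvfft(t(epoch$data))
  n_bins <- floor(n / 2) + 1L
  amp <- 2 * Mod(x[seq_len(n_bins), , drop = FALSE]) / n
  amp[1L, ] <- amp[1L, ] / 2
  if (n %% 2 == 0) amp[n_bins, ] <- amp[n_bins, ] / 2
  amplitudes <- t(amp)
  rownames(amplitudes) <- epoch$channel_labels
  structure(
    list(
      amplitudes = amplitudes,
      bin_resolution = epoch$sampling_rate / n,
      channel_labels = epoch$channel_labels,
      n_averaged_sequences = epoch$metadata$n_averaged %||% 1L,
      montage = epoch$montage,
      subject_id = epoch$subject_id
    ),
    class = "fpvs_spectrum"
  )
}

#' @export
print.fpvs_spectrum <- function(x, ...) {
  cat(sprintf(
    "<fpvs_spectrum> %d channels x %d bins, resolution %g Hz (n averaged = %d)\n",
    nrow(x$amplitudes), ncol(x$amplitudes), x$bin_resolution,
    x$n_averaged_sequences
  ))
  invisible(x)
}

#' Bin index of a frequency
#'
#' Maps a frequency to its exact 0-based DFT bin index. The frequency must
#' lie on the bin grid (within 1e-9 of `k * bin_resolution`); off-grid
#' frequencies raise an error rather than snapping silently.
#'
#' @param f Frequency in Hz.
#' @param spectrum An `fpvs_spectrum` (or metric spectrum).
#' @return Integer bin index (0 = DC), so that bin `k` is frequency
#'   `k * bin_resolution`.
#' @export
bin_index <- function(f, spectrum) {
  df <- spectrum$bin_resolution
  k <- f / df
  if (abs(k - round(k)) > 1e-9) {
    abort_invalid(sprintf(
      "frequency %g Hz is not aligned with the %g Hz bin grid", f, df))
  }
  k <- as.integer(round(k))
  nb <- ncol(spectrum$amplitudes %||% spectrum$values)
  if (k < 0L || k >= nb) abort_invalid("frequency outside the spectrum")
  k
}

neighbor_offsets <- function(n_per_side = 10L, skip_adjacent = 1L) {
  o <- (skip_adjacent + 1L):(skip_adjacent + n_per_side)
  c(-rev(o), o)
}

# shared scaffolding for the SNR and Z metrics: per-bin neighbour sums via
# running (cumulative) sums — the symmetric neighbourhood [k-b, k+b] minus
# the excluded core [k-a+1, k+a-1]
neighborhood_stats <- function(amplitudes, n_per_side, skip_adjacent) {
  a <- skip_adjacent + 1L
  b <- skip_adjacent + n_per_side
  nb <- ncol(amplitudes)
  nch <- nrow(amplitudes)
  defined <- seq_len(nb) - 1L >= b & seq_len(nb) - 1L <= nb - 1L - b
  window_sums <- function(m, half) {
    cs <- cbind(0, t(apply(m, 1L, cumsum))) # nch x (nb + 1); cs[, j+1] = sum of bins 1..j
    out <- matrix(NA_real_, nch, nb)
    k <- which(defined)
    out[, k] <- cs[, k + half + 1L, drop = FALSE] -
      cs[, k - half, drop = FALSE]
    out
  }
  # the inner window [k - (a-1), k + (a-1)] always contains the centre bin,
  # so subtracting it removes both the bin itself and the skipped adjacents
  s <- window_sums(amplitudes, b) - window_sums(amplitudes, a - 1L)
  sq <- amplitudes^2
  s2 <- window_sums(sq, b) - window_sums(sq, a - 1L)
  list(sum = s, sumsq = s2, n = 2L * n_per_side, defined = defined)
}

new_metric <- function(values, metric, spectrum, defined,
                       n_per_side, skip_adjacent) {
  rownames(values) <- spectrum$channel_labels
  structure(
    list(
      values = values,
      metric = metric,
      neighborhood = list(n_per_side = n_per_side,
                          skip_adjacent = skip_adjacent),
      defined = defined,
      bin_resolution = spectrum$bin_resolution,
      channel_labels = spectrum$channel_labels,
      parent = spectrum
    ),
    class = "fpvs_metric"
  )
}

#' @export
print.fpvs_metric <- function(x, ...) {
  cat(sprintf(
    "<fpvs_metric> %s, %d channels x %d bins (%d neighbour bins per side, skipping %d)\n",
    x$metric, nrow(x$values), ncol(x$values),
    x$neighborhood$n_per_side, x$neighborhood$skip_adjacent
  ))
  invisible(x)
}

#' Neighbour-bin signal-to-noise ratio spectrum
#'
#' The SNR at each bin is its amplitude divided by the mean amplitude of
#' the 20 surrounding bins — 10 on each side, excluding the immediately
#' adjacent bin (offsets 2..11) — so 1 is the noise level. Bins without a
#' full neighbourhood on both sides are flagged undefined (`NA`), as are
#' bins whose neighbourhood mean is zero.
#'
#' @param spectrum An [amplitude_spectrum()].
#' @param n_per_side Neighbour bins per side (default 10).
#' @param skip_adjacent Adjacent bins excluded per side (default 1).
#' @return An `fpvs_metric` with `metric = "snr"`.
#' @export
snr_spectrum <- function(spectrum, n_per_side = 10L, skip_adjacent = 1L) {
  stopifnot(inherits(spectrum, "fpvs_spectrum"))
  st <- neighborhood_stats(spectrum$amplitudes, n_per_side, skip_adjacent)
  m <- st$sum / st$n
  vals <- spectrum$amplitudes / m
  vals[, !st$defined] <- NA_real_
  vals[!is.na(m) & m == 0] <- NA_real_
  new_metric(vals, "snr", spectrum, st$defined, n_per_side, skip_adjacent)
}

#' Neighbour-bin Z-score spectrum
#'
#' The Z-score at each bin is its amplitude minus the mean of the 20
#' surrounding bins, divided by the sample standard deviation (n - 1) of
#' those bins; tested one-tailed against 1.64 for signal-above-noise. Uses
#' the same neighbourhood as [snr_spectrum()]. Bins with an incomplete
#' neighbourhood or zero neighbour variance are flagged undefined (`NA`).
#'
#' @inheritParams snr_spectrum
#' @return An `fpvs_metric` with `metric = "zscore"`.
#' @export
zscore_spectrum <- function(spectrum, n_per_side = 10L, skip_adjacent = 1L) {
  stopifnot(inherits(spectrum, "fpvs_spectrum"))
  st <- neighborhood_stats(spectrum$amplitudes, n_per_side, skip_adjacent)
  m <- st$sum / st$n
  var_s <- (st$sumsq - st$n * m^2) / (st$n - 1)
  sd_s <- sqrt(pmax(var_s, 0))
  vals <- (spectrum$amplitudes - m) / sd_s
  vals[, !st$defined] <- NA_real_
  vals[!is.na(sd_s) & sd_s <= 0] <- NA_real_
  new_metric(vals, "zscore", spectrum, st$defined, n_per_side, skip_adjacent)
}

#' Percent signal increase above the noise level
#'
#' Converts a neighbour-bin SNR into the percentage by which the signal
#' exceeds the noise baseline of 1: an SNR of 2.56 is a 156% increase.
#'
#' @param snr SNR value(s).
#' @return `(snr - 1) * 100`, in percent.
#' @export
percent_signal_increase <- function(snr) {
  if (!is.numeric(snr)) abort_invalid("`snr` must be numeric")
  (snr - 1) * 100
}

#' Look up a metric value at a channel and frequency
#'
#' @param metric An `fpvs_metric` (from [snr_spectrum()] or
#'   [zscore_spectrum()]) or an `fpvs_spectrum`.
#' @param channel Channel label.
#' @param f Bin-aligned frequency in Hz.
#' @return The scalar value; `NA` where the metric is undefined.
#' @export
value_at <- function(metric, channel, f) {
  values <- metric$values %||% metric$amplitudes
  stopifnot_channels(rownames(values), channel)
  k <- bin_index(f, metric)
  unname(values[channel, k + 1L])
}

#' @rdname tidy.fpvs_spectrum
#' @method tidy fpvs_metric
#' @export
tidy.fpvs_metric <- function(x, ...) {
  nb <- ncol(x$values)
  tibble::tibble(
    channel = rep(x$channel_labels, times = nb),
    frequency = rep((seq_len(nb) - 1) * x$bin_resolution,
                    each = length(x$channel_labels)),
    value = as.vector(x$values),
    defined = rep(x$defined, each = length(x$channel_labels))
  )
}

#' Tidy spectra and metric spectra
#'
#' Long-format views of the channels x bins matrices, one row per channel
#' and frequency bin.
#'
#' @param x An `fpvs_spectrum` or `fpvs_metric`.
#' @param ... Unused.
#' @return A tibble with `channel`, `frequency` and the value column
#'   (`amplitude` for spectra; `value` plus `defined` for metrics).
#' @method tidy fpvs_spectrum
#' @export
tidy.fpvs_spectrum <- function(x, ...) {
  nb <- ncol(x$amplitudes)
  tibble::tibble(
    channel = rep(x$channel_labels, times = nb),
    frequency = rep((seq_len(nb) - 1) * x$bin_resolution,
                    each = length(x$channel_labels)),
    amplitude = as.vector(x$amplitudes)
  )
}

#' Combined spectrum table
#'
#' One row per channel and frequency bin with amplitude, SNR, Z-score and
#' the defined flag — the export schema shared by per-subject and
#' grand-average spectra.
#'
#' @param spectrum An [amplitude_spectrum()].
#' @param ... Passed to [snr_spectrum()] and [zscore_spectrum()].
#' @return A tibble with columns `channel`, `frequency`, `amplitude`,
#'   `snr`, `z`, `defined`.
#' @export
spectrum_table <- function(spectrum, ...) {
  amp <- tidy.fpvs_spectrum(spectrum)
  snr <- tidy.fpvs_metric(snr_spectrum(spectrum, ...))
  z <- tidy.fpvs_metric(zscore_spectrum(spectrum, ...))
  amp$snr <- snr$value
  amp$z <- z$value
  amp$defined <- snr$defined
  amp
}
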