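#' Construct a multi-channel EEG recording
#'
#' The central signal container: a channels x samples matrix in microvolts,
#' its sampling rate, the electrode montage, and a trigger/event table.
#' Trigger sample indices are 0-based offsets from the first sample (the
#' data column for a trigger at `sample` s is `data[, s + 1]`).
#'
#' @param data Numeric matrix, channels x samples (microvolts). Row names,
#'   if present, must match `channel_labels`.
#' @param sampling_rate Sampling rate in Hz (> 0).
#' @param channel_labels Character vector of 10-20 channel names, one per
#'   row of `data`.
#' @param montage Optional tibble with columns `label`, `x`, `y`, `z`
#'   giving electrode positions (see [montage_biosemi32()]).
#' @param triggers Tibble with columns `sample` (0-based integer) and
#'   `code` (character); may have zero rows.
#' @param metadata Free-form provenance list; the preprocessing functions
#'   append a `chain` entry describing each applied step.
#' @return An object of class `fpvs_recording`.
#' @export
eeg_recording <- function(data, sampling_rate, channel_labels = rownames(data),
                          montage = NULL,
                          triggers = tibble::tibble(sample = integer(),
                                                    code = character()),
                          metadata = list()) {
  if (!is.matrix(data) || !is.numeric(data)) {
    abort_invalid("`data` must be a numeric channels x samples matrix")
  }
  if (is.null(channel_labels)) {
    abort_invalid("`channel_labels` must be supplied when `data` has no rownames")
  }
  channel_labels <- as.character(channel_labels)
  if (length(channel_labels) != nrow(data)) {
    abort_invalid("length(channel_labels) must equal nrow(data)")
  }
  if (!is_number(sampling_rate) || sampling_rate <= 0) {
    abort_invalid("`sampling_rate` must be a positive number")
  }
  triggers <- tibble::as_tibble(triggers)
  if (!all(c("sample", "code") %in% names(triggers))) {
    abort_invalid("`triggers` must have columns `sample` and `code`")
  }
  if (nrow(triggers) > 0 &&
      (min(triggers$sample) < 0 || max(triggers$sample) >= ncol(data))) {
    abort_invalid("trigger sample indices must lie within [0, n_samples)")
  }
  rownames(data) <- channel_labels
  structure(
    list(
      data = data,
      sampling_rate = sampling_rate,
      channel_labels = channel_labels,
      montage = montage,
      triggers = triggers,
      metadata = metadata
    ),
    class = "fpvs_recording"
  )
}

#' @export
print.fpvs_recording <- function(x, ...) {
  cat(sprintf(
    "<fpvs_recording> %d channels x %d samples @ %g Hz (%.1f s), %d triggers\n",
    nrow(x$data), ncol(x$data), x$sampling_rate,
    ncol(x$data) / x$sampling_rate, nrow(x$triggers)
  ))
  chain <- x$metadata$chain
  if (length(chain)) cat("  chain:", paste(unlist(chain), collapse = " -> "), "\n")
  invisible(x)
}

n_samples <- function(rec) ncol(rec$data)

append_chain <- function(rec, step) {
  rec$metadata$chain <- c(rec$metadata$chain, step)
  rec
}

#' Construct an epoch
#'
#' One segmented stimulation sequence of one subject. `window` records
#' whether the epoch is the full segment (baselines + fades + stimulation)
#' or the cropped full-contrast analysis window, which downstream spectral
#' functions require.
#'
#' @param data Numeric channels x samples matrix (microvolts).
#' @param sampling_rate Sampling rate in Hz.
#' @param window `"full"` or `"analysis"`.
#' @param sequence_id Integer index of the sequence within the recording.
#' @param subject_id Subject identifier string.
#' @param channel_labels Channel names (defaults to rownames).
#' @param montage Optional montage tibble, carried for interpolation.
#' @param metadata Provenance list.
#' @return An object of class `fpvs_epoch`.
#' @export
new_epoch <- function(data, sampling_rate, window = c("full", "analysis"),
                      sequence_id = 1L, subject_id = "s01",
                      channel_labels = rownames(data), montage = NULL,
                      metadata = list()) {
  window <- match.arg(window)
  if (!is.matrix(data) || !is.numeric(data)) {
    abort_invalid("`data` must be a numeric channels x samples matrix")
  }
  if (is.null(channel_labels)) {
    abort_invalid("`channel_labels` must be supplied when `data` has no rownames")
  }
  rownames(data) <- channel_labels
  structure(
    list(
      data = data,
      sampling_rate = sampling_rate,
      window = window,
      sequence_id = as.integer(sequence_id),
      subject_id = subject_id,
      channel_labels = as.character(channel_labels),
      montage = montage,
      metadata = metadata
    ),
    class = "fpvs_epoch"
  )
}

#' @export
print.fpvs_epoch <- function(x, ...) {
  cat(sprintf(
    "<fpvs_epoch> %s window, %d channels x %d samples @ %g Hz (subject %s, seq %d)\n",
    x$window, nrow(x$data), ncol(x$data), x$sampling_rate,
    x$subject_id, x$sequence_id
  ))
  invisible(x)
}
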