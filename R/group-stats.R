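# Group-level aggregation and inference: grand-averaged amplitude spectra,
# channel-wise Z-tests with Bonferroni correction, t-tests of SNR against
# the noise level, paired contrasts, and per-subject significance tallies.

#' Grand-average amplitude spectrum
#'
#' Per-bin, per-channel arithmetic mean of the subjects' amplitude spectra.
#' Averaging happens in the amplitude domain, after each subject's FFT;
#' SNR and Z-scores of the grand average are then computed on the averaged
#' spectrum with [snr_spectrum()] / [zscore_spectrum()].
#'
#' @param spectra Non-empty list of [amplitude_spectrum()] objects on
#'   identical bin grids and channel sets.
#' @return An `fpvs_spectrum`.
#' @export
grand_average_spectrum <- function(spectra) {
  if (!is.list(spectra) || length(spectra) == 0L) {
    abort_invalid("`spectra` must be a non-empty list")
  }
  ref <- spectra[[1L]]
  for (sp in spectra) {
    stopifnot(inherits(sp, "fpvs_spectrum"))
    if (!identical(dim(sp$amplitudes), dim(ref$amplitudes)) ||
        abs(sp$bin_resolution - ref$bin_resolution) > 1e-12 ||
        !identical(sp$channel_labels, ref$channel_labels)) {
      abort_invalid("spectra differ in bin grid or channel set")
    }
  }
  out <- ref
  out$amplitudes <- Reduce(`+`, lapply(spectra, `[[`, "amplitudes")) /
    length(spectra)
  out$n_averaged_sequences <- sum(vapply(spectra, `[[`, 0,
                                         "n_averaged_sequences"))
  out$subject_id <- "grand_average"
  out
}

new_test_result <- function(test, statistic, df, p_one, p_two, alpha,
                            corrected_alpha, significant, n,
                            channel = NA_character_, frequency = NA_real_,
                            tail = "one") {
  structure(
    tibble::tibble(
      test = test,
      channel = channel,
      frequency = frequency,
      statistic = statistic,
      df = df,
      p_one_tailed = p_one,
      p_two_tailed = p_two,
      alpha = alpha,
      corrected_alpha = corrected_alpha,
      tail = tail,
      significant = significant,
      n = n
    ),
    class = c("fpvs_test", "tbl_df", "tbl", "data.frame")
  )
}

#' Channel-wise Z-tests of a grand-averaged spectrum
#'
#' Converts the neighbour-bin Z-score of every channel at a target
#' frequency into a one-tailed normal p-value (the directional hypothesis
#' is signal above noise; the uncorrected one-tailed criterion at
#' `alpha = 0.05` is Z > 1.64) and flags significance against the
#' Bonferroni-corrected level `alpha / n_channels_for_correction`
#' (0.05 / 32 = 0.0015625 for a whole 32-channel montage).
#'
#' @param grand A grand-averaged [amplitude_spectrum()].
#' @param f Bin-aligned target frequency in Hz.
#' @param alpha Family-wise significance level (default 0.05).
#' @param n_channels_for_correction Number of channels in the Bonferroni
#'   correction (default: all channels of the spectrum).
#' @return A tibble of class `fpvs_test`, one row per channel; channels
#'   with an undefined Z carry `NA` statistics and `significant = NA`
#'   (untestable).
#' @export
z_test_channels <- function(grand, f, alpha = 0.05,
                            n_channels_for_correction =
                              length(grand$channel_labels)) {
  stopifnot(inherits(grand, "fpvs_spectrum"))
  z <- zscore_spectrum(grand)
  corrected <- alpha / n_channels_for_correction
  rows <- lapply(grand$channel_labels, function(ch) {
    zv <- value_at(z, ch, f)
    p1 <- stats::pnorm(zv, lower.tail = FALSE)
    new_test_result(
      test = "z_vs_noise",
      channel = ch, frequency = f,
      statistic = zv, df = NA_real_,
      p_one = p1, p_two = 2 * pmin(p1, 1 - p1),
      alpha = alpha, corrected_alpha = corrected,
      significant = if (is.na(zv)) NA else p1 < corrected,
      n = grand$n_averaged_sequences
    )
  })
  dplyr::bind_rows(rows)
}

#' One-sample t-test of SNR values against the noise level
#'
#' Tests whether individual-subject SNR values at a target frequency
#' exceed 1 (signal above noise). Both tails are reported; the directional
#' hypothesis makes the one-tailed p drive the default significance flag.
#'
#' @param values Numeric vector of per-subject SNR values (n >= 2).
#' @param alpha Significance level (default 0.05).
#' @param tail `"one"` (default) or `"two"`: which p-value sets the
#'   significance flag.
#' @param null Noise-level null value (default 1).
#' @return A one-row `fpvs_test` tibble.
#' @export
t_test_vs_noise <- function(values, alpha = 0.05, tail = c("one", "two"),
                            null = 1) {
  tail <- match.arg(tail)
  if (!is.numeric(values) || length(values) < 2L || anyNA(values) ||
      any(!is.finite(values))) {
    abort_invalid("`values` must be >= 2 finite SNR values")
  }
  if (stats::sd(values) == 0) {
    if (mean(values) == null) {
      # exactly at the noise level: t = 0 by convention
      return(new_test_result(
        test = "t_vs_noise", statistic = 0, df = length(values) - 1,
        p_one = 0.5, p_two = 1, alpha = alpha, corrected_alpha = alpha,
        significant = FALSE, n = length(values), tail = tail
      ))
    }
    abort_invalid("`values` have zero variance; the t-statistic is undefined")
  }
  tt <- stats::t.test(values, mu = null, alternative = "two.sided")
  stat <- unname(tt$statistic)
  df <- unname(tt$parameter)
  p1 <- stats::pt(stat, df, lower.tail = FALSE)
  p2 <- unname(tt$p.value)
  new_test_result(
    test = "t_vs_noise",
    statistic = stat, df = df,
    p_one = p1, p_two = p2,
    alpha = alpha, corrected_alpha = alpha,
    significant = (if (tail == "one") p1 else p2) < alpha,
    n = length(values), tail = tail
  )
}

#' Paired t-test between two matched sets of values
#'
#' One-sample t-test on the per-subject differences `values_a - values_b`
#' (e.g. right vs left occipito-temporal SNR, or natural vs scrambled
#' conditions). Both tails reported; condition contrasts conventionally
#' use the two-tailed p, lateralization contrasts the one-tailed p.
#'
#' @param values_a,values_b Equal-length numeric vectors paired by subject.
#' @param alpha Significance level.
#' @param tail `"two"` (default) or `"one"` for the significance flag; the
#'   one-tailed p tests `values_a > values_b`.
#' @return A one-row `fpvs_test` tibble.
#' @export
paired_t <- function(values_a, values_b, alpha = 0.05,
                     tail = c("two", "one")) {
  tail <- match.arg(tail)
  if (!is.numeric(values_a) || !is.numeric(values_b) ||
      length(values_a) != length(values_b) || length(values_a) < 2L) {
    abort_invalid("`values_a` and `values_b` must be numeric, equal length >= 2")
  }
  d <- values_a - values_b
  if (anyNA(d) || any(!is.finite(d))) abort_invalid("values must be finite")
  if (stats::sd(d) == 0 && mean(d) == 0) {
    # all-equal pairs: t = 0 by convention
    return(new_test_result(
      test = "paired_t", statistic = 0, df = length(d) - 1,
      p_one = 0.5, p_two = 1, alpha = alpha, corrected_alpha = alpha,
      significant = FALSE, n = length(d), tail = tail
    ))
  }
  if (stats::sd(d) == 0) {
    abort_invalid("paired differences have zero variance; t is undefined")
  }
  tt <- stats::t.test(d, mu = 0, alternative = "two.sided")
  stat <- unname(tt$statistic)
  df <- unname(tt$parameter)
  p1 <- stats::pt(stat, df, lower.tail = FALSE)
  p2 <- unname(tt$p.value)
  new_test_result(
    test = "paired_t",
    statistic = stat, df = df,
    p_one = p1, p_two = p2,
    alpha = alpha, corrected_alpha = alpha,
    significant = (if (tail == "one") p1 else p2) < alpha,
    n = length(d), tail = tail
  )
}

#' Count subjects with an individually significant response
#'
#' Counts subjects whose per-subject Z at the given channel and frequency
#' strictly exceeds `z_threshold` (1.64 for one-tailed p < 0.05). For each
#' non-significant subject, also reports whether *any other* channel
#' exceeds the threshold — the fallback tally used when reporting that the
#' remaining infants responded elsewhere on the scalp.
#'
#' @param cohort A cohort table (see [cohort_table()]) with columns
#'   `subject_id`, `channel`, `frequency`, `z`.
#' @param channel Channel of interest.
#' @param f Target frequency in Hz.
#' @param z_threshold Threshold (default 1.64).
#' @return A list with `count_significant` and a `subjects` tibble
#'   (`subject_id`, `z`, `significant`, `other_channel_significant`).
#' @export
per_subject_significance <- function(cohort, channel, f, z_threshold = 1.64) {
  stopifnot(is.data.frame(cohort))
  at <- dplyr::filter(cohort, .data$channel == !!channel,
                      abs(.data$frequency - f) < 1e-9)
  if (nrow(at) == 0L) {
    return(list(count_significant = 0L,
                subjects = tibble::tibble(subject_id = character(),
                                          z = numeric(),
                                          significant = logical(),
                                          other_channel_significant = logical())))
  }
  others <- dplyr::filter(cohort, .data$channel != !!channel,
                          abs(.data$frequency - f) < 1e-9)
  other_sig <- others |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::summarise(other = any(.data$z > z_threshold, na.rm = TRUE))
  subjects <- at |>
    dplyr::transmute(
      subject_id = .data$subject_id,
      z = .data$z,
      significant = !is.na(.data$z) & .data$z > z_threshold
    ) |>
    dplyr::left_join(other_sig, by = "subject_id") |>
    dplyr::mutate(
      other_channel_significant = dplyr::if_else(
        .data$significant, NA, dplyr::coalesce(.data$other, FALSE))
    ) |>
    dplyr::select(-"other")
  list(
    count_significant = sum(subjects$significant),
    subjects = subjects
  )
}

#' Per-subject metric table at target frequencies
#'
#' One row per subject, channel and target frequency carrying the
#' neighbour-bin SNR and Z of that subject's (sequence-averaged) amplitude
#' spectrum — the tabular backbone of all group-level statistics.
#'
#' @param spectra List of per-subject [amplitude_spectrum()] objects.
#' @param target_freqs Bin-aligned frequencies of interest (Hz).
#' @param condition Condition label stored with every row.
#' @param n_sequences Optional integer vector: sequences retained per
#'   subject (defaults to each spectrum's `n_averaged_sequences`).
#' @return A tibble with columns `subject_id`, `condition`, `channel`,
#'   `frequency`, `snr`, `z`, `n_sequences`.
#' @export
cohort_table <- function(spectra, target_freqs = c(6, 1.2, 2.4),
                         condition = "natural", n_sequences = NULL) {
  rows <- purrr::imap(spectra, function(sp, i) {
    snr <- snr_spectrum(sp)
    z <- zscore_spectrum(sp)
    n_seq <- if (is.null(n_sequences)) sp$n_averaged_sequences else n_sequences[i]
    purrr::map_dfr(target_freqs, function(f) {
      tibble::tibble(
        subject_id = sp$subject_id %||% sprintf("s%02d", i),
        condition = condition,
        channel = sp$channel_labels,
        frequency = f,
        snr = vapply(sp$channel_labels, function(ch) value_at(snr, ch, f), 0),
        z = vapply(sp$channel_labels, function(ch) value_at(z, ch, f), 0),
        n_sequences = n_seq
      )
    })
  })
  dplyr::bind_rows(rows)
}

#' Topography table of a metric at one frequency
#'
#' Flat per-channel export (channel, x, y, value) consumable by any
#' plotting tool; y is the anterior-posterior axis of the idealised head.
#'
#' @param metric An `fpvs_metric` or `fpvs_spectrum` with a montage.
#' @param f Bin-aligned frequency (Hz).
#' @return A tibble with `channel`, `x`, `y`, `value`.
#' @export
topography_table <- function(metric, f) {
  montage <- metric$montage %||% metric$parent$montage
  if (is.null(montage)) abort_invalid("no montage attached; cannot export")
  vals <- vapply(montage$label, function(ch) value_at(metric, ch, f), 0)
  tibble::tibble(
    channel = montage$label,
    x = montage$x,
    y = montage$y,
    value = unname(vals)
  )
}
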