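#' Oddball frequency of a periodic oddball design
#'
#' In a fast periodic visual stimulation (FPVS) oddball paradigm, stimuli
#' appear at a base rate and every `divisor`-th stimulus belongs to the
#' oddball category, so the oddball category is tagged at
#' `base_rate / divisor` Hz (6 Hz / 5 = 1.2 Hz in the canonical infant
#' face-categorization design).
#'
#' @param base_rate Stimulus presentation rate in Hz. Must be positive.
#' @param divisor Integer periodicity of the oddball (every n-th stimulus).
#' @return The oddball frequency in Hz.
#' @examples
#' oddball_frequency(6, 5) # 1.2
#' @export
oddball_frequency <- function(base_rate, divisor) {
  if (!is_number(base_rate) || base_rate <= 0) {
    abort_invalid("`base_rate` must be a positive number")
  }
  if (!is_integerish(divisor) || divisor < 1) {
    abort_invalid("`divisor` must be an integer >= 1")
  }
  base_rate / round(divisor)
}

#' Harmonic series of a tagged frequency
#'
#' Periodic neural responses appear at a fundamental and its integer
#' harmonics; quantification typically collects harmonics up to some
#' maximum while excluding harmonics that coincide with the base
#' stimulation rate (e.g. 5 x 1.2 Hz = 6 Hz).
#'
#' @param fundamental Fundamental frequency in Hz (> 0).
#' @param max_freq Highest frequency to include, in Hz (>= fundamental).
#' @param exclude Frequencies to drop from the series (Hz), compared with a
#'   1e-9 Hz tolerance.
#' @return Numeric vector of harmonic frequencies in Hz.
#' @examples
#' harmonic_frequencies(1.2, 2.5) # 1.2, 2.4
#' harmonic_frequencies(1.2, 6.1, exclude = 6) # drops the base-rate overlap
#' @export
harmonic_frequencies <- function(fundamental, max_freq, exclude = numeric()) {
  if (!is_number(fundamental) || fundamental <= 0) {
    abort_invalid("`fundamental` must be a positive number")
  }
  if (!is_number(max_freq) || max_freq < fundamental) {
    abort_invalid("`max_freq` must be >= `fundamental`")
  }
  k <- seq_len(floor(max_freq / fundamental + 1e-9))
  freqs <- k * fundamental
  keep <- vapply(
    freqs,
    function(f) all(abs(f - exclude) > 1e-9),
    logical(1)
  )
  freqs[keep]
}

#' Build an FPVS oddball stimulation sequence
#'
#' Constructs the full timeline of one stimulation sequence: a pre-stimulus
#' baseline, a linear fade-in, a full-contrast stimulation window, a linear
#' fade-out and a post-stimulus baseline. Stimuli are presented by
#' sinusoidal contrast modulation at `base_rate` Hz starting from 0%
#' contrast (grey background); every `divisor`-th stimulus is the oddball.
#' The default parameters give the canonical design: 6 Hz base rate,
#' oddball every 5th image (1.2 Hz), 20-s stimulation flanked by 2-s fades
#' and 2-s baselines (28 s in total), i.e. 120 images per 20-s window of
#' which 24 are oddballs.
#'
#' One continuous cycle count runs across fade-in, full-contrast window and
#' fade-out, so the base/oddball alternation keeps its phase throughout the
#' sequence. Cycle onsets (0% contrast minima) fall at
#' `cycle_index / base_rate` seconds from fade-in onset.
#'
#' @param base_rate Presentation rate in Hz.
#' @param divisor Oddball periodicity (integer >= 1).
#' @param stim_duration Duration of the full-contrast window in seconds;
#'   `stim_duration * base_rate / divisor` must be an integer so the oddball
#'   frequency is bin-aligned with the analysis window.
#' @param fade_in,fade_out Durations of the linear contrast-depth ramps (s).
#' @param pre_baseline,post_baseline Durations of the flanking baselines (s).
#' @return An object of class `fpvs_sequence`: a list with the design
#'   parameters, derived frequencies, and an `events` tibble with columns
#'   `onset` (s from fade-in onset), `category` (`"base"`/`"oddball"`),
#'   `cycle_index` (0-based) and `full_contrast` (logical).
#' @examples
#' seq <- build_sequence()
#' sum(seq$events$full_contrast) # 120 images in the 20-s window
#' @export
build_sequence <- function(base_rate = 6, divisor = 5, stim_duration = 20,
                           fade_in = 2, fade_out = 2,
                           pre_baseline = 2, post_baseline = 2) {
  if (!is_number(base_rate) || base_rate <= 0) {
    abort_invalid("`base_rate` must be a positive number")
  }
  if (!is_integerish(divisor) || divisor < 1) {
    abort_invalid("`divisor` must be an integer >= 1")
  }
  for (nm in c("stim_duration", "fade_in", "fade_out",
               "pre_baseline", "post_baseline")) {
    v <- get(nm)
    if (!is_number(v) || v < 0) abort_invalid(paste0("`", nm, "` must be >= 0"))
  }
  n_oddball_cycles <- stim_duration * base_rate / divisor
  if (!is_integerish(n_oddball_cycles)) {
    abort_invalid(
      paste0("invalid design: stim_duration x oddball frequency = ",
             format(n_oddball_cycles),
             " is not an integer number of oddball cycles"),
      class = "fpvs_invalid_design"
    )
  }
  stim_total <- fade_in + stim_duration + fade_out
  n_cycles <- stim_total * base_rate
  if (!is_integerish(n_cycles)) {
    abort_invalid(
      "invalid design: fades + stimulation do not span a whole number of cycles",
      class = "fpvs_invalid_design"
    )
  }
  n_cycles <- round(n_cycles)
  cycle_index <- seq_len(n_cycles) - 1L
  onset <- cycle_index / base_rate
  category <- ifelse((cycle_index + 1L) %% divisor == 0L, "oddball", "base")
  events <- tibble::tibble(
    onset = onset,
    category = category,
    cycle_index = cycle_index,
    full_contrast = onset >= fade_in - 1e-12 &
      onset < fade_in + stim_duration - 1e-12
  )
  structure(
    list(
      base_rate = base_rate,
      divisor = divisor,
      oddball_rate = base_rate / divisor,
      stim_duration = stim_duration,
      fade_in = fade_in,
      fade_out = fade_out,
      pre_baseline = pre_baseline,
      post_baseline = post_baseline,
      total_span = pre_baseline + stim_total + post_baseline,
      stim_total = stim_total,
      events = events
    ),
    class = "fpvs_sequence"
  )
}

#' @export
print.fpvs_sequence <- function(x, ...) {
  cat(sprintf(
    "<fpvs_sequence> %g Hz base, oddball every %d (%g Hz), %g s stimulation\n",
    x$base_rate, x$divisor, x$oddball_rate, x$stim_duration
  ))
  cat(sprintf(
    "  span %g s = %g baseline + %g fade-in + %g stim + %g fade-out + %g baseline\n",
    x$total_span, x$pre_baseline, x$fade_in, x$stim_duration,
    x$fade_out, x$post_baseline
  ))
  cat(sprintf("  %d cycles (%d oddball) during fades + stimulation\n",
              nrow(x$events), sum(x$events$category == "oddball")))
  invisible(x)
}

#' Stimulus contrast envelope at a time point
#'
#' The contrast of the displayed stimulus as a function of time from epoch
#' start (baseline onset). Within the stimulation period the envelope is the
#' raised cosine `0.5 * (1 - cos(2 * pi * base_rate * t'))` of time `t'`
#' from fade-in onset — zero at each cycle onset, full contrast midway
#' through each cycle — multiplied by the linear contrast-modulation depth
#' ramp (0 to 1 over the fade-in, 1 to 0 over the fade-out). During the
#' baselines the screen stays at 0% contrast.
#'
#' @param seq An [build_sequence()] object.
#' @param t Time(s) in seconds from epoch start; must lie in
#'   `[0, seq$total_span]`.
#' @return Contrast value(s) in `[0, 1]`.
#' @export
envelope_at <- function(seq, t) {
  stopifnot(inherits(seq, "fpvs_sequence"))
  if (!is.numeric(t) || anyNA(t)) abort_invalid("`t` must be numeric")
  if (any(t < -1e-12 | t > seq$total_span + 1e-12)) {
    abort_invalid(
      sprintf("`t` outside the epoch [0, %g] s", seq$total_span),
      class = "fpvs_out_of_range"
    )
  }
  ts <- t - seq$pre_baseline # time from fade-in onset
  depth <- numeric(length(t))
  in_stim <- ts >= 0 & ts <= seq$stim_total
  ramp_in <- in_stim & ts < seq$fade_in
  full <- in_stim & ts >= seq$fade_in & ts <= seq$fade_in + seq$stim_duration
  ramp_out <- in_stim & ts > seq$fade_in + seq$stim_duration
  if (seq$fade_in > 0) depth[ramp_in] <- ts[ramp_in] / seq$fade_in
  depth[full] <- 1
  if (seq$fade_out > 0) {
    depth[ramp_out] <- (seq$stim_total - ts[ramp_out]) / seq$fade_out
  }
  carrier <- 0.5 * (1 - cos(2 * pi * seq$base_rate * pmax(ts, 0)))
  out <- depth * carrier
  pmin(pmax(out, 0), 1)
}

#' Trigger table for a stimulation sequence
#'
#' Emulates the acquisition-side trigger scheme: one trigger at trial start
#' (fade-in onset) and one at the 0%-contrast minimum of every stimulation
#' cycle, coded by stimulus category. Sample indices are 0-based offsets
#' from trial start, computed as `round(onset * sampling_rate)` with
#' half-away-from-zero rounding.
#'
#' @param seq An [build_sequence()] object.
#' @param sampling_rate Sampling rate in Hz; must exceed twice the base rate.
#' @return A tibble with columns `sample` (0-based), `code` (`"trial_start"`,
#'   `"base"`, `"oddball"`) and `onset` (s from trial start).
#' @export
triggers_for <- function(seq, sampling_rate) {
  stopifnot(inherits(seq, "fpvs_sequence"))
  if (!is_number(sampling_rate) || sampling_rate <= 2 * seq$base_rate) {
    abort_invalid("`sampling_rate` must exceed twice the base rate")
  }
  ev <- seq$events
  tibble::tibble(
    sample = as.integer(round_half_up(c(0, ev$onset) * sampling_rate)),
    code = c("trial_start", ev$category),
    onset = c(0, ev$onset)
  )
}

#' Phase-scramble an image
#'
#' Randomises the phases of the 2-D Fourier transform of an intensity image
#' while preserving its amplitude (power) spectrum exactly. The result has
#' the same low-level spectral content as the input but is unrecognisable.
#' Random phases come from the Fourier transform of a white-noise image,
#' which guarantees Hermitian symmetry and hence a real-valued output;
#' self-conjugate bins (DC and Nyquist combinations), whose phase is pinned
#' to 0 or pi for any real image, keep their original values, so a constant
#' image is returned unchanged.
#'
#' @param pixels A numeric matrix of pixel intensities.
#' @param seed Integer seed making the scramble reproducible.
#' @return A real-valued matrix with the same dimensions and the same 2-D
#'   amplitude spectrum as `pixels`.
#' @export
phase_scramble_image <- function(pixels, seed) {
  if (!is.matrix(pixels) || !is.numeric(pixels) || length(pixels) == 0L) {
    abort_invalid("`pixels` must be a non-empty numeric matrix")
  }
  if (!is_integerish(seed)) abort_invalid("`seed` must be an integer")
  nr <- nrow(pixels)
  nc <- ncol(pixels)
  fwd <- stats::fft(pixels)
  noise <- withr::with_seed(as.integer(seed), {
    matrix(stats::rnorm(nr * nc), nr, nc)
  })
  phase <- Arg(stats::fft(noise))
  scrambled <- Mod(fwd) * exp(1i * phase)
  # self-conjugate bins: row/col index maps to itself under reflection
  self_r <- which(((seq_len(nr) - 1L) * 2L) %% nr == 0L)
  self_c <- which(((seq_len(nc) - 1L) * 2L) %% nc == 0L)
  scrambled[self_r, self_c] <- fwd[self_r, self_c]
  out <- Re(stats::fft(scrambled, inverse = TRUE)) / (nr * nc)
  dimnames(out) <- dimnames(pixels)
  out
}

#' Events of a stimulation sequence as a tibble
#'
#' @param x An [build_sequence()] object.
#' @param ... Unused.
#' @return The `events` tibble (onset, category, cycle_index, full_contrast).
#' @method tidy fpvs_sequence
#' @export
tidy.fpvs_sequence <- function(x, ...) x$events

#' Write the event list of a sequence as JSON
#'
#' Exports `(onset_s, category, cycle_index)` records, one per stimulation
#' cycle, for use by external presentation or analysis tools.
#'
#' @param seq An [build_sequence()] object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_sequence_events <- function(seq, path) {
  stopifnot(inherits(seq, "fpvs_sequence"))
  ev <- data.frame(
    onset_s = seq$events$onset,
    category = seq$events$category,
    cycle_index = seq$events$cycle_index
  )
  jsonlite::write_json(ev, path, digits = NA)
  invisible(path)
}
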