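# Synthetic EEG cohorts: frequency-tagged harmonic responses on scalp
# topographies over 1/f background noise, with the acquisition-side trigger
# scheme, so the full preprocessing + quantification chain can be exercised
# end to end.

#' Describe a frequency-tagged neural component
#'
#' A steady-state generator: a fundamental frequency, peak amplitudes for
#' its harmonics, per-harmonic phases, and a scalp topography of channel
#' weights in `[0, 1]`. During simulation the component contributes
#' `weight * amplitude_k * sin(2 pi k f t + phase_k)` at each listed
#' channel, scaled by the contrast-modulation depth ramp during fades and
#' silent during baselines.
#'
#' @param fundamental Fundamental frequency in Hz; must span an integer
#'   number of cycles of the analysis window so its bins are leakage-free.
#' @param harmonic_amplitudes Named numeric vector: names are harmonic
#'   numbers (`"1"`, `"2"`, ...), values peak amplitudes in microvolts.
#' @param phase Phase in radians, recycled across harmonics.
#' @param topography Named numeric vector of channel weights in `[0, 1]`.
#' @param role `"base"` or `"oddball"`; the scrambled condition silences
#'   oddball components.
#' @return An object of class `fpvs_component`.
#' @export
neural_component <- function(fundamental, harmonic_amplitudes, phase = 0,
                             topography, role = c("base", "oddball")) {
  role <- match.arg(role)
  if (!is_number(fundamental) || fundamental <= 0) {
    abort_invalid("`fundamental` must be a positive number")
  }
  if (is.null(names(harmonic_amplitudes)) || any(harmonic_amplitudes < 0)) {
    abort_invalid("`harmonic_amplitudes` must be named (by harmonic) and >= 0")
  }
  if (is.null(names(topography)) || length(topography) == 0L ||
      all(topography <= 0)) {
    abort_invalid("`topography` needs named weights with at least one > 0")
  }
  phase <- rep_len(phase, length(harmonic_amplitudes))
  structure(
    list(
      fundamental = fundamental,
      harmonic_amplitudes = harmonic_amplitudes,
      phase = phase,
      topography = topography,
      role = role
    ),
    class = "fpvs_component"
  )
}

#' Background-noise model
#'
#' Pink (`1/f^alpha` power) background noise plus an optional broadband
#' white floor, synthesised per channel by shaping white Gaussian noise in
#' the frequency domain over the `band` of interest. Channels are
#' independent; the per-channel metrics quantified downstream do not
#' depend on spatial noise correlation.
#'
#' @param exponent Spectral slope alpha of the power spectrum, in `[0, 3]`.
#' @param scale RMS of the shaped noise within `band`, in microvolts.
#' @param white_floor RMS of the additional white noise, in microvolts.
#' @param band Frequency support of the shaped noise (Hz).
#' @return An object of class `fpvs_noise`.
#' @export
noise_model <- function(exponent = 1, scale = 2, white_floor = 0.1,
                        band = c(0.1, 100)) {
  if (!is_number(exponent) || exponent < 0 || exponent > 3) {
    abort_invalid("`exponent` must lie in [0, 3]")
  }
  if (!is_number(scale) || scale < 0) abort_invalid("`scale` must be >= 0")
  if (!is_number(white_floor) || white_floor < 0) {
    abort_invalid("`white_floor` must be >= 0")
  }
  structure(
    list(exponent = exponent, scale = scale, white_floor = white_floor,
         band = band),
    class = "fpvs_noise"
  )
}

#' Default tagged components of the oddball design
#'
#' The base-rate component (6 Hz, medial occipital, 1 microvolt at Oz with
#' a smaller second harmonic) models visual synchronization to the
#' stimulation stream; the oddball component (1.2 Hz plus a 2.4 Hz second
#' harmonic, right occipito-temporal, 0.15 microvolt at P8 with a 0.55
#' weight at the homologous left channel P7) models the category
#' discrimination response. Amplitudes are free parameters of the
#' simulation, chosen so that single-sequence base-rate SNR comfortably
#' clears the QC threshold and cohort-level oddball SNR lands in the
#' low-single-digit range typical of infant recordings.
#'
#' @return List of two [neural_component()] objects.
#' @export
default_components <- function() {
  list(
    neural_component(
      fundamental = 6,
      harmonic_amplitudes = c("1" = 1.0, "2" = 0.25),
      topography = c(Oz = 1, O1 = 0.8, O2 = 0.8, PO3 = 0.5, PO4 = 0.5,
                     Pz = 0.3),
      role = "base"
    ),
    neural_component(
      fundamental = 1.2,
      harmonic_amplitudes = c("1" = 0.15, "2" = 0.06),
      topography = c(P8 = 1, P7 = 0.55, O1 = 0.3, O2 = 0.3, PO3 = 0.3,
                     PO4 = 0.3),
      role = "oddball"
    )
  )
}

#' Simulation configuration
#'
#' Bundles everything needed to simulate one subject or a cohort: montage,
#' tagged components, noise model, stimulation design, number of sequences,
#' native acquisition rate, between-subject amplitude variability and the
#' condition. In the `"scrambled"` condition (phase-scrambled images:
#' identical power spectra, no recognisable category) the oddball
#' components are silenced — amplitudes forced to 0 — while the base-rate
#' response is kept.
#'
#' @param montage Montage tibble (default [montage_biosemi32()]).
#' @param components List of [neural_component()] objects.
#' @param noise A [noise_model()].
#' @param n_sequences Sequences per subject when simulating a single
#'   subject (cohorts draw per-subject counts; see [simulate_cohort()]).
#' @param sequence The [build_sequence()] stimulation design.
#' @param native_rate Acquisition sampling rate in Hz (>= 500 so the
#'   0.1-100 Hz band is representable with headroom).
#' @param subject_variability Sigma of the lognormal multiplicative spread
#'   of component amplitudes across subjects.
#' @param condition `"natural"` or `"scrambled"`.
#' @param seed Master seed controlling all randomness.
#' @return An object of class `fpvs_sim_config`.
#' @export
sim_config <- function(montage = montage_biosemi32(),
                       components = default_components(),
                       noise = noise_model(),
                       n_sequences = 8,
                       sequence = build_sequence(),
                       native_rate = 512,
                       subject_variability = 0.5,
                       condition = c("natural", "scrambled"),
                       seed = 1L) {
  condition <- match.arg(condition)
  if (!is_integerish(n_sequences) || n_sequences < 1) {
    abort_invalid("`n_sequences` must be an integer >= 1")
  }
  if (!is_number(native_rate) || native_rate < 500) {
    abort_invalid("`native_rate` must be >= 500 Hz")
  }
  for (comp in components) {
    stopifnot(inherits(comp, "fpvs_component"))
    ks <- as.numeric(names(comp$harmonic_amplitudes))
    if (max(ks * comp$fundamental) >= native_rate / 2) {
      abort_invalid("component harmonic above the native Nyquist frequency",
                    class = "fpvs_invalid_config")
    }
    nc <- comp$fundamental * sequence$stim_duration
    if (!is_integerish(nc)) {
      abort_invalid(
        "component fundamental is not bin-aligned with the analysis window",
        class = "fpvs_invalid_config"
      )
    }
    stopifnot_channels(montage$label, names(comp$topography))
  }
  if (condition == "scrambled") {
    components <- lapply(components, function(comp) {
      if (comp$role == "oddball") {
        comp$harmonic_amplitudes[] <- 0
      }
      comp
    })
  }
  structure(
    list(
      montage = montage,
      components = components,
      noise = noise,
      n_sequences = as.integer(n_sequences),
      sequence = sequence,
      native_rate = native_rate,
      subject_variability = subject_variability,
      condition = condition,
      seed = as.integer(seed)
    ),
    class = "fpvs_sim_config"
  )
}

# linear contrast-depth ramp over one stimulation period, sampled at fs
depth_profile <- function(seq, fs) {
  n <- round(seq$stim_total * fs)
  t <- (seq_len(n) - 1) / fs
  depth <- rep(1, n)
  if (seq$fade_in > 0) {
    idx <- t < seq$fade_in
    depth[idx] <- t[idx] / seq$fade_in
  }
  if (seq$fade_out > 0) {
    idx <- t > seq$fade_in + seq$stim_duration
    depth[idx] <- (seq$stim_total - t[idx]) / seq$fade_out
  }
  depth
}

# channels x samples tagged-component signal for samples [s0, s0 + len) of
# a recording described by `manifest` (0-based s0)
component_signal <- function(manifest, s0, len, labels) {
  fs <- manifest$native_rate
  seq <- manifest$sequence
  out <- matrix(0, length(labels), len)
  depth <- depth_profile(seq, fs)
  n_stim <- length(depth)
  for (start in manifest$sequence_starts) {
    stim0 <- round((start + seq$pre_baseline) * fs) # 0-based fade-in onset
    lo <- max(stim0, s0)
    hi <- min(stim0 + n_stim, s0 + len)
    if (lo >= hi) next
    rel <- (lo:(hi - 1)) - stim0 # samples from fade-in onset
    t_sig <- rel / fs - seq$fade_in # 0 at full-contrast onset
    d <- depth[rel + 1L]
    for (comp in manifest$components) {
      ks <- as.numeric(names(comp$harmonic_amplitudes))
      wave <- numeric(length(rel))
      for (j in seq_along(ks)) {
        a <- comp$harmonic_amplitudes[j]
        if (a == 0) next
        wave <- wave + a * sin(2 * pi * ks[j] * comp$fundamental * t_sig +
                                 comp$phase[j])
      }
      if (all(wave == 0)) next
      wave <- wave * d
      rows <- match(names(comp$topography), labels)
      cols <- (lo - s0 + 1L):(hi - s0)
      out[rows, cols] <- out[rows, cols] +
        outer(unname(comp$topography), wave)
    }
  }
  out
}

#' Simulate one subject's EEG recording
#'
#' Produces a continuous multi-channel recording containing `n_sequences`
#' stimulation sequences (each with trial-start and per-cycle triggers),
#' tagged harmonic components present only during stimulation — scaled by
#' the contrast-modulation depth during fades — on top of per-channel 1/f
#' background noise. Fixing the seed makes the output bit-identical.
#'
#' @param config A [sim_config()].
#' @param subject_id Subject identifier.
#' @param n_sequences Number of sequences (defaults to the config value).
#' @param amp_factors Multiplicative amplitude factor per component
#'   (between-subject variability; default 1).
#' @param seed Seed for this subject (defaults to the config master seed).
#' @return An [eeg_recording()] whose metadata carries the generative
#'   manifest (components after scaling, sequence start times, seed).
#' @export
simulate_subject <- function(config, subject_id = "s01",
                             n_sequences = config$n_sequences,
                             amp_factors = rep(1, length(config$components)),
                             seed = config$seed) {
  stopifnot(inherits(config, "fpvs_sim_config"))
  fs <- config$native_rate
  seq <- config$sequence
  span <- seq$total_span
  # sequences sit back to back: each carries its own flanking baselines,
  # which double as the segmentation margins
  duration <- n_sequences * span
  n <- round(duration * fs)
  labels <- config$montage$label
  nch <- length(labels)

  components <- purrr::map2(config$components, amp_factors, function(comp, f) {
    comp$harmonic_amplitudes <- comp$harmonic_amplitudes * f
    comp
  })
  sequence_starts <- (seq_len(n_sequences) - 1) * span
  manifest <- list(
    components = components,
    sequence = seq,
    sequence_starts = sequence_starts,
    native_rate = fs,
    condition = config$condition,
    seed = as.integer(seed),
    subject_id = subject_id
  )

  noise <- config$noise
  data <- withr::with_seed(as.integer(seed), {
    if (noise$scale > 0 || noise$white_floor > 0) {
      # Gaussian noise synthesised in the frequency domain. Independent
      # processes add in power, so pink + white floor is one process shaped
      # by the root of the summed power spectra; and the real and imaginary
      # parts of the inverse DFT of circularly-symmetric complex Gaussian
      # coefficients are two independent channels with that spectrum, so
      # one transform yields two channels.
      f <- (seq_len(n) - 1) / n * fs
      f <- pmin(f, fs - f)
      gain_pink <- ifelse(f >= noise$band[1] & f <= noise$band[2] & f > 0,
                          f^(-noise$exponent / 2), 0)
      if (noise$scale > 0) {
        gain_pink <- gain_pink * noise$scale / sqrt(mean(gain_pink^2))
      } else {
        gain_pink[] <- 0
      }
      in_band <- f >= noise$band[1] & f <= noise$band[2] & f > 0
      nb <- sum(in_band)
      # the white floor shares the noise band (content outside it would be
      # removed by the band-pass stage anyway); scaled so its RMS is
      # `white_floor` over the recording
      gain <- numeric(n)
      gain[in_band] <- sqrt(gain_pink[in_band]^2 +
                              noise$white_floor^2 * n / nb)
      half <- (nch + 1L) %/% 2L
      coef <- matrix(0 + 0i, n, half)
      coef[in_band, ] <- matrix(complex(
        real = stats::rnorm(nb * half),
        imaginary = stats::rnorm(nb * half)
      ), nb, half) * (gain[in_band] * sqrt(n))
      y <- stats::mvfft(coef, inverse = TRUE) / n
      shaped <- cbind(Re(y), Im(y))[, seq_len(nch), drop = FALSE]
    } else {
      shaped <- matrix(0, n, nch)
    }
    t(shaped)
  })
  rownames(data) <- labels
  data <- data + component_signal(manifest, 0L, n, labels)

  trig_one <- triggers_for(seq, fs)
  triggers <- purrr::map_dfr(sequence_starts, function(start) {
    base_sample <- round(start * fs) + round(seq$pre_baseline * fs)
    tibble::tibble(sample = as.integer(base_sample + trig_one$sample),
                   code = trig_one$code)
  })
  eeg_recording(
    data, fs,
    channel_labels = labels,
    montage = config$montage,
    triggers = triggers,
    metadata = list(
      subject_id = subject_id,
      condition = config$condition,
      seed = as.integer(seed),
      manifest = manifest,
      chain = list("simulate")
    )
  )
}

#' Simulate a cohort of subjects
#'
#' Per-subject seeds are derived deterministically from the master seed, so
#' the whole cohort is reproducible end to end; subject amplitudes are
#' drawn from the configured lognormal spread and per-subject sequence
#' counts uniformly from `n_seq_range`. Because the random draws do not
#' depend on the condition, a natural and a scrambled cohort built from the
#' same master seed share noise realisations subject by subject.
#'
#' @param config A [sim_config()].
#' @param n_subjects Number of subjects (Exp 1: 15; Exp 2: 10).
#' @param n_seq_range Inclusive range of sequences per subject (default
#'   5-12, the Exp-1 design).
#' @return A list of [eeg_recording()] objects.
#' @export
simulate_cohort <- function(config, n_subjects, n_seq_range = c(5, 12)) {
  stopifnot(inherits(config, "fpvs_sim_config"))
  if (!is_integerish(n_subjects) || n_subjects < 1) {
    abort_invalid("`n_subjects` must be an integer >= 1")
  }
  lapply(seq_len(n_subjects), function(i) {
    seed_i <- derive_seed(config$seed, i)
    draws <- withr::with_seed(seed_i, {
      list(
        n_seq = sample(seq.int(n_seq_range[1], n_seq_range[2]), 1L),
        factors = stats::rlnorm(length(config$components), 0,
                                config$subject_variability)
      )
    })
    simulate_subject(
      config,
      subject_id = sprintf("s%02d", i),
      n_sequences = draws$n_seq,
      amp_factors = draws$factors,
      seed = derive_seed(seed_i, 1L)
    )
  })
}

#' Scrambled-condition twin of a simulated recording
#'
#' Returns the recording the same subject would have produced in the
#' phase-scrambled condition: identical noise and base-rate response, with
#' the oddball components removed. Because [simulate_cohort()] draws the
#' same random numbers regardless of condition, this equals (to floating
#' point rounding) simulating the subject under a scrambled
#' [sim_config()] with the same master seed, at a fraction of the cost.
#'
#' @param rec A simulated [eeg_recording()] with its generative manifest.
#' @return An [eeg_recording()] for the scrambled condition.
#' @export
scrambled_twin <- function(rec) {
  stopifnot(inherits(rec, "fpvs_recording"))
  manifest <- rec$metadata$manifest
  if (is.null(manifest)) {
    abort_invalid("recording carries no generative manifest")
  }
  odd <- manifest
  odd$components <- purrr::keep(manifest$components,
                                function(c) c$role == "oddball")
  if (length(odd$components) > 0L) {
    rec$data <- rec$data -
      component_signal(odd, 0L, n_samples(rec), rec$channel_labels)
  }
  rec$metadata$condition <- "scrambled"
  rec$metadata$manifest$condition <- "scrambled"
  rec$metadata$manifest$components <- lapply(
    manifest$components,
    function(c) {
      if (c$role == "oddball") c$harmonic_amplitudes[] <- 0
      c
    }
  )
  rec
}

#' Inject an artifact into a recording
#'
#' Two controlled corruptions for exercising the QC path: `bad_channel`
#' replaces one channel with high-variance white noise (an electrode gone
#' off), and `gap` removes the tagged components — not the noise — over a
#' time span, mimicking an infant looking away so that the affected
#' sequence fails the base-rate QC criterion downstream.
#'
#' @param rec A simulated [eeg_recording()] (the `gap` kind needs the
#'   generative manifest in the metadata).
#' @param kind `"bad_channel"` or `"gap"`.
#' @param params For `bad_channel`: `channel`, `rms` (microvolts), optional
#'   `seed`. For `gap`: `from`, `to` (seconds). An empty `params` list
#'   returns the recording unchanged.
#' @return The modified recording.
#' @export
inject_artifact <- function(rec, kind = c("bad_channel", "gap"),
                            params = list()) {
  stopifnot(inherits(rec, "fpvs_recording"))
  if (length(params) == 0L) return(rec)
  kind <- match.arg(kind)
  if (kind == "bad_channel") {
    ch <- params$channel
    stopifnot_channels(rec$channel_labels, ch)
    rms <- params$rms %||% 100
    noise <- withr::with_seed(as.integer(params$seed %||% 1L), {
      stats::rnorm(n_samples(rec), sd = rms)
    })
    rec$data[ch, ] <- noise
    rec <- append_chain(rec, sprintf("inject(bad_channel %s)", ch))
  } else {
    manifest <- rec$metadata$manifest
    if (is.null(manifest)) {
      abort_invalid("`gap` injection needs the generative manifest in metadata")
    }
    fs <- rec$sampling_rate
    s0 <- round(params$from * fs)
    s1 <- min(round(params$to * fs), n_samples(rec))
    if (is.null(params$from) || is.null(params$to) || s1 <= s0) {
      abort_invalid("`gap` needs `from` < `to` within the recording")
    }
    comp <- component_signal(manifest, s0, s1 - s0, rec$channel_labels)
    rec$data[, (s0 + 1L):s1] <- rec$data[, (s0 + 1L):s1] - comp
    rec <- append_chain(rec, sprintf("inject(gap %g-%g s)",
                                     params$from, params$to))
  }
  rec
}
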