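# Named-experiment orchestration: simulate -> preprocess -> spectral ->
# group statistics, with reproducible report bundles.

write_tsv_file <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Experiment configuration
#'
#' Bundles the stimulation design, simulation settings, QC settings,
#' target frequencies and channels of interest for a named experiment run.
#' Validation happens here, before any computation: target frequencies
#' must be bin-aligned with the analysis window and all referenced
#' channels must exist in the montage.
#'
#' @param sim A [sim_config()]; its `sequence` is the presented design and
#'   its `seed` the master seed of the run.
#' @param n_subjects Cohort size.
#' @param n_seq_range Inclusive per-subject sequence-count range.
#' @param target_freqs Frequencies quantified and tested (Hz); default the
#'   base rate, the oddball rate and its second harmonic.
#' @param channels_of_interest Channels singled out in reports.
#' @param qc_threshold,qc_channels Sequence-QC settings (see
#'   [sequence_qc()]).
#' @param low,high,target_rate Preprocessing settings.
#' @param out_dir Optional directory for the report bundle.
#' @return An object of class `fpvs_experiment_config`.
#' @export
experiment_config <- function(sim = sim_config(),
                              n_subjects = 15,
                              n_seq_range = c(5, 12),
                              target_freqs = c(6, 1.2, 2.4),
                              channels_of_interest = c("Oz", "O1", "O2",
                                                       "P7", "P8"),
                              qc_threshold = 2,
                              qc_channels = c("Oz", "O1", "O2"),
                              low = 0.1, high = 100, target_rate = 250,
                              out_dir = NULL) {
  stopifnot(inherits(sim, "fpvs_sim_config"))
  for (f in target_freqs) {
    if (!is_integerish(f * sim$sequence$stim_duration)) {
      abort_invalid(sprintf(
        "target frequency %g Hz is not bin-aligned with the %g-s analysis window",
        f, sim$sequence$stim_duration))
    }
  }
  stopifnot_channels(sim$montage$label,
                     c(channels_of_interest, qc_channels))
  structure(
    list(
      sim = sim,
      n_subjects = as.integer(n_subjects),
      n_seq_range = n_seq_range,
      target_freqs = target_freqs,
      channels_of_interest = channels_of_interest,
      qc_threshold = qc_threshold,
      qc_channels = qc_channels,
      low = low, high = high, target_rate = target_rate,
      out_dir = out_dir
    ),
    class = "fpvs_experiment_config"
  )
}

#' Analyse a cohort of recordings
#'
#' Runs the preprocessing chain and spectral quantification on every
#' recording: band-pass filter, downsample, segment, common average
#' reference, crop, per-sequence QC, time-domain averaging of the retained
#' sequences, per-subject amplitude spectrum, cohort table at the target
#' frequencies and the grand-averaged spectrum. Subjects are retained as
#' long as at least one of their sequences passes QC.
#'
#' @param recordings List of [eeg_recording()] objects.
#' @param config An [experiment_config()].
#' @param condition Condition label for the cohort table.
#' @return A list: `spectra` (per retained subject), `cohort` (tibble),
#'   `grand` (`fpvs_spectrum`), `qc` (tibble over all sequences),
#'   `noise_flags` (tibble from [flag_noisy_sequences()]).
#' @export
analyze_cohort <- function(recordings, config = experiment_config(),
                           condition = "natural") {
  seq <- config$sim$sequence
  spectra <- list()
  qc_all <- list()
  n_kept <- integer()
  for (rec in recordings) {
    pp <- preprocess_subject(
      rec, seq, low = config$low, high = config$high,
      target_rate = config$target_rate,
      qc_threshold = config$qc_threshold,
      qc_channels = config$qc_channels
    )
    qc_all[[length(qc_all) + 1L]] <- pp$qc
    if (length(pp$epochs) == 0L) next
    avg <- average_epochs(pp$epochs)
    spectra[[length(spectra) + 1L]] <- amplitude_spectrum(avg)
    n_kept <- c(n_kept, length(pp$epochs))
  }
  if (length(spectra) == 0L) {
    abort_invalid("no subject retained any sequence after QC")
  }
  cohort <- cohort_table(spectra, config$target_freqs, condition,
                         n_sequences = n_kept)
  list(
    spectra = spectra,
    cohort = cohort,
    grand = grand_average_spectrum(spectra),
    qc = dplyr::bind_rows(qc_all),
    noise_flags = flag_noisy_sequences(spectra)
  )
}

cohort_values <- function(cohort, channel, f, col = "snr",
                          condition = NULL) {
  rows <- dplyr::filter(cohort, .data$channel == !!channel,
                        abs(.data$frequency - f) < 1e-9)
  if (!is.null(condition)) {
    rows <- dplyr::filter(rows, .data$condition == !!condition)
  }
  rows <- dplyr::arrange(rows, .data$subject_id)
  stats::setNames(rows[[col]], rows$subject_id)
}

#' Run the single-condition oddball experiment
#'
#' Simulates a cohort viewing natural images (default 15 subjects, 5-12
#' sequences each), analyses it, and computes the group statistics of the
#' design: Bonferroni-corrected channel-wise Z-tests of the grand average
#' at the base and oddball frequencies, one-sample t-tests of individual
#' SNRs against the noise level at the medial-occipital base-rate site and
#' the right occipito-temporal oddball site, the right-vs-left paired
#' lateralization contrast, and per-subject significance tallies. The
#' bundle is bit-reproducible given the master seed.
#'
#' @param config An [experiment_config()].
#' @return An `fpvs_report` list: `cohort`, `grand`, `tests` (tibble),
#'   `tallies`, `qc`, `noise_flags`, `manifest`. Written to
#'   `config$out_dir` as TSV + JSON when set (see [write_report()]).
#' @export
run_experiment1 <- function(config = experiment_config()) {
  stopifnot(inherits(config, "fpvs_experiment_config"))
  f_base <- config$sim$sequence$base_rate
  f_odd <- config$sim$sequence$oddball_rate
  recs <- simulate_cohort(config$sim, config$n_subjects, config$n_seq_range)
  an <- analyze_cohort(recs, config, condition = config$sim$condition)
  nch <- length(config$sim$montage$label)
  tests <- dplyr::bind_rows(
    z_test_channels(an$grand, f_odd, 0.05, nch),
    z_test_channels(an$grand, f_base, 0.05, nch),
    t_test_vs_noise(cohort_values(an$cohort, "Oz", f_base)) |>
      dplyr::mutate(channel = "Oz", frequency = f_base),
    t_test_vs_noise(cohort_values(an$cohort, "P8", f_odd)) |>
      dplyr::mutate(channel = "P8", frequency = f_odd),
    paired_t(cohort_values(an$cohort, "P8", f_odd),
             cohort_values(an$cohort, "P7", f_odd), tail = "one") |>
      dplyr::mutate(channel = "P8-P7", frequency = f_odd)
  )
  tallies <- list(
    oddball_P8 = per_subject_significance(an$cohort, "P8", f_odd),
    base_Oz = per_subject_significance(an$cohort, "Oz", f_base)
  )
  report <- structure(
    list(
      experiment = "experiment1",
      cohort = an$cohort,
      grand = an$grand,
      spectra = an$spectra,
      tests = tests,
      tallies = tallies,
      qc = an$qc,
      noise_flags = an$noise_flags,
      manifest = run_manifest(config)
    ),
    class = "fpvs_report"
  )
  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

#' Run the natural-vs-scrambled control experiment
#'
#' Simulates paired cohorts (default 10 subjects) viewing natural and
#' phase-scrambled sequences. The scrambled condition shares each
#' subject's seed — hence noise realisation and sequence count — with the
#' natural condition but has its oddball components silenced, mirroring
#' stimuli that keep the power spectrum while destroying category content.
#' Emits the base-rate natural-vs-scrambled comparison and the paired
#' oddball contrast at the right occipito-temporal site, plus per-condition
#' t-tests against noise level and grand-average Z-tests.
#'
#' @param config An [experiment_config()]; sensible Exp-2 defaults are
#'   `n_subjects = 10`, `n_seq_range = c(2, 7)`.
#' @return An `fpvs_report` (cohort table holds both conditions).
#' @export
run_experiment2 <- function(config = experiment_config(n_subjects = 10,
                                                       n_seq_range = c(2, 7))) {
  stopifnot(inherits(config, "fpvs_experiment_config"))
  f_base <- config$sim$sequence$base_rate
  f_odd <- config$sim$sequence$oddball_rate
  sim_nat <- config$sim
  recs_nat <- simulate_cohort(sim_nat, config$n_subjects, config$n_seq_range)
  an_nat <- analyze_cohort(recs_nat, config, condition = "natural")
  # the scrambled cohort shares per-subject seeds (noise, sequence counts)
  # with the natural cohort; derive it by removing the oddball components
  an_scr <- analyze_cohort(lapply(recs_nat, scrambled_twin),
                           config, condition = "scrambled")
  cohort <- dplyr::bind_rows(an_nat$cohort, an_scr$cohort)
  # pair on subjects retained in both conditions
  common <- intersect(unique(an_nat$cohort$subject_id),
                      unique(an_scr$cohort$subject_id))
  pair <- function(channel, f, col = "snr") {
    a <- cohort_values(an_nat$cohort, channel, f, col)[common]
    b <- cohort_values(an_scr$cohort, channel, f, col)[common]
    list(a = a, b = b)
  }
  p_odd <- pair("P8", f_odd)
  p_base <- pair("Oz", f_base)
  tests <- dplyr::bind_rows(
    paired_t(p_odd$a, p_odd$b, tail = "two") |>
      dplyr::mutate(test = "paired_natural_vs_scrambled",
                    channel = "P8", frequency = f_odd),
    paired_t(p_base$a, p_base$b, tail = "two") |>
      dplyr::mutate(test = "paired_natural_vs_scrambled",
                    channel = "Oz", frequency = f_base),
    t_test_vs_noise(cohort_values(an_nat$cohort, "P8", f_odd)) |>
      dplyr::mutate(test = "t_vs_noise_natural",
                    channel = "P8", frequency = f_odd),
    t_test_vs_noise(cohort_values(an_scr$cohort, "P8", f_odd)) |>
      dplyr::mutate(test = "t_vs_noise_scrambled",
                    channel = "P8", frequency = f_odd),
    z_test_channels(an_nat$grand, f_odd, 0.05,
                    length(config$sim$montage$label)) |>
      dplyr::mutate(test = "z_vs_noise_natural"),
    z_test_channels(an_scr$grand, f_odd, 0.05,
                    length(config$sim$montage$label)) |>
      dplyr::mutate(test = "z_vs_noise_scrambled")
  )
  report <- structure(
    list(
      experiment = "experiment2",
      cohort = cohort,
      grand = an_nat$grand,
      grand_scrambled = an_scr$grand,
      spectra = c(an_nat$spectra, an_scr$spectra),
      tests = tests,
      tallies = list(
        oddball_P8_natural = per_subject_significance(an_nat$cohort, "P8",
                                                      f_odd)
      ),
      qc = dplyr::bind_rows(
        dplyr::mutate(an_nat$qc, condition = "natural"),
        dplyr::mutate(an_scr$qc, condition = "scrambled")
      ),
      noise_flags = an_nat$noise_flags,
      manifest = run_manifest(config)
    ),
    class = "fpvs_report"
  )
  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

run_manifest <- function(config) {
  cfg <- config
  cfg$out_dir <- NULL
  list(
    seed = config$sim$seed,
    condition = config$sim$condition,
    n_subjects = config$n_subjects,
    n_seq_range = config$n_seq_range,
    target_freqs = config$target_freqs,
    config_hash = rlang::hash(cfg),
    package_version = as.character(utils::packageVersion("fpvs")),
    r_version = as.character(getRversion())
  )
}

#' Write a report bundle to disk
#'
#' Emits the tabular artefacts of a run — cohort table, test results, QC
#' log, grand-average spectrum table, oddball topography table — as TSV,
#' the run manifest (seed, config hash, versions) as JSON, and a short
#' markdown summary whose every number is taken from those tables.
#'
#' @param report An `fpvs_report`.
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_report <- function(report, out_dir) {
  stopifnot(inherits(report, "fpvs_report"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(out_dir, ...)
  write_tsv_file(report$cohort, p("cohort.tsv"))
  write_tsv_file(report$tests, p("tests.tsv"))
  write_tsv_file(report$qc, p("qc.tsv"))
  write_tsv_file(spectrum_table(report$grand), p("grand_spectrum.tsv"))
  f_odd <- report$cohort$frequency[which.min(report$cohort$frequency)]
  topo <- topography_table(snr_spectrum(report$grand), f_odd)
  write_tsv_file(topo, p("topography_oddball_snr.tsv"))
  jsonlite::write_json(report$manifest, p("manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  lines <- c(
    paste0("# FPVS report: ", report$experiment),
    "",
    sprintf("Seed %d; %d subjects in cohort table.",
            report$manifest$seed,
            length(unique(report$cohort$subject_id))),
    "",
    "## Tests (from tests.tsv)",
    "",
    utils::capture.output(print.data.frame(
      as.data.frame(report$tests[, c("test", "channel", "frequency",
                                     "statistic", "df", "p_one_tailed",
                                     "p_two_tailed", "significant")]),
      row.names = FALSE, digits = 4))
  )
  writeLines(lines, p("report.md"))
  invisible(out_dir)
}

#' @export
print.fpvs_report <- function(x, ...) {
  cat(sprintf("<fpvs_report> %s: %d subjects, %d tests\n",
              x$experiment, length(unique(x$cohort$subject_id)),
              nrow(x$tests)))
  print(x$tests[, c("test", "channel", "frequency", "statistic",
                    "p_one_tailed", "p_two_tailed", "significant")])
  invisible(x)
}

#' Headline numbers of a report
#'
#' @param x An `fpvs_report`.
#' @param ... Unused.
#' @return A one-row tibble with the oddball-site grand SNR/Z and the main
#'   test p-values.
#' @method glance fpvs_report
#' @export
glance.fpvs_report <- function(x, ...) {
  f_odd <- min(x$cohort$frequency)
  snr_g <- value_at(snr_spectrum(x$grand), "P8", f_odd)
  z_g <- value_at(zscore_spectrum(x$grand), "P8", f_odd)
  t_row <- dplyr::filter(x$tests, grepl("t_vs_noise", .data$test),
                         .data$channel == "P8")
  tibble::tibble(
    experiment = x$experiment,
    n_subjects = length(unique(x$cohort$subject_id)),
    grand_snr_P8 = snr_g,
    grand_z_P8 = z_g,
    t_P8 = t_row$statistic[1],
    p_one_tailed_P8 = t_row$p_one_tailed[1]
  )
}

#' Tidy the test results of a report
#'
#' @param x An `fpvs_report`.
#' @param ... Unused.
#' @return The `tests` tibble.
#' @method tidy fpvs_report
#' @export
tidy.fpvs_report <- function(x, ...) x$tests
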