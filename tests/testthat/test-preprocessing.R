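test_that("native round trip preserves data, triggers and metadata", {
  rec <- simulate_subject(small_sim(seed = 2))
  path <- withr::local_tempfile(fileext = ".eeg")
  write_recording(rec, path, "native")
  back <- read_recording(path, "native")
  # payload is 32-bit float: identical after a second round trip
  expect_equal(back$data, rec$data, tolerance = 1e-6)
  path2 <- withr::local_tempfile(fileext = ".eeg")
  write_recording(back, path2, "native")
  expect_identical(readBin(path, raw(), file.size(path)),
                   readBin(path2, raw(), file.size(path2)))
  expect_equal(back$sampling_rate, rec$sampling_rate)
  expect_equal(back$channel_labels, rec$channel_labels)
  expect_equal(back$triggers$sample, rec$triggers$sample)
  expect_equal(back$triggers$code, rec$triggers$code)
})

test_that("truncated or inconsistent native files raise a parse error", {
  rec <- simulate_subject(small_sim(seed = 2))
  path <- withr::local_tempfile(fileext = ".eeg")
  write_recording(rec, path, "native")
  raw <- readBin(path, raw(), file.size(path))
  writeBin(raw[1:(length(raw) - 100)], path)
  expect_error(read_recording(path, "native"), class = "fpvs_parse_error")
  expect_error(read_recording(withr::local_tempfile(), "native"),
               class = "fpvs_invalid_argument")
})

test_that("EDF and BDF round trips preserve signal within quantisation", {
  rec <- simulate_subject(small_sim(seed = 2))
  for (fmt in c("edf", "bdf")) {
    path <- withr::local_tempfile(fileext = paste0(".", fmt))
    write_recording(rec, path, fmt)
    back <- read_recording(path, fmt)
    scale <- max(abs(rec$data))
    tol <- if (fmt == "edf") scale / 32767 else scale / 8388607
    expect_lt(max(abs(back$data - rec$data)), 2 * tol)
    expect_equal(back$sampling_rate, rec$sampling_rate)
    expect_equal(back$channel_labels, rec$channel_labels)
    expect_equal(back$triggers$sample, rec$triggers$sample)
    expect_equal(back$triggers$code, rec$triggers$code)
    # EDF carries no electrode positions: flagged absent, not invented
    expect_null(back$montage)
    expect_true(back$metadata$montage_absent)
  }
})

test_that("truncated EDF files raise a parse error naming the records", {
  rec <- simulate_subject(small_sim(seed = 2))
  path <- withr::local_tempfile(fileext = ".edf")
  write_recording(rec, path, "edf")
  raw <- readBin(path, raw(), file.size(path))
  writeBin(raw[1:(length(raw) - 50)], path)
  expect_error(read_recording(path, "edf"), "truncated",
               class = "fpvs_parse_error")
})

test_that("the band-pass filter preserves the passband and kills the stopband", {
  fs <- 512
  t <- (0:(fs * 8 - 1)) / fs
  mk <- function(x) eeg_recording(matrix(x, 1), fs, "ch1")
  # passband identity at 6 Hz
  out <- bandpass_filter(mk(sin(2 * pi * 6 * t)), 0.1, 100)
  expect_equal(max(abs(out$data)), 1, tolerance = 1e-3)
  # DC removed
  out <- bandpass_filter(mk(rep(10, length(t))), 0.1, 100)
  expect_lt(sqrt(mean(out$data^2)), 0.1)
  # stopband attenuation beyond 40 dB at 150 Hz
  out <- bandpass_filter(mk(sin(2 * pi * 150 * t)), 0.1, 100)
  expect_lt(max(abs(out$data)), 0.01)
  expect_equal(ncol(out$data), length(t))
  expect_error(bandpass_filter(mk(t), 0.1, 300),
               class = "fpvs_invalid_argument")
})

test_that("Fourier resampling keeps sample counts and amplitudes exact", {
  fs <- 512
  t <- (0:(fs * 28 - 1)) / fs
  rec <- eeg_recording(matrix(sin(2 * pi * 6 * t), 1), fs, "ch1",
                       triggers = tibble::tibble(sample = c(0L, 1024L),
                                                 code = c("a", "b")))
  out <- downsample(rec, 250)
  expect_equal(ncol(out$data), 7000) # 28 s x 250 Hz
  expect_equal(out$sampling_rate, 250)
  # bin-aligned sinusoid survives with unit amplitude
  amp <- 2 * Mod(stats::fft(out$data[1, ]))[6 * 28 + 1] / 7000
  expect_equal(amp, 1, tolerance = 1e-3)
  expect_equal(out$triggers$sample, c(0L, 500L))
  expect_error(downsample(rec, 600), class = "fpvs_invalid_argument")
})

test_that("fused filtering + resampling equals the sequential operations", {
  rec <- simulate_subject(small_sim(seed = 15))
  fused <- fpvs:::filter_resample(rec, 0.1, 100, 250)
  sequential <- downsample(bandpass_filter(rec, 0.1, 100), 250)
  expect_equal(fused$data, sequential$data, tolerance = 1e-10)
  expect_identical(fused$triggers, sequential$triggers)
})

test_that("segmentation cuts one epoch per trial trigger", {
  fs <- 250
  n <- fs * 230
  starts <- 2 * fs + (0:7) * 28 * fs
  rec <- eeg_recording(
    matrix(0, 1, n), fs, "ch1",
    triggers = tibble::tibble(sample = as.integer(starts),
                              code = "trial_start")
  )
  eps <- segment(rec)
  expect_length(eps, 8)
  expect_true(all(vapply(eps, function(e) ncol(e$data), 0L) == 7000))
  expect_equal(vapply(eps, `[[`, 0L, "sequence_id"), 1:8)
})

test_that("triggers too close to the recording edge are skipped and logged", {
  fs <- 250
  rec <- eeg_recording(
    matrix(0, 1, fs * 40), fs, "ch1",
    triggers = tibble::tibble(sample = c(100L, as.integer(2 * fs)),
                              code = "trial_start")
  )
  eps <- segment(rec)
  expect_length(eps, 1)
  skipped <- attr(eps, "skipped")
  expect_equal(nrow(skipped), 1)
  expect_match(skipped$reason, "before trigger")
})

test_that("channel interpolation is an inverse-distance neighbour mean", {
  mk_epoch <- function(values) {
    data <- rbind(T0 = rep(99, 10), N1 = rep(values[1], 10),
                  N2 = rep(values[2], 10), N3 = rep(values[3], 10),
                  FAR = rep(1000, 10))
    new_epoch(data, 250, window = "full", montage = toy_montage())
  }
  # equidistant neighbours: plain mean; the distant channel is ignored
  out <- interpolate_channel(mk_epoch(c(1, 2, 3)), "T0")
  expect_equal(unname(out$data["T0", ]), rep(2, 10))
  # flat-zero neighbours give zeros; identical signals are reproduced
  expect_equal(unname(interpolate_channel(mk_epoch(c(0, 0, 0)),
                                          "T0")$data["T0", ]), rep(0, 10))
  expect_equal(unname(interpolate_channel(mk_epoch(c(7, 7, 7)),
                                          "T0")$data["T0", ]), rep(7, 10))
  expect_error(interpolate_channel(mk_epoch(c(1, 2, 3)), "ZZ"),
               class = "fpvs_invalid_argument")
})

test_that("common average referencing zeroes the channel mean at every sample", {
  set.seed(8)
  ep <- new_epoch(matrix(rnorm(6 * 500), 6, 500), 250, window = "full",
                  channel_labels = paste0("c", 1:6))
  out <- rereference_common_average(ep)
  expect_lt(max(abs(colMeans(out$data))), 1e-9)
  # idempotent
  expect_equal(rereference_common_average(out)$data, out$data)
  # an already average-referenced pair is unchanged
  a <- matrix(rnorm(300), 1)
  pair <- new_epoch(rbind(a, -a), 250, window = "full",
                    channel_labels = c("p", "m"))
  expect_equal(rereference_common_average(pair)$data, pair$data)
  single <- new_epoch(a, 250, window = "full", channel_labels = "p")
  expect_error(rereference_common_average(single),
               class = "fpvs_invalid_argument")
})

test_that("cropping keeps exactly the 20-s full-contrast window", {
  rec <- simulate_subject(small_sim(seed = 6))
  rec <- fpvs:::filter_resample(rec, 0.1, 100, 250)
  ep <- segment(rec)[[1]]
  expect_equal(ncol(ep$data), 7000)
  cropped <- crop_analysis_window(ep)
  expect_equal(ncol(cropped$data), 5000)
  expect_equal(cropped$window, "analysis")
  # the window spans an integer number of oddball cycles
  expect_equal((ncol(cropped$data) / 250) * 1.2, 24)
  expect_error(crop_analysis_window(cropped), class = "fpvs_invalid_argument")
})

test_that("the QC rule rejects only when all occipital channels are below threshold", {
  qc <- function(snrs) {
    sequence_qc(make_flat_epoch(snrs), base_rate = 6, threshold = 2)
  }
  r <- qc(c(Oz = 1.5, O1 = 1.2, O2 = 1.9))
  expect_equal(r$verdict, "reject")
  expect_match(r$reasons, "low_base_snr")
  expect_equal(r$base_snr_Oz, 1.5, tolerance = 1e-9)
  # one channel at or above threshold keeps the sequence
  expect_equal(qc(c(Oz = 2.5, O1 = 0.5, O2 = 0.5))$verdict, "keep")
  # strict inequality: exactly 2 is not below 2
  expect_equal(qc(c(Oz = 2.0, O1 = 1.0, O2 = 1.0))$verdict, "keep")
  # external annotations force rejection
  r <- sequence_qc(make_flat_epoch(c(Oz = 5, O1 = 5, O2 = 5)),
                   annotations = "no_fixation")
  expect_equal(r$verdict, "reject")
  expect_match(r$reasons, "no_fixation")
})

test_that("a gap-injected sequence fails QC while intact ones pass", {
  rec <- simulate_subject(small_sim(seed = 30))
  rec <- inject_artifact(rec, "gap", list(from = 0, to = 28))
  pp <- preprocess_subject(rec)
  expect_equal(pp$qc$verdict, c("reject", "keep"))
  expect_match(pp$qc$reasons[1], "low_base_snr")
  expect_length(pp$epochs, 1)
})

test_that("the preprocessing chain is deterministic and audited", {
  rec <- simulate_subject(small_sim(seed = 12))
  a <- preprocess_subject(rec)
  b <- preprocess_subject(rec)
  expect_identical(a$epochs[[1]]$data, b$epochs[[1]]$data)
  expect_identical(a$qc, b$qc)
  chain <- unlist(a$epochs[[1]]$metadata$chain)
  expect_equal(grep("bandpass", chain), 2L) # after "simulate"
  expect_equal(grep("downsample", chain), 3L)
})

test_that("noisy-sequence flagging marks spectrum outliers without dropping them", {
  sp_ok <- lapply(1:6, function(i) make_spectrum(matrix(1, 2, 100) * i / 6))
  sp_bad <- make_spectrum(matrix(10, 2, 100))
  flags <- flag_noisy_sequences(c(sp_ok, list(sp_bad)), k = 3)
  expect_equal(nrow(flags), 7)
  expect_true(flags$flagged[7])
  expect_false(any(flags$flagged[1:6]))
})
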