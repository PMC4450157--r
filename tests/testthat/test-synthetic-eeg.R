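test_that("noise-free components are recovered exactly at their bins", {
  cfg <- sim_config(
    components = list(neural_component(6, c("1" = 1), topography = c(Oz = 1))),
    noise = noise_model(scale = 0, white_floor = 0),
    n_sequences = 1, seed = 4
  )
  rec <- simulate_subject(cfg)
  ep <- crop_analysis_window(segment(rec)[[1]])
  sp <- amplitude_spectrum(ep)
  expect_equal(value_at(sp, "Oz", 6), 1, tolerance = 1e-3)
  # no energy anywhere else: off-harmonic bins and other channels
  k6 <- bin_index(6, sp) + 1L
  expect_lt(max(sp$amplitudes["Oz", -k6]), 1e-6)
  expect_lt(max(sp$amplitudes["P8", ]), 1e-9)
})

test_that("topography weights scale the recovered amplitudes", {
  cfg <- sim_config(
    components = list(neural_component(
      1.2, c("1" = 0.5, "2" = 0.2), topography = c(P8 = 1, P7 = 0.55))),
    noise = noise_model(scale = 0, white_floor = 0),
    n_sequences = 1, seed = 4
  )
  sp <- amplitude_spectrum(crop_analysis_window(segment(simulate_subject(cfg))[[1]]))
  expect_equal(value_at(sp, "P8", 1.2), 0.5, tolerance = 1e-3)
  expect_equal(value_at(sp, "P8", 2.4), 0.2, tolerance = 1e-3)
  expect_equal(value_at(sp, "P7", 1.2), 0.5 * 0.55, tolerance = 1e-3)
  expect_equal(value_at(sp, "P7", 2.4), 0.2 * 0.55, tolerance = 1e-3)
})

test_that("tagged components are silent during the baselines", {
  cfg <- sim_config(
    components = default_components(),
    noise = noise_model(scale = 0, white_floor = 0),
    n_sequences = 2, seed = 4
  )
  rec <- simulate_subject(cfg)
  fs <- rec$sampling_rate
  pre <- rec$data[, 1:(2 * fs)] # first pre-baseline
  expect_equal(max(abs(pre)), 0)
  post <- rec$data[, (26 * fs + 1):(28 * fs)] # first post-baseline
  expect_equal(max(abs(post)), 0)
})

test_that("simulation is deterministic under the seed", {
  cfg <- small_sim(seed = 21)
  a <- simulate_subject(cfg)
  b <- simulate_subject(cfg)
  expect_identical(a$data, b$data)
  expect_identical(a$triggers, b$triggers)
  c <- simulate_subject(cfg, seed = 22)
  expect_false(isTRUE(all.equal(a$data, c$data)))
})

test_that("the scrambled condition silences only the oddball components", {
  cfg <- sim_config(condition = "scrambled", seed = 3, n_sequences = 2)
  amps <- vapply(cfg$components, function(c) max(c$harmonic_amplitudes), 0)
  roles <- vapply(cfg$components, `[[`, "", "role")
  expect_true(all(amps[roles == "oddball"] == 0))
  expect_true(all(amps[roles == "base"] > 0))
})

test_that("scrambled cohorts average to SNR about 1 at the oddball frequency", {
  # many noise-bearing subjects, oddball silenced: the oddball bin is pure
  # background, so its neighbour-bin SNR is noise-level on average
  cfg <- sim_config(condition = "scrambled", n_sequences = 1, seed = 77)
  snrs <- vapply(1:60, function(i) {
    rec <- simulate_subject(cfg, seed = 7700 + i)
    sp <- amplitude_spectrum(crop_analysis_window(segment(rec)[[1]]))
    value_at(snr_spectrum(sp), "P8", 1.2)
  }, 0)
  expect_gt(mean(snrs), 0.9)
  expect_lt(mean(snrs), 1.1)
})

test_that("cohorts draw per-subject sequence counts and amplitudes", {
  cfg <- small_sim(seed = 5)
  recs <- simulate_cohort(cfg, 15)
  expect_length(recs, 15)
  n_seq <- vapply(recs, function(r) sum(r$triggers$code == "trial_start"), 0L)
  expect_true(all(n_seq >= 5 & n_seq <= 12))
  expect_gt(length(unique(n_seq)), 1)
  ids <- vapply(recs, function(r) r$metadata$subject_id, "")
  expect_equal(ids, sprintf("s%02d", 1:15))
  # reproducible end to end
  recs2 <- simulate_cohort(cfg, 15)
  expect_identical(recs[[7]]$data, recs2[[7]]$data)
})

test_that("zero subject variability yields identical component amplitudes", {
  cfg <- sim_config(subject_variability = 0, seed = 5, n_sequences = 1)
  recs <- simulate_cohort(cfg, 3, n_seq_range = c(1, 1))
  amps <- lapply(recs, function(r) {
    vapply(r$metadata$manifest$components,
           function(c) unname(c$harmonic_amplitudes["1"]), 0)
  })
  expect_equal(amps[[1]], amps[[2]])
  expect_equal(amps[[2]], amps[[3]])
})

test_that("noise spectral slope is recovered from noise-only recordings", {
  cfg <- sim_config(
    components = list(),
    noise = noise_model(exponent = 1, scale = 2, white_floor = 0),
    n_sequences = 20, seed = 31
  )
  rec <- simulate_subject(cfg)
  spectra <- lapply(segment(rec), function(ep) {
    amplitude_spectrum(crop_analysis_window(ep))
  })
  g <- grand_average_spectrum(spectra)
  f <- (seq_len(ncol(g$amplitudes)) - 1) * g$bin_resolution
  keep <- f >= 1 & f <= 40
  mean_amp <- colMeans(g$amplitudes)[keep]
  fit <- stats::lm(log(mean_amp) ~ log(f[keep]))
  expect_equal(unname(stats::coef(fit)[2]), -0.5, tolerance = 0.15)
})

test_that("bad-channel injection produces a high-variance channel", {
  rec <- simulate_subject(small_sim(seed = 9))
  bad <- inject_artifact(rec, "bad_channel",
                         list(channel = "P8", rms = 100, seed = 2))
  v <- apply(bad$data, 1, stats::var)
  expect_gte(v["P8"], 10 * stats::median(v))
  expect_error(
    inject_artifact(rec, "bad_channel", list(channel = "XX", rms = 10)),
    class = "fpvs_invalid_argument"
  )
})

test_that("empty artifact parameters leave the recording unchanged", {
  rec <- simulate_subject(small_sim(seed = 9))
  expect_identical(inject_artifact(rec, "gap", list()), rec)
})

test_that("a gap over a sequence removes its tagged components only", {
  rec <- simulate_subject(small_sim(seed = 9))
  gapped <- inject_artifact(rec, "gap", list(from = 0, to = 28))
  fs <- rec$sampling_rate
  # second sequence untouched
  idx2 <- (28 * fs + 1):(56 * fs)
  expect_identical(gapped$data[, idx2], rec$data[, idx2])
  # first sequence now carries noise only: subtracting the manifest's
  # component signal from the original matches the gapped data
  comp <- fpvs:::component_signal(rec$metadata$manifest, 0L, 28 * fs,
                                  rec$channel_labels)
  expect_equal(gapped$data[, 1:(28 * fs)],
               rec$data[, 1:(28 * fs)] - comp)
})

test_that("the scrambled twin equals a scrambled-condition simulation", {
  cfg_n <- small_sim(seed = 13)
  cfg_s <- sim_config(condition = "scrambled", n_sequences = 2, seed = 13)
  twin <- scrambled_twin(simulate_subject(cfg_n))
  direct <- simulate_subject(cfg_s)
  expect_equal(twin$data, direct$data, tolerance = 1e-12)
  expect_identical(twin$triggers, direct$triggers)
})

test_that("components above the native Nyquist are rejected", {
  expect_error(
    sim_config(components = list(
      neural_component(6, c("60" = 0.1), topography = c(Oz = 1))
    ), native_rate = 512),
    class = "fpvs_invalid_config"
  )
  expect_error(sim_config(native_rate = 400), class = "fpvs_invalid_argument")
})
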