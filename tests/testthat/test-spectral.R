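test_that("time-domain averaging keeps phase-locked signal and shrinks noise", {
  ep <- make_flat_epoch(c(Oz = 3))
  # identity and cancellation
  expect_equal(average_epochs(list(ep))$data, ep$data)
  neg <- ep
  neg$data <- -ep$data
  expect_equal(max(abs(average_epochs(list(ep, neg))$data)), 0)
  # noise shrinks by about 1/sqrt(n)
  withr::with_seed(42, {
    fs <- 250
    t <- (0:(20 * fs - 1)) / fs
    signal <- sin(2 * pi * 6 * t)
    eps <- lapply(1:16, function(i) {
      new_epoch(matrix(signal + rnorm(length(t)), 1), fs,
                window = "analysis", channel_labels = "ch1")
    })
    avg <- average_epochs(eps)
    resid <- avg$data[1, ] - signal
    single <- eps[[1]]$data[1, ] - signal
    ratio <- sqrt(mean(single^2)) / sqrt(mean(resid^2))
    expect_equal(ratio, 4, tolerance = 0.15)
    expect_equal(avg$metadata$n_averaged, 16)
  })
  bad <- new_epoch(matrix(0, 1, 10), 250, window = "analysis",
                   channel_labels = "ch1")
  expect_error(average_epochs(list(ep, bad)), class = "fpvs_invalid_argument")
})

test_that("amplitude spectra use sinusoid-peak normalisation on a 0.05 Hz grid", {
  fs <- 250
  t <- (0:(20 * fs - 1)) / fs
  ep <- new_epoch(matrix(sin(2 * pi * 6 * t), 1), fs, window = "analysis",
                  channel_labels = "Oz")
  sp <- amplitude_spectrum(ep)
  expect_equal(sp$bin_resolution, 0.05)
  expect_equal(ncol(sp$amplitudes), 2501)
  expect_equal(unname(sp$amplitudes["Oz", 121]), 1) # bin 120 = 6 Hz
  expect_lt(max(sp$amplitudes["Oz", -121]), 1e-9)
  # all-zero epoch gives an all-zero spectrum
  zero <- new_epoch(matrix(0, 1, 5000), fs, window = "analysis",
                    channel_labels = "Oz")
  expect_equal(max(amplitude_spectrum(zero)$amplitudes), 0)
  full <- new_epoch(matrix(0, 1, 7000), fs, window = "full",
                    channel_labels = "Oz")
  expect_error(amplitude_spectrum(full), class = "fpvs_invalid_argument")
})

test_that("bin lookup is exact and refuses off-grid frequencies", {
  sp <- make_spectrum(matrix(1, 1, 200))
  expect_identical(bin_index(1.2, sp), 24L)
  expect_identical(bin_index(6, sp), 120L)
  expect_identical(bin_index(0, sp), 0L)
  expect_error(bin_index(1.23, sp), class = "fpvs_invalid_argument")
  expect_error(bin_index(11, sp), class = "fpvs_invalid_argument")
})

test_that("the neighbour-bin SNR matches direct arithmetic", {
  # flat spectrum: SNR is 1 at every defined bin, undefined at the edges
  flat <- snr_spectrum(make_spectrum(matrix(2, 1, 100)))
  expect_true(all(flat$values[1, flat$defined] == 1))
  expect_true(all(is.na(flat$values[1, !flat$defined])))
  expect_equal(which(flat$defined), 12:89)
  # spike over a known floor
  A <- matrix(1, 1, 100)
  A[1, 51] <- 5
  expect_equal(unname(snr_spectrum(make_spectrum(A))$values[1, 51]), 5)
  A[1, 51] <- 3.12
  A[1, 51 + c(-(11:2), 2:11)] <- 2
  expect_equal(unname(snr_spectrum(make_spectrum(A))$values[1, 51]), 1.56)
  # zero neighbourhood flagged undefined, not infinite
  Z <- matrix(0, 1, 100)
  Z[1, 51] <- 1
  expect_true(is.na(snr_spectrum(make_spectrum(Z))$values[1, 51]))
})

test_that("the neighbour-bin Z-score uses the sample SD of the 20 neighbours", {
  A <- matrix(1, 1, 100)
  A[1, 51] <- 4
  A[1, 51 + c(-(11:2))] <- 1 # ten 1.0s below
  A[1, 51 + (2:11)] <- 3 # ten 3.0s above
  z <- zscore_spectrum(make_spectrum(A))
  expect_equal(unname(z$values[1, 51]), (4 - 2) / sqrt(20 / 19), tolerance = 1e-9)
  expect_equal(round(unname(z$values[1, 51]), 4), 1.9494)
  # target equal to the neighbour mean gives zero
  A[1, 51] <- 2
  expect_equal(unname(zscore_spectrum(make_spectrum(A))$values[1, 51]), 0)
  # flat spectrum: zero SD, undefined everywhere
  flat <- zscore_spectrum(make_spectrum(matrix(1, 1, 100)))
  expect_true(all(is.na(flat$values)))
})

test_that("vectorised SNR and Z equal a brute-force neighbour scan", {
  withr::with_seed(99, {
    for (i in 1:5) {
      A <- matrix(abs(rnorm(3 * 200, mean = 2)), 3, 200)
      sp <- make_spectrum(A)
      snr <- snr_spectrum(sp)$values
      z <- zscore_spectrum(sp)$values
      bs <- brute_force_metric(A, "snr")
      bz <- brute_force_metric(A, "z")
      expect_lt(max(abs(snr - bs), na.rm = TRUE), 1e-12)
      expect_lt(max(abs(z - bz), na.rm = TRUE), 1e-12)
      expect_identical(unname(is.na(snr)), is.na(bs))
    }
  })
})

test_that("SNR and Z are invariant under amplitude rescaling", {
  withr::with_seed(17, {
    A <- matrix(abs(rnorm(2 * 150, mean = 2)), 2, 150)
    for (c in c(0.001, 3.7, 4096)) {
      s1 <- snr_spectrum(make_spectrum(A))$values
      s2 <- snr_spectrum(make_spectrum(c * A))$values
      expect_equal(s1, s2, tolerance = 1e-12)
      z1 <- zscore_spectrum(make_spectrum(A))$values
      z2 <- zscore_spectrum(make_spectrum(c * A))$values
      expect_equal(z1, z2, tolerance = 1e-12)
    }
  })
})

test_that("noise-free sinusoid over a deterministic floor gives SNR a/b", {
  fs <- 250
  t <- (0:(20 * fs - 1)) / fs
  n <- length(t)
  floor_b <- 0.04
  a <- 0.3
  x <- a * cos(2 * pi * 6 * t)
  x[1] <- x[1] + floor_b * n / 2 # impulse: flat spectrum of amplitude b
  ep <- new_epoch(matrix(x, 1), fs, window = "analysis",
                  channel_labels = "Oz")
  snr <- snr_spectrum(amplitude_spectrum(ep))
  expect_equal(value_at(snr, "Oz", 6), (a + floor_b) / floor_b,
               tolerance = 1e-9)
})

test_that("null calibration: white-noise spectra give noise-level metrics", {
  withr::with_seed(2024, {
    # 200 independent noise epochs, analysed channel-wise in one pass
    data <- matrix(rnorm(200 * 5000), 200, 5000)
    ep <- new_epoch(data, 250, window = "analysis",
                    channel_labels = sprintf("n%03d", 1:200))
    sp <- amplitude_spectrum(ep)
    snr <- snr_spectrum(sp)
    z <- zscore_spectrum(sp)
    vals <- snr$values[, snr$defined]
    expect_gt(mean(vals), 0.97)
    expect_lt(mean(vals), 1.05)
    zfrac <- mean(z$values[, z$defined] > 1.64)
    expect_gt(zfrac, 0.02)
    expect_lt(zfrac, 0.10)
  })
})

test_that("percent signal increase converts SNR against the noise level of 1", {
  expect_equal(percent_signal_increase(2.56), 156)
  expect_equal(percent_signal_increase(1), 0)
  expect_equal(percent_signal_increase(8.87), 787)
  expect_equal(percent_signal_increase(c(1.5, 0.5)), c(50, -50))
})

test_that("value lookup is consistent with the metric matrices", {
  A <- matrix(1, 2, 200)
  A[2, 25] <- 4 # 1.2 Hz on the second channel
  sp <- make_spectrum(A, channel_labels = c("Oz", "P8"))
  snr <- snr_spectrum(sp)
  expect_equal(value_at(snr, "Oz", 6), 1)
  expect_equal(value_at(snr, "P8", 1.2), 4)
  expect_true(is.na(value_at(snr, "P8", 0.1))) # edge bin: undefined
  expect_error(value_at(snr, "P8", 1.23), class = "fpvs_invalid_argument")
  expect_error(value_at(snr, "XX", 1.2), class = "fpvs_invalid_argument")
})

test_that("spectrum tables carry amplitude, SNR, Z and the defined flag", {
  ep <- make_flat_epoch(c(Oz = 3, O1 = 2))
  tab <- spectrum_table(amplitude_spectrum(ep))
  expect_named(tab, c("channel", "frequency", "amplitude", "snr", "z",
                      "defined"))
  expect_equal(nrow(tab), 2 * 2501)
  row <- tab[tab$channel == "Oz" & abs(tab$frequency - 6) < 1e-9, ]
  expect_equal(row$snr, 3, tolerance = 1e-9)
  expect_true(row$defined)
})
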