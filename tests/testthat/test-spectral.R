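# Welch cross-spectral estimation and narrow-band filtering.

test_that("coherence of a signal with itself is one at every bin", {
  x <- noise_ts(fs = 250, dur = 30, seed = 1)
  cs <- estimate_cross_spectra(x, x)
  co <- msc(cs)[2:100]
  expect_true(all(abs(co - 1) < 1e-12))
})

test_that("independent white noise gives null-level coherence at most bins", {
  a <- noise_ts(fs = 250, dur = 60, seed = 2)
  b <- noise_ts(fs = 250, dur = 60, seed = 3)
  cs <- estimate_cross_spectra(a, b, segment_len_s = 1, overlap_frac = 0)
  co <- sqrt(msc(cs))
  thr <- 3 / sqrt(cs$n_segments) # null coherence scale over K averaged segments
  expect_gt(mean(co < thr, na.rm = TRUE), 0.95)
})

test_that("cross-spectral phase follows the stated sign convention", {
  # b lags a by pi/4 at 3 Hz; with cab = E[A conj(B)] the phase is -pi/4
  a <- sine_ts(3, fs = 250, dur = 20)
  b <- sine_ts(3, fs = 250, dur = 20, phase = pi / 4)
  cs <- estimate_cross_spectra(a, b, segment_len_s = 1) # 3 full cycles/segment
  expect_equal(Arg(cs$cab[1, 1, nearest_bin(cs$freqs, 3)]), -pi / 4,
               tolerance = 0.01)
})

test_that("estimation validates alignment and data sufficiency", {
  a <- noise_ts(fs = 250, dur = 4, seed = 1)
  expect_error(estimate_cross_spectra(a, noise_ts(fs = 200, dur = 5, seed = 1)),
               "sampling rates")
  expect_error(estimate_cross_spectra(a, noise_ts(fs = 250, dur = 5, seed = 1)),
               "lengths")
  expect_error(estimate_cross_spectra(a, a, segment_len_s = 4), "insufficient|segment")
  expect_error(estimate_cross_spectra(a, a, segment_len_s = 0.02), "16 samples")
})

test_that("joint cross-spectral matrix is PSD up to round-off at every bin", {
  set.seed(4)
  M <- matrix(rnorm(12), 4) # mix 3 latent channels onto 4 + 2 spaces
  z <- matrix(rnorm(3 * 5000), 3)
  a <- ts_set((M %*% z)[1:2, , drop = FALSE] + 0.1 * matrix(rnorm(2 * 5000), 2), 200)
  b <- ts_set((M %*% z)[3:4, , drop = FALSE] + 0.1 * matrix(rnorm(2 * 5000), 2), 200)
  cs <- estimate_cross_spectra(a, b)
  for (bin in seq_along(cs$freqs)) {
    J <- xfcacoh:::joint_csd(cs, bin)
    ev <- eigen(J, symmetric = FALSE, only.values = TRUE)$values
    expect_true(all(Re(ev) >= -1e-10 * Re(sum(diag(J)))))
    expect_true(all(abs(Im(ev)) < 1e-10 * max(1, Mod(sum(diag(J))))))
  }
})

test_that("swapping spaces conjugate-transposes the between block", {
  a <- noise_ts(2, fs = 200, dur = 10, seed = 5)
  b <- noise_ts(3, fs = 200, dur = 10, seed = 6)
  cs1 <- estimate_cross_spectra(a, b)
  cs2 <- estimate_cross_spectra(b, a)
  for (bin in c(2, 10, 40)) {
    expect_equal(cs1$cab[, , bin], Conj(t(cs2$cab[, , bin])), tolerance = 1e-12)
  }
  expect_equal(cs1$caa, cs2$cbb, tolerance = 1e-12)
})

test_that("channel scaling acts linearly on cross-spectral rows and columns", {
  a <- noise_ts(2, fs = 200, dur = 10, seed = 7)
  b <- noise_ts(1, fs = 200, dur = 10, seed = 8)
  a2 <- ts_set(a$data * c(3, 1), a$fs, a$labels)
  cs1 <- estimate_cross_spectra(a, b)
  cs2 <- estimate_cross_spectra(a2, b)
  expect_equal(cs2$cab[1, 1, ], 3 * cs1$cab[1, 1, ], tolerance = 1e-12)
  expect_equal(cs2$caa[1, 1, ], 9 * cs1$caa[1, 1, ], tolerance = 1e-12)
  expect_equal(cs2$caa[1, 2, ], 3 * cs1$caa[1, 2, ], tolerance = 1e-12)
  expect_equal(cs2$caa[2, 2, ], cs1$caa[2, 2, ], tolerance = 1e-12)
})

test_that("single-channel estimate reproduces a reference Welch coherence", {
  set.seed(9)
  n <- 6000; fs <- 200
  z <- rnorm(n)
  x <- z + 0.5 * rnorm(n)
  y <- z + 0.5 * rnorm(n)
  cs <- estimate_cross_spectra(ts_set(matrix(x, 1), fs), ts_set(matrix(y, 1), fs))
  expect_equal(msc(cs), ref_welch_msc(x, y, fs, fs), tolerance = 1e-10)
})

test_that("band_filter preserves a passband-center sinusoid", {
  fs <- 250
  x <- sine_ts(3, fs = fs, dur = 30)
  y <- band_filter(x, 3, 1)
  keep <- (2 * fs):(28 * fs)
  expect_equal(sqrt(mean(y$data[1, keep]^2)), sqrt(mean(x$data[1, keep]^2)),
               tolerance = 0.01)
  expect_identical(attr(y, "edge_s"), 2)
})

test_that("band_filter attenuates 9 Hz by at least 40 dB relative to 3 Hz", {
  x <- noise_ts(fs = 250, dur = 120, seed = 10)
  y <- band_filter(x, 3, 1)
  cs <- estimate_cross_spectra(y, y, segment_len_s = 2)
  p <- Re(cs$caa[1, 1, ])
  p3 <- p[nearest_bin(cs$freqs, 3)]
  p9 <- p[nearest_bin(cs$freqs, 9)]
  expect_lt(10 * log10(p9 / p3), -40)
})

test_that("band_filter is zero-phase: cross-correlation peaks at lag 0", {
  x <- make_oscillator(5, 1, duration_s = 30, fs = 250, seed = 11)
  y <- band_filter(x, 5, 1.5)
  cc <- ccf(x$data[1, ], y$data[1, ], lag.max = 25, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)
})

test_that("band_filter rejects bands outside the Nyquist range", {
  x <- noise_ts(fs = 100, dur = 5)
  expect_error(band_filter(x, 2, 3), "0 Hz")
  expect_error(band_filter(x, 48, 3), "Nyquist")
})

test_that("nearest_bin picks the closest bin with low-frequency tie-breaking", {
  expect_identical(nearest_bin(1:20, 3.0), 3L)
  expect_identical(nearest_bin(c(2.5, 3.5), 3.0), 1L) # tie -> lower frequency
  freqs <- seq(0, 20, by = 0.5)
  expect_equal(freqs[nearest_bin(freqs, 9.26)], 9.5)
  expect_warning(nearest_bin(c(1, 2, 3), 7), "from the nearest bin")
})

test_that("cross-spectra serialize to JSON + TSV and back", {
  a <- noise_ts(2, fs = 100, dur = 5, seed = 12)
  b <- noise_ts(1, fs = 100, dur = 5, seed = 13)
  cs <- estimate_cross_spectra(a, b, freq_range = c(0, 20))
  prefix <- file.path(tempdir(), "cs_test")
  write_cross_spectra(cs, prefix)
  cs2 <- read_cross_spectra(prefix)
  expect_equal(cs2$freqs, cs$freqs)
  expect_equal(cs2$caa, cs$caa, tolerance = 1e-14)
  expect_equal(cs2$cab, cs$cab, tolerance = 1e-14)
  expect_equal(cs2$n_segments, cs$n_segments)
})
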