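# Canonical coherence maximization, patterns, CKC / XF-CKC fits.

test_that("scalar spaces reduce to ordinary coherence with closed-form phase", {
  m <- rand_csd_instance(1, 1)
  cs <- structure(list(freqs = 3, caa = array(m$caa, c(1, 1, 1)),
                       cbb = array(m$cbb, c(1, 1, 1)),
                       cab = array(m$cab, c(1, 1, 1)),
                       n_segments = 8, fs = 100, labels_a = "a1",
                       labels_b = "b1", df = 1), class = "cross_spectra")
  sol <- maximize_cacoh(cs, 3, gamma = 0, seed = 1)
  expected <- Mod(m$cab[1, 1]) / sqrt(Re(m$caa[1, 1]) * Re(m$cbb[1, 1]))
  expect_equal(sol$coherence, expected, tolerance = 1e-10)
  expect_equal(abs(sol$phi), abs(Arg(m$cab[1, 1])), tolerance = 1e-10)
})

test_that("zero between-space block gives zero coherence", {
  m <- rand_csd_instance(2, 2)
  cs <- structure(list(freqs = 3, caa = array(m$caa, c(2, 2, 1)),
                       cbb = array(m$cbb, c(2, 2, 1)),
                       cab = array(0i, c(2, 2, 1)),
                       n_segments = 8, fs = 100, labels_a = c("a1", "a2"),
                       labels_b = c("b1", "b2"), df = 1),
                  class = "cross_spectra")
  expect_equal(maximize_cacoh(cs, 3, seed = 1)$coherence, 0, tolerance = 1e-12)
})

test_that("alternating solver matches the exhaustive grid oracle", {
  set.seed(10)
  for (i in 1:10) {
    pb <- if (i %% 2 == 0) 2 else 1
    m <- rand_csd_instance(2, pb)
    oracle <- grid_cacoh_oracle(m$caa, m$cbb, m$cab)
    sol <- xfcacoh:::cacoh_core(m$caa, m$cbb, m$cab, n_restarts = 10,
                                gamma = 0, seed = 20 + i)
    expect_equal(sol$coherence, oracle, tolerance = 1e-3)
  }
})

test_that("solver matches the closed-form eigen oracle for univariate space B", {
  set.seed(11)
  for (i in 1:10) {
    m <- rand_csd_instance(5, 1)
    sol <- xfcacoh:::cacoh_core(m$caa, m$cbb, m$cab, n_restarts = 10,
                                gamma = 0, seed = 30 + i)
    expect_equal(sol$coherence, eigen_cacoh_oracle(m$caa, m$cbb, m$cab),
                 tolerance = 1e-6)
  }
})

test_that("filters map to patterns through the real cross-spectrum", {
  alpha <- c(0.3, -0.8, 0.5)
  expect_equal(filters_to_pattern(diag(3), alpha), -alpha) # sign: largest |.| positive
  d <- c(2, 1, 4)
  p <- filters_to_pattern(diag(d), abs(alpha))
  expect_equal(unname(p), d * abs(alpha))
  expect_error(filters_to_pattern(diag(2), alpha), "dimension mismatch")
})

test_that("rank-1 sources are recovered by the pattern map", {
  set.seed(12)
  m <- rnorm(8)
  caa <- outer(m, m) + 1e-3 * diag(8)
  alpha <- solve(caa, m) # the matched filter for this source
  p <- filters_to_pattern(caa, alpha)
  expect_lt(recovery_error(m, p), 0.01)
})

test_that("maximized coherence is invariant under invertible channel mixing", {
  set.seed(13)
  eeg <- small_bundle()$eeg
  eeg4 <- ts_set(eeg$data[1:4, ], eeg$fs, eeg$labels[1:4])
  periph <- small_bundle()$peripheral
  f1 <- ckc(eeg4, periph, 3, gamma = 0, seed = 2, freq_range = c(1, 5))
  for (i in 1:3) {
    Tm <- matrix(rnorm(16), 4)
    while (abs(det(Tm)) < 0.1) Tm <- matrix(rnorm(16), 4)
    mixed <- ts_set(Tm %*% eeg4$data, eeg4$fs, eeg4$labels)
    f2 <- ckc(mixed, periph, 3, gamma = 0, seed = 2, freq_range = c(1, 5))
    expect_equal(f2$coherence, f1$coherence, tolerance = 1e-6)
  }
})

test_that("reported coherence is self-consistent with the projected pair", {
  b <- small_bundle()
  fit <- ckc(b$eeg, b$peripheral, 3, seed = 3, freq_range = c(1, 5))
  proj <- ts_set(matrix(drop(crossprod(matrix(fit$solution$alpha), b$eeg$data)), 1),
                 b$eeg$fs)
  cs <- estimate_cross_spectra(proj, b$peripheral)
  co <- sqrt(msc(cs)[nearest_bin(cs$freqs, 3)])
  expect_equal(co, fit$coherence, tolerance = 0.02)
})

test_that("ckc localizes a peripheral embedded in one channel", {
  set.seed(14)
  fs <- 250; n <- 40 * fs
  eeg <- matrix(rnorm(6 * n), 6)
  periph <- make_oscillator(3, 1, 40, fs, seed = 15)
  eeg[2, ] <- periph$data[1, ] + 0.1 * rnorm(n)
  fit <- ckc(ts_set(eeg, fs), periph, 3, seed = 4, freq_range = c(1, 5))
  expect_gt(fit$coherence, 0.9)
  p <- fit$solution$pattern_a
  expect_gt(abs(p[2]) / sqrt(sum(p^2)), 0.9)
})

test_that("xf_ckc finds a channel carrying the warped peripheral", {
  set.seed(16)
  fs <- 250; n <- 40 * fs
  periph <- make_oscillator(3, 1, 40, fs, seed = 17)
  w <- warp_frequency(periph, 2, 3, 1)
  eeg <- matrix(rnorm(6 * n), 6)
  eeg[4, ] <- w$data[1, ]
  fit <- xf_ckc(ts_set(eeg, fs), periph, coupling_spec(3, r = 2), seed = 5,
                freq_range = c(4, 8))
  expect_gt(fit$coherence, 0.95)
  p <- fit$solution$pattern_a
  expect_gt(abs(p[4]) / sqrt(sum(p^2)), 0.95)
})

test_that("xf_ckc with r = 1 reduces to ckc", {
  b <- small_bundle()
  f1 <- ckc(b$eeg, b$peripheral, 3, seed = 6, freq_range = c(1, 5))
  f2 <- xf_ckc(b$eeg, b$peripheral, coupling_spec(3, r = 1), seed = 6,
               freq_range = c(1, 5))
  expect_equal(f2$coherence, f1$coherence, tolerance = 1e-6)
  expect_equal(f2$solution$alpha, f1$solution$alpha, tolerance = 1e-6)
})

test_that("projection extracts single channels and is linear in the filter", {
  b <- small_bundle()
  e3 <- c(0, 0, 1, rep(0, 13))
  p1 <- project(b$eeg, e3, 6, 2)
  ref <- band_filter(pick_channel(b$eeg, 3), 6, 2)
  expect_equal(unname(p1$data), unname(ref$data), tolerance = 1e-12)
  p2 <- project(b$eeg, 2.5 * e3, 6, 2)
  expect_equal(p2$data, 2.5 * p1$data, tolerance = 1e-12)
})

test_that("projected source stays synchronized with the peripheral at high SNR", {
  b <- small_bundle()
  fit <- ckc(b$eeg, b$peripheral, 3, seed = 7, freq_range = c(1, 5))
  proj <- predict(fit, b$eeg)
  expect_gte(cross_freq_sync(proj, b$peripheral, coupling_spec(3, r = 1))$k_sync, 0.8)
})

test_that("fit objects expose standard accessors", {
  b <- small_bundle()
  fit <- ckc(b$eeg, b$peripheral, 3, seed = 8, freq_range = c(1, 5))
  co <- coef(fit)
  expect_named(co, c("alpha", "beta"))
  expect_length(co$alpha, n_channels(b$eeg))
  expect_output(print(fit), "coherence")
  expect_output(summary(fit), "strongest pattern channels")
  # unit projected power normalization
  cs <- estimate_cross_spectra(b$eeg, b$peripheral, freq_range = c(1, 5))
  Raa <- Re(cs$caa[, , nearest_bin(cs$freqs, 3)])
  expect_equal(drop(crossprod(co$alpha, Raa %*% co$alpha)), 1, tolerance = 1e-8)
  # polarity convention
  p <- fit$solution$pattern_a
  expect_gt(p[which.max(abs(p))], 0)
})
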