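# Analytic signal extraction and integer frequency warping.

test_that("analytic signal of a sinusoid has constant amplitude and linear phase", {
  fs <- 250
  x <- sine_ts(5, fs = fs, dur = 20, amp = 2.5)
  an <- analytic_signal(x)
  keep <- (2 * fs):(18 * fs)
  expect_equal(mean(an$amplitude[keep]), 2.5, tolerance = 0.01)
  expect_lt(diff(range(an$amplitude[keep])) / 2.5, 0.02)
  incr <- diff(an$phase_unwrapped[keep])
  expect_equal(mean(incr), 2 * pi * 5 / fs, tolerance = 1e-4)
})

test_that("analytic signal reconstruction a*cos(phi) recovers the input", {
  fs <- 250
  x <- make_oscillator(4, 1, duration_s = 30, fs = fs, seed = 1)
  an <- analytic_signal(x)
  rec <- an$amplitude * cos(an$phase)
  keep <- (2 * fs):(28 * fs)
  expect_lt(sqrt(mean((rec[keep] - x$data[1, keep])^2)), 1e-6)
})

test_that("zero input yields zero amplitude and zero phase by convention", {
  z <- ts_set(matrix(0, 1, 500), 100)
  an <- analytic_signal(z)
  expect_true(all(an$amplitude == 0))
  expect_true(all(an$phase == 0))
})

test_that("AM envelope is recovered accurately", {
  fs <- 250
  t <- seq(0, 40 - 1 / fs, by = 1 / fs)
  env <- 1 + 0.5 * cos(2 * pi * 0.2 * t)
  x <- ts_set(matrix(env * cos(2 * pi * 3 * t), 1), fs)
  an <- analytic_signal(x)
  keep <- (2 * fs):(38 * fs)
  rms_err <- sqrt(mean((an$amplitude[keep] - env[keep])^2))
  expect_lt(rms_err / mean(env), 0.02)
})

test_that("analytic_signal rejects multichannel input and warns on broadband input", {
  expect_error(analytic_signal(noise_ts(2, dur = 5)), "univariate")
  expect_warning(analytic_signal(noise_ts(1, dur = 5, seed = 2)), "broadband")
})

test_that("warping with r = 1 reproduces the band-filtered input", {
  x <- noise_ts(fs = 250, dur = 20, seed = 3)
  w <- warp_frequency(x, 1, 3, 1)
  f <- band_filter(x, 3, 1)
  expect_lt(sqrt(mean((w$data - f$data)^2)), 1e-6)
})

test_that("warping a sinusoid doubles its frequency exactly", {
  fs <- 250
  x <- sine_ts(3, fs = fs, dur = 30)
  w <- warp_frequency(x, 2, 3, 1)
  expected <- sine_ts(6, fs = fs, dur = 30)$data[1, ]
  keep <- (3 * fs):(27 * fs)
  expect_lt(sqrt(mean((w$data[1, keep] - expected[keep])^2)) /
              sqrt(mean(expected[keep]^2)), 0.01)
})

test_that("warping preserves the amplitude envelope and shifts the peak", {
  fs <- 250
  x <- make_oscillator(3, 1, duration_s = 60, fs = fs, seed = 4)
  w <- warp_frequency(x, 3, 3, 1)
  keep <- (2 * fs):(58 * fs)
  env_in <- analytic_signal(x)$amplitude[keep]
  env_out <- analytic_signal(w)$amplitude[keep]
  expect_lt(sqrt(mean((env_out - env_in)^2)) / mean(env_in), 0.02)
  expect_gt(cor(env_in, env_out), 0.98)
  pg <- Mod(fft(w$data[1, ]))^2
  fr <- (seq_along(pg) - 1) * fs / length(pg)
  half <- fr > 0 & fr < fs / 2
  expect_equal(fr[half][which.max(pg[half])], 9, tolerance = 0.3)
})

test_that("warped phase equals r times the input phase", {
  fs <- 250
  x <- make_oscillator(3, 1, duration_s = 60, fs = fs, seed = 5)
  for (r in c(2, 3)) {
    w <- warp_frequency(x, r, 3, 1)
    keep <- (2 * fs):(58 * fs)
    an_in <- analytic_signal(x)
    ph_out <- analytic_signal(w)$phase[keep]
    d <- Arg(exp(1i * (ph_out - r * an_in$phase[keep])))
    # instantaneous phase is undefined where the envelope vanishes; assess
    # the phase relation where amplitude carries information
    amp <- an_in$amplitude[keep]
    expect_lt(sqrt(mean(d[amp > quantile(amp, 0.1)]^2)), 0.1)
  }
})

test_that("warping rejects factors that alias past Nyquist", {
  x <- noise_ts(fs = 100, dur = 10, seed = 6)
  expect_error(warp_frequency(x, 20, 3, 1), "aliasing")
  expect_error(warp_frequency(x, 1.5, 3, 1), "positive integer")
})
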