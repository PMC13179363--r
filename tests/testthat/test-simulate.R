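# Simulation generators: oscillators, peripheral composition, leadfield,
# background noise, scenario assembly.

test_that("oscillators are unit-variance, narrow-band and seed-independent", {
  fs <- 250
  o1 <- make_oscillator(3, 1, duration_s = 120, fs = fs, seed = 1)
  o2 <- make_oscillator(3, 1, duration_s = 120, fs = fs, seed = 2)
  expect_equal(var(o1$data[1, ]), 1, tolerance = 0.02)
  expect_lt(abs(cor(o1$data[1, ], o2$data[1, ])), 0.05)
  pg <- Mod(fft(o1$data[1, ]))^2
  fr <- (seq_along(pg) - 1) * fs / length(pg)
  half <- fr > 0 & fr < fs / 2
  expect_lt(abs(fr[half][which.max(pg[half])] - 3), 1)
  expect_identical(o1$data, make_oscillator(3, 1, duration_s = 120, fs = fs,
                                            seed = 1)$data)
})

test_that("peripheral composition respects power ratios and realized SNR", {
  per <- make_peripheral("S1", fs = 250, duration_s = 120, seed = 3)
  v <- vapply(per$components, function(cm) var(cm$data[1, ]), numeric(1))
  expect_equal(v[3] / v[1], 0.25, tolerance = 0.02)
  expect_equal(v[2] / v[1], 0.5, tolerance = 0.02)
  osc_sum <- Reduce(`+`, lapply(per$components, function(cm) cm$data[1, ]))
  expect_equal(var(osc_sum) / var(per$noise), 10, tolerance = 0.5)
  expect_equal(per$peripheral$data[1, ], osc_sum + per$noise, tolerance = 1e-12)
})

test_that("only S2/S3 peripheral components are cross-frequency coupled", {
  s1 <- make_peripheral("S1", fs = 250, duration_s = 120, seed = 4)
  s2 <- make_peripheral("S2", fs = 250, duration_s = 120, seed = 4)
  sp <- coupling_spec(3, r = 2)
  expect_gte(cross_freq_sync(s2$components[[1]], s2$components[[2]], sp)$k_sync,
             0.99)
  expect_lt(cross_freq_sync(s1$components[[1]], s1$components[[2]], sp)$k_sync,
            0.1)
})

test_that("synthetic leadfield columns are unit-norm, distinct and smooth", {
  lf <- synthetic_leadfield(61, 5, seed = 5)
  expect_equal(unname(sqrt(colSums(lf^2))), rep(1, 5), tolerance = 1e-12)
  cosines <- abs(crossprod(lf))
  expect_true(all(cosines[upper.tri(cosines)] < 0.8))
  # spatial smoothness: neighboring electrodes carry correlated weights
  layout <- attr(lf, "layout")
  d <- matrix(acos(pmin(1, pmax(-1, crossprod(layout)))), ncol(layout))
  diag(d) <- Inf
  nn <- apply(d, 1, which.min)
  for (s in 1:5) {
    expect_gt(cor(lf[, s], lf[nn, s]), 0.5)
  }
  expect_identical(lf, synthetic_leadfield(61, 5, seed = 5))
})

test_that("background noise has a 1/f spectrum and full spatial rank", {
  fs <- 200
  bg <- pink_background(16, 100, duration_s = 30, fs = fs, seed = 6)
  cs <- estimate_cross_spectra(pick_channel(bg, 1), pick_channel(bg, 1),
                               segment_len_s = 2)
  keep <- cs$freqs >= 1 & cs$freqs <= 40
  fit <- lm(log10(Re(cs$caa[1, 1, keep])) ~ log10(cs$freqs[keep]))
  expect_equal(unname(coef(fit)[2]), -1, tolerance = 0.2)
  expect_equal(qr(bg$data %*% t(bg$data))$rank, 16)
  # 1/f noise is long-memory, so decorrelation needs the study-length record
  bga <- pink_background(16, 100, duration_s = 300, fs = fs, seed = 6)
  bgb <- pink_background(16, 100, duration_s = 300, fs = fs, seed = 7)
  expect_lt(mean(abs(diag(cor(t(bga$data), t(bgb$data))))), 0.05)
})

test_that("assembled scenarios honor the brain lag and SNR definition", {
  b <- small_bundle("S1", snr = 0.5, seed = 8, dur = 60, fs = 250)
  lag_samples <- round(20 * 250 / 1000)
  src <- b$truth_sources[["3:3"]]$data[1, ]
  per3 <- b$peripheral_components[[1]]$data[1, ]
  cc <- ccf(src, per3, lag.max = 4 * lag_samples, plot = FALSE)
  expect_lte(abs(cc$lag[which.max(cc$acf)] - lag_samples), 1)
  # re-measure the enforced per-component variance-ratio SNR
  bg_var <- mean(apply(b$eeg$data -
    Reduce(`+`, lapply(names(b$truth_sources), function(l) {
      outer(b$truth_patterns[[l]], b$truth_sources[[l]]$data[1, ])
    })), 1, var))
  for (l in names(b$truth_sources)) {
    proj_var <- mean(b$truth_patterns[[l]]^2) * var(b$truth_sources[[l]]$data[1, ])
    expect_equal(proj_var / bg_var, 0.5, tolerance = 0.025)
  }
})

test_that("bundles are fully deterministic given scenario and seed", {
  sc <- simulation_scenario("S2", snr_brain = 0.1, duration_s = 40, fs = 250,
                            n_channels = 12, n_noise_dipoles = 50, seed = 9)
  b1 <- assemble_scenario(sc)
  b2 <- assemble_scenario(sc)
  expect_identical(b1$eeg$data, b2$eeg$data)
  expect_identical(b1$peripheral$data, b2$peripheral$data)
  expect_identical(b1$truth_patterns, b2$truth_patterns)
})

test_that("warped truth sources stay locked to the slow peripheral component", {
  b <- small_bundle("S1", snr = 0.5, seed = 8, dur = 60, fs = 250)
  per3 <- b$peripheral_components[[1]]
  for (lab in c("3:6", "3:9")) {
    r <- as.numeric(sub("3:", "", lab)) / 3
    k <- cross_freq_sync(per3, b$truth_sources[[lab]],
                         coupling_spec(3, r = r))$k_sync
    expect_gte(k, 0.95)
  }
})

test_that("S3 co-locates the coupled sources on one topography", {
  sc <- simulation_scenario("S3", snr_brain = 0.5, duration_s = 40, fs = 250,
                            n_channels = 12, n_noise_dipoles = 50, seed = 10)
  b <- assemble_scenario(sc)
  expect_equal(recovery_error(b$truth_patterns[["3:6"]],
                              b$truth_patterns[["3:9"]]), 0)
  expect_gt(recovery_error(b$truth_patterns[["3:6"]],
                           b$truth_patterns[["independent"]]), 0.2)
})

test_that("snr_sweep reports recovery degradation toward low SNR", {
  tab <- snr_sweep("S1", snr_grid = c(0.5, 0.01), n_repetitions = 2,
                   n_permutations = 0, seed = 11, interactions = "3:3",
                   duration_s = 40, fs = 250, n_channels = 12,
                   n_noise_dipoles = 50, n_restarts = 5)
  expect_equal(nrow(tab), 4)
  m <- aggregate(rerror ~ snr, tab, mean)
  expect_lt(m$rerror[m$snr == 0.5], m$rerror[m$snr == 0.01])
})
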