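# Shared fixtures and independent oracles for the test suite.

# deterministic sinusoid signal
sine_ts <- function(f, fs = 250, dur = 10, phase = 0, amp = 1) {
  t <- seq(0, dur - 1 / fs, by = 1 / fs)
  ts_set(matrix(amp * cos(2 * pi * f * t + phase), 1), fs)
}

noise_ts <- function(n_ch = 1, fs = 250, dur = 10, seed = 1) {
  set.seed(seed)
  ts_set(matrix(rnorm(n_ch * round(dur * fs)), n_ch), fs)
}

# random joint-PSD cross-spectral instance (P_A x P_B), Hermitian blocks
rand_csd_instance <- function(pa, pb, n_avg = 8) {
  X <- matrix(complex(real = rnorm(n_avg * (pa + pb)),
                      imaginary = rnorm(n_avg * (pa + pb))), n_avg, pa + pb)
  J <- t(Conj(X)) %*% X / n_avg
  list(caa = J[seq_len(pa), seq_len(pa), drop = FALSE],
       cbb = J[pa + seq_len(pb), pa + seq_len(pb), drop = FALSE],
       cab = J[seq_len(pa), pa + seq_len(pb), drop = FALSE])
}

# Exhaustive grid-search oracle for 2x2 (and 2x1) canonical coherence:
# parameterizes unit filters by angle; the phase maximization is implicit in
# the squared modulus. Independent of the alternating solver.
grid_cacoh_oracle <- function(caa, cbb, cab, step = 0.002) {
  th_a <- seq(0, pi, by = step)
  A <- rbind(cos(th_a), sin(th_a))
  qa <- colSums(A * (Re(caa) %*% A))
  if (nrow(cbb) == 2) {
    th_b <- seq(0, pi, by = step)
    B <- rbind(cos(th_b), sin(th_b))
    qb <- colSums(B * (Re(cbb) %*% B))
    L <- Mod(t(A) %*% cab %*% B)^2 / outer(qa, qb)
  } else {
    L <- Mod(t(A) %*% cab)^2 / (qa * Re(cbb[1, 1]))
  }
  sqrt(max(L))
}

# Closed-form oracle for univariate space B: the maximal coherence is the top
# eigenvalue of a 2-D Rayleigh problem spanned by Re(cab), Im(cab).
eigen_cacoh_oracle <- function(caa, cbb, cab) {
  Rinv <- solve(Re(caa))
  C <- cbind(Re(cab), Im(cab))
  M <- t(C) %*% Rinv %*% C / Re(cbb[1, 1])
  sqrt(max(eigen(M, symmetric = TRUE)$values))
}

# Independent reference Welch magnitude-squared coherence for two univariate
# signals (plain loop, Hann window, mean removal) — written separately from
# the package's estimator.
ref_welch_msc <- function(x, y, fs, seg_len, overlap = 0.5) {
  step <- round(seg_len * (1 - overlap))
  starts <- seq(1, length(x) - seg_len + 1, by = step)
  w <- 0.5 * (1 - cos(2 * pi * seq(0, seg_len - 1) / (seg_len - 1)))
  sxx <- syy <- numeric(floor(seg_len / 2) + 1)
  sxy <- complex(real = sxx)
  for (s in starts) {
    xs <- x[s:(s + seg_len - 1)]; ys <- y[s:(s + seg_len - 1)]
    X <- fft((xs - mean(xs)) * w)[seq_along(sxx)]
    Y <- fft((ys - mean(ys)) * w)[seq_along(sxx)]
    sxx <- sxx + Mod(X)^2; syy <- syy + Mod(Y)^2; sxy <- sxy + X * Conj(Y)
  }
  Mod(sxy)^2 / (sxx * syy)
}

# small, quick simulation bundle for pipeline tests (cached per session)
small_bundle <- local({
  cache <- list()
  function(set_id = "S1", snr = 0.5, seed = 3, dur = 60, fs = 250,
           n_ch = 16, n_dip = 100) {
    key <- paste(set_id, snr, seed, dur, fs, n_ch, n_dip, sep = "_")
    if (is.null(cache[[key]])) {
      sc <- simulation_scenario(set_id, snr_brain = snr, duration_s = dur,
                                fs = fs, n_channels = n_ch,
                                n_noise_dipoles = n_dip, seed = seed)
      cache[[key]] <<- assemble_scenario(sc)
    }
    cache[[key]]
  }
})
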