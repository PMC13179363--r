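# Simulation framework: coupled narrow-band oscillators, composite peripheral
# signal, synthetic leadfield projection, 1/f dipole background, SNR control.

#' Narrow-band Gaussian oscillator
#'
#' White Gaussian noise band-pass filtered around `center_hz` (zero-phase
#' Butterworth, see [band_filter()]) and rescaled to exactly unit variance.
#'
#' @param center_hz center frequency (Hz).
#' @param half_bw_hz half bandwidth; defaults to `center_hz / 3` so relative
#'   bandwidth is constant across 3/6/9 Hz.
#' @param duration_s,fs duration (s) and sampling rate (Hz).
#' @param seed integer seed (deterministic output per seed).
#' @return univariate [ts_set()].
#' @export
make_oscillator <- function(center_hz, half_bw_hz = center_hz / 3,
                            duration_s = 300, fs = 500, seed = NULL) {
  n <- round(duration_s * fs)
  w <- with_seed(seed, stats::rnorm(n))
  x <- band_filter(ts_set(matrix(w, 1), fs, "osc"), center_hz, half_bw_hz)
  v <- x$data[1, ]
  v <- v / stats::sd(v)
  out <- ts_set(matrix(v - mean(v), 1), fs, sprintf("osc%g", center_hz))
  attr(out, "band") <- attr(x, "band")
  attr(out, "edge_s") <- 2
  out
}

scale_to_var <- function(v, target_var) {
  v <- v - mean(v)
  v * sqrt(target_var / stats::var(v))
}

#' Composite peripheral (kinematic) signal
#'
#' Builds the simulated peripheral signal from three narrow-band oscillators
#' at 3, 6 and 9 Hz with variance ratios `power_ratios` (default 1 : 1/2 :
#' 1/4), summed with white Gaussian noise scaled so the realized variance
#' ratio `var(oscillator sum) / var(noise)` equals `snr_peripheral` exactly.
#'
#' For set `"S1"` the three oscillators are mutually independent. For `"S2"`
#' and `"S3"` the 6 and 9 Hz components are frequency-warped copies
#' (`r = 2, 3`) of the 3 Hz oscillator, so the peripheral signal is
#' non-sinusoidal with genuine 3:6 and 3:9 phase coupling.
#'
#' @param set_id `"S1"`, `"S2"` or `"S3"`.
#' @param fs,duration_s sampling rate (Hz) and duration (s).
#' @param power_ratios length-3 variance ratios for the 3/6/9 Hz components.
#' @param snr_peripheral peripheral signal-to-noise variance ratio
#'   (default 10).
#' @param seed integer seed.
#' @return list with `peripheral` (univariate `ts_set`), `components` (list
#'   of three univariate `ts_set`s, exact variances `power_ratios`), and
#'   `noise` (numeric vector).
#' @export
make_peripheral <- function(set_id = c("S1", "S2", "S3"), fs = 500,
                            duration_s = 300, power_ratios = c(1, 1 / 2, 1 / 4),
                            snr_peripheral = 10, seed = NULL) {
  set_id <- match.arg(set_id)
  stopifnot(length(power_ratios) == 3, all(power_ratios > 0), snr_peripheral > 0)
  freqs <- c(3, 6, 9)
  o3 <- make_oscillator(3, duration_s = duration_s, fs = fs,
                        seed = child_seed(seed, 1))
  comps <- vector("list", 3)
  if (set_id == "S1") {
    comps[[1]] <- o3
    comps[[2]] <- make_oscillator(6, duration_s = duration_s, fs = fs,
                                  seed = child_seed(seed, 2))
    comps[[3]] <- make_oscillator(9, duration_s = duration_s, fs = fs,
                                  seed = child_seed(seed, 3))
  } else {
    comps[[1]] <- o3
    comps[[2]] <- warp_frequency(o3, 2, 3)
    comps[[3]] <- warp_frequency(o3, 3, 3)
  }
  for (i in 1:3) {
    v <- scale_to_var(comps[[i]]$data[1, ], power_ratios[i])
    band <- attr(comps[[i]], "band")
    comps[[i]] <- ts_set(matrix(v, 1), fs, sprintf("periph%g", freqs[i]))
    attr(comps[[i]], "band") <- band
    attr(comps[[i]], "edge_s") <- 2
  }
  total <- comps[[1]]$data[1, ] + comps[[2]]$data[1, ] + comps[[3]]$data[1, ]
  noise <- with_seed(child_seed(seed, 4), stats::rnorm(length(total)))
  noise <- scale_to_var(noise, stats::var(total) / snr_peripheral)
  list(
    peripheral = ts_set(matrix(total + noise, 1), fs, "peripheral"),
    components = comps,
    noise = noise
  )
}

#' Quasi-equiangular electrode layout on a spherical cap
#'
#' Electrode positions as unit vectors on concentric rings of a spherical
#' cap: ring k carries `6k` electrodes (plus the vertex), which gives exactly
#' 61 positions with five rings — a stylized dense EEG montage.
#'
#' @param n_channels number of electrodes (>= 8).
#' @param cap_angle polar angle of the outermost ring (radians).
#' @return 3 x n matrix of unit position vectors, with column names
#'   `E01`, ...
#' @export
electrode_layout <- function(n_channels = 61, cap_angle = 1.2) {
  stopifnot(n_channels >= 8)
  counts <- 1
  k <- 1
  while (sum(counts) < n_channels) {
    counts <- c(counts, 6 * k)
    k <- k + 1
  }
  n_rings <- length(counts)
  pos <- matrix(0, 3, 0)
  placed <- 0
  for (ring in seq_len(n_rings)) {
    m <- min(counts[ring], n_channels - placed)
    if (m <= 0) break
    theta <- cap_angle * (ring - 1) / (n_rings - 1)
    az <- 2 * pi * (seq_len(m) - 1) / m + (ring %% 2) * pi / max(m, 1)
    pos <- cbind(pos, rbind(sin(theta) * cos(az), sin(theta) * sin(az),
                            rep(cos(theta), m)))
    placed <- placed + m
  }
  colnames(pos) <- sprintf("E%02d", seq_len(ncol(pos)))
  pos
}

# Great-circle angular distance between a 3 x n layout and one unit vector.
angular_dist <- function(layout, center) {
  acos(pmin(1, pmax(-1, drop(crossprod(layout, center)))))
}

random_cap_point <- function(max_theta = 1.0) {
  # area-uniform draw on the cap
  u <- stats::runif(1, cos(max_theta), 1)
  theta <- acos(u)
  az <- stats::runif(1, 0, 2 * pi)
  c(sin(theta) * cos(az), sin(theta) * sin(az), cos(theta))
}

rotate_towards <- function(v, delta) {
  # rotate v by angle delta in a random tangent direction
  t1 <- c(-v[2], v[1], 0)
  if (sum(t1^2) < 1e-12) t1 <- c(1, 0, 0)
  t1 <- t1 / sqrt(sum(t1^2))
  t2 <- c(v[2] * t1[3] - v[3] * t1[2], v[3] * t1[1] - v[1] * t1[3],
          v[1] * t1[2] - v[2] * t1[1])
  az <- stats::runif(1, 0, 2 * pi)
  d <- cos(az) * t1 + sin(az) * t2
  w <- cos(delta) * v + sin(delta) * d
  w / sqrt(sum(w^2))
}

#' Synthetic leadfield with pseudo-dipolar topographies
#'
#' A stand-in forward model replacing anatomically realistic volume
#' conduction: each source column is a smooth pseudo-dipolar topography — the
#' difference of two spatial Gaussians centered at nearby random locations on
#' the electrode cap — unit-normalized. Columns of designated distinct
#' sources are resampled until every pairwise absolute cosine is below
#' `max_abs_cos`, so truth patterns are spatially distinguishable.
#'
#' @param n_channels number of electrodes (>= 8).
#' @param n_sources number of source columns.
#' @param layout optional 3 x n electrode position matrix
#'   (default [electrode_layout()]); a user-supplied matrix restores a
#'   realistic montage.
#' @param seed integer seed.
#' @param max_abs_cos maximum allowed |cosine| between distinct columns.
#' @param sigma spatial Gaussian width (radians).
#' @return `n_channels x n_sources` matrix with unit-norm columns; attribute
#'   `layout` carries the electrode positions.
#' @export
synthetic_leadfield <- function(n_channels = 61, n_sources = 1, layout = NULL,
                                seed = NULL, max_abs_cos = 0.8, sigma = 0.45) {
  if (is.null(layout)) layout <- electrode_layout(n_channels)
  stopifnot(ncol(layout) == n_channels, n_channels >= 8)
  one_column <- function() {
    c1 <- random_cap_point()
    c2 <- rotate_towards(c1, 0.35)
    g <- exp(-angular_dist(layout, c1)^2 / (2 * sigma^2)) -
      0.6 * exp(-angular_dist(layout, c2)^2 / (2 * (sigma * 1.2)^2))
    g / sqrt(sum(g^2))
  }
  lf <- with_seed(seed, {
    m <- matrix(0, n_channels, n_sources)
    for (s in seq_len(n_sources)) {
      ok <- FALSE
      for (try in seq_len(100)) {
        cand <- one_column()
        if (s == 1 ||
            all(abs(crossprod(m[, seq_len(s - 1), drop = FALSE], cand)) < max_abs_cos)) {
          m[, s] <- cand; ok <- TRUE; break
        }
      }
      if (!ok) stop("could not draw a sufficiently distinct source topography in 100 tries")
    }
    m
  })
  rownames(lf) <- colnames(layout)
  attr(lf, "layout") <- layout
  lf
}

# m independent 1/f time courses of length n (rows = time): power ~ 1/f.
one_over_f_courses <- function(n, m, fs) {
  W <- matrix(stats::rnorm(n * m), n, m)
  Z <- stats::mvfft(W)
  fr <- c(0, seq_len(n - 1)) * fs / n
  fr <- pmin(fr, fs - fr) # two-sided frequency axis
  amp <- ifelse(fr > 0, 1 / sqrt(fr), 0)
  Re(stats::mvfft(Z * amp, inverse = TRUE)) / n
}

#' Multichannel 1/f background from random dipoles
#'
#' Sums `n_noise_dipoles` independent pink-noise (power proportional to 1/f)
#' time courses, each projected through a random unit topography — the
#' spatially structured background against which brain SNR is defined.
#'
#' @param n_channels number of channels.
#' @param n_noise_dipoles number of background dipoles (default 500).
#' @param duration_s,fs duration and sampling rate.
#' @param seed integer seed.
#' @return a [ts_set()] of `n_channels` channels.
#' @export
pink_background <- function(n_channels = 61, n_noise_dipoles = 500,
                            duration_s = 300, fs = 500, seed = NULL) {
  n <- round(duration_s * fs)
  acc <- with_seed(seed, {
    acc <- matrix(0, n_channels, n)
    chunk <- 50
    done <- 0
    while (done < n_noise_dipoles) {
      m <- min(chunk, n_noise_dipoles - done)
      topo <- matrix(stats::rnorm(n_channels * m), n_channels, m)
      topo <- sweep(topo, 2, sqrt(colSums(topo^2)), `/`)
      acc <- acc + topo %*% t(one_over_f_courses(n, m, fs))
      done <- done + m
    }
    acc
  })
  ts_set(acc, fs, sprintf("E%02d", seq_len(n_channels)))
}

#' Simulation scenario description
#'
#' Bundles the generator parameters of one simulated recording: the
#' simulation set (`S1` independent oscillators; `S2` non-sinusoidal coupled
#' peripheral; `S3` as S2 with co-located coupled cortical sources), the
#' per-component brain SNR, and the sampling/montage defaults (300 s at
#' 500 Hz, 61 channels, 500 background dipoles, 20 ms brain lag, peripheral
#' SNR 10, power ratios 1 : 1/2 : 1/4 at 3/6/9 Hz).
#'
#' @param set_id `"S1"`, `"S2"` or `"S3"`.
#' @param snr_brain per-component brain SNR: mean-over-channels variance of a
#'   projected source divided by mean-over-channels variance of the 1/f
#'   background. Study grid: 0.5, 0.25, 0.1, 0.05, 0.025, 0.01.
#' @param snr_peripheral peripheral variance SNR (default 10).
#' @param duration_s,fs,n_channels,n_noise_dipoles,lag_ms,power_ratios see
#'   above.
#' @param seed integer seed; the full bundle is a deterministic function of
#'   the scenario.
#' @return object of class `sim_scenario`.
#' @export
simulation_scenario <- function(set_id = c("S1", "S2", "S3"), snr_brain = 0.5,
                                snr_peripheral = 10, duration_s = 300, fs = 500,
                                n_channels = 61, n_noise_dipoles = 500,
                                lag_ms = 20, power_ratios = c(1, 1 / 2, 1 / 4),
                                seed = 1) {
  set_id <- match.arg(set_id)
  stopifnot(snr_brain > 0, snr_peripheral > 0)
  if (duration_s * fs < 1e4) stop("scenario too short: need duration_s * fs >= 1e4 samples")
  structure(
    list(set_id = set_id, snr_brain = snr_brain, snr_peripheral = snr_peripheral,
         duration_s = duration_s, fs = fs, n_channels = n_channels,
         n_noise_dipoles = n_noise_dipoles, lag_ms = lag_ms,
         power_ratios = power_ratios, seed = seed),
    class = "sim_scenario"
  )
}

#' @export
print.sim_scenario <- function(x, ...) {
  cat(sprintf("<sim_scenario> %s, brain SNR %g, %g s @ %g Hz, %d ch, seed %s\n",
              x$set_id, x$snr_brain, x$duration_s, x$fs, x$n_channels,
              format(x$seed)))
  invisible(x)
}

#' Assemble a full simulated EEG + peripheral recording
#'
#' Generates the peripheral signal, the brain source time courses dictated by
#' the simulation set, projects them through a synthetic leadfield, adds the
#' 1/f dipole background, and records the ground truth.
#'
#' Sources per set (each delayed by `lag_ms` relative to the periphery and
#' scaled so its projected mean-channel variance over the background's is
#' exactly `snr_brain`):
#' * `S1`: within-frequency copies of the three peripheral oscillators
#'   (labels `3:3`, `6:6`, `9:9`) plus warped copies of the 3 Hz oscillator
#'   at 6 and 9 Hz (`3:6`, `3:9`); five distinct topographies.
#' * `S2`: warped 3 Hz oscillator at 6 and 9 Hz (`3:6`, `3:9`; these equal
#'   the peripheral's own harmonic components) plus an `independent` 6 Hz
#'   oscillator; three distinct topographies.
#' * `S3`: as S2, but the two coupled sources share one topography.
#'
#' @param scenario a [simulation_scenario()].
#' @param leadfield optional user-supplied `n_channels x n_sources` forward
#'   matrix (unit-norm columns) replacing the synthetic one.
#' @return object of class `sim_bundle`: `eeg` ([ts_set()]), `peripheral`
#'   (univariate `ts_set`), `truth_patterns` (named list of channel-space
#'   patterns), `truth_sources` (named list of univariate `ts_set`s),
#'   `leadfield`, `scenario`.
#' @export
assemble_scenario <- function(scenario, leadfield = NULL) {
  stopifnot(inherits(scenario, "sim_scenario"))
  sc <- scenario
  per <- make_peripheral(sc$set_id, sc$fs, sc$duration_s, sc$power_ratios,
                         sc$snr_peripheral, seed = child_seed(sc$seed, 11))
  lag <- round(sc$lag_ms * sc$fs / 1000)
  o <- lapply(per$components, function(cmp) cmp$data[1, ])

  if (sc$set_id == "S1") {
    labels <- c("3:3", "6:6", "9:9", "3:6", "3:9")
    w6 <- warp_frequency(per$components[[1]], 2, 3)$data[1, ]
    w9 <- warp_frequency(per$components[[1]], 3, 3)$data[1, ]
    courses <- list(o[[1]], o[[2]], o[[3]], w6, w9)
    n_src <- 5
    col_of <- seq_len(5)
  } else {
    labels <- c("3:6", "3:9", "independent")
    ind <- make_oscillator(6, duration_s = sc$duration_s, fs = sc$fs,
                           seed = child_seed(sc$seed, 12))$data[1, ]
    courses <- list(o[[2]], o[[3]], ind)
    if (sc$set_id == "S2") {
      n_src <- 3
      col_of <- c(1, 2, 3)
    } else { # S3: coupled sources co-located
      n_src <- 2
      col_of <- c(1, 1, 2)
    }
  }

  lf <- leadfield %||% synthetic_leadfield(sc$n_channels, n_src,
                                           seed = child_seed(sc$seed, 13))
  if (ncol(lf) < n_src) stop("leadfield has too few columns for this set")
  bg <- pink_background(sc$n_channels, sc$n_noise_dipoles, sc$duration_s,
                        sc$fs, seed = child_seed(sc$seed, 14))
  v_bg <- mean(apply(bg$data, 1, stats::var))

  eeg_data <- bg$data
  truth_patterns <- list()
  truth_sources <- list()
  for (i in seq_along(labels)) {
    m <- lf[, col_of[i]]
    u <- delay_samples(courses[[i]], lag)
    # mean-over-channels variance of m u' is var(u) * mean(m^2)
    target_var <- sc$snr_brain * v_bg / mean(m^2)
    u <- scale_to_var(u, target_var)
    eeg_data <- eeg_data + outer(m, u)
    truth_patterns[[labels[i]]] <- m
    src <- ts_set(matrix(u, 1), sc$fs, labels[i])
    # truth sources are narrow-band at the fast frequency by construction
    f_src <- if (labels[i] == "independent") 6 else
      as.numeric(strsplit(labels[i], ":", fixed = TRUE)[[1]][2])
    attr(src, "band") <- c(center = f_src, half_bw = f_src / 3)
    attr(src, "edge_s") <- 2
    truth_sources[[labels[i]]] <- src
  }

  structure(
    list(eeg = ts_set(eeg_data, sc$fs, rownames(lf) %||% bg$labels),
         peripheral = per$peripheral,
         peripheral_components = per$components,
         truth_patterns = truth_patterns, truth_sources = truth_sources,
         leadfield = lf, scenario = sc),
    class = "sim_bundle"
  )
}

#' @export
print.sim_bundle <- function(x, ...) {
  cat(sprintf("<sim_bundle> %s: %d-ch EEG, %g s @ %g Hz, interactions: %s\n",
              x$scenario$set_id, n_channels(x$eeg), x$scenario$duration_s,
              x$scenario$fs, paste(names(x$truth_patterns), collapse = ", ")))
  invisible(x)
}

# Interaction label -> analysis recipe.
parse_interaction <- function(label) {
  if (label == "independent") {
    return(list(kind = "within", f = 6, truth = "independent"))
  }
  fq_fr <- as.numeric(strsplit(label, ":", fixed = TRUE)[[1]])
  if (length(fq_fr) != 2 || any(is.na(fq_fr))) stop("bad interaction label: ", label)
  if (fq_fr[1] == fq_fr[2]) {
    list(kind = "within", f = fq_fr[1], truth = label)
  } else {
    list(kind = "xf", spec = coupling_spec(fq_fr[1], r = round(fq_fr[2] / fq_fr[1])),
         truth = label)
  }
}

#' SNR sweep with permutation-based failure analysis
#'
#' Repeats the full recovery experiment over a grid of brain SNR values:
#' for each SNR and repetition a fresh bundle is generated, each interaction
#' is estimated (within-frequency caCOH at `f`, XF-caCOH for `f_q:f_r`), the
#' pattern recovery error against the ground truth is computed, and a
#' permutation null of the recovery error is built by shuffling peripheral
#' epochs and re-running the estimation. An interaction *fails* at an SNR
#' when the observed error is not significantly smaller than its null
#' (p > 0.05, p = proportion of permuted errors <= observed).
#'
#' @param set_id simulation set.
#' @param snr_grid numeric vector of brain SNR values (paper grid:
#'   0.5, 0.25, 0.1, 0.05, 0.025, 0.01).
#' @param n_repetitions repetitions (fresh source locations) per SNR.
#' @param n_permutations permutations for the null (0 skips the null).
#' @param seed master seed.
#' @param interactions interaction labels; defaults to all labels of the set.
#' @param duration_s,fs,n_channels,n_noise_dipoles scenario size overrides.
#' @param epoch_len_s epoch length for trial permutation (default 1 s).
#' @param ... further arguments to the estimator (e.g. `n_restarts`).
#' @return data.frame with one row per (snr, repetition, interaction):
#'   `coherence`, `rerror`, `null95_rerror`, `p_value`, `fail`; an attribute
#'   `"failure_rates"` holds the aggregated failure proportion per
#'   snr x interaction.
#' @export
snr_sweep <- function(set_id = "S1", snr_grid = c(0.5, 0.25, 0.1, 0.05, 0.025, 0.01),
                      n_repetitions = 10, n_permutations = 199, seed = 1,
                      interactions = NULL, duration_s = 300, fs = 500,
                      n_channels = 61, n_noise_dipoles = 500,
                      epoch_len_s = 1, ...) {
  stopifnot(length(snr_grid) >= 1)
  rows <- list()
  for (si in seq_along(snr_grid)) {
    for (rep_i in seq_len(n_repetitions)) {
      sc <- simulation_scenario(set_id, snr_brain = snr_grid[si],
                                duration_s = duration_s, fs = fs,
                                n_channels = n_channels,
                                n_noise_dipoles = n_noise_dipoles,
                                seed = child_seed(seed, 1000 * si + rep_i))
      bundle <- assemble_scenario(sc)
      labs <- interactions %||% names(bundle$truth_patterns)
      for (lab in labs) {
        res <- rerror_significance(bundle, lab, n_perm = n_permutations,
                                   seed = child_seed(seed, 7000 + 100 * si + rep_i),
                                   epoch_len_s = epoch_len_s, ...)
        rows[[length(rows) + 1]] <- data.frame(
          set_id = set_id, snr = snr_grid[si], repetition = rep_i,
          interaction = lab, coherence = res$coherence,
          rerror = res$observed, null95_rerror = res$percentile_95,
          p_value = res$p_value, fail = res$p_value > 0.05,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  out <- do.call(rbind, rows)
  agg <- stats::aggregate(fail ~ snr + interaction, data = out, FUN = mean,
                          na.action = stats::na.pass)
  names(agg)[names(agg) == "fail"] <- "failure_rate"
  attr(out, "failure_rates") <- agg
  out
}
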