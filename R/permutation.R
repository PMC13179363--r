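# Permutation nulls for coupling strength and pattern recovery error.

#' Shuffle peripheral epochs
#'
#' Permutes the order of epoch contents within the peripheral signal,
#' destroying temporal alignment with the brain recording while preserving
#' the amplitude distribution and all within-epoch structure. Samples outside
#' the epochs (e.g. a trailing remainder) stay in place.
#'
#' @param peripheral univariate [ts_set()].
#' @param epochs list of `c(start, end)` 0-based half-open intervals of equal
#'   length; defaults to the signal's own epochs, else consecutive
#'   `epoch_len_s`-second chunks.
#' @param seed integer seed.
#' @param epoch_len_s epoch length used when no epochs are available.
#' @return univariate `ts_set` with the same epochs.
#' @export
permute_peripheral <- function(peripheral, epochs = NULL, seed = NULL,
                               epoch_len_s = 1) {
  assert_univariate(peripheral, "peripheral")
  epochs <- epochs %||% peripheral$epochs %||% default_epochs(peripheral, epoch_len_s)
  if (length(epochs) < 3) stop("need at least 3 epochs to permute")
  lens <- vapply(epochs, function(e) e[2] - e[1], numeric(1))
  if (length(unique(lens)) != 1) stop("epochs must have equal length for permutation")
  ord <- with_seed(seed, sample.int(length(epochs)))
  v <- peripheral$data[1, ]
  out <- v
  for (i in seq_along(epochs)) {
    src <- epochs[[ord[i]]]; dst <- epochs[[i]]
    out[(dst[1] + 1):dst[2]] <- v[(src[1] + 1):src[2]]
  }
  ts_set(matrix(out, 1), peripheral$fs, peripheral$labels, epochs)
}

# Single-bin caCOH engine: caches the EEG-side per-segment spectra and the
# regularized Cholesky factor of Re(C_AA) at the bin of interest, so that a
# permutation null can re-run the full estimation pipeline on a permuted
# peripheral signal at the cost of one univariate spectral pass per draw.
# Produces results identical (to rounding) to estimate_cross_spectra +
# maximize_cacoh restricted to the bin.
make_bin_engine <- function(eeg, f_hz, segment_len_s = 1, overlap_frac = 0.5,
                            taper = "hann", gamma = 1e-4, n_restarts = 10,
                            tol = 1e-8, max_iter = 200) {
  fs <- eeg$fs
  L <- round(segment_len_s * fs)
  if (L < 16) stop("segment too short")
  step <- max(1L, round(L * (1 - overlap_frac)))
  n <- n_samples(eeg)
  starts <- seq(1, n - L + 1, by = step)
  K <- length(starts)
  if (K < 2) stop("insufficient data: fewer than 2 complete segments")
  grid <- (seq_len(floor(L / 2) + 1) - 1) * fs / L
  bin <- nearest_bin(grid, f_hz)
  w <- taper_window(taper, L)
  scale <- 1 / sqrt(sum(w^2) * fs)
  E <- w * exp(-2i * pi * (bin - 1) * seq(0, L - 1) / L) * scale

  pa <- n_channels(eeg)
  za <- matrix(0i, pa, K)
  for (k in seq_len(K)) {
    seg <- eeg$data[, starts[k]:(starts[k] + L - 1), drop = FALSE]
    seg <- seg - rowMeans(seg)
    za[, k] <- seg %*% E
  }
  caa <- za %*% Conj(t(za)) / K
  Raa <- Re(caa)
  Raa_r <- shrink_reg(Raa, gamma)
  if (kappa(Raa_r, exact = FALSE) > 1e12) {
    stop("EEG cross-spectrum numerically singular after regularization")
  }
  Raa_ch <- chol(Raa_r)

  b_spectra <- function(bvec) {
    S <- matrix(bvec[outer(0:(L - 1), starts, `+`)], L, K)
    S <- sweep(S, 2, colMeans(S), `-`)
    drop(crossprod(S, E))
  }

  fit <- function(bvec, seed = NULL) {
    zb <- b_spectra(bvec)
    cbb <- matrix(mean(Mod(zb)^2), 1, 1)
    cab <- (za %*% Conj(zb)) / K
    Rbb_r <- shrink_reg(Re(cbb), gamma)
    core <- cacoh_core(caa, cbb, cab, n_restarts = n_restarts, tol = tol,
                       max_iter = max_iter, gamma = gamma, seed = seed,
                       chols = list(Raa_r = Raa_r, Rbb_r = Rbb_r,
                                    Raa_ch = Raa_ch, Rbb_ch = chol(Rbb_r)))
    names(core$alpha) <- names(core$pattern_a) <- eeg$labels
    core$bin_hz <- grid[bin]
    core
  }

  list(fit = fit, bin_hz = grid[bin], n_segments = K, f_hz = f_hz)
}

# Peripheral preprocessing for an interaction: identity for within-frequency
# coupling, band-filter + warp for cross-frequency coupling.
prep_peripheral_fun <- function(recipe, half_bw_hz = NULL) {
  if (recipe$kind == "within") {
    function(p) p$data[1, ]
  } else {
    spec <- recipe$spec
    hb <- half_bw_hz %||% (spec$f_q / 3)
    function(p) {
      if (spec$r == 1) p$data[1, ]
      else warp_frequency(p, spec$r, spec$f_q, hb)$data[1, ]
    }
  }
}

new_perm_null <- function(statistic_name, observed, null_values, p_value,
                          n_perm, seed, significant, extra = list()) {
  pct <- if (length(null_values)) {
    sort(null_values)[ceiling(0.95 * length(null_values))] # nearest-rank
  } else NA_real_
  structure(
    c(list(statistic_name = statistic_name, observed = observed,
           null_values = null_values, percentile_95 = pct,
           p_value = p_value, n_perm = n_perm, seed = seed,
           significant = significant),
      extra),
    class = "perm_null"
  )
}

#' @export
print.perm_null <- function(x, ...) {
  cat(sprintf("<perm_null> %s: observed %.4f, null 95th pct %.4f, p = %.4g (%d permutations)\n",
              x$statistic_name, x$observed, x$percentile_95, x$p_value, x$n_perm))
  invisible(x)
}

perm_p_value <- function(n_extreme, n_perm, method) {
  if (method == "add_one") (1 + n_extreme) / (1 + n_perm) else n_extreme / n_perm
}

#' Permutation significance of CKC / XF-CKC coupling strength
#'
#' Tests the fitted coherence against the null hypothesis of temporal
#' independence between brain and peripheral signals: the peripheral epochs
#' are shuffled `n_perm` times and the complete estimation pipeline
#' (filtering/warping for cross-frequency interactions, cross-spectral
#' estimation, coherence maximization with full restarts) is re-run on each
#' shuffle. The observed value is significant when it exceeds the null's
#' 95th percentile (nearest-rank).
#'
#' @param eeg multichannel [ts_set()].
#' @param peripheral univariate [ts_set()].
#' @param spec a [coupling_spec()]; `r = 1` gives the within-frequency test
#'   at `f_q`.
#' @param n_perm number of permutations (>= 100 recommended; e.g. 199).
#' @param seed master seed (restart draws and shuffles).
#' @param epochs,epoch_len_s epoching for the shuffle, see
#'   [permute_peripheral()].
#' @param half_bw_hz peripheral filter half bandwidth for warping.
#' @param p_method `"add_one"` (default; `p = (1 + #{null >= obs}) /
#'   (1 + n_perm)`, never exactly zero) or `"plain"` (the raw proportion).
#' @param segment_len_s,overlap_frac,taper,gamma,n_restarts,tol,max_iter
#'   estimation parameters, see [ckc()] and [maximize_cacoh()].
#' @return object of class `perm_null`: `observed` coherence, `null_values`,
#'   nearest-rank `percentile_95`, `p_value`, `significant`, and the observed
#'   solution in `$solution`.
#' @export
coupling_significance <- function(eeg, peripheral, spec, n_perm = 199, seed = 1,
                                  epochs = NULL, epoch_len_s = 1,
                                  half_bw_hz = NULL,
                                  p_method = c("add_one", "plain"),
                                  segment_len_s = 1, overlap_frac = 0.5,
                                  taper = "hann", gamma = 1e-4,
                                  n_restarts = 10, tol = 1e-8, max_iter = 200) {
  p_method <- match.arg(p_method)
  stopifnot(inherits(spec, "coupling_spec"))
  if (n_perm < 100) warning("fewer than 100 permutations: p-value resolution is coarse")
  recipe <- if (spec$r == 1) list(kind = "within", f = spec$f_q)
            else list(kind = "xf", spec = spec)
  prep <- prep_peripheral_fun(recipe, half_bw_hz)
  f_target <- if (recipe$kind == "within") recipe$f else spec$f_r
  engine <- make_bin_engine(eeg, f_target, segment_len_s, overlap_frac, taper,
                            gamma, n_restarts, tol, max_iter)
  obs <- engine$fit(prep(peripheral), seed = child_seed(seed, 0))
  null_values <- vapply(seq_len(n_perm), function(j) {
    pp <- permute_peripheral(peripheral, epochs, seed = child_seed(seed, j),
                             epoch_len_s = epoch_len_s)
    # non-convergence on a flat null objective is expected; best iterate is used
    suppressWarnings(engine$fit(prep(pp), seed = child_seed(seed, j))$coherence)
  }, numeric(1))
  p <- perm_p_value(sum(null_values >= obs$coherence), n_perm, p_method)
  out <- new_perm_null("coherence", obs$coherence, null_values, p, n_perm, seed,
                       significant = obs$coherence > sort(null_values)[ceiling(0.95 * n_perm)],
                       extra = list(solution = obs, spec = spec))
  out
}

#' Permutation significance of pattern recovery error
#'
#' For a simulated bundle and one interaction, measures the recovery error of
#' the estimated spatial pattern against the ground-truth topography and
#' builds its permutation null by shuffling peripheral epochs and re-running
#' the estimation. The p-value is the proportion of permuted errors smaller
#' than or equal to the observed error (recovery is deemed to have *failed*
#' when p > 0.05, i.e. the observed error is not reliably below chance
#' level). Random patterns in a high-dimensional channel space are nearly
#' orthogonal, so the null concentrates at high error values.
#'
#' @param bundle a [assemble_scenario()] result.
#' @param interaction interaction label (e.g. `"3:3"`, `"3:6"`,
#'   `"independent"`).
#' @param n_perm number of permutations (0 skips the null).
#' @param seed master seed.
#' @inheritParams coupling_significance
#' @return a `perm_null` with `observed` = recovery error, plus fields
#'   `coherence` and `fail`.
#' @export
rerror_significance <- function(bundle, interaction, n_perm = 199, seed = 1,
                                epochs = NULL, epoch_len_s = 1,
                                half_bw_hz = NULL,
                                p_method = c("add_one", "plain"),
                                segment_len_s = 1, overlap_frac = 0.5,
                                taper = "hann", gamma = 1e-4,
                                n_restarts = 10, tol = 1e-8, max_iter = 200) {
  p_method <- match.arg(p_method)
  stopifnot(inherits(bundle, "sim_bundle"))
  recipe <- parse_interaction(interaction)
  truth <- bundle$truth_patterns[[recipe$truth]]
  if (is.null(truth)) stop("no ground-truth pattern for interaction ", interaction)
  prep <- prep_peripheral_fun(recipe, half_bw_hz)
  f_target <- if (recipe$kind == "within") recipe$f else recipe$spec$f_r
  engine <- make_bin_engine(bundle$eeg, f_target, segment_len_s, overlap_frac,
                            taper, gamma, n_restarts, tol, max_iter)
  obs <- engine$fit(prep(bundle$peripheral), seed = child_seed(seed, 0))
  obs_err <- recovery_error(truth, obs$pattern_a)
  if (n_perm < 1) {
    return(new_perm_null("rerror", obs_err, numeric(0), NA_real_, 0L, seed,
                         significant = NA,
                         extra = list(coherence = obs$coherence, fail = NA,
                                      solution = obs)))
  }
  null_values <- vapply(seq_len(n_perm), function(j) {
    pp <- permute_peripheral(bundle$peripheral, epochs,
                             seed = child_seed(seed, j),
                             epoch_len_s = epoch_len_s)
    fit_j <- suppressWarnings(engine$fit(prep(pp), seed = child_seed(seed, j)))
    recovery_error(truth, fit_j$pattern_a)
  }, numeric(1))
  p <- perm_p_value(sum(null_values <= obs_err), n_perm, p_method)
  new_perm_null("rerror", obs_err, null_values, p, n_perm, seed,
                significant = p <= 0.05,
                extra = list(coherence = obs$coherence, fail = p > 0.05,
                             solution = obs))
}
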