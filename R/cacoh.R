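# Canonical coherence: real spatial filters maximizing coherence between two
# channel spaces at a frequency bin, plus the cross-frequency extension.

csd_at_bin <- function(cs, bin) {
  pa <- length(cs$labels_a); pb <- length(cs$labels_b)
  list(
    caa = matrix(cs$caa[, , bin], pa, pa),
    cbb = matrix(cs$cbb[, , bin], pb, pb),
    cab = matrix(cs$cab[, , bin], pa, pb)
  )
}

shrink_reg <- function(R, gamma) {
  P <- nrow(R)
  (1 - gamma) * R + gamma * (sum(diag(R)) / P) * diag(P)
}

#' Maximize canonical coherence at a frequency bin
#'
#' Finds real projection vectors `alpha` (space A) and `beta` (space B)
#' maximizing
#' `L = |alpha' C_AB beta|^2 / ((alpha' C_AA alpha)(beta' C_BB beta))`
#' at one frequency bin of a [estimate_cross_spectra()] result. The solver
#' alternates closed-form updates: with `(beta, phi)` fixed,
#' `alpha = Re(C_AA)^{-1} Re(C_AB e^{-j phi}) beta`; symmetrically for
#' `beta`; and `phi = arg(alpha' C_AB beta)` — a per-bin phase rotation
#' standing for the optimal delay of the projected pair. Each sweep is
#' non-decreasing in `L` (asserted), and the best of `n_restarts` random
#' initializations is kept, deterministically for a given `seed`.
#'
#' @param cs a `cross_spectra`.
#' @param bin_hz frequency of interest (nearest bin is used).
#' @param n_restarts random restarts (default 10).
#' @param tol relative objective-change convergence tolerance.
#' @param max_iter maximum alternating sweeps per restart.
#' @param gamma shrinkage regularization weight applied to `Re(C_AA)` and
#'   `Re(C_BB)` as `(1 - gamma) C + gamma (trace/P) I` (default `1e-4`;
#'   needed for stable inversion with dense electrode montages).
#' @param seed optional integer seed for the restart draws.
#' @return object of class `cacoh_solution`: `alpha`, `beta` (normalized to
#'   unit projected power `alpha' Re(C_AA) alpha = 1`), `phi`, `coherence`
#'   (`sqrt(max L)`, in `[0, 1]`), `coherence_sq`, `bin_hz` (bin center
#'   actually used), `pattern_a`, `pattern_b` (filters mapped through the
#'   real part of the within-space cross-spectrum, polarity such that the
#'   largest-magnitude entry of `pattern_a` is positive),
#'   `n_restarts_used`, `converged`.
#' @export
maximize_cacoh <- function(cs, bin_hz, n_restarts = 10, tol = 1e-8,
                           max_iter = 200, gamma = 1e-4, seed = NULL) {
  stopifnot(inherits(cs, "cross_spectra"))
  bin <- nearest_bin(cs$freqs, bin_hz)
  m <- csd_at_bin(cs, bin)
  core <- cacoh_core(m$caa, m$cbb, m$cab, n_restarts = n_restarts, tol = tol,
                     max_iter = max_iter, gamma = gamma, seed = seed)
  a <- core$alpha; b <- core$beta
  names(a) <- names(core$pattern_a) <- cs$labels_a
  names(b) <- names(core$pattern_b) <- cs$labels_b
  structure(
    list(alpha = a, beta = b, phi = core$phi,
         coherence = core$coherence, coherence_sq = core$coherence_sq,
         bin_hz = cs$freqs[bin], bin = bin,
         pattern_a = core$pattern_a, pattern_b = core$pattern_b,
         n_restarts_used = n_restarts, converged = core$converged),
    class = "cacoh_solution"
  )
}

# Core alternating optimizer on per-bin matrices; `chols` optionally carries
# precomputed regularized Cholesky factors (reused across permutation refits).
cacoh_core <- function(caa, cbb, cab, n_restarts = 10, tol = 1e-8,
                       max_iter = 200, gamma = 1e-4, seed = NULL,
                       chols = NULL) {
  Raa <- Re(caa); Rbb <- Re(cbb); Cab <- cab
  pa <- nrow(Raa); pb <- nrow(Rbb)
  if (is.null(chols)) chols <- cacoh_chols(Raa, Rbb, gamma)
  Raa_r <- chols$Raa_r; Rbb_r <- chols$Rbb_r
  Raa_ch <- chols$Raa_ch; Rbb_ch <- chols$Rbb_ch

  quad <- function(R, v) drop(crossprod(v, R %*% v))
  objective <- function(a, b) {
    Mod(drop(crossprod(a, Cab %*% b)))^2 / (quad(Raa_r, a) * quad(Rbb_r, b))
  }

  run_restart <- function(a, b) {
    a <- a / sqrt(quad(Raa_r, a)); b <- b / sqrt(quad(Rbb_r, b))
    obj <- objective(a, b)
    conv <- FALSE
    for (it in seq_len(max_iter)) {
      phi <- Arg(drop(crossprod(a, Cab %*% b)))
      D <- Re(Cab * exp(-1i * phi))
      an <- backsolve(Raa_ch, forwardsolve(t(Raa_ch), D %*% b))
      if (sqrt(sum(an^2)) < 1e-300) { obj <- 0; conv <- TRUE; break }
      a <- drop(an); a <- a / sqrt(quad(Raa_r, a))
      bn <- backsolve(Rbb_ch, forwardsolve(t(Rbb_ch), crossprod(D, a)))
      if (sqrt(sum(bn^2)) < 1e-300) { obj <- 0; conv <- TRUE; break }
      b <- drop(bn); b <- b / sqrt(quad(Rbb_r, b))
      new_obj <- objective(a, b)
      if (new_obj < obj - 1e-10 * max(1, obj)) {
        stop("internal error: alternating objective decreased")
      }
      if (abs(new_obj - obj) <= tol * max(obj, .Machine$double.eps)) {
        obj <- new_obj; conv <- TRUE; break
      }
      obj <- new_obj
    }
    list(a = a, b = b, obj = obj, converged = conv)
  }

  best <- NULL
  with_seed(seed, {
    for (rs in seq_len(n_restarts)) {
      a0 <- stats::rnorm(pa); b0 <- stats::rnorm(pb)
      res <- run_restart(a0, b0)
      if (is.null(best) || res$obj > best$obj) best <- res
    }
  })
  if (!best$converged) {
    warning("maximize_cacoh did not converge in max_iter sweeps; best iterate returned")
  }

  a <- best$a; b <- best$b
  # report on the unregularized scale
  a <- a / sqrt(max(quad(Raa, a), .Machine$double.xmin))
  b <- b / sqrt(max(quad(Rbb, b), .Machine$double.xmin))
  num <- drop(crossprod(a, Cab %*% b))
  coh2 <- min(1, max(0, Mod(num)^2 / (quad(Raa, a) * quad(Rbb, b))))
  phi <- Arg(num)
  pat_a <- drop(Raa %*% a)
  pat_b <- drop(Rbb %*% b)
  if (pat_a[which.max(abs(pat_a))] < 0) {
    a <- -a; pat_a <- -pat_a; phi <- wrap_phase(phi + pi)
  }
  list(alpha = a, beta = b, phi = phi,
       coherence = sqrt(coh2), coherence_sq = coh2,
       pattern_a = pat_a, pattern_b = pat_b, converged = best$converged)
}

cacoh_chols <- function(Raa, Rbb, gamma) {
  Raa_r <- shrink_reg(Raa, gamma); Rbb_r <- shrink_reg(Rbb, gamma)
  if (kappa(Raa_r, exact = FALSE) > 1e12 || kappa(Rbb_r, exact = FALSE) > 1e12) {
    stop("within-space cross-spectrum is numerically singular after regularization")
  }
  list(Raa_r = Raa_r, Rbb_r = Rbb_r, Raa_ch = chol(Raa_r), Rbb_ch = chol(Rbb_r))
}

#' @export
print.cacoh_solution <- function(x, ...) {
  cat(sprintf("<cacoh_solution> coherence %.4f at %.3g Hz (phi = %.3f rad%s)\n",
              x$coherence, x$bin_hz, x$phi,
              if (x$converged) "" else ", NOT converged"))
  invisible(x)
}

#' Spatial pattern from a spatial filter
#'
#' Maps a filter to its forward-model-like topography by multiplying it with
#' the real part of the within-space cross-spectrum at the selected bin:
#' `p = Re(C_AA) alpha`, with polarity fixed so the largest-magnitude entry
#' is positive. The pattern — not the filter — is the interpretable source
#' projection. No normalization is applied (comparison metrics normalize).
#'
#' @param caa_bin Hermitian (or real symmetric) matrix at one bin.
#' @param alpha real filter vector.
#' @return real pattern vector.
#' @export
filters_to_pattern <- function(caa_bin, alpha) {
  if (nrow(caa_bin) != length(alpha)) stop("dimension mismatch between caa_bin and alpha")
  p <- drop(Re(caa_bin) %*% alpha)
  if (p[which.max(abs(p))] < 0) p <- -p
  names(p) <- rownames(caa_bin) %||% names(alpha)
  p
}

new_cacoh_fit <- function(solution, spec, method, cs, call, params) {
  structure(
    list(solution = solution, spec = spec, method = method,
         coherence = solution$coherence,
         labels = cs$labels_a, fs = cs$fs, n_segments = cs$n_segments,
         null_percentile_95 = NULL, significant = NULL,
         call = call, params = params),
    class = "cacoh_fit"
  )
}

#' Within-frequency cortico-kinematic coherence (CKC)
#'
#' Fits caCOH between a multichannel recording (space A, e.g. EEG) and a
#' univariate peripheral signal (space B, e.g. the first principal component
#' of an accelerometer) at one frequency: cross-spectra are estimated by
#' Welch averaging and the coherence of the projected pair is maximized at
#' the bin nearest `f`. With a univariate peripheral the method identifies
#' spatial filters for the multichannel space only (`beta` is a scalar).
#'
#' @param eeg multichannel [ts_set()].
#' @param peripheral univariate [ts_set()], time-aligned with `eeg`.
#' @param f frequency of interest in Hz.
#' @param segment_len_s,overlap_frac,taper Welch parameters, see
#'   [estimate_cross_spectra()].
#' @param n_restarts,tol,max_iter,gamma,seed optimizer parameters, see
#'   [maximize_cacoh()].
#' @param freq_range optional `c(lo, hi)` in Hz: restrict cross-spectral
#'   estimation to these bins (saves time when only one bin is needed).
#' @return object of class `cacoh_fit` with the `cacoh_solution`, the
#'   `coupling_spec`, channel labels and fit parameters. Methods: `print`,
#'   `summary`, `coef` (filters), `predict` (project new data onto the
#'   filter), `plot` (pattern topography as a bar chart).
#' @seealso [xf_ckc()] for cross-frequency coupling, [coupling_significance()]
#'   for a permutation test of the fitted coherence.
#' @export
ckc <- function(eeg, peripheral, f, segment_len_s = 1, overlap_frac = 0.5,
                taper = "hann", n_restarts = 10, tol = 1e-8, max_iter = 200,
                gamma = 1e-4, seed = NULL, freq_range = NULL) {
  assert_univariate(peripheral, "peripheral")
  cs <- estimate_cross_spectra(eeg, peripheral, segment_len_s, overlap_frac,
                               taper, freq_range)
  sol <- maximize_cacoh(cs, f, n_restarts, tol, max_iter, gamma, seed)
  new_cacoh_fit(sol, coupling_spec(f, r = 1), "ckc", cs, match.call(),
                list(segment_len_s = segment_len_s, overlap_frac = overlap_frac,
                     taper = taper, n_restarts = n_restarts, tol = tol,
                     max_iter = max_iter, gamma = gamma, seed = seed))
}

#' Cross-frequency cortico-kinematic coherence (XF-CKC)
#'
#' Fits the cross-frequency extension of caCOH for an `f_q : f_r`
#' interaction with `f_r = r * f_q`: the peripheral signal is band-filtered
#' around the slow frequency `f_q`, frequency-warped by the integer factor
#' `r` (amplitude envelope preserved, instantaneous phase multiplied by `r`),
#' and caCOH is then applied at the fast bin `f_r`. With `r = 1` the warp is
#' the identity and the fit equals [ckc()] at `f_q`.
#'
#' @inheritParams ckc
#' @param spec a [coupling_spec()] with `q = 1`.
#' @param half_bw_hz half bandwidth of the peripheral filter at `f_q`
#'   (default `f_q / 3`).
#' @return a `cacoh_fit` (see [ckc()]) whose solution lives at the fast bin.
#' @export
xf_ckc <- function(eeg, peripheral, spec, half_bw_hz = spec$f_q / 3,
                   segment_len_s = 1, overlap_frac = 0.5, taper = "hann",
                   n_restarts = 10, tol = 1e-8, max_iter = 200,
                   gamma = 1e-4, seed = NULL, freq_range = NULL) {
  stopifnot(inherits(spec, "coupling_spec"))
  if (spec$q != 1) stop("xf_ckc requires q = 1 (integer-harmonic interactions)")
  assert_univariate(peripheral, "peripheral")
  warped <- if (spec$r == 1) peripheral else {
    warp_frequency(peripheral, spec$r, spec$f_q, half_bw_hz)
  }
  cs <- estimate_cross_spectra(eeg, warped, segment_len_s, overlap_frac,
                               taper, freq_range)
  sol <- maximize_cacoh(cs, spec$f_r, n_restarts, tol, max_iter, gamma, seed)
  new_cacoh_fit(sol, spec, "xf_ckc", cs, match.call(),
                list(half_bw_hz = half_bw_hz, segment_len_s = segment_len_s,
                     overlap_frac = overlap_frac, taper = taper,
                     n_restarts = n_restarts, tol = tol, max_iter = max_iter,
                     gamma = gamma, seed = seed))
}

#' Project multichannel data onto a spatial filter
#'
#' Computes the filter output `alpha' x(t)` as a univariate time series and
#' band-filters it around a frequency of interest — the source-level time
#' course used for projected-source synchronization analyses.
#'
#' @param eeg multichannel [ts_set()].
#' @param alpha real filter vector (length = channels), or a `cacoh_fit`
#'   whose `alpha` is used.
#' @param band_center,half_bw band for the output filter (Hz). `half_bw`
#'   defaults to `band_center / 3`.
#' @return univariate `ts_set`.
#' @export
project <- function(eeg, alpha, band_center, half_bw = band_center / 3) {
  if (inherits(alpha, "cacoh_fit")) alpha <- alpha$solution$alpha
  if (length(alpha) != n_channels(eeg)) stop("filter length must equal channel count")
  v <- drop(crossprod(matrix(alpha), eeg$data))
  band_filter(ts_set(matrix(v, 1), eeg$fs, "projection", eeg$epochs),
              band_center, half_bw)
}

#' @export
print.cacoh_fit <- function(x, ...) {
  cat(sprintf("<cacoh_fit> %s %g:%g Hz\n", x$method, x$spec$f_q, x$spec$f_r))
  cat(sprintf("  coherence %.4f at bin %.3g Hz (%d Welch segments)\n",
              x$coherence, x$solution$bin_hz, x$n_segments))
  if (!is.null(x$significant)) {
    cat(sprintf("  permutation null 95th pct %.4f -> %s\n",
                x$null_percentile_95,
                if (x$significant) "significant" else "not significant"))
  }
  invisible(x)
}

#' @export
summary.cacoh_fit <- function(object, n_top = 5, ...) {
  x <- object
  print(x)
  cat(sprintf("  phi = %.3f rad, converged: %s, restarts: %d\n",
              x$solution$phi, x$solution$converged, x$solution$n_restarts_used))
  p <- x$solution$pattern_a
  top <- order(abs(p), decreasing = TRUE)[seq_len(min(n_top, length(p)))]
  cat("  strongest pattern channels:\n")
  for (i in top) cat(sprintf("    %-8s %+.4g\n", names(p)[i], p[i]))
  invisible(x)
}

#' @export
coef.cacoh_fit <- function(object, ...) {
  list(alpha = object$solution$alpha, beta = object$solution$beta)
}

#' @export
#' @rdname ckc
#' @param object,newdata for `predict`: a fitted object and a multichannel
#'   `ts_set` to project onto the fitted EEG filter at the fitted bin.
#' @param ... unused.
predict.cacoh_fit <- function(object, newdata, ...) {
  project(newdata, object$solution$alpha, object$solution$bin_hz)
}

#' @export
plot.cacoh_fit <- function(x, ...) {
  p <- x$solution$pattern_a
  graphics::barplot(p, names.arg = names(p), las = 2, cex.names = 0.6,
                    main = sprintf("%s %g:%g Hz pattern (coherence %.3f)",
                                   x$method, x$spec$f_q, x$spec$f_r, x$coherence),
                    ylab = "pattern weight", ...)
  invisible(x)
}
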