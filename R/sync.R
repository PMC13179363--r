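# n:m phase synchronization between univariate signals.

# Band-filter a signal around `center_hz` unless it is already narrow-band at
# that center (band attribute set by band_filter/warp_frequency): refiltering
# an already isolated band is redundant and only perturbs the instantaneous
# phase by reshaping in-band spectral weights.
isolate_band <- function(x, center_hz, half_bw_hz) {
  ba <- attr(x, "band")
  if (!is.null(ba) && abs(ba[["center"]] - center_hz) <= 0.25 * center_hz) {
    return(x)
  }
  band_filter(x, center_hz, half_bw_hz)
}

#' Frequency-ratio contract of a cross-frequency interaction
#'
#' Describes an `f_q : f_r` interaction with integer cycle counts `q` and `r`
#' satisfying `q * f_r = r * f_q` (approximately). The public analysis surface
#' of this package fixes `q = 1` (a faster cortical rhythm at an integer
#' multiple of a slower peripheral one); the synchronization core accepts
#' general `(q, r)`.
#'
#' @param f_q slow (peripheral) frequency in Hz.
#' @param r positive integer: fast cycles per slow cycle.
#' @param f_r fast frequency in Hz; default `r * f_q`.
#' @param q positive integer, default 1.
#' @param tol_hz tolerance for checking `q * f_r = r * f_q`.
#' @return object of class `coupling_spec`.
#' @export
#' @examples
#' coupling_spec(3, r = 2) # the 3:6 Hz interaction
coupling_spec <- function(f_q, r, f_r = r * f_q, q = 1, tol_hz = 0.5) {
  stopifnot(q >= 1, q == round(q), r >= 1, r == round(r), f_q > 0, f_r > 0)
  if (abs(q * f_r - r * f_q) > tol_hz) {
    stop(sprintf("q*f_r (%.3g) and r*f_q (%.3g) differ by more than %g Hz",
                 q * f_r, r * f_q, tol_hz))
  }
  structure(list(f_q = f_q, f_r = f_r, q = as.integer(q), r = as.integer(r)),
            class = "coupling_spec")
}

#' @export
print.coupling_spec <- function(x, ...) {
  cat(sprintf("<coupling_spec> %g:%g Hz (q = %d, r = %d)\n", x$f_q, x$f_r, x$q, x$r))
  invisible(x)
}

#' Generalized n:m phase difference
#'
#' `psi(t) = q * phi_r(t) - r * phi_q(t)`, wrapped to `(-pi, pi]`. A
#' concentrated (non-uniform) distribution of `psi` indicates n:m phase
#' synchronization.
#'
#' @param phi_q,phi_r instantaneous phase vectors (radians), equal length.
#' @param q,r positive integers defining the frequency ratio.
#' @return wrapped phase-difference vector.
#' @export
generalized_phase_difference <- function(phi_q, phi_r, q, r) {
  if (length(phi_q) != length(phi_r)) stop("phase vectors must have equal length")
  wrap_phase(q * phi_r - r * phi_q)
}

#' n:m phase synchronization index
#'
#' Modulus of the circular mean of `exp(j psi)` where `psi` is the
#' generalized phase difference: 0 means a uniform phase difference (no
#' synchronization), 1 perfect phase locking.
#'
#' @inheritParams generalized_phase_difference
#' @param spec optional [coupling_spec()] recorded in the result.
#' @return object of class `sync_result`: fields `k_sync`, `n_used`, `spec`.
#' @export
sync_index <- function(phi_q, phi_r, q = 1, r = 1, spec = NULL) {
  if (!length(phi_q)) stop("empty input")
  if (length(phi_q) != length(phi_r)) stop("phase vectors must have equal length")
  if (length(phi_q) < 100) warning("fewer than 100 samples: k_sync estimate is noisy")
  psi <- generalized_phase_difference(phi_q, phi_r, q, r)
  k <- Mod(mean(exp(1i * psi)))
  structure(list(k_sync = k, n_used = length(psi),
                 spec = spec %||% list(q = q, r = r)),
            class = "sync_result")
}

#' @export
print.sync_result <- function(x, ...) {
  cat(sprintf("<sync_result> k_sync = %.4f (N = %d)\n", x$k_sync, x$n_used))
  invisible(x)
}

#' Cross-frequency phase synchronization between two signals
#'
#' Band-filters `x` around the slow frequency `f_q` and `y` around the fast
#' frequency `f_r`, extracts instantaneous phases by the Hilbert transform,
#' drops `edge_s` seconds at each end, and returns the n:m synchronization
#' index with the spec's `(q, r)`. Peripheral self-coupling (e.g. 3:6 within
#' an accelerometer component) is this function applied to `(x, x)`.
#'
#' @param x,y univariate [ts_set()] objects with equal sampling rates.
#' @param spec a [coupling_spec()].
#' @param half_bw_hz half bandwidth at the slow frequency; the fast band uses
#'   `half_bw_hz * f_r / f_q` so relative bandwidth is constant. Default
#'   `f_q / 3`.
#' @param edge_s seconds discarded at each end after filtering (default 2).
#' @return a `sync_result`.
#' @export
cross_freq_sync <- function(x, y, spec, half_bw_hz = spec$f_q / 3, edge_s = 2) {
  assert_univariate(x, "x"); assert_univariate(y, "y")
  if (x$fs != y$fs) stop("alignment error: sampling rates differ")
  stopifnot(inherits(spec, "coupling_spec"))
  phx <- analytic_signal(isolate_band(x, spec$f_q, half_bw_hz))$phase
  phy <- analytic_signal(isolate_band(y, spec$f_r,
                                      half_bw_hz * spec$f_r / spec$f_q))$phase
  ne <- round(edge_s * x$fs)
  keep <- seq.int(ne + 1, length(phx) - ne)
  if (length(keep) < 2) stop("signal too short after edge exclusion")
  sync_index(phx[keep], phy[keep], spec$q, spec$r, spec = spec)
}
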