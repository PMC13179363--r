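# Hilbert analytic signal and integer frequency warping.

# FFT-based analytic signal of a numeric vector:
# s = x + j * Hilbert{x}; negative frequencies zeroed, positives doubled.
hilbert_analytic <- function(v) {
  n <- length(v)
  X <- stats::fft(v)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

#' Analytic representation of a narrow-band signal
#'
#' Computes the analytic signal `s(t) = x(t) + j H{x(t)}` via the FFT and
#' returns its instantaneous amplitude `a(t) = |s(t)|` and phase
#' `phi(t) = arg(s(t))` (wrapped to `(-pi, pi]`; an unwrapped copy is kept for
#' phase arithmetic). The caller is responsible for the input being
#' narrow-band; a warning is given when the spectrum looks broadband.
#' A zero input yields zero amplitude and (by convention) zero phase.
#'
#' @param x univariate [ts_set()].
#' @param flatness_warn spectral-flatness threshold above which a broadband
#'   warning is given (geometric/arithmetic mean of the periodogram).
#' @return object of class `analytic_series` with fields `amplitude`, `phase`,
#'   `phase_unwrapped`, `fs`.
#' @export
analytic_signal <- function(x, flatness_warn = 0.5) {
  assert_univariate(x, "analytic_signal input")
  v <- as.numeric(x$data[1, ])
  if (all(v == 0)) {
    n <- length(v)
    return(structure(list(amplitude = numeric(n), phase = numeric(n),
                          phase_unwrapped = numeric(n), fs = x$fs),
                     class = "analytic_series"))
  }
  # spectral flatness from a segment-averaged periodogram (averaging tames
  # the exponential scatter of single-periodogram bins)
  nseg <- 8L
  L <- floor(length(v) / nseg)
  pg <- Reduce(`+`, lapply(seq_len(nseg), function(k) {
    seg <- v[((k - 1) * L + 1):(k * L)]
    Mod(stats::fft(seg - mean(seg)))[2:floor(L / 2)]^2
  }))
  pg <- pg[pg > 0]
  flat <- exp(mean(log(pg))) / mean(pg)
  if (is.finite(flat) && flat > flatness_warn) {
    warning(sprintf("input looks broadband (spectral flatness %.2f); analytic phase may be meaningless", flat))
  }
  s <- hilbert_analytic(v)
  phase <- Arg(s)
  structure(
    list(amplitude = Mod(s), phase = phase,
         phase_unwrapped = as.numeric(signal::unwrap(phase)), fs = x$fs),
    class = "analytic_series"
  )
}

#' @export
print.analytic_series <- function(x, ...) {
  cat(sprintf("<analytic_series> %d samples @ %g Hz, mean amplitude %.4g\n",
              length(x$amplitude), x$fs, mean(x$amplitude)))
  invisible(x)
}

#' Integer frequency warping of a narrow-band signal
#'
#' Scales the dominant frequency of a univariate signal by an integer factor
#' `r` while preserving its amplitude envelope: the signal is band-filtered
#' around `center_hz` (skipped when the input is already isolated at that
#' band, to avoid redundant in-band reshaping), its analytic amplitude `a(t)`
#' and unwrapped phase `phi(t)` are extracted, and the output is
#' `Re{a(t) exp(j r phi(t))}`. With `r = 1` this reproduces the band-filtered
#' input exactly.
#'
#' @param x univariate [ts_set()].
#' @param r positive integer warping factor.
#' @param center_hz center of the band of interest (Hz).
#' @param half_bw_hz half bandwidth of the filter (Hz); defaults to
#'   `center_hz / 3` (1 Hz at 3 Hz, scaled proportionally).
#' @return univariate `ts_set` of the same length and sampling rate, dominant
#'   spectral peak at `r * center_hz`; attribute `edge_s = 2` flags edge
#'   samples to exclude from phase-based indices.
#' @export
warp_frequency <- function(x, r, center_hz, half_bw_hz = center_hz / 3) {
  assert_univariate(x, "warp_frequency input")
  if (r < 1 || r != round(r)) stop("r must be a positive integer")
  if (r * (center_hz + half_bw_hz) >= x$fs / 2) {
    stop("aliasing: r * (center_hz + half_bw_hz) reaches the Nyquist frequency")
  }
  xf <- isolate_band(x, center_hz, half_bw_hz)
  an <- analytic_signal(xf)
  out <- Re(an$amplitude * exp(1i * r * an$phase_unwrapped))
  y <- ts_set(matrix(out, 1), x$fs, x$labels, x$epochs)
  attr(y, "edge_s") <- 2
  attr(y, "band") <- c(center = r * center_hz, half_bw = r * half_bw_hz)
  y
}
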