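# Welch cross-spectral estimation and zero-phase narrow-band filtering.

#' Zero-phase Butterworth band-pass filter
#'
#' Filters every channel with a 4th-order Butterworth band-pass (two poles per
#' band edge) applied forward and backward (zero phase). The signal is
#' reflect-padded by three filter time constants before filtering to suppress
#' edge transients; downstream phase-based analyses additionally discard 2 s
#' at each end (recorded in the `edge_s` attribute).
#'
#' @param x a [ts_set()].
#' @param center_hz passband center in Hz.
#' @param half_bw_hz half bandwidth in Hz; passband is
#'   `[center - half_bw, center + half_bw]`.
#' @return a `ts_set` of the same shape with attribute `edge_s = 2` and
#'   attribute `band = c(center_hz, half_bw_hz)`.
#' @export
band_filter <- function(x, center_hz, half_bw_hz) {
  stopifnot(inherits(x, "ts_set"))
  lo <- center_hz - half_bw_hz
  hi <- center_hz + half_bw_hz
  if (lo <= 0) stop("band edge at or below 0 Hz")
  if (hi >= x$fs / 2) stop("band edge at or above Nyquist frequency")
  bf <- signal::butter(2, c(lo, hi) / (x$fs / 2), type = "pass")
  n <- n_samples(x)
  pad <- min(n - 1, round(3 * x$fs / half_bw_hz))
  out <- x$data
  for (ch in seq_len(nrow(out))) {
    v <- out[ch, ]
    # odd reflection keeps the padded signal continuous in value and slope
    head_pad <- 2 * v[1] - v[seq(pad + 1, 2)]
    tail_pad <- 2 * v[n] - v[seq(n - 1, n - pad)]
    vf <- signal::filtfilt(bf, c(head_pad, v, tail_pad))
    out[ch, ] <- vf[(pad + 1):(pad + n)]
  }
  y <- ts_set(out, x$fs, x$labels, x$epochs)
  attr(y, "edge_s") <- 2
  attr(y, "band") <- c(center = center_hz, half_bw = half_bw_hz)
  y
}

#' Index of the frequency bin nearest a target
#'
#' Ties are broken toward the lower frequency. If the nearest bin is farther
#' away than the bin spacing, a warning is issued (target falls between
#' frequency grids).
#'
#' @param freqs numeric vector of bin centers (Hz).
#' @param target_hz target frequency (Hz).
#' @return integer index into `freqs`.
#' @export
nearest_bin <- function(freqs, target_hz) {
  stopifnot(length(freqs) >= 1)
  idx <- which.min(abs(freqs - target_hz)) # which.min takes the first (lower) tie
  spacing <- if (length(freqs) > 1) min(diff(sort(freqs))) else Inf
  if (abs(freqs[idx] - target_hz) > spacing) {
    warning(sprintf("target %.3g Hz is %.3g Hz from the nearest bin (spacing %.3g)",
                    target_hz, abs(freqs[idx] - target_hz), spacing))
  }
  idx
}

taper_window <- function(name, L) {
  switch(tolower(name),
    hann = ,
    hanning = 0.5 * (1 - cos(2 * pi * seq(0, L - 1) / (L - 1))),
    rect = ,
    boxcar = rep(1, L),
    stop("unknown taper: ", name)
  )
}

# Per-segment tapered FFTs of a channels-by-samples matrix.
# Returns list(z = array [n_bins, P, K], freqs, scale). Forward DFT with
# e^{-j 2 pi f t} convention (R's fft), per-segment mean removal.
segment_spectra <- function(data, fs, seg_len, step, window) {
  P <- nrow(data); n <- ncol(data)
  starts <- seq(1, n - seg_len + 1, by = step)
  K <- length(starts)
  w <- taper_window(window, seg_len)
  n_bins <- floor(seg_len / 2) + 1
  z <- array(0i, dim = c(n_bins, P, K))
  scale <- 1 / sqrt(sum(w^2) * fs)
  for (k in seq_len(K)) {
    seg <- data[, starts[k]:(starts[k] + seg_len - 1), drop = FALSE]
    seg <- seg - rowMeans(seg)
    seg <- sweep(seg, 2, w, `*`)
    zz <- stats::mvfft(t(seg)) # seg_len x P
    z[, , k] <- zz[seq_len(n_bins), , drop = FALSE] * scale
  }
  list(z = z, freqs = (seq_len(n_bins) - 1) * fs / seg_len, n_segments = K)
}

#' Welch-averaged cross-spectral matrices of two channel spaces
#'
#' Estimates per-frequency-bin cross-spectral matrices for two time-aligned
#' multichannel signal blocks A and B: within-space blocks `caa`, `cbb`
#' (Hermitian) and the between-space block `cab`. Segments are demeaned,
#' tapered, Fourier-transformed and the outer products averaged. The phase
#' convention is the forward DFT `e^{-j 2 pi f t}`, so
#' `cab[p, q] = E[A_p(f) * Conj(B_q(f))]`: a signal B lagging A at frequency f
#' gives a positive `Arg(cab)`.
#'
#' @param a,b [ts_set()] objects with the same sampling rate and length.
#' @param segment_len_s Welch segment length in seconds (default 1 s; at the
#'   default the bin spacing is 1 Hz, putting 3, 6 and 9 Hz on exact bins).
#' @param overlap_frac fractional segment overlap in `[0, 1)` (default 0.5).
#' @param taper window name, `"hann"` (default) or `"rect"`.
#' @param freq_range optional `c(lo, hi)` in Hz restricting the stored bins.
#' @return object of class `cross_spectra` with fields `freqs`, `caa`
#'   (`P_A x P_A x n_bins`), `cbb`, `cab` (`P_A x P_B x n_bins`),
#'   `n_segments`, `fs`, `labels_a`, `labels_b`, `df`.
#' @export
estimate_cross_spectra <- function(a, b, segment_len_s = 1, overlap_frac = 0.5,
                                   taper = "hann", freq_range = NULL) {
  stopifnot(inherits(a, "ts_set"), inherits(b, "ts_set"))
  if (a$fs != b$fs) stop("alignment error: sampling rates differ")
  if (n_samples(a) != n_samples(b)) stop("alignment error: signal lengths differ")
  if (overlap_frac < 0 || overlap_frac >= 1) stop("overlap_frac must be in [0, 1)")
  L <- round(segment_len_s * a$fs)
  if (L < 16) stop("segment too short: need segment_len_s * fs >= 16 samples")
  step <- max(1L, round(L * (1 - overlap_frac)))
  if (n_samples(a) < L + step) stop("insufficient data: fewer than 2 complete segments")

  pa <- n_channels(a); pb <- n_channels(b)
  ss <- segment_spectra(rbind(a$data, b$data), a$fs, L, step, taper)
  keep <- seq_along(ss$freqs)
  if (!is.null(freq_range)) {
    keep <- which(ss$freqs >= freq_range[1] & ss$freqs <= freq_range[2])
    if (!length(keep)) stop("freq_range contains no bins")
  }
  nb <- length(keep)
  caa <- array(0i, c(pa, pa, nb))
  cbb <- array(0i, c(pb, pb, nb))
  cab <- array(0i, c(pa, pb, nb))
  K <- ss$n_segments
  for (i in seq_len(nb)) {
    zf <- ss$z[keep[i], , , drop = TRUE]           # P x K (or vector if P==1)
    if (is.null(dim(zf))) zf <- matrix(zf, nrow = pa + pb)
    za <- zf[seq_len(pa), , drop = FALSE]
    zb <- zf[pa + seq_len(pb), , drop = FALSE]
    caa[, , i] <- (za %*% Conj(t(za))) / K
    cbb[, , i] <- (zb %*% Conj(t(zb))) / K
    cab[, , i] <- (za %*% Conj(t(zb))) / K
  }
  structure(
    list(freqs = ss$freqs[keep], caa = caa, cbb = cbb, cab = cab,
         n_segments = K, fs = a$fs, labels_a = a$labels, labels_b = b$labels,
         df = a$fs / L,
         params = list(segment_len_s = segment_len_s,
                       overlap_frac = overlap_frac, taper = taper)),
    class = "cross_spectra"
  )
}

#' @export
print.cross_spectra <- function(x, ...) {
  cat(sprintf(
    "<cross_spectra> %d x %d channels, %d bins (%.3g-%.3g Hz, df = %.3g), %d segments\n",
    length(x$labels_a), length(x$labels_b), length(x$freqs),
    min(x$freqs), max(x$freqs), x$df, x$n_segments
  ))
  invisible(x)
}

#' Magnitude-squared coherence between single channels of a cross_spectra
#'
#' Convenience accessor: `|cab|^2 / (caa * cbb)` for one channel pair across
#' all bins.
#' @param cs a `cross_spectra`.
#' @param i,j channel indices into spaces A and B.
#' @return numeric vector over bins.
#' @export
msc <- function(cs, i = 1, j = 1) {
  num <- Mod(cs$cab[i, j, ])^2
  den <- Re(cs$caa[i, i, ]) * Re(cs$cbb[j, j, ])
  out <- num / den
  out[den == 0] <- NA_real_
  out
}

# Joint [[caa, cab], [cab^H, cbb]] matrix at one bin (for PSD checks).
joint_csd <- function(cs, bin) {
  ca <- cs$caa[, , bin]; cb <- cs$cbb[, , bin]; cab <- cs$cab[, , bin]
  pa <- length(cs$labels_a); pb <- length(cs$labels_b)
  ca <- matrix(ca, pa, pa); cb <- matrix(cb, pb, pb); cab <- matrix(cab, pa, pb)
  rbind(cbind(ca, cab), cbind(Conj(t(cab)), cb))
}
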