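# Multichannel time-series container used throughout the package.

#' Multichannel time-series set
#'
#' Lightweight container for a block of synchronously sampled signals:
#' a channels-by-samples matrix, a sampling rate, channel labels, and an
#' optional list of half-open epoch intervals (in samples, 0-based
#' `[start, end)`), e.g. task blocks used for trial permutation.
#'
#' @param data numeric matrix, channels in rows, samples in columns. A plain
#'   vector is treated as a single channel.
#' @param fs sampling rate in Hz (positive scalar).
#' @param labels character vector of channel names; defaults to `"ch1"`, ...
#' @param epochs optional list of length-2 integer vectors `c(start, end)`,
#'   0-based half-open, sorted and non-overlapping, within `[0, n_samples)`.
#'
#' @return An object of class `ts_set` with fields `data`, `fs`, `labels`,
#'   `epochs`.
#' @export
#' @examples
#' x <- ts_set(matrix(rnorm(2 * 100), 2), fs = 100)
#' n_channels(x); n_samples(x)
ts_set <- function(data, fs, labels = NULL, epochs = NULL) {
  if (is.vector(data) && is.numeric(data)) data <- matrix(data, nrow = 1)
  stopifnot(is.matrix(data), is.numeric(data))
  if (ncol(data) < 2) stop("ts_set needs at least 2 samples")
  if (!is.numeric(fs) || length(fs) != 1 || fs <= 0) stop("fs must be a positive scalar")
  if (is.null(labels)) labels <- paste0("ch", seq_len(nrow(data)))
  if (length(labels) != nrow(data)) stop("labels length must equal number of channels")
  if (!is.null(epochs)) validate_epochs(epochs, ncol(data))
  structure(
    list(data = data, fs = fs, labels = as.character(labels), epochs = epochs),
    class = "ts_set"
  )
}

validate_epochs <- function(epochs, n) {
  stopifnot(is.list(epochs))
  last_end <- 0
  for (e in epochs) {
    if (length(e) != 2 || e[1] >= e[2]) stop("each epoch must be c(start, end) with start < end")
    if (e[1] < last_end) stop("epochs must be sorted and non-overlapping")
    if (e[1] < 0 || e[2] > n) stop("epochs must lie within [0, n_samples)")
    last_end <- e[2]
  }
  invisible(TRUE)
}

#' @rdname ts_set
#' @param x a `ts_set`.
#' @export
n_channels <- function(x) nrow(x$data)

#' @rdname ts_set
#' @export
n_samples <- function(x) ncol(x$data)

#' @export
print.ts_set <- function(x, ...) {
  cat(sprintf(
    "<ts_set> %d channel%s x %d samples @ %g Hz (%.1f s)\n",
    n_channels(x), if (n_channels(x) == 1) "" else "s",
    n_samples(x), x$fs, n_samples(x) / x$fs
  ))
  if (!is.null(x$epochs)) cat(sprintf("  epochs: %d\n", length(x$epochs)))
  cat("  labels:", paste(utils::head(x$labels, 8), collapse = ", "),
      if (n_channels(x) > 8) "..." else "", "\n")
  invisible(x)
}

#' Extract one channel as a univariate ts_set
#' @param x a `ts_set`.
#' @param channel channel index or label.
#' @return a single-channel `ts_set`.
#' @export
pick_channel <- function(x, channel) {
  if (is.character(channel)) channel <- match(channel, x$labels)
  stopifnot(!is.na(channel), channel >= 1, channel <= n_channels(x))
  ts_set(x$data[channel, , drop = FALSE], x$fs, x$labels[channel], x$epochs)
}

assert_univariate <- function(x, what = "input") {
  if (!inherits(x, "ts_set")) stop(what, " must be a ts_set")
  if (n_channels(x) != 1) stop(what, " must be univariate (single channel)")
  invisible(TRUE)
}

#' Default 1-second epoching of a signal
#'
#' Cuts `[0, n)` into consecutive `len_s`-second epochs (remainder samples at
#' the end are left out of every epoch).
#' @param x a `ts_set`.
#' @param len_s epoch length in seconds.
#' @return list of `c(start, end)` 0-based half-open intervals.
#' @export
default_epochs <- function(x, len_s = 1) {
  L <- round(len_s * x$fs)
  k <- floor(n_samples(x) / L)
  if (k < 1) stop("signal shorter than one epoch")
  lapply(seq_len(k) - 1, function(i) c(i * L, (i + 1) * L))
}
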