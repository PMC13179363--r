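# Readers and writers: delimited text + JSON sidecar, EDF, pattern tables.

#' Write / read a time-series set as TSV + JSON sidecar
#'
#' The TSV holds one row per channel (tab-separated samples, no header); the
#' JSON sidecar (`<path>.json`) records `fs`, `labels` and any epochs. The
#' round-trip is exact to full double precision.
#'
#' @param x a [ts_set()].
#' @param path TSV file path (sidecar written next to it).
#' @return `write_ts_tsv` returns `path` invisibly; `read_ts_tsv` a
#'   `ts_set`.
#' @export
write_ts_tsv <- function(x, path) {
  stopifnot(inherits(x, "ts_set"))
  utils::write.table(format(x$data, digits = 17, trim = TRUE, scientific = TRUE),
                     path, sep = "\t", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  meta <- list(fs = x$fs, labels = x$labels)
  if (!is.null(x$epochs)) meta$epochs <- x$epochs
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_ts_tsv
#' @export
read_ts_tsv <- function(path) {
  sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar)) stop("missing JSON sidecar: ", sidecar)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  if (is.null(meta$fs)) stop("sidecar has no fs field")
  meta$fs <- as.numeric(meta$fs)
  m <- as.matrix(utils::read.table(path, sep = "\t", header = FALSE))
  dimnames(m) <- NULL
  epochs <- NULL
  if (!is.null(meta$epochs)) {
    epochs <- if (is.matrix(meta$epochs)) {
      lapply(seq_len(nrow(meta$epochs)), function(i) as.numeric(meta$epochs[i, ]))
    } else lapply(meta$epochs, as.numeric)
  }
  ts_set(m, meta$fs, meta$labels, epochs)
}

#' Read a multichannel recording (EDF or TSV)
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"edf"` or `"tsv"`.
#' @return a [ts_set()].
#' @export
read_eeg <- function(path, format = c("auto", "edf", "tsv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "tsv"
  }
  if (format == "edf") read_edf(path) else read_ts_tsv(path)
}

trimws_field <- function(raw) trimws(rawToChar(raw))

#' Minimal EDF (European Data Format) reader
#'
#' Parses the 256-byte EDF header plus per-signal headers, reads the 16-bit
#' little-endian sample records and applies the physical calibration
#' `phys = (dig - dig_min) * (phys_max - phys_min) / (dig_max - dig_min) +
#' phys_min`. All signals must share one sampling rate (records/duration).
#'
#' @param path EDF file path.
#' @return a [ts_set()] with labels and sampling rate from the header.
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(nc) trimws_field(readBin(con, "raw", nc))
  num <- function(s) suppressWarnings(as.numeric(s))
  int <- function(s) suppressWarnings(as.integer(s))
  version <- rd(8)
  invisible(rd(80)); invisible(rd(80)) # patient, recording id
  invisible(rd(8)); invisible(rd(8))   # start date, time
  header_bytes <- int(rd(8))
  invisible(rd(44))
  n_records <- int(rd(8))
  rec_dur <- num(rd(8))
  ns <- int(rd(4))
  if (is.na(ns) || ns < 1) stop("malformed EDF header: bad signal count in ", path)
  fields <- function(nc) vapply(seq_len(ns), function(i) rd(nc), character(1))
  labels <- fields(16)
  invisible(fields(80)); invisible(fields(8)) # transducer, physical dimension
  phys_min <- num(fields(8)); phys_max <- num(fields(8))
  dig_min <- num(fields(8)); dig_max <- num(fields(8))
  invisible(fields(80))
  spr <- int(fields(8))
  invisible(fields(32))
  if (any(is.na(c(phys_min, phys_max, dig_min, dig_max, spr))) ||
      is.na(n_records) || is.na(rec_dur) || rec_dur <= 0) {
    stop("malformed EDF header in ", path)
  }
  if (length(unique(spr)) != 1) {
    stop("EDF signals have differing sampling rates; not supported")
  }
  expected_header <- 256L + 256L * ns
  if (!is.na(header_bytes) && header_bytes != expected_header) {
    stop(sprintf("malformed EDF header: header size %d, expected %d", header_bytes, expected_header))
  }
  fs <- spr[1] / rec_dur
  data <- matrix(0, ns, n_records * spr[1])
  for (r in seq_len(n_records)) {
    for (s in seq_len(ns)) {
      dig <- readBin(con, "integer", spr[s], size = 2, signed = TRUE,
                     endian = "little")
      if (length(dig) < spr[s]) stop("EDF file truncated at record ", r)
      phys <- (dig - dig_min[s]) * (phys_max[s] - phys_min[s]) /
        (dig_max[s] - dig_min[s]) + phys_min[s]
      data[s, ((r - 1) * spr[s] + 1):(r * spr[s])] <- phys
    }
  }
  ts_set(data, fs, labels)
}

pad_field <- function(x, nc) {
  s <- substr(format(x), 1, nc)
  sprintf(paste0("%-", nc, "s"), s)
}

#' Minimal EDF writer
#'
#' Writes a [ts_set()] as EDF with 1-second data records and 16-bit
#' quantization over the per-channel physical range (a trailing partial
#' second is dropped). Mainly used to generate test recordings.
#'
#' @param x a [ts_set()] with integer `fs`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(x, path) {
  stopifnot(inherits(x, "ts_set"), x$fs == round(x$fs))
  ns <- n_channels(x)
  spr <- as.integer(x$fs)
  n_records <- floor(n_samples(x) / spr)
  if (n_records < 1) stop("signal shorter than one EDF record")
  phys_min <- apply(x$data, 1, min); phys_max <- apply(x$data, 1, max)
  flat <- phys_max - phys_min < .Machine$double.eps
  phys_max[flat] <- phys_min[flat] + 1
  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(s, nc) writeBin(charToRaw(pad_field(s, nc)), con)
  wr("0", 8); wr("X X X X", 80); wr("Startdate X X X X", 80)
  wr("01.01.26", 8); wr("00.00.00", 8)
  wr(as.character(256L + 256L * ns), 8); wr("", 44)
  wr(as.character(n_records), 8); wr("1", 8); wr(as.character(ns), 4)
  for (lab in x$labels) wr(lab, 16)
  for (i in seq_len(ns)) wr("", 80)
  for (i in seq_len(ns)) wr("uV", 8)
  for (v in phys_min) wr(sprintf("%.8g", v), 8)
  for (v in phys_max) wr(sprintf("%.8g", v), 8)
  for (i in seq_len(ns)) wr("-32768", 8)
  for (i in seq_len(ns)) wr("32767", 8)
  for (i in seq_len(ns)) wr("", 80)
  for (i in seq_len(ns)) wr(as.character(spr), 8)
  for (i in seq_len(ns)) wr("", 32)
  for (r in seq_len(n_records)) {
    for (s in seq_len(ns)) {
      seg <- x$data[s, ((r - 1) * spr + 1):(r * spr)]
      dig <- round((seg - phys_min[s]) / (phys_max[s] - phys_min[s]) * 65535 - 32768)
      writeBin(as.integer(pmin(32767, pmax(-32768, dig))), con, size = 2,
               endian = "little")
    }
  }
  invisible(path)
}

#' Write / read a spatial pattern table
#'
#' Three-column TSV: channel label, filter weight, pattern value.
#'
#' @param labels channel labels.
#' @param weights filter (projection) weights.
#' @param pattern pattern values.
#' @param path output path; for `read_pattern_tsv`, the input path.
#' @return `read_pattern_tsv` returns a data.frame with columns `label`,
#'   `weight`, `pattern`.
#' @export
write_pattern_tsv <- function(labels, weights, pattern, path) {
  stopifnot(length(labels) == length(weights), length(labels) == length(pattern))
  utils::write.table(
    data.frame(label = labels, weight = weights, pattern = pattern),
    path, sep = "\t", row.names = FALSE, quote = FALSE
  )
  invisible(path)
}

#' @rdname write_pattern_tsv
#' @export
read_pattern_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}

#' Serialize cross-spectra to a JSON + TSV pair
#'
#' Writes `<prefix>.json` (frequencies, dimensions, labels, parameters) and
#' `<prefix>.tsv` (one row per bin/block/entry with real and imaginary
#' parts) — a binary-free representation readable from any language.
#'
#' @param cs a `cross_spectra`.
#' @param prefix path prefix without extension.
#' @return `read_cross_spectra` returns the reconstructed `cross_spectra`.
#' @export
write_cross_spectra <- function(cs, prefix) {
  stopifnot(inherits(cs, "cross_spectra"))
  jsonlite::write_json(
    list(freqs = cs$freqs, n_segments = cs$n_segments, fs = cs$fs,
         labels_a = cs$labels_a, labels_b = cs$labels_b, df = cs$df,
         params = cs$params),
    paste0(prefix, ".json"), auto_unbox = TRUE, digits = NA
  )
  blocks <- list(caa = cs$caa, cbb = cs$cbb, cab = cs$cab)
  rows <- do.call(rbind, lapply(names(blocks), function(bn) {
    arr <- blocks[[bn]]
    d <- dim(arr)
    idx <- expand.grid(i = seq_len(d[1]), j = seq_len(d[2]), bin = seq_len(d[3]))
    data.frame(block = bn, bin = idx$bin, i = idx$i, j = idx$j,
               re = Re(arr[as.matrix(idx)]), im = Im(arr[as.matrix(idx)]))
  }))
  utils::write.table(format(rows, digits = 17, trim = TRUE), paste0(prefix, ".tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(prefix)
}

#' @rdname write_cross_spectra
#' @export
read_cross_spectra <- function(prefix) {
  meta <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  tab <- utils::read.table(paste0(prefix, ".tsv"), sep = "\t", header = TRUE)
  pa <- length(meta$labels_a); pb <- length(meta$labels_b)
  nb <- length(meta$freqs)
  dims <- list(caa = c(pa, pa, nb), cbb = c(pb, pb, nb), cab = c(pa, pb, nb))
  blocks <- lapply(names(dims), function(bn) {
    sub <- tab[tab$block == bn, ]
    arr <- array(0i, dims[[bn]])
    arr[cbind(sub$i, sub$j, sub$bin)] <- complex(real = sub$re, imaginary = sub$im)
    arr
  })
  names(blocks) <- names(dims)
  structure(
    list(freqs = meta$freqs, caa = blocks$caa, cbb = blocks$cbb,
         cab = blocks$cab, n_segments = meta$n_segments, fs = meta$fs,
         labels_a = meta$labels_a, labels_b = meta$labels_b, df = meta$df,
         params = meta$params),
    class = "cross_spectra"
  )
}

#' First principal component of a 3-axis accelerometer signal
#'
#' Mean-centers the three axes and projects onto the first principal axis of
#' their covariance, yielding a quasi-oscillatory univariate movement signal
#' (in contrast to the strictly positive Euclidean norm). The loading with
#' the largest magnitude is made positive so the output polarity is
#' reproducible.
#'
#' @param acc3d [ts_set()] with exactly 3 channels.
#' @return univariate `ts_set`; attributes `loading` (unit loading vector)
#'   and `explained_var` (fraction of variance explained).
#' @export
acc_first_pc <- function(acc3d) {
  stopifnot(inherits(acc3d, "ts_set"))
  if (n_channels(acc3d) != 3) stop("acc_first_pc expects exactly 3 channels")
  X <- acc3d$data - rowMeans(acc3d$data)
  C <- X %*% t(X) / (ncol(X) - 1)
  if (sum(diag(C)) <= 0) stop("zero-variance accelerometer input")
  e <- eigen(C, symmetric = TRUE)
  load <- e$vectors[, 1]
  if (load[which.max(abs(load))] < 0) load <- -load
  out <- ts_set(matrix(drop(crossprod(load, X)), 1), acc3d$fs, "acc_pc1",
                acc3d$epochs)
  attr(out, "loading") <- stats::setNames(load, acc3d$labels)
  attr(out, "explained_var") <- e$values[1] / sum(e$values)
  out
}
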