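# Pattern-space quality and comparison measures.

as_pattern_values <- function(p) {
  if (inherits(p, "cacoh_fit")) p <- p$solution$pattern_a
  v <- stats::setNames(as.numeric(p), names(p))
  if (!all(is.finite(v))) stop("pattern contains non-finite values")
  if (sqrt(sum(v^2)) == 0) stop("pattern has zero norm")
  v
}

check_labels <- function(p1, p2) {
  l1 <- names(p1); l2 <- names(p2)
  if (!is.null(l1) && !is.null(l2) && !identical(l1, l2)) {
    stop("pattern channel labels do not match")
  }
}

#' Pattern recovery error
#'
#' `RError = 1 - |p_orig' p_rec| / (||p_orig|| ||p_rec||)`: one minus the
#' absolute cosine similarity between an original and a recovered spatial
#' pattern. Invariant to scaling and sign of either pattern; 0 iff the
#' patterns are collinear, 1 iff orthogonal.
#'
#' @param p_orig,p_rec numeric pattern vectors (or `cacoh_fit` objects, whose
#'   `pattern_a` is used); equal length, matching labels if named.
#' @return a value in `[0, 1]`.
#' @export
recovery_error <- function(p_orig, p_rec) {
  1 - pattern_similarity(p_orig, p_rec)
}

#' Pattern similarity index
#'
#' `k_sim = |p_1' p_2| / (||p_1|| ||p_2||)`: the absolute cosine similarity
#' between two spatial patterns, from 0 (orthogonal topographies) to 1 (equal
#' up to scale and sign). `k_sim = 1 - recovery_error` by construction.
#'
#' @param p1,p2 numeric pattern vectors (or `cacoh_fit` objects).
#' @return a value in `[0, 1]`.
#' @export
pattern_similarity <- function(p1, p2) {
  v1 <- as_pattern_values(p1); v2 <- as_pattern_values(p2)
  check_labels(v1, v2)
  if (length(v1) != length(v2)) stop("patterns must have equal length")
  min(1, abs(sum(v1 * v2)) / (sqrt(sum(v1^2)) * sqrt(sum(v2^2))))
}

#' Polarity-aligned average of spatial patterns
#'
#' Each pattern is unit-normalized, sign-flipped so its dot product with the
#' reference pattern is positive (preventing cancellation between
#' topographies of opposite polarity), and the arithmetic mean is returned.
#' A pattern exactly orthogonal to the reference keeps its polarity, with a
#' warning.
#'
#' @param patterns list of numeric pattern vectors (or `cacoh_fit` objects),
#'   all of equal length.
#' @param reference_index index of the alignment reference within `patterns`.
#' @return averaged pattern vector (not re-normalized).
#' @export
average_patterns <- function(patterns, reference_index = 1) {
  if (!length(patterns)) stop("empty pattern list")
  vs <- lapply(patterns, as_pattern_values)
  n <- unique(lengths(vs))
  if (length(n) != 1) stop("patterns must all have equal length")
  stopifnot(reference_index >= 1, reference_index <= length(vs))
  ref <- vs[[reference_index]]
  out <- rowMeans(vapply(vs, function(v) {
    v <- v / sqrt(sum(v^2))
    d <- sum(v * ref)
    if (d < 0) v <- -v
    if (d == 0) warning("pattern orthogonal to reference: polarity left unchanged")
    v
  }, numeric(n)))
  nm <- names(if (inherits(patterns[[1]], "cacoh_fit")) patterns[[1]]$solution$pattern_a else patterns[[1]])
  if (!is.null(nm)) names(out) <- nm
  out
}

#' Correlation between pattern similarity and source synchronization
#'
#' For a family of comparisons, correlates `k_sim` (pattern similarity)
#' values with `k_sync` (projected-source synchronization) values across
#' observations (e.g. subjects) and applies the Holm-Bonferroni step-down
#' adjustment over the family. High correlated similarity and synchrony are
#' the diagnostic of a shared underlying generator (non-sinusoidal waveform)
#' rather than two distinct coupled sources.
#'
#' @param k_sim_values,k_sync_values either numeric vectors (one comparison)
#'   or lists of numeric vectors (one entry per comparison in the family).
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return data.frame with one row per comparison: `r`, `p_value`,
#'   `p_adjusted` (Holm), `n`.
#' @export
sim_sync_correlation <- function(k_sim_values, k_sync_values, method = "pearson") {
  if (!is.list(k_sim_values)) k_sim_values <- list(k_sim_values)
  if (!is.list(k_sync_values)) k_sync_values <- list(k_sync_values)
  stopifnot(length(k_sim_values) == length(k_sync_values))
  rows <- mapply(function(a, b) {
    if (length(a) != length(b) || length(a) < 3) stop("need equal lengths >= 3")
    if (stats::sd(a) == 0 || stats::sd(b) == 0) {
      stop("constant input: correlation undefined")
    }
    ct <- stats::cor.test(a, b, method = method, exact = FALSE)
    c(r = unname(ct$estimate), p_value = ct$p.value, n = length(a))
  }, k_sim_values, k_sync_values)
  out <- as.data.frame(t(rows))
  out$p_adjusted <- stats::p.adjust(out$p_value, method = "holm")
  nm <- names(k_sim_values)
  if (!is.null(nm)) rownames(out) <- nm
  out[, c("r", "p_value", "p_adjusted", "n")]
}
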