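#' Automatic singular-value threshold at the spectrum inflection
#'
#' Operationalizes "the inflection point of the singular value curve" as the
#' interior index maximizing the discrete second difference (discrete
#' curvature) of the log10 singular values; the cutoff rank is one less than
#' that index, i.e. everything before the knee is clutter. Log domain makes
#' the rule invariant to overall amplitude scaling; ties break toward the
#' smallest index. Zero singular values are floored at machine-epsilon times
#' the largest value before taking logs.
#'
#' @param d numeric vector of singular values, non-increasing, length >= 4.
#' @return integer cutoff rank in `[1, length(d) - 1]`: components `1..cutoff`
#'   are treated as clutter.
#' @export
select_threshold_inflection <- function(d) {
  if (length(d) < 4L) stop("need at least 4 singular values")
  if (is.unsorted(rev(d))) stop("singular values must be non-increasing")
  # values at the numerical-noise floor carry no shape information and would
  # fake a knee where the spectrum collapses (rank-deficient synthetic data)
  floor_ <- max(d) * 1e-9
  n_eff <- max(which(d > floor_))
  if (n_eff < 4L) stop("spectrum collapses to numerical zero too early")
  d <- pmax(d[seq_len(n_eff)], floor_)
  ld <- log10(d)
  interior <- 2:(length(d) - 1L)
  curv <- ld[interior - 1L] - 2 * ld[interior] + ld[interior + 1L]
  # ties (within float noise) break toward the smallest index
  knee <- interior[which(curv >= max(curv) - 1e-9)[1L]]
  max(1L, knee - 1L)
}

#' SVD clutter filtering of a frame stack
#'
#' Decomposes the Casorati matrix (pixels x time) by singular value
#' decomposition and removes the low-order components, which hold the
#' high-amplitude, temporally coherent tissue clutter; the remainder carries
#' the moving-microbubble signal. With `cutoff = "auto"` the clutter rank is
#' chosen at the inflection point of the singular value curve
#' ([select_threshold_inflection()]).
#'
#' @param stack a `frame_stack` with at least 3 frames.
#' @param cutoff integer clutter rank in `[1, T-1]`, or `"auto"`.
#' @return list with `filtered` (a `frame_stack`; may contain negative
#'   residual values), and `spectrum` (class `singular_spectrum`: `values`,
#'   `cutoff`).
#' @export
svd_filter <- function(stack, cutoff = "auto") {
  d <- dim(stack$frames)
  T_ <- d[3]
  if (T_ < 3L) stop("need at least 3 frames for SVD filtering")
  M <- stack_to_casorati(stack)
  if (!all(is.finite(M))) stop("frame stack contains non-finite values")
  sv <- svd(M)
  if (identical(cutoff, "auto")) {
    cutoff <- select_threshold_inflection(sv$d)
  }
  cutoff <- as.integer(cutoff)
  if (cutoff < 1L || cutoff >= T_) stop("cutoff must be an integer in [1, T-1]")
  keep <- (cutoff + 1L):length(sv$d)
  filt <- sv$u[, keep, drop = FALSE] %*%
    (sv$d[keep] * t(sv$v[, keep, drop = FALSE]))
  list(
    filtered = casorati_to_stack(filt, stack),
    spectrum = structure(list(values = sv$d, cutoff = cutoff),
                         class = "singular_spectrum")
  )
}

#' @export
print.singular_spectrum <- function(x, ...) {
  cat(sprintf("singular_spectrum: %d values, cutoff rank %d (sv1 = %.3g, sv at cutoff+1 = %.3g)\n",
              length(x$values), x$cutoff, x$values[1], x$values[x$cutoff + 1L]))
  invisible(x)
}
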