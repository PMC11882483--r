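#' Construct a frame stack
#'
#' @param frames numeric array `H x W x T` of non-negative beamformed
#'   amplitudes (T >= 2, all finite).
#' @param pixel_size_um pixel size in micrometers.
#' @param frame_rate_hz frame rate in Hz.
#' @return object of class `frame_stack`.
#' @export
frame_stack <- function(frames, pixel_size_um, frame_rate_hz) {
  stopifnot(length(dim(frames)) == 3L, dim(frames)[3] >= 2L,
            all(is.finite(frames)))
  structure(list(frames = frames, pixel_size_um = pixel_size_um,
                 frame_rate_hz = frame_rate_hz), class = "frame_stack")
}

#' @export
print.frame_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("frame_stack: %d frames of %d x %d px (%.1f um, %g Hz)\n",
              d[3], d[1], d[2], x$pixel_size_um, x$frame_rate_hz))
  invisible(x)
}

#' Casorati (space x time) matrix of a frame stack
#'
#' Columns are vectorized frames; the reshape is lossless and inverted by
#' [casorati_to_stack()].
#'
#' @param stack a `frame_stack`.
#' @return numeric matrix of shape `(H*W) x T`.
#' @export
stack_to_casorati <- function(stack) {
  d <- dim(stack$frames)
  matrix(stack$frames, nrow = d[1] * d[2], ncol = d[3])
}

#' Inverse of [stack_to_casorati()]
#' @param mat `(H*W) x T` matrix.
#' @param like a `frame_stack` supplying shape and metadata.
#' @return a `frame_stack` with the same metadata as `like`.
#' @export
casorati_to_stack <- function(mat, like) {
  d <- dim(like$frames)
  out <- like
  out$frames <- array(mat, dim = d)
  out
}

# deterministic smooth spatial mode on an H x W grid (product of low-order
# cosines with random frequency/phase); positive = TRUE keeps it in [0.5, 1]
clutter_mode <- function(H, W, positive = FALSE) {
  fx <- stats::runif(1, 0.5, 2); fy <- stats::runif(1, 0.5, 2)
  px <- stats::runif(1, 0, 2 * pi); py <- stats::runif(1, 0, 2 * pi)
  m <- outer(cos(2 * pi * fy * (0:(H - 1)) / H + py),
             cos(2 * pi * fx * (0:(W - 1)) / W + px))
  if (positive) 0.75 + 0.25 * m else m
}

#' Render a microbubble movie with tissue clutter and noise
#'
#' Each bubble position becomes an isotropic Gaussian spot of unit peak
#' amplitude. Tissue clutter is built as a sum of `clutter$rank` outer
#' products of smooth spatial modes and slowly varying temporal modes, so its
#' Casorati matrix has exactly that rank; the leading mode is strictly
#' positive (tissue echo) with amplitude `clutter$amplitude` times the bubble
#' peak, and successive modes decay threefold. White Gaussian noise of
#' standard deviation `noise_sigma` is added and the result clamped at zero
#' (envelope amplitudes are non-negative).
#'
#' @param trajectories a `bubble_trajectories` object.
#' @param psf_sigma_um Gaussian point-spread sigma in micrometers (> 0).
#' @param clutter list with `rank` (>= 0), `amplitude` (ratio to bubble peak,
#'   >= 0) and `drift` (relative temporal modulation depth).
#' @param noise_sigma additive noise SD in bubble-peak units.
#' @param seed integer RNG seed (clutter modes and noise).
#' @return a `frame_stack`.
#' @export
render_movie <- function(trajectories, psf_sigma_um = 20,
                         clutter = list(rank = 2L, amplitude = 100, drift = 0.1),
                         noise_sigma = 0.01, seed = 1L) {
  stopifnot(psf_sigma_um > 0)
  grid <- attr(trajectories, "grid")
  fr <- attr(trajectories, "frame_rate")
  T_ <- attr(trajectories, "duration")
  H <- grid$H; W <- grid$W; ps <- grid$pixel_size_um
  amp <- clutter$amplitude %||% 0
  stopifnot(amp >= 0)
  set.seed(as.integer(seed))

  frames <- array(0, dim = c(H, W, T_))
  sig <- psf_sigma_um / ps
  pad <- ceiling(4 * sig)
  for (i in seq_len(nrow(trajectories))) {
    t <- trajectories$frame[i]
    if (t < 1L || t > T_) next
    px <- trajectories$x_um[i] / ps  # 0-based pixel coords
    py <- trajectories$y_um[i] / ps
    c0 <- max(1L, floor(px) - pad + 1L); c1 <- min(W, ceiling(px) + pad + 1L)
    r0 <- max(1L, floor(py) - pad + 1L); r1 <- min(H, ceiling(py) + pad + 1L)
    if (c0 > c1 || r0 > r1) next
    rr <- r0:r1; cc <- c0:c1
    spot <- exp(-outer((rr - 1L - py)^2, (cc - 1L - px)^2, `+`) / (2 * sig^2))
    frames[rr, cc, t] <- frames[rr, cc, t] + spot
  }

  rank <- clutter$rank %||% 0L
  if (rank > 0L && amp > 0) {
    drift <- clutter$drift %||% 0.1
    tt <- seq_len(T_) / T_
    for (k in seq_len(rank)) {
      mode <- clutter_mode(H, W, positive = (k == 1L))
      a_k <- amp / 3^(k - 1L)
      cyc <- stats::runif(1, 0.5, 2)
      ph <- stats::runif(1, 0, 2 * pi)
      # every temporal mode has O(1) norm; the amplitude ladder alone sets
      # the (slow) singular-value decay, as in real tissue clutter
      w_k <- if (k == 1L) 1 + drift * sin(2 * pi * cyc * tt + ph) else
        0.5 * sin(2 * pi * cyc * tt + ph)
      for (t in seq_len(T_)) frames[, , t] <- frames[, , t] + a_k * w_k[t] * mode
    }
  }
  if (noise_sigma > 0) {
    frames <- frames + array(stats::rnorm(length(frames), 0, noise_sigma),
                             dim = dim(frames))
  }
  frames <- pmax(frames, 0)
  frame_stack(frames, ps, fr)
}
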