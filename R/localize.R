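#' Detect candidate bubble pixels in one frame
#'
#' Local maxima (8-neighborhood) above `intensity_threshold` times the
#' frame's robust noise scale (median absolute deviation, normal-consistent)
#' are kept greedily by descending intensity subject to a minimum pairwise
#' Euclidean separation.
#'
#' @param frame numeric matrix (one filtered frame).
#' @param intensity_threshold threshold as a multiple of the robust noise
#'   scale (default 4).
#' @param min_separation minimum candidate separation in pixels.
#' @return data frame with 0-based integer pixel coordinates `x`, `y` and
#'   `intensity`, ordered by descending intensity; possibly empty.
#' @export
detect_candidates <- function(frame, intensity_threshold = 4, min_separation = 4) {
  stopifnot(all(is.finite(frame)))
  scale <- stats::mad(frame)
  if (scale <= 0) scale <- stats::sd(frame)
  thr <- intensity_threshold * scale
  H <- nrow(frame); W <- ncol(frame)
  pad <- matrix(-Inf, H + 2L, W + 2L)
  pad[2:(H + 1L), 2:(W + 1L)] <- frame
  is_max <- frame > thr
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0L && dc == 0L) next
    is_max <- is_max & frame >= pad[(2:(H + 1L)) + dr, (2:(W + 1L)) + dc]
  }
  idx <- which(is_max)
  if (length(idx) == 0L)
    return(data.frame(x = integer(0), y = integer(0), intensity = numeric(0)))
  y <- (idx - 1L) %% H          # 0-based row
  x <- (idx - 1L) %/% H         # 0-based col
  o <- order(frame[idx], decreasing = TRUE)
  x <- x[o]; y <- y[o]; val <- frame[idx][o]
  keep <- logical(length(x))
  for (i in seq_along(x)) {
    if (i == 1L || all((x[keep] - x[i])^2 + (y[keep] - y[i])^2 >= min_separation^2)) {
      keep[i] <- TRUE
    }
  }
  data.frame(x = x[keep], y = y[keep], intensity = val[keep])
}

#' Sub-pixel center by radial symmetry
#'
#' Gradient-based radial-symmetry estimator: image gradients around a
#' radially symmetric spot point at (or away from) its center, so the center
#' is the weighted least-squares intersection of the lines through each
#' gradient midpoint along its gradient direction. Gradients are taken on the
#' half-pixel-offset midpoint grid via diagonal (Roberts-cross) differences
#' and weighted by squared gradient magnitude over distance to the intensity
#' centroid. Deterministic and parameter-free.
#'
#' @param window square numeric matrix of odd side `2w + 1`, `w >= 2`,
#'   fully inside the frame.
#' @return numeric `c(dx, dy)`: sub-pixel offset of the spot center from the
#'   window center, in pixels (x = column, y = row direction).
#' @export
localize_radial_symmetry <- function(window) {
  M <- nrow(window)
  stopifnot(ncol(window) == M, M %% 2L == 1L, M >= 5L)
  if (max(window) - min(window) <= 0) stop("constant window: center undefined")
  # midpoint grid coordinates relative to the window center
  m <- M - 1L
  xm <- matrix(rep(seq(-(m - 1) / 2, (m - 1) / 2), each = m), m, m)
  ym <- matrix(rep(seq(-(m - 1) / 2, (m - 1) / 2), times = m), m, m)
  du <- window[1:m, 2:(m + 1L)] - window[2:(m + 1L), 1:m]   # along (+x, -y)
  dv <- window[1:m, 1:m] - window[2:(m + 1L), 2:(m + 1L)]   # along (-x, -y)
  # 3x3 box smoothing of the gradient fields
  box <- function(a) {
    p <- matrix(0, m + 2L, m + 2L)
    p[2:(m + 1L), 2:(m + 1L)] <- a
    n <- matrix(0, m + 2L, m + 2L)
    n[2:(m + 1L), 2:(m + 1L)] <- 1
    s <- cnt <- matrix(0, m, m)
    for (dr in -1:1) for (dc in -1:1) {
      s <- s + p[(2:(m + 1L)) + dr, (2:(m + 1L)) + dc]
      cnt <- cnt + n[(2:(m + 1L)) + dr, (2:(m + 1L)) + dc]
    }
    s / cnt
  }
  du <- box(du); dv <- box(dv)
  gx <- (du - dv) / sqrt(2)
  gy <- (-du - dv) / sqrt(2)
  g2 <- gx^2 + gy^2
  if (sum(g2) <= 0) stop("zero gradient everywhere: center undefined")
  # gradient-magnitude-weighted centroid as distance reference
  xc <- sum(g2 * xm) / sum(g2)
  yc <- sum(g2 * ym) / sum(g2)
  w <- g2 / pmax(sqrt((xm - xc)^2 + (ym - yc)^2), 0.25)
  # least-squares point minimizing sum_k w_k * dist^2(c, line through p_k
  # along unit gradient g_k): A c = b with A = sum w (I - g g^T)
  gn <- pmax(sqrt(g2), .Machine$double.eps)
  ux <- gx / gn; uy <- gy / gn
  a11 <- sum(w * (1 - ux^2)); a22 <- sum(w * (1 - uy^2))
  a12 <- sum(w * (-ux * uy))
  b1 <- sum(w * ((1 - ux^2) * xm - ux * uy * ym))
  b2 <- sum(w * (-ux * uy * xm + (1 - uy^2) * ym))
  det <- a11 * a22 - a12^2
  if (abs(det) < .Machine$double.eps * max(a11, a22, 1))
    stop("degenerate gradient structure: center undefined")
  dx <- (b1 * a22 - b2 * a12) / det
  dy <- (b2 * a11 - b1 * a12) / det
  wmax <- (M - 1) / 2
  c(dx = max(-wmax, min(wmax, dx)), dy = max(-wmax, min(wmax, dy)))
}

#' Localize all bubbles in one frame to sub-pixel precision
#'
#' Runs [detect_candidates()] and refines each candidate with
#' [localize_radial_symmetry()] on a `(2w+1) x (2w+1)` window. Candidates
#' whose window would leave the frame are dropped; candidates whose
#' refinement fails (degenerate window) keep their integer-pixel position.
#'
#' @param frame numeric matrix.
#' @param pixel_size_um pixel size to convert to micrometers.
#' @param intensity_threshold,min_separation passed to [detect_candidates()].
#' @param w window half-size in pixels (default 3).
#' @return data frame with `x_um`, `y_um`, `intensity` (one row per bubble).
#' @export
localize_frame <- function(frame, pixel_size_um, intensity_threshold = 4,
                           min_separation = 4, w = 3L) {
  cand <- detect_candidates(frame, intensity_threshold, min_separation)
  H <- nrow(frame); W <- ncol(frame)
  out_x <- out_y <- out_i <- numeric(0)
  for (i in seq_len(nrow(cand))) {
    x <- cand$x[i]; y <- cand$y[i]
    if (x - w < 0L || x + w > W - 1L || y - w < 0L || y + w > H - 1L) next
    win <- frame[(y - w):(y + w) + 1L, (x - w):(x + w) + 1L]
    off <- tryCatch(localize_radial_symmetry(win), error = function(e) c(0, 0))
    out_x <- c(out_x, (x + off[1]) * pixel_size_um)
    out_y <- c(out_y, (y + off[2]) * pixel_size_um)
    out_i <- c(out_i, cand$intensity[i])
  }
  data.frame(x_um = out_x, y_um = out_y, intensity = out_i)
}

#' Localize every frame of a filtered stack
#'
#' @param stack a `frame_stack` (typically the SVD-filtered movie).
#' @param ... passed to [localize_frame()].
#' @return data frame with `frame`, `x_um`, `y_um`, `intensity`.
#' @export
localize_stack <- function(stack, ...) {
  T_ <- dim(stack$frames)[3]
  res <- vector("list", T_)
  for (t in seq_len(T_)) {
    loc <- localize_frame(stack$frames[, , t], stack$pixel_size_um, ...)
    if (nrow(loc)) res[[t]] <- cbind(frame = t, loc)
  }
  out <- do.call(rbind, res)
  if (is.null(out))
    out <- data.frame(frame = integer(0), x_um = numeric(0), y_um = numeric(0),
                      intensity = numeric(0))
  rownames(out) <- NULL
  out
}
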