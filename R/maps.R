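#' Accumulate tracks into super-resolved maps
#'
#' Every track localization (optionally densified by linear interpolation at
#' the super-resolution pixel pitch, so fast bubbles do not leave gaps)
#' increments the density map at its super-res pixel. The velocity map is
#' the per-pixel mean of contributing step speeds, the direction map the
#' per-pixel circular mean of step directions; both are defined only where
#' density is positive. Per-pixel circular dispersion (1 - mean resultant
#' length) is retained for downstream orientation statistics.
#'
#' The acquisition pixel `i` covers `[i - 0.5, i + 0.5)` pixel units (pixel
#' centers at integers, 0-based), so a position `x_um` lands in super-res
#' column `floor((x_um / pixel_size + 0.5) * grid_factor)`; integer-block
#' downsampling of a `grid_factor = k` density map therefore reproduces the
#' `grid_factor = 1` map exactly.
#'
#' @param tracks an `ulm_tracks` object.
#' @param grid list with `H`, `W`, `pixel_size_um` (acquisition grid).
#' @param frame_rate frame rate in Hz.
#' @param grid_factor integer upsampling factor (default 8).
#' @param interpolate densify steps at super-res pitch (default TRUE).
#' @return object of class `super_res_maps`: matrices `density`, `velocity`,
#'   `direction`, `dispersion` (NA where density is 0), plus `grid_factor`,
#'   `pixel_size_um` (super-res) and the acquisition `grid`.
#' @export
accumulate_maps <- function(tracks, grid, frame_rate, grid_factor = 8L,
                            interpolate = TRUE) {
  grid_factor <- as.integer(grid_factor)
  stopifnot(grid_factor >= 1L)
  H <- grid$H * grid_factor
  W <- grid$W * grid_factor
  ps <- grid$pixel_size_um
  sr_ps <- ps / grid_factor

  pts <- lapply(tracks, function(tr) {
    v <- track_velocities(tr, frame_rate)
    n <- nrow(tr)
    i <- seq_len(n - 1L)
    if (interpolate) {
      step_len <- sqrt(diff(tr$x_um)^2 + diff(tr$y_um)^2)
      k <- pmax(1L, ceiling(step_len / sr_ps))
      i_rep <- rep(i, k)
      f <- unlist(lapply(k, function(m) (0:(m - 1L)) / m))
    } else {
      i_rep <- i
      f <- rep(0, n - 1L)
    }
    px <- tr$x_um[i_rep] + f * (tr$x_um[i_rep + 1L] - tr$x_um[i_rep])
    py <- tr$y_um[i_rep] + f * (tr$y_um[i_rep + 1L] - tr$y_um[i_rep])
    # the final localization carries the last step's velocity
    cbind(x = c(px, tr$x_um[n]), y = c(py, tr$y_um[n]),
          sp = c(v$speed_mm_s[i_rep], v$speed_mm_s[n - 1L]),
          an = c(v$angle_rad[i_rep], v$angle_rad[n - 1L]))
  })
  dens <- vsum <- csum <- ssum <- matrix(0, H, W)
  if (length(pts)) {
    pp <- do.call(rbind, pts)
    col <- floor((pp[, "x"] / ps + 0.5) * grid_factor) + 1L
    row <- floor((pp[, "y"] / ps + 0.5) * grid_factor) + 1L
    ok <- col >= 1L & col <= W & row >= 1L & row <= H
    lin <- (col[ok] - 1L) * H + row[ok]
    dens[] <- tabulate(lin, nbins = H * W)
    rs <- rowsum(cbind(pp[ok, "sp"], cos(pp[ok, "an"]), sin(pp[ok, "an"])), lin)
    at <- as.integer(rownames(rs))
    vsum[at] <- rs[, 1L]; csum[at] <- rs[, 2L]; ssum[at] <- rs[, 3L]
  }

  vel <- dir <- disp <- matrix(NA_real_, H, W)
  nz <- dens > 0
  vel[nz] <- vsum[nz] / dens[nz]
  dir[nz] <- atan2(ssum[nz], csum[nz])
  disp[nz] <- 1 - sqrt(csum[nz]^2 + ssum[nz]^2) / dens[nz]
  structure(list(density = dens, velocity = vel, direction = dir,
                 dispersion = disp, grid_factor = grid_factor,
                 pixel_size_um = sr_ps, grid = grid),
            class = "super_res_maps")
}

#' @export
print.super_res_maps <- function(x, ...) {
  cat(sprintf("super_res_maps: %d x %d px at %.3g um (grid_factor %d), %d localizations\n",
              nrow(x$density), ncol(x$density), x$pixel_size_um, x$grid_factor,
              sum(x$density)))
  invisible(x)
}

#' Integer-block downsampling of a density map
#'
#' Sums `factor x factor` blocks; used to check grid-refinement consistency
#' against a coarser reconstruction.
#'
#' @param density numeric matrix whose dimensions are multiples of `factor`.
#' @param factor integer block size.
#' @return matrix reduced by `factor` in both dimensions.
#' @export
downsample_density <- function(density, factor) {
  H <- nrow(density) / factor; W <- ncol(density) / factor
  stopifnot(H == round(H), W == round(W))
  out <- matrix(0, H, W)
  for (dr in seq_len(factor)) for (dc in seq_len(factor)) {
    out <- out + density[seq(dr, nrow(density), by = factor),
                         seq(dc, ncol(density), by = factor)]
  }
  out
}
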