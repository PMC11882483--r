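#' Parabolic (Poiseuille) velocity profile
#'
#' Laminar flow in a cylindrical vessel has the parabolic profile
#' `v(rho) = 2 * v_mean * (1 - rho^2)` with `rho` the radial position as a
#' fraction of the lumen radius: the centerline moves at twice the mean axial
#' speed and the wall is at rest (no slip).
#'
#' @param mean_speed mean axial speed (mm/s).
#' @param rho radial offset fraction in `[0, 1]`.
#' @return local axial speed (mm/s).
#' @export
poiseuille_speed <- function(mean_speed, rho) {
  stopifnot(all(rho >= 0), all(rho <= 1))
  2 * mean_speed * (1 - rho^2)
}

# cumulative arclength and interpolated point + unit normal at arclength s
path_point <- function(path, cum, s) {
  i <- findInterval(s, cum, rightmost.closed = TRUE)
  i <- max(1L, min(i, nrow(path) - 1L))
  f <- (s - cum[i]) / max(cum[i + 1L] - cum[i], .Machine$double.eps)
  p <- path[i, ] + f * (path[i + 1L, ] - path[i, ])
  tang <- path[i + 1L, ] - path[i, ]
  tang <- tang / max(sqrt(sum(tang^2)), .Machine$double.eps)
  list(p = p, normal = c(-tang[2], tang[1]))
}

#' Simulate microbubble transit through a phantom
#'
#' Bubbles arrive as a Poisson process (`bubbles_per_frame` expected arrivals
#' per frame), each entering at the start of a vessel segment chosen with
#' probability proportional to segment length. A bubble samples a position
#' uniformly over the circular lumen cross-section and keeps the axial speed
#' of the parabolic Poiseuille profile at that radial position (so the
#' ensemble mean of sampled speeds equals the segment's mean axial speed).
#' It then advects along the centerline, laterally displaced by the in-plane
#' component of its cross-sectional offset, until it exits the segment or the
#' movie ends.
#'
#' @param phantom a `vascular_phantom`.
#' @param bubbles_per_frame expected number of new bubbles per frame (> 0).
#' @param duration number of frames (>= 1).
#' @param frame_rate frame rate in Hz.
#' @param seed integer RNG seed.
#' @param rho optional fixed radial profile position in `[0, 1]` for every
#'   bubble (0 = centerline, 1 = wall); by default each bubble samples its
#'   position uniformly over the lumen cross-section.
#' @return object of class `bubble_trajectories`: data frame with columns
#'   `bubble`, `frame` (1-based), `x_um`, `y_um`, `speed_mm_s`, with the
#'   phantom grid, `frame_rate` and `duration` attached as attributes.
#' @export
simulate_bubble_flow <- function(phantom, bubbles_per_frame, duration,
                                 frame_rate, seed = 1L, rho = NULL) {
  if (length(phantom$segments) == 0L) stop("phantom has no segments")
  if (duration < 1L) stop("duration must be at least one frame")
  if (bubbles_per_frame <= 0) stop("bubble rate must be positive")
  set.seed(as.integer(seed))

  lens <- vapply(phantom$segments, function(s) segment_pathlen(s$path), numeric(1))
  cums <- lapply(phantom$segments, function(s)
    c(0, cumsum(sqrt(rowSums(diff(s$path)^2)))))

  n_new <- stats::rpois(duration, bubbles_per_frame)
  rows <- list()
  id <- 0L
  for (t0 in seq_len(duration)) {
    for (b in seq_len(n_new[t0])) {
      id <- id + 1L
      k <- sample.int(length(lens), 1L, prob = lens)
      seg <- phantom$segments[[k]]
      rho_b <- rho %||% sqrt(stats::runif(1))  # area-uniform radial position
      psi <- stats::runif(1, 0, 2 * pi)
      lat_um <- rho_b * cos(psi) * seg$radius_um  # in-plane offset component
      v <- poiseuille_speed(seg$speed_mm_s, rho_b)
      ds <- v * 1000 / frame_rate           # um per frame
      s <- 0
      fr <- t0
      xs <- ys <- numeric(0)
      while (s <= lens[k] && fr <= duration) {
        pt <- path_point(seg$path, cums[[k]], s)
        xs <- c(xs, pt$p[1] + lat_um * pt$normal[1])
        ys <- c(ys, pt$p[2] + lat_um * pt$normal[2])
        s <- s + ds
        fr <- fr + 1L
        if (ds <= 0) break  # wall-adjacent bubble never advances
      }
      if (length(xs)) {
        rows[[length(rows) + 1L]] <- data.frame(
          bubble = id, frame = t0:(t0 + length(xs) - 1L),
          x_um = xs, y_um = ys, speed_mm_s = v)
      }
    }
  }
  traj <- if (length(rows)) do.call(rbind, rows) else
    data.frame(bubble = integer(0), frame = integer(0), x_um = numeric(0),
               y_um = numeric(0), speed_mm_s = numeric(0))
  # keep only positions inside the grid
  W_um <- (phantom$grid$W - 1L) * phantom$grid$pixel_size_um
  H_um <- (phantom$grid$H - 1L) * phantom$grid$pixel_size_um
  traj <- traj[traj$x_um >= 0 & traj$x_um <= W_um &
               traj$y_um >= 0 & traj$y_um <= H_um, , drop = FALSE]
  rownames(traj) <- NULL
  structure(traj, grid = phantom$grid, frame_rate = frame_rate,
            duration = as.integer(duration),
            class = c("bubble_trajectories", "data.frame"))
}
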