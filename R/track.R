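#' Link per-frame localizations into trajectories
#'
#' Frame-to-frame matching by optimal assignment on the squared-Euclidean
#' cost matrix: pairings farther than `max_link_um` are forbidden, leaving a
#' detection unmatched costs the squared gate distance, and the total cost is
#' minimized per consecutive frame pair (Hungarian algorithm). Unmatched
#' detections start new tracks; a track that fails to find a match terminates
#' (no gap closing, so a missed detection ends the trajectory). Tracks
#' shorter than `min_track_len` frames are discarded.
#'
#' Within each frame detections are processed in a canonical order (by
#' `y_um`, then `x_um`) so the assignment, and therefore the whole tracking
#' output, is deterministic.
#'
#' @param localizations data frame with `frame`, `x_um`, `y_um` and
#'   optionally `intensity` (e.g. from [localize_stack()]).
#' @param max_link_um gating distance in micrometers (> 0).
#' @param min_track_len minimum track length in frames (default 15).
#' @return list of class `ulm_tracks`; each element a data frame with
#'   `frame`, `x_um`, `y_um`, `intensity` on strictly consecutive frames.
#' @export
link_tracks <- function(localizations, max_link_um, min_track_len = 15L) {
  stopifnot(max_link_um > 0)
  if (is.null(localizations$intensity))
    localizations$intensity <- rep(NA_real_, nrow(localizations))
  out <- list()
  if (nrow(localizations) == 0L)
    return(structure(out, class = "ulm_tracks"))
  frames <- sort(unique(localizations$frame))
  by_frame <- split(localizations, localizations$frame)
  by_frame <- lapply(by_frame, function(d) d[order(d$y_um, d$x_um), , drop = FALSE])

  active <- list()   # each: data frame of the growing track
  gate2 <- max_link_um^2
  flush <- function(tr) {
    if (nrow(tr) >= min_track_len) out[[length(out) + 1L]] <<- tr
  }
  prev_frame <- -Inf
  for (f in frames) {
    det <- by_frame[[as.character(f)]]
    if (f != prev_frame + 1L || length(active) == 0L) {
      for (tr in active) flush(tr)
      active <- lapply(seq_len(nrow(det)), function(i) det[i, , drop = FALSE])
    } else {
      heads_x <- vapply(active, function(tr) tr$x_um[nrow(tr)], numeric(1))
      heads_y <- vapply(active, function(tr) tr$y_um[nrow(tr)], numeric(1))
      cost <- outer(heads_x, det$x_um, `-`)^2 + outer(heads_y, det$y_um, `-`)^2
      cost[cost > gate2] <- Inf
      m <- match_gated(cost, gate2)
      nxt <- list()
      taken <- logical(nrow(det))
      for (i in seq_along(active)) {
        if (!is.na(m[i])) {
          nxt[[length(nxt) + 1L]] <- rbind(active[[i]], det[m[i], , drop = FALSE])
          taken[m[i]] <- TRUE
        } else {
          flush(active[[i]])
        }
      }
      for (j in which(!taken)) nxt[[length(nxt) + 1L]] <- det[j, , drop = FALSE]
      active <- nxt
    }
    prev_frame <- f
  }
  for (tr in active) flush(tr)
  out <- lapply(out, function(tr) { rownames(tr) <- NULL; tr })
  structure(out, class = "ulm_tracks")
}

#' @export
print.ulm_tracks <- function(x, ...) {
  lens <- vapply(x, nrow, integer(1))
  cat(sprintf("ulm_tracks: %d tracks", length(x)))
  if (length(x)) cat(sprintf(" (length %d-%d frames, median %g)",
                             min(lens), max(lens), stats::median(lens)))
  cat("\n")
  invisible(x)
}

#' Per-step velocities and mean speed of a track
#'
#' Step `i` velocity is `(position[i+1] - position[i]) * frame_rate`,
#' reported in mm/s; the mean speed is the mean of step-speed magnitudes.
#'
#' @param track data frame with `x_um`, `y_um` on consecutive frames
#'   (length >= 2).
#' @param frame_rate frame rate in Hz.
#' @return list with `vx_mm_s`, `vy_mm_s`, `speed_mm_s` (length n-1),
#'   `angle_rad` (step directions) and scalar `mean_speed_mm_s`.
#' @export
track_velocities <- function(track, frame_rate) {
  if (nrow(track) < 2L) stop("track must have at least 2 positions")
  dx <- diff(track$x_um) * frame_rate / 1000   # um/frame * Hz -> mm/s
  dy <- diff(track$y_um) * frame_rate / 1000
  sp <- sqrt(dx^2 + dy^2)
  list(vx_mm_s = dx, vy_mm_s = dy, speed_mm_s = sp,
       angle_rad = atan2(dy, dx), mean_speed_mm_s = mean(sp))
}

#' Flatten tracks to a tidy data frame
#'
#' @param tracks an `ulm_tracks` object.
#' @param frame_rate frame rate in Hz (for per-step velocities; the last
#'   point of a track repeats the final step's velocity).
#' @return data frame with `track_id`, `frame`, `x_um`, `y_um`, `vx_mm_s`,
#'   `vy_mm_s`, `speed_mm_s`.
#' @export
tracks_to_df <- function(tracks, frame_rate) {
  if (length(tracks) == 0L)
    return(data.frame(track_id = integer(0), frame = integer(0),
                      x_um = numeric(0), y_um = numeric(0),
                      vx_mm_s = numeric(0), vy_mm_s = numeric(0),
                      speed_mm_s = numeric(0)))
  do.call(rbind, lapply(seq_along(tracks), function(i) {
    tr <- tracks[[i]]
    v <- track_velocities(tr, frame_rate)
    n <- nrow(tr)
    data.frame(track_id = i, frame = tr$frame, x_um = tr$x_um, y_um = tr$y_um,
               vx_mm_s = c(v$vx_mm_s, v$vx_mm_s[n - 1L]),
               vy_mm_s = c(v$vy_mm_s, v$vy_mm_s[n - 1L]),
               speed_mm_s = c(v$speed_mm_s, v$speed_mm_s[n - 1L]))
  }))
}
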