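# shared fixture builders; everything is generated in code

# symmetric Gaussian spot on an M x M window, center at (x0, y0) in 0-based px
gauss_window <- function(M, x0, y0, sigma = 2) {
  i <- 0:(M - 1)
  outer(exp(-(i - y0)^2 / (2 * sigma^2)), exp(-(i - x0)^2 / (2 * sigma^2)))
}

# single straight horizontal vessel phantom through the grid center
straight_vessel_config <- function(radius_um = 20, speed_mm_s = 5,
                                   H = 64L, W = 64L, pixel_size_um = 10) {
  list(
    grid = list(H = H, W = W, pixel_size_um = pixel_size_um),
    regions = list(
      core = list(seeds = list(list(x_um = 0, y_um = (H / 2) * pixel_size_um,
                                    theta = 0, radius_um = radius_um,
                                    speed_mm_s = speed_mm_s)),
                  branch_prob = 0, tortuosity = 0,
                  radius_um = c(radius_um, radius_um),
                  speed_mm_s = c(speed_mm_s, speed_mm_s))
    ),
    dir_noise = 0, min_steps = 6L, max_steps = 1000L,
    step_um = pixel_size_um
  )
}

straight_vessel_phantom <- function(...) generate_phantom(straight_vessel_config(...), seed = 1L)

# semicircular-arc phantom built directly (for analytic curvature)
arc_phantom <- function(R_um = 250, n_pts = 400L, radius_um = 10,
                        speed_mm_s = 5, H = 128L, W = 128L, pixel_size_um = 10) {
  th <- seq(0, pi, length.out = n_pts)
  cx <- (W - 1) * pixel_size_um / 2
  path <- cbind(x_um = cx + R_um * cos(th), y_um = 200 + R_um * sin(th))
  ph <- generate_phantom(straight_vessel_config(H = H, W = W), seed = 1L)
  ph$segments <- list(list(path = path, radius_um = radius_um,
                           speed_mm_s = speed_mm_s, region = "core"))
  ph$branch_points <- ph$branch_points[0, ]
  ph$region_map <- matrix("core", H, W)
  ph$grid <- list(H = H, W = W, pixel_size_um = pixel_size_um)
  ph
}

# brute-force minimum-cost gated matching by permutation enumeration;
# objective: sum of matched costs + gate_cost per unmatched detection
oracle_match_cost <- function(cost, gate_cost) {
  na <- nrow(cost); nb <- ncol(cost)
  best <- Inf
  # enumerate all injective partial matchings a -> b
  rec <- function(i, used, acc) {
    if (acc >= best) return()
    if (i > na) {
      tot <- acc + gate_cost * sum(!used)   # unmatched b
      if (tot < best) best <<- tot
      return()
    }
    rec(i + 1L, used, acc + gate_cost)      # a_i unmatched
    for (j in seq_len(nb)) {
      if (!used[j] && is.finite(cost[i, j]))
        rec(i + 1L, `[<-`(used, j, TRUE), acc + cost[i, j])
    }
  }
  rec(1L, logical(nb), 0)
  best
}

# cost actually realized by match_gated under the same objective
realized_match_cost <- function(cost, gate_cost, m) {
  matched <- !is.na(m)
  sum(cost[cbind(which(matched), m[matched])]) +
    gate_cost * (sum(!matched) + (ncol(cost) - sum(matched)))
}

# Sierpinski triangle raster at depth d (2^d x 2^d, the bitwise-AND carpet)
sierpinski_mask <- function(depth = 6L) {
  n <- 2^depth
  outer(0:(n - 1), 0:(n - 1), function(i, j) bitwAnd(i, j) == 0)
}

# tiny deterministic two-spot frame
two_spot_frame <- function(H = 32L, W = 32L, p1 = c(8, 8), p2 = c(24, 20),
                           sigma = 2) {
  i <- 0:(H - 1); j <- 0:(W - 1)
  outer(exp(-(i - p1[2])^2 / (2 * sigma^2)), exp(-(j - p1[1])^2 / (2 * sigma^2))) +
    0.8 * outer(exp(-(i - p2[2])^2 / (2 * sigma^2)), exp(-(j - p2[1])^2 / (2 * sigma^2)))
}

# frame-level detection precision/recall vs truth, 1 px gate, excluding truth
# within the unlocalizable 3-px border
detection_pr <- function(traj, locs, n_frames, grid_um = 1270, tol_um = 10) {
  tp <- fp <- fn <- 0
  lo <- 30; hi <- grid_um - 30
  for (t in seq_len(n_frames)) {
    det <- locs[locs$frame == t, ]
    tt <- traj[traj$frame == t, ]
    tt <- tt[tt$x_um >= lo & tt$x_um <= hi & tt$y_um >= lo & tt$y_um <= hi, ]
    if (nrow(tt) == 0) { fp <- fp + nrow(det); next }
    if (nrow(det) == 0) { fn <- fn + nrow(tt); next }
    cost <- outer(tt$x_um, det$x_um, `-`)^2 + outer(tt$y_um, det$y_um, `-`)^2
    cost[cost > tol_um^2] <- Inf
    m <- match_gated(cost, tol_um^2)
    tp <- tp + sum(!is.na(m))
    fn <- fn + sum(is.na(m))
    fp <- fp + nrow(det) - sum(!is.na(m))
  }
  c(precision = tp / (tp + fp), recall = tp / (tp + fn))
}

# track-level recovery: a truth trajectory is recovered when >= 80% of its
# (interior) frames have a recovered track point within 1 px; a recovered
# track is correct when >= 80% of its points sit within 1 px of truth
track_recovery <- function(traj, tracks, frame_rate, grid_um = 1270,
                           tol_um = 10, min_len = 15L) {
  pts <- tracks_to_df(tracks, frame_rate)
  lo <- 30; hi <- grid_um - 30
  truth <- split(traj, traj$bubble)
  truth <- lapply(truth, function(d)
    d[d$x_um >= lo & d$x_um <= hi & d$y_um >= lo & d$y_um <= hi, ])
  truth <- truth[vapply(truth, nrow, 1L) >= min_len]
  covered <- function(a_frame, a_x, a_y, b) {
    vapply(seq_along(a_frame), function(i) {
      bb <- b[b$frame == a_frame[i], , drop = FALSE]
      nrow(bb) > 0 &&
        min((bb$x - a_x[i])^2 + (bb$y - a_y[i])^2) <= tol_um^2
    }, logical(1))
  }
  bpts <- data.frame(frame = pts$frame, x = pts$x_um, y = pts$y_um)
  rec <- vapply(truth, function(tt)
    mean(covered(tt$frame, tt$x_um, tt$y_um, bpts)) >= 0.8, logical(1))
  tdf <- data.frame(frame = traj$frame, x = traj$x_um, y = traj$y_um)
  prc <- vapply(tracks, function(tr)
    mean(covered(tr$frame, tr$x_um, tr$y_um, tdf)) >= 0.8, logical(1))
  c(recall = mean(rec), precision = mean(prc), n_truth = length(truth),
    n_tracks = length(tracks))
}

# two-region phantom (invasive-like vs core-like halves), the configuration
# used for end-to-end parameter-recovery runs
two_region_config <- function(seed) {
  cfg <- default_run_config(seed = seed)
  cfg$phantom$regions <- cfg$phantom$regions[c("core", "invasive")]
  cfg
}

# sign agreement between recovered and true invasive-minus-core differences
recovery_signs <- function(res) {
  ph <- res$phantom
  ti <- phantom_truth_metrics(ph, region_roi(ph, "invasive"), axial = TRUE)
  tc <- phantom_truth_metrics(ph, region_roi(ph, "core"), axial = TRUE)
  ri <- res$metrics[res$metrics$region == "invasive", ]
  rc <- res$metrics[res$metrics$region == "core", ]
  pars <- c("density", "branches", "branch_points", "curvature",
            "fractal_dimension", "orientation_variance")
  vapply(pars, function(p)
    sign(ri[[p]] - rc[[p]]) == sign(ti[[p]] - tc[[p]]), logical(1))
}
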