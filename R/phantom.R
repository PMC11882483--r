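#' Default phantom configuration
#'
#' Three vertical tissue strips (tumor core, invasive zone, normal tissue,
#' left to right) on a 128 x 128 grid of 10 um pixels. Region parameters are
#' chosen so that the invasive zone is denser, more branched and more tortuous
#' than either the core or normal tissue, with larger vessel caliber than the
#' core and intermediate flow speed (core slightly above invasive, normal
#' lowest) -- the contrast pattern of peritumoral neovascularization.
#'
#' @param grid list with `H`, `W` (pixels) and `pixel_size_um`.
#' @return nested list accepted by [generate_phantom()].
#' @export
default_phantom_config <- function(grid = list(H = 128L, W = 128L, pixel_size_um = 10)) {
  list(
    grid = grid,
    regions = list(
      core = list(n_seeds = 3L, branch_prob = 0.012, tortuosity = 0.15,
                  radius_um = c(5, 8), speed_mm_s = c(4, 7)),
      invasive = list(n_seeds = 8L, branch_prob = 0.05, tortuosity = 0.6,
                      radius_um = c(8, 12), speed_mm_s = c(3.5, 6.5)),
      normal = list(n_seeds = 3L, branch_prob = 0.01, tortuosity = 0.10,
                    radius_um = c(4, 6), speed_mm_s = c(2, 4))
    ),
    step_um = grid$pixel_size_um,
    wavelength_um = 150,
    dir_noise = 0.035,
    branch_angle = pi / 6,
    min_steps = 6L,
    max_steps = 400L,
    max_segments_per_region = 50L
  )
}

region_strip_map <- function(H, W, regions) {
  # vertical strips in the order given (defaults: core | invasive | normal)
  nms <- names(regions)
  cuts <- round(seq(0, W, length.out = length(nms) + 1L))
  map <- matrix(nms[length(nms)], H, W)
  for (i in seq_along(nms)) {
    map[, (cuts[i] + 1L):cuts[i + 1L]] <- nms[i]
  }
  map
}

region_at <- function(map, x_um, y_um, pixel_size) {
  col <- round(x_um / pixel_size) + 1L
  row <- round(y_um / pixel_size) + 1L
  if (col < 1L || col > ncol(map) || row < 1L || row > nrow(map)) return(NA_character_)
  map[row, col]
}

#' Generate a synthetic vascular phantom
#'
#' Vessels grow as biased-persistent random walks with a sinusoidal heading
#' perturbation (tortuosity) and stochastic side branching. Each walk starts
#' at a seed point inside its region and stops on leaving the region or the
#' grid, so regional architecture stays distinct. All geometry is stored as
#' centerline polylines in micrometers with a constant radius and mean axial
#' flow speed per segment, which makes every downstream metric computable
#' analytically from the phantom itself.
#'
#' Per-region parameters: `n_seeds` (number of root vessels), `branch_prob`
#' (per-step probability of spawning a child branch), `tortuosity` (heading
#' oscillation amplitude, rad), `radius_um` (range), `speed_mm_s` (range of
#' mean axial speeds). A region may instead (or additionally) carry `seeds`,
#' a list of explicit `list(x_um=, y_um=, theta=)` starting conditions, which
#' makes fully deterministic single-vessel configurations expressible.
#'
#' @param config configuration list, see [default_phantom_config()].
#' @param seed integer RNG seed; identical seeds give identical phantoms.
#' @return object of class `vascular_phantom`: `segments` (list of
#'   `path` n x 2 matrix of (x_um, y_um), `radius_um`, `speed_mm_s`,
#'   `region`), `branch_points` (data frame x_um, y_um, region),
#'   `region_map` (H x W character matrix), `grid`.
#' @export
generate_phantom <- function(config = default_phantom_config(), seed = 1L) {
  grid <- config$grid
  if (grid$H < 64L || grid$W < 64L) stop("grid must be at least 64 x 64 pixels")
  ps <- grid$pixel_size_um
  regions <- config$regions
  for (r in regions) {
    if (!is.null(r$branch_prob) && (r$branch_prob < 0 || r$branch_prob > 1))
      stop("branch_prob must be in [0, 1]")
  }
  n_total <- sum(vapply(regions, function(r)
    (r$n_seeds %||% 0L) + length(r$seeds %||% list()), numeric(1)))
  if (n_total == 0) stop("degenerate config: no seeds in any region")

  set.seed(as.integer(seed))
  map <- region_strip_map(grid$H, grid$W, regions)
  W_um <- (grid$W - 1L) * ps
  H_um <- (grid$H - 1L) * ps

  segments <- list()
  branch_x <- branch_y <- numeric(0)
  branch_region <- character(0)
  step <- config$step_um %||% ps
  lambda <- config$wavelength_um %||% 150
  dir_noise <- config$dir_noise %||% 0.06
  branch_angle <- config$branch_angle %||% (pi / 4)
  min_steps <- config$min_steps %||% 6L
  max_steps <- config$max_steps %||% 400L
  max_seg <- config$max_segments_per_region %||% 40L

  grow <- function(x0, y0, theta0, radius, speed, region, rp) {
    # returns list(path, children = list of (x, y, theta, radius, speed))
    n_pts <- max_steps + 1L
    xs <- ys <- numeric(n_pts)
    xs[1] <- x0; ys[1] <- y0
    phase <- stats::runif(1, 0, 2 * pi)
    drift <- 0
    children <- list()
    k <- 1L
    for (i in seq_len(max_steps)) {
      s <- (i - 1L) * step
      drift <- drift + stats::rnorm(1, 0, dir_noise)
      heading <- theta0 + (rp$tortuosity %||% 0) * sin(2 * pi * s / lambda + phase) + drift
      nx <- xs[k] + step * cos(heading)
      ny <- ys[k] + step * sin(heading)
      if (nx < 0 || nx > W_um || ny < 0 || ny > H_um) break
      if (!identical(region_at(map, nx, ny, ps), region)) break
      k <- k + 1L
      xs[k] <- nx; ys[k] <- ny
      if (stats::runif(1) < (rp$branch_prob %||% 0)) {
        children[[length(children) + 1L]] <- list(
          x = nx, y = ny,
          theta = heading + sample(c(-1, 1), 1) * branch_angle,
          radius = radius * 0.8,
          speed = speed * stats::runif(1, 0.7, 1.0)
        )
      }
    }
    list(path = cbind(x_um = xs[1:k], y_um = ys[1:k]), children = children, n = k)
  }

  for (rn in names(regions)) {
    rp <- regions[[rn]]
    # seed in the region interior (away from strip boundaries) so root
    # vessels are not cut short; same rule for every region
    rmask <- map == rn
    dt <- EBImage::distmap(matrix(as.numeric(rmask), nrow(rmask)))
    margin <- min(6, max(1, floor(max(dt) / 2)))
    in_region <- which(rmask & dt >= margin, arr.ind = TRUE)
    if (nrow(in_region) == 0L) in_region <- which(rmask, arr.ind = TRUE)
    queue <- list()
    for (sd_ in rp$seeds %||% list()) {
      queue[[length(queue) + 1L]] <- list(
        x = sd_$x_um, y = sd_$y_um, theta = sd_$theta,
        radius = sd_$radius_um %||% mean(rp$radius_um),
        speed = sd_$speed_mm_s %||% mean(rp$speed_mm_s))
    }
    for (i in seq_len(rp$n_seeds %||% 0L)) {
      px <- in_region[sample(nrow(in_region), 1L), ]
      queue[[length(queue) + 1L]] <- list(
        x = (px[["col"]] - 1L) * ps, y = (px[["row"]] - 1L) * ps,
        # roots run roughly along the strip axis (either way) with jitter
        theta = sample(c(-pi / 2, pi / 2), 1L) + stats::runif(1, -0.4, 0.4),
        radius = stats::runif(1, rp$radius_um[1], rp$radius_um[2]),
        speed = stats::runif(1, rp$speed_mm_s[1], rp$speed_mm_s[2]))
    }
    n_reg <- 0L
    while (length(queue) > 0L && n_reg < max_seg) {
      q <- queue[[1L]]; queue <- queue[-1L]
      g <- grow(q$x, q$y, q$theta, q$radius, q$speed, rn, rp)
      if (g$n >= min_steps + 1L) {
        segments[[length(segments) + 1L]] <- list(
          path = g$path, radius_um = q$radius, speed_mm_s = q$speed, region = rn)
        n_reg <- n_reg + 1L
        for (ch in g$children) {
          branch_x <- c(branch_x, ch$x); branch_y <- c(branch_y, ch$y)
          branch_region <- c(branch_region, rn)
          queue[[length(queue) + 1L]] <- list(
            x = ch$x, y = ch$y, theta = ch$theta, radius = ch$radius, speed = ch$speed)
        }
      }
    }
  }
  if (length(segments) == 0L) stop("no vessel segment survived the minimum-length rule")

  # branch points whose child never materialized are dropped
  structure(list(
    segments = segments,
    branch_points = data.frame(x_um = branch_x, y_um = branch_y,
                               region = branch_region, stringsAsFactors = FALSE),
    region_map = map,
    grid = grid
  ), class = "vascular_phantom")
}

#' @export
print.vascular_phantom <- function(x, ...) {
  cat(sprintf("vascular_phantom: %d segments on %d x %d grid (%.1f um px)\n",
              length(x$segments), x$grid$H, x$grid$W, x$grid$pixel_size_um))
  tab <- table(vapply(x$segments, `[[`, "", "region"))
  for (n in names(tab)) cat(sprintf("  %-9s %d segments\n", n, tab[[n]]))
  invisible(x)
}

#' Rasterize the true vessel mask of a phantom
#'
#' Each segment is stamped as the union of discs of its radius along the
#' centerline (a 2D tube). Pixel centers are at integer pixel coordinates.
#'
#' @param phantom a `vascular_phantom`.
#' @param grid_factor integer upsampling factor relative to the acquisition
#'   grid (1 = acquisition resolution).
#' @return logical matrix of size `(H*grid_factor) x (W*grid_factor)`.
#' @export
phantom_vessel_mask <- function(phantom, grid_factor = 1L) {
  ps <- phantom$grid$pixel_size_um / grid_factor
  H <- phantom$grid$H * grid_factor
  W <- phantom$grid$W * grid_factor
  mask <- matrix(FALSE, H, W)
  for (seg in phantom$segments) {
    r_px <- seg$radius_um / ps
    pad <- ceiling(r_px)
    p <- seg$path / ps  # 0-based pixel coords on the target grid
    for (i in seq_len(nrow(p))) {
      c0 <- max(1L, floor(p[i, 1]) - pad + 1L); c1 <- min(W, ceiling(p[i, 1]) + pad + 1L)
      r0 <- max(1L, floor(p[i, 2]) - pad + 1L); r1 <- min(H, ceiling(p[i, 2]) + pad + 1L)
      if (c0 > c1 || r0 > r1) next
      cc <- c0:c1; rr <- r0:r1
      d2 <- outer((rr - 1L - p[i, 2])^2, (cc - 1L - p[i, 1])^2, `+`)
      mask[rr, cc] <- mask[rr, cc] | (d2 <= r_px^2)
    }
  }
  mask
}

#' Logical ROI mask for one phantom region
#'
#' @param phantom a `vascular_phantom`.
#' @param region region name present in the phantom's region map.
#' @param grid_factor integer upsampling factor.
#' @return logical matrix.
#' @export
region_roi <- function(phantom, region, grid_factor = 1L) {
  m <- phantom$region_map == region
  if (grid_factor > 1L) m <- upscale_mask(m, grid_factor)
  m
}

#' Nearest-neighbor upsampling of a mask
#' @param mask logical matrix.
#' @param factor integer upsampling factor.
#' @return logical matrix enlarged by `factor` in both dimensions.
#' @export
upscale_mask <- function(mask, factor) {
  factor <- as.integer(factor)
  mask[rep(seq_len(nrow(mask)), each = factor),
       rep(seq_len(ncol(mask)), each = factor)]
}

segment_pathlen <- function(path) {
  if (nrow(path) < 2L) return(0)
  sum(sqrt(rowSums(diff(path)^2)))
}

segment_in_roi <- function(seg, roi, pixel_size) {
  p <- round(seg$path / pixel_size) + 1L
  ok <- p[, 1] >= 1L & p[, 1] <= ncol(roi) & p[, 2] >= 1L & p[, 2] <= nrow(roi)
  inside <- roi[cbind(p[ok, 2], p[ok, 1])]
  mean(c(inside, rep(FALSE, sum(!ok)))) > 0.5
}

#' Ground-truth regional metrics from phantom geometry
#'
#' Computes the nine regional quantities directly from centerline polylines,
#' radii and flow speeds -- no imaging, rendering or skeletonization -- so it
#' serves as the analytic oracle for recovery tests. A segment belongs to the
#' ROI when the majority of its centerline points fall inside it.
#'
#' @param phantom a `vascular_phantom`.
#' @param roi logical matrix on the acquisition grid.
#' @param axial axial orientation statistics (theta modulo pi) instead of
#'   signed flow directions.
#' @return a `region_metrics` list: `density`, `diameter_um`, `branches`,
#'   `branch_points`, `curvature`, `fractal_dimension`, `orientation_variance`,
#'   `velocity_mm_s`, `flow_volume_nl_s`, plus `n_segments` and `empty` flag.
#' @export
phantom_truth_metrics <- function(phantom, roi, axial = FALSE) {
  if (!any(roi)) stop("empty ROI")
  ps <- phantom$grid$pixel_size_um
  segs <- Filter(function(s) segment_in_roi(s, roi, ps), phantom$segments)
  mask <- phantom_vessel_mask(phantom)
  density <- sum(mask & roi) / sum(roi)
  if (length(segs) == 0L) {
    return(empty_region_metrics(density = density))
  }
  curv <- vapply(segs, function(s) {
    lc <- segment_pathlen(s$path)
    l <- sqrt(sum((s$path[nrow(s$path), ] - s$path[1L, ])^2))
    if (l <= 0) NA_real_ else lc / l
  }, numeric(1))
  lens <- vapply(segs, function(s) segment_pathlen(s$path), numeric(1))
  speeds <- vapply(segs, `[[`, numeric(1), "speed_mm_s")
  radii <- vapply(segs, `[[`, numeric(1), "radius_um")
  # step directions of all in-ROI centerline points
  ang <- unlist(lapply(segs, function(s) {
    d <- diff(s$path)
    atan2(d[, 2], d[, 1])
  }))
  bp <- phantom$branch_points
  bp_in <- if (nrow(bp)) {
    col <- round(bp$x_um / ps) + 1L; row <- round(bp$y_um / ps) + 1L
    ok <- col >= 1 & col <= ncol(roi) & row >= 1 & row <= nrow(roi)
    sum(ok & roi[cbind(pmax(row, 1), pmax(col, 1))], na.rm = TRUE)
  } else 0L
  fd <- tryCatch(fractal_dimension(mask & roi)$fd, error = function(e) NA_real_)
  structure(list(
    density = density,
    diameter_um = mean(2 * radii),
    branches = length(segs),
    branch_points = as.integer(bp_in),
    curvature = mean(curv, na.rm = TRUE),
    fractal_dimension = fd,
    orientation_variance = orientation_variance(ang, axial = axial),
    velocity_mm_s = sum(lens * speeds) / sum(lens),
    flow_volume_nl_s = sum(flow_volume(2 * radii, speeds)),
    n_segments = length(segs),
    empty = FALSE
  ), class = "region_metrics")
}

empty_region_metrics <- function(density = 0) {
  structure(list(density = density, diameter_um = 0, branches = 0L,
                 branch_points = 0L, curvature = NA_real_,
                 fractal_dimension = NA_real_, orientation_variance = NA_real_,
                 velocity_mm_s = 0, flow_volume_nl_s = 0, n_segments = 0L,
                 empty = TRUE), class = "region_metrics")
}

#' @export
print.region_metrics <- function(x, ...) {
  cat("region_metrics:\n")
  for (n in setdiff(names(x), "empty"))
    cat(sprintf("  %-22s %s\n", n, format(x[[n]], digits = 4)))
  invisible(x)
}
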