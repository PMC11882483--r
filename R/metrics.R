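#' Vessel segment curvature (arc-chord ratio)
#'
#' Tortuosity of a segment: the actual path length `Lc` over the straight
#' (chord) distance `L` between its endpoints. Equals 1 for a straight
#' vessel and pi/2 for a semicircular arc.
#'
#' @param lc_um path length in micrometers.
#' @param l_um chord length in micrometers (> 0).
#' @return dimensionless ratio >= 1 (up to discretization).
#' @export
curvature <- function(lc_um, l_um) {
  if (any(l_um <= 0)) stop("chord length must be positive (self-loops are excluded)")
  lc_um / l_um
}

#' Box-counting fractal dimension of a binary mask
#'
#' Counts the number of occupied `r x r` grid boxes (anchored at the mask
#' origin) at descending scales and fits `log M(r)` against `log(1/r)` by
#' least squares; the slope is the fractal dimension. Following the
#' scale-selection rule, the contiguous sub-range of at least `min_scales`
#' scales with the highest R-squared above `r2_min` is used for the fit; if
#' no sub-range reaches `r2_min`, the best available one is used and
#' flagged.
#'
#' @param mask logical matrix, non-empty.
#' @param scales integer box sizes in pixels, descending; default powers of
#'   2 from `floor(min(dim)/4)` down to 2.
#' @param r2_min minimum acceptable R-squared (default 0.99).
#' @param min_scales minimum number of scales in the fitted sub-range.
#' @return list: `fd`, `r_squared`, `scales` (those used), `all_scales`,
#'   `counts`, `r2_ok` (TRUE if the R-squared rule was met).
#' @export
fractal_dimension <- function(mask, scales = NULL, r2_min = 0.99,
                              min_scales = 4L) {
  mask <- mask != 0
  if (!any(mask)) stop("empty mask: fractal dimension undefined")
  if (is.null(scales)) {
    smax <- floor(min(dim(mask)) / 4)
    scales <- 2^(seq.int(floor(log2(max(smax, 2))), 1))
  }
  scales <- sort(unique(as.integer(scales)), decreasing = TRUE)
  if (length(scales) < min_scales) stop("need at least ", min_scales, " scales")
  pix <- which(mask, arr.ind = TRUE)
  counts <- vapply(scales, function(r) {
    nrow(unique(cbind((pix[, 1] - 1L) %/% r, (pix[, 2] - 1L) %/% r)))
  }, numeric(1))
  lx <- log(1 / scales)
  ly <- log(counts)
  n <- length(scales)
  best <- NULL
  for (len in n:min_scales) {
    for (s in 1:(n - len + 1L)) {
      ii <- s:(s + len - 1L)
      if (stats::var(ly[ii]) == 0) next
      fit <- stats::lm.fit(cbind(1, lx[ii]), ly[ii])
      r2 <- 1 - sum(fit$residuals^2) / sum((ly[ii] - mean(ly[ii]))^2)
      cand <- list(fd = fit$coefficients[2], r2 = r2, ii = ii)
      if (is.null(best) || r2 > best$r2) best <- cand
    }
  }
  if (is.null(best)) {
    # degenerate: all counts equal at every sub-range; a flat set
    return(list(fd = 0, r_squared = NA_real_, scales = scales,
                all_scales = scales, counts = counts, r2_ok = FALSE))
  }
  # prefer the highest-R2 sub-range that satisfies the rule; `best` already
  # is the global optimum, which satisfies the rule iff any sub-range does
  list(fd = unname(best$fd), r_squared = best$r2, scales = scales[best$ii],
       all_scales = scales, counts = counts, r2_ok = best$r2 > r2_min)
}

#' Orientation variance of a set of directions
#'
#' Mean squared angular deviation around the circular mean direction:
#' `(1/N) * sum(wrap(theta_i - theta_bar)^2)` with differences wrapped into
#' `(-pi, pi]`. In `axial` mode directions are treated modulo pi (vessel
#' orientation without a flow sign): angles are doubled before wrapping and
#' deviations halved after.
#'
#' @param directions angles in radians (N >= 1).
#' @param weights optional non-negative weights.
#' @param axial treat directions as axial (theta equivalent to theta + pi).
#' @return variance in rad^2.
#' @export
orientation_variance <- function(directions, weights = NULL, axial = FALSE) {
  if (length(directions) == 0L) stop("no directions given")
  if (is.null(weights)) weights <- rep(1, length(directions))
  th <- if (axial) 2 * directions else directions
  mu <- circular_mean(th, weights)
  dev <- wrap_angle(th - mu)
  if (axial) dev <- dev / 2
  sum(weights * dev^2) / sum(weights)
}

#' Blood flow volume under the Poiseuille assumption
#'
#' `Q = A * V` with the cross-sectional area `A = pi * (d/2)^2` of a
#' cylindrical vessel; reported in nL/s (1 nL = 1e6 um^3).
#'
#' @param diameter_um vessel diameter in micrometers (>= 0).
#' @param velocity_mm_s mean flow velocity in mm/s (>= 0).
#' @return flow volume in nL/s.
#' @export
flow_volume <- function(diameter_um, velocity_mm_s) {
  if (any(diameter_um < 0) || any(velocity_mm_s < 0))
    stop("diameter and velocity must be non-negative")
  area_um2 <- pi * (diameter_um / 2)^2
  q_um3_s <- area_um2 * velocity_mm_s * 1000   # mm/s -> um/s
  q_um3_s / 1e6
}

#' Vascular density: vessel-area fraction within an ROI
#'
#' @param mask logical vessel mask.
#' @param roi logical ROI of the same size, non-empty.
#' @return fraction in `[0, 1]`.
#' @export
vascular_density <- function(mask, roi) {
  stopifnot(identical(dim(mask), dim(roi)))
  if (!any(roi)) stop("empty ROI")
  sum(mask & roi) / sum(roi)
}

#' Regional structural and hemodynamic metrics
#'
#' Aggregates the nine quantities for one ROI: vascular density (mask-area
#' fraction), mean segment diameter, branches (number of segments assigned
#' to the ROI), branch points (nodes in the ROI), mean curvature
#' (self-loops with zero chord excluded), box-counting fractal dimension of
#' the masked ROI, orientation variance of flow directions (direction-map
#' pixels in the ROI, localization-weighted), mean velocity over
#' velocity-map pixels in the ROI, and total flow volume as the sum of
#' per-segment `Q = A * V` with the segment velocity read off the velocity
#' map along its centerline. A segment is assigned to the ROI holding the
#' majority of its centerline points.
#'
#' @param maps a `super_res_maps` object.
#' @param graph a `vessel_graph` with diameters ([estimate_diameters()]).
#' @param mask logical vessel mask on the super-res grid.
#' @param roi logical ROI on the super-res grid.
#' @param axial use axial orientation statistics (default FALSE: signed
#'   flow directions).
#' @param min_chord_um segments with a chord shorter than this contribute
#'   nothing to the curvature statistic (tortuosity of near-point fragments
#'   is pure discretization noise); default 20 um.
#' @return a `region_metrics` object (see [phantom_truth_metrics()]); if the
#'   ROI holds no vessel the metrics are zero/NA with `empty = TRUE`.
#' @export
region_metrics <- function(maps, graph, mask, roi, axial = FALSE,
                           min_chord_um = 20) {
  stopifnot(identical(dim(maps$density), dim(roi)),
            identical(dim(mask), dim(roi)))
  if (!any(roi)) stop("empty ROI")
  density <- vascular_density(mask, roi)

  in_roi <- function(px) {
    ok <- px[, 1] >= 1L & px[, 1] <= nrow(roi) & px[, 2] >= 1L & px[, 2] <= ncol(roi)
    ins <- roi[px[ok, , drop = FALSE]]
    mean(c(ins, rep(FALSE, sum(!ok))))
  }
  seg_in <- vapply(graph$segments, function(s) in_roi(s$pixels) > 0.5, logical(1))
  segs <- graph$segments[seg_in]

  node_px <- cbind(round(graph$nodes$y_um / graph$pixel_size_um) + 1L,
                   round(graph$nodes$x_um / graph$pixel_size_um) + 1L)
  bp <- graph$nodes$kind == "branch_point"
  bp_in <- 0L
  if (any(bp)) {
    pxb <- node_px[bp, , drop = FALSE]
    ok <- pxb[, 1] >= 1L & pxb[, 1] <= nrow(roi) & pxb[, 2] >= 1L & pxb[, 2] <= ncol(roi)
    bp_in <- sum(roi[pxb[ok, , drop = FALSE]])
  }

  if (length(segs) == 0L) {
    m <- empty_region_metrics(density = density)
    m$branch_points <- as.integer(bp_in)
    return(m)
  }

  diam <- vapply(segs, function(s) s$diameter_um %||% NA_real_, numeric(1))
  lc <- vapply(segs, `[[`, numeric(1), "lc_um")
  l <- vapply(segs, `[[`, numeric(1), "l_um")
  curv <- ifelse(l > 0, lc / l, NA_real_)
  # length-weighted mean over sufficiently long segments: tortuosity of very
  # short fragments is mostly discretization noise
  cw <- ifelse(is.na(curv) | l < min_chord_um, 0, lc)

  seg_speed <- vapply(segs, function(s) {
    v <- maps$velocity[s$pixels]
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  }, numeric(1))
  q <- flow_volume(ifelse(is.na(diam), 0, diam),
                   ifelse(is.na(seg_speed), 0, seg_speed))

  sel <- roi & !is.na(maps$direction)
  ovar <- if (any(sel)) {
    orientation_variance(maps$direction[sel], weights = maps$density[sel],
                         axial = axial)
  } else NA_real_
  velsel <- roi & !is.na(maps$velocity)
  vel <- if (any(velsel)) mean(maps$velocity[velsel]) else 0

  fd <- tryCatch(fractal_dimension(mask & roi)$fd, error = function(e) NA_real_)
  structure(list(
    density = density,
    diameter_um = mean(diam, na.rm = TRUE),
    branches = length(segs),
    branch_points = as.integer(bp_in),
    curvature = if (sum(cw) > 0) sum(cw * ifelse(is.na(curv), 0, curv)) / sum(cw)
                else mean(curv, na.rm = TRUE),
    fractal_dimension = fd,
    orientation_variance = ovar,
    velocity_mm_s = vel,
    flow_volume_nl_s = sum(q),
    n_segments = length(segs),
    empty = FALSE
  ), class = "region_metrics")
}

#' Histopathology mask indices VD-H and VMI-H
#'
#' VD-H is the CD31-positive area fraction of the region; VMI-H is the
#' fraction of the CD31-positive area that is also smooth-muscle-actin
#' positive (mature, pericyte-covered vessels).
#'
#' @param cd31_mask,asma_mask,region_mask logical matrices of one shape.
#' @return list with `vd_h` in `[0, 1]` and `vmi_h` in `[0, 1]` (`NA` when
#'   no CD31-positive pixel lies in the region).
#' @export
histology_mask_metrics <- function(cd31_mask, asma_mask, region_mask) {
  stopifnot(identical(dim(cd31_mask), dim(asma_mask)),
            identical(dim(cd31_mask), dim(region_mask)))
  if (!any(region_mask)) stop("empty region mask")
  cd31 <- cd31_mask & region_mask
  vd_h <- sum(cd31) / sum(region_mask)
  vmi_h <- if (sum(cd31) == 0) NA_real_ else sum(cd31 & asma_mask) / sum(cd31)
  list(vd_h = vd_h, vmi_h = vmi_h)
}

#' Convert region metrics to a one-row data frame
#' @param m a `region_metrics` object.
#' @param region optional region label column.
#' @return one-row data frame.
#' @export
region_metrics_df <- function(m, region = NA_character_) {
  data.frame(region = region, density = m$density, diameter_um = m$diameter_um,
             branches = m$branches, branch_points = m$branch_points,
             curvature = m$curvature, fractal_dimension = m$fractal_dimension,
             orientation_variance = m$orientation_variance,
             velocity_mm_s = m$velocity_mm_s,
             flow_volume_nl_s = m$flow_volume_nl_s,
             stringsAsFactors = FALSE)
}
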