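test_that("curvature follows the arc-chord ratio on analytic cases", {
  expect_equal(curvature(100, 100), 1)
  # semicircle sampled at 200+ points
  th <- seq(0, pi, length.out = 300)
  path <- cbind(cos(th), sin(th)) * 50
  lc <- sum(sqrt(rowSums(diff(path)^2)))
  l <- sqrt(sum((path[300, ] - path[1, ])^2))
  expect_equal(curvature(lc, l), pi / 2, tolerance = 0.01)
  # right-angle elbow of two unit legs
  expect_equal(curvature(2, sqrt(2)), sqrt(2), tolerance = 1e-12)
  expect_error(curvature(10, 0), "positive")
})

test_that("box-counting dimension matches analytic sets", {
  sq <- matrix(TRUE, 512, 512)
  expect_equal(fractal_dimension(sq)$fd, 2, tolerance = 0.05)
  line <- matrix(FALSE, 512, 512); line[256, ] <- TRUE
  expect_equal(fractal_dimension(line)$fd, 1, tolerance = 0.05)
  sp <- sierpinski_mask(6)
  fit <- fractal_dimension(sp)
  expect_equal(fit$fd, log(3) / log(2), tolerance = 0.1)
  expect_true(fit$r2_ok)
  expect_error(fractal_dimension(matrix(FALSE, 64, 64)), "empty")
})

test_that("fractal dimension is monotone across line, Sierpinski, filled square", {
  line <- matrix(FALSE, 256, 256); line[128, ] <- TRUE
  lf <- fractal_dimension(line)$fd
  sf <- fractal_dimension(sierpinski_mask(6))$fd
  qf <- fractal_dimension(matrix(TRUE, 256, 256))$fd
  expect_lt(lf, sf)
  expect_lt(sf, qf)
})

test_that("the R-squared scale-selection rule picks a high-fit sub-range", {
  sp <- sierpinski_mask(6)
  fit <- fractal_dimension(sp, r2_min = 0.99)
  expect_gte(length(fit$scales), 4L)
  expect_gt(fit$r_squared, 0.99)
})

test_that("orientation variance handles wrap-around and axial mode", {
  expect_equal(orientation_variance(rep(0.7, 10)), 0)
  th <- c(rep(1 + 0.2, 5), rep(1 - 0.2, 5))
  expect_equal(orientation_variance(th), 0.04, tolerance = 1e-12)
  # 179 and -179 degrees are 2 degrees apart, not 358
  th2 <- c(179, -179) * pi / 180
  expect_equal(orientation_variance(th2), (pi / 180)^2, tolerance = 1e-9)
  # invariance under global rotation
  set.seed(3)
  base <- runif(50, -pi, pi)
  v0 <- orientation_variance(base)
  for (rot in c(0.5, 2, -3)) {
    expect_equal(orientation_variance(wrap_angle(base + rot)), v0,
                 tolerance = 1e-6)
  }
  # axial mode: anti-parallel directions are the same orientation
  expect_equal(orientation_variance(c(0, pi, 0, pi), axial = TRUE), 0,
               tolerance = 1e-12)
  expect_error(orientation_variance(numeric(0)), "no directions")
})

test_that("flow volume follows Q = A x V with correct unit conversion", {
  expect_equal(flow_volume(0, 5), 0)
  # d = 40 um, V = 5 mm/s: Q = pi * 400 um^2 * 5000 um/s = 6.283e6 um^3/s
  expect_equal(flow_volume(40, 5), pi * 400 * 5000 / 1e6, tolerance = 1e-12)
  expect_equal(flow_volume(80, 5), 4 * flow_volume(40, 5), tolerance = 1e-12)
  expect_error(flow_volume(-1, 5), "non-negative")
})

test_that("vascular density is the mask fraction of the ROI", {
  roi <- matrix(TRUE, 10, 10)
  expect_equal(vascular_density(roi, roi), 1)
  expect_equal(vascular_density(matrix(FALSE, 10, 10), roi), 0)
  half <- matrix(FALSE, 10, 10); half[, 1:5] <- TRUE
  expect_equal(vascular_density(half, roi), 0.5)
  expect_error(vascular_density(half, matrix(FALSE, 10, 10)), "empty ROI")
})

test_that("histology mask indices follow their area-ratio definitions", {
  region <- matrix(TRUE, 20, 20)
  m <- histology_mask_metrics(region, region, region)
  expect_equal(m$vd_h, 1); expect_equal(m$vmi_h, 1)

  cd31 <- matrix(FALSE, 20, 20); cd31[1:6, ] <- TRUE       # 30% of region
  asma <- matrix(FALSE, 20, 20); asma[1:3, ] <- TRUE       # half of cd31
  m2 <- histology_mask_metrics(cd31, asma, region)
  expect_equal(m2$vd_h, 0.30)
  expect_equal(m2$vmi_h, 0.50)

  m3 <- histology_mask_metrics(cd31, matrix(FALSE, 20, 20), region)
  expect_equal(m3$vmi_h, 0)
  m4 <- histology_mask_metrics(matrix(FALSE, 20, 20), asma, region)
  expect_true(is.na(m4$vmi_h))
})

test_that("per-segment flow volume equals an independent recomputation", {
  ph <- generate_phantom(seed = 9)
  tm <- phantom_truth_metrics(ph, region_roi(ph, "invasive"))
  segs <- Filter(function(s)
    ulmvasc:::segment_in_roi(s, region_roi(ph, "invasive"),
                             ph$grid$pixel_size_um), ph$segments)
  q <- sum(vapply(segs, function(s)
    pi * s$radius_um^2 * s$speed_mm_s * 1000 / 1e6, numeric(1)))
  expect_equal(tm$flow_volume_nl_s, q, tolerance = 1e-9)
})

test_that("region metrics on a single straight vessel reconstruction are sane", {
  ph <- straight_vessel_phantom(radius_um = 15, speed_mm_s = 5)
  traj <- simulate_bubble_flow(ph, 2, 200, 500, seed = 2)
  tracks <- structure(lapply(split(traj, traj$bubble), function(d)
    data.frame(frame = d$frame, x_um = d$x_um, y_um = d$y_um, intensity = 1)),
    class = "ulm_tracks")
  tracks <- structure(tracks[vapply(tracks, nrow, 1L) >= 15],
                      class = "ulm_tracks")
  maps <- accumulate_maps(tracks, ph$grid, 500, 4L)
  mask <- binarize_density(maps$density, list(method = "count", k = 1), 2, 30)
  g <- estimate_diameters(mask, extract_graph(skeletonize_mask(mask),
                                              maps$pixel_size_um, 5))
  roi <- matrix(TRUE, 64L * 4L, 64L * 4L)
  m <- region_metrics(maps, g, mask, roi)
  expect_identical(m$branch_points, 0L)
  expect_gte(m$branches, 1L)
  expect_lt(abs(m$curvature - 1), 0.05)
  expect_lt(abs(m$velocity_mm_s - 5) / 5, 0.35)  # lumen-average of profile
  # disjoint ROIs: per-ROI branches sum to at most the total segments
  left <- roi; left[, 129:256] <- FALSE
  right <- roi; right[, 1:128] <- FALSE
  bl <- region_metrics(maps, g, mask, left)$branches
  br <- region_metrics(maps, g, mask, right)$branches
  expect_lte(bl + br, length(g$segments))
})

test_that("an ROI without vessels yields flagged empty metrics, not an error", {
  ph <- straight_vessel_phantom()
  traj <- simulate_bubble_flow(ph, 2, 100, 500, seed = 2)
  tracks <- link_tracks(data.frame(frame = traj$frame, x_um = traj$x_um,
                                   y_um = traj$y_um), 40, 15)
  maps <- accumulate_maps(tracks, ph$grid, 500, 2L)
  mask <- binarize_density(maps$density)
  g <- extract_graph(skeletonize_mask(mask), maps$pixel_size_um)
  roi <- matrix(FALSE, 128, 128); roi[1:10, 1:10] <- TRUE  # empty corner
  m <- region_metrics(maps, g, mask, roi)
  expect_true(m$empty)
  expect_identical(m$branches, 0L)
})
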