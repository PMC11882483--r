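test_that("a single straight horizontal vessel gives one segment with curvature 1", {
  ph <- straight_vessel_phantom(radius_um = 20, speed_mm_s = 5)
  expect_s3_class(ph, "vascular_phantom")
  expect_length(ph$segments, 1L)
  tm <- phantom_truth_metrics(ph, matrix(TRUE, ph$grid$H, ph$grid$W))
  expect_equal(tm$curvature, 1, tolerance = 1e-9)
  expect_identical(tm$branch_points, 0L)
  expect_identical(tm$branches, 1L)
})

test_that("phantom generation is deterministic in the seed", {
  a <- generate_phantom(seed = 42)
  b <- generate_phantom(seed = 42)
  expect_identical(a, b)
  c <- generate_phantom(seed = 43)
  expect_false(identical(a, c))
})

test_that("phantom invariants hold: radii, speeds positive, points in grid", {
  ph <- generate_phantom(seed = 5)
  for (s in ph$segments) {
    expect_gt(s$radius_um, 0)
    expect_gt(s$speed_mm_s, 0)
    expect_true(all(s$path[, 1] >= 0 & s$path[, 1] <= (ph$grid$W - 1) * ph$grid$pixel_size_um))
    expect_true(all(s$path[, 2] >= 0 & s$path[, 2] <= (ph$grid$H - 1) * ph$grid$pixel_size_um))
    expect_true(s$region %in% c("core", "invasive", "normal"))
  }
})

test_that("degenerate config with no seeds errors", {
  cfg <- default_phantom_config()
  for (r in names(cfg$regions)) cfg$regions[[r]]$n_seeds <- 0L
  expect_error(generate_phantom(cfg, seed = 1), "no seeds")
})

test_that("tripling a region's seed density raises its true vessel-area fraction", {
  cfg <- default_phantom_config()
  cfg$regions$invasive$n_seeds <- 3L * cfg$regions$core$n_seeds
  # identical radii/tortuosity so area reflects seeding alone
  cfg$regions$invasive$radius_um <- cfg$regions$core$radius_um
  cfg$regions$invasive$tortuosity <- cfg$regions$core$tortuosity
  cfg$regions$invasive$branch_prob <- cfg$regions$core$branch_prob
  ph <- generate_phantom(cfg, seed = 2)
  d_inv <- phantom_truth_metrics(ph, region_roi(ph, "invasive"))$density
  d_core <- phantom_truth_metrics(ph, region_roi(ph, "core"))$density
  expect_gt(d_inv, d_core)
})

test_that("semicircular arc has true curvature pi/2 and the flow-volume arithmetic", {
  ph <- arc_phantom(R_um = 250, n_pts = 400, radius_um = 20, speed_mm_s = 5)
  tm <- phantom_truth_metrics(ph, matrix(TRUE, 128, 128))
  expect_equal(tm$curvature, pi / 2, tolerance = 0.01)
  # Q = pi r^2 v = pi * (20 um)^2 * 5 mm/s = 2pi e6 um^3/s = 2pi nL/s
  expect_equal(tm$flow_volume_nl_s, pi * 20^2 * 5000 / 1e6, tolerance = 1e-9)
})

test_that("default-config truth metrics order invasive above core and normal", {
  ph <- generate_phantom(seed = 17)
  ti <- phantom_truth_metrics(ph, region_roi(ph, "invasive"))
  tc <- phantom_truth_metrics(ph, region_roi(ph, "core"))
  tn <- phantom_truth_metrics(ph, region_roi(ph, "normal"))
  for (p in c("density", "branches", "branch_points", "curvature",
              "fractal_dimension")) {
    expect_gt(ti[[p]], tc[[p]])
    expect_gt(ti[[p]], tn[[p]])
  }
})

test_that("empty ROI errors", {
  ph <- straight_vessel_phantom()
  expect_error(phantom_truth_metrics(ph, matrix(FALSE, 64, 64)), "empty ROI")
})

test_that("bubble speeds sample the Poiseuille profile with the correct mean", {
  expect_equal(poiseuille_speed(5, 0), 10)    # centerline maximum = 2x mean
  expect_equal(poiseuille_speed(5, 1), 0)     # no slip at the wall
  ph <- straight_vessel_phantom(radius_um = 20, speed_mm_s = 5)
  traj <- simulate_bubble_flow(ph, bubbles_per_frame = 3, duration = 60,
                               frame_rate = 1000, seed = 4)
  v <- tapply(traj$speed_mm_s, traj$bubble, `[`, 1)
  expect_gt(length(v), 80)
  expect_lt(abs(mean(v) - 5) / 5, 0.2)
})

test_that("truth trajectories advect at speed/frame_rate along a straight vessel", {
  ph <- straight_vessel_phantom(radius_um = 20, speed_mm_s = 5)
  traj <- simulate_bubble_flow(ph, 2, 40, 1000, seed = 9)
  for (b in unique(traj$bubble)) {
    d <- traj[traj$bubble == b, ]
    expect_true(all(diff(d$frame) == 1L))
    if (nrow(d) >= 2) {
      step <- sqrt(diff(d$x_um)^2 + diff(d$y_um)^2)
      expect_equal(step, rep(d$speed_mm_s[1] * 1000 / 1000, nrow(d) - 1L),
                   tolerance = 1e-6)
    }
  }
})

test_that("flow simulation rejects a phantom without segments", {
  ph <- straight_vessel_phantom()
  ph$segments <- list()
  expect_error(simulate_bubble_flow(ph, 1, 10, 500, 1), "no segments")
})
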