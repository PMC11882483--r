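test_that("binarization keeps a well-sampled track as one component and handles zeros", {
  dens <- matrix(0, 40, 40)
  dens[20, 5:35] <- 3
  mask <- binarize_density(dens, list(method = "count", k = 1), close_radius = 1,
                           min_size = 5)
  lab <- ulmvasc:::label_components(mask)
  expect_identical(max(lab), 1L)

  empty <- binarize_density(matrix(0, 16, 16))
  expect_false(any(empty))
})

test_that("skeleton of a wide bar is a one-pixel line inside the mask", {
  mask <- matrix(FALSE, 20, 40)
  mask[8:12, 5:35] <- TRUE
  sk <- skeletonize_mask(mask)
  expect_true(all(mask[sk]))               # skeleton subset of mask
  expect_identical(sum(sk & !mask), 0L)
  rows <- unique(which(sk, arr.ind = TRUE)[, 1])
  expect_identical(length(rows), 1L)       # single row: 1 px wide
  expect_identical(sum(skeletonize_mask(matrix(FALSE, 8, 8))), 0L)
})

test_that("plus-sign mask skeletonizes to one branch point with four arms", {
  mask <- matrix(FALSE, 21, 21)
  mask[9:13, 2:20] <- TRUE
  mask[2:20, 9:13] <- TRUE
  sk <- skeletonize_mask(mask)
  nbc <- ulmvasc:::neighbor_count(sk); nbc[!sk] <- 0L
  expect_gte(sum(nbc >= 3), 1L)
  g <- extract_graph(sk, pixel_size_um = 10, prune_px = 3)
  expect_identical(sum(g$nodes$kind == "branch_point"), 1L)
  expect_identical(length(g$segments), 4L)
  expect_identical(sum(g$nodes$kind == "endpoint"), 4L)
})

test_that("straight-line skeleton gives one segment with Lc = L and two endpoints", {
  sk <- matrix(FALSE, 10, 30)
  sk[5, 3:27] <- TRUE
  g <- extract_graph(sk, pixel_size_um = 10, prune_px = 0)
  expect_identical(length(g$segments), 1L)
  expect_identical(sum(g$nodes$kind == "endpoint"), 2L)
  expect_identical(sum(g$nodes$kind == "branch_point"), 0L)
  expect_equal(g$segments[[1]]$lc_um, g$segments[[1]]$l_um, tolerance = 1e-9)
  expect_equal(g$segments[[1]]$lc_um, 240)
})

test_that("Y-shaped skeleton gives one branch point, three segments, three endpoints", {
  sk <- matrix(FALSE, 24, 24)
  sk[12, 2:12] <- TRUE                        # stem
  for (k in 1:9) { sk[12 - k, 12 + k] <- TRUE; sk[12 + k, 12 + k] <- TRUE }
  g <- extract_graph(sk, pixel_size_um = 10, prune_px = 3)
  expect_identical(sum(g$nodes$kind == "branch_point"), 1L)
  expect_identical(length(g$segments), 3L)
  expect_identical(sum(g$nodes$kind == "endpoint"), 3L)
})

test_that("Lc >= L for all segments and segments partition the skeleton", {
  ph <- generate_phantom(seed = 12)
  mask <- phantom_vessel_mask(ph, 2L)
  sk <- skeletonize_mask(mask)
  g <- extract_graph(sk, pixel_size_um = 5, prune_px = 0)
  for (s in g$segments) expect_gte(s$lc_um, s$l_um - 1e-9)
  # every skeleton pixel is covered by >= 1 segment polyline or is a node
  cov <- matrix(FALSE, nrow(sk), ncol(sk))
  for (s in g$segments) cov[s$pixels] <- TRUE
  node_px <- matrix(FALSE, nrow(sk), ncol(sk))
  nbc <- ulmvasc:::neighbor_count(sk); nbc[!sk] <- 0L
  node_px[sk & (nbc >= 3 | nbc <= 1)] <- TRUE
  expect_true(all(cov[sk] | node_px[sk]))
  # interior (non-node) pixels belong to exactly one segment
  hits <- matrix(0L, nrow(sk), ncol(sk))
  for (s in g$segments) {
    interior <- s$pixels[-c(1, nrow(s$pixels)), , drop = FALSE]
    hits[interior] <- hits[interior] + 1L
  }
  expect_true(all(hits[sk & !node_px] <= 1L))
})

test_that("full binary tree bookkeeping: b branch points give 2b + 1 segments", {
  # depth-2 binary tree drawn on a grid: 3 branch points, 7 segments
  sk <- matrix(FALSE, 40, 40)
  sk[20, 2:10] <- TRUE
  for (k in 1:6) { sk[20 - k, 10 + k] <- TRUE; sk[20 + k, 10 + k] <- TRUE }
  for (k in 1:5) {
    sk[14 - k, 16 + k] <- TRUE; sk[14 + k, 16 + k] <- TRUE
    sk[26 - k, 16 + k] <- TRUE; sk[26 + k, 16 + k] <- TRUE
  }
  g <- extract_graph(sk, 10, prune_px = 3)
  b <- sum(g$nodes$kind == "branch_point")
  expect_identical(b, 3L)
  expect_identical(length(g$segments), 2L * b + 1L)
})

test_that("diameters from the distance transform match bar width", {
  mask <- matrix(FALSE, 20, 40)
  mask[8:12, 3:37] <- TRUE                    # 5 px wide bar
  sk <- skeletonize_mask(mask)
  g <- extract_graph(sk, pixel_size_um = 10, prune_px = 0)
  g <- estimate_diameters(mask, g)
  expect_equal(g$segments[[1]]$diameter_um, 50, tolerance = 10)

  thin <- matrix(FALSE, 10, 20)
  thin[5, 2:18] <- TRUE
  gt <- estimate_diameters(thin, extract_graph(thin, 10, prune_px = 0))
  expect_equal(gt$segments[[1]]$diameter_um, 10, tolerance = 1e-9)

  off <- g; off$segments[[1]]$pixels[1, ] <- c(1L, 1L)
  expect_error(estimate_diameters(mask, off), "outside mask")
})

test_that("phantom vessel diameter is recovered within 20 percent", {
  ph <- straight_vessel_phantom(radius_um = 20, speed_mm_s = 5,
                                H = 64L, W = 64L)
  traj <- simulate_bubble_flow(ph, 2, 300, 500, seed = 3)
  tracks <- structure(lapply(split(traj, traj$bubble), function(d)
    data.frame(frame = d$frame, x_um = d$x_um, y_um = d$y_um, intensity = 1)),
    class = "ulm_tracks")
  tracks <- structure(tracks[vapply(tracks, nrow, 1L) >= 15],
                      class = "ulm_tracks")
  maps <- accumulate_maps(tracks, ph$grid, 500, 4L)
  mask <- binarize_density(maps$density, list(method = "count", k = 1),
                           close_radius = 2, min_size = 30)
  g <- estimate_diameters(mask, extract_graph(skeletonize_mask(mask),
                                              maps$pixel_size_um, 5))
  d <- stats::median(vapply(g$segments, `[[`, numeric(1), "diameter_um"))
  expect_lt(abs(d - 40) / 40, 0.2)
})

test_that("well-sampled default phantom passes the Dice segmentation gate", {
  ph <- generate_phantom(seed = 1)
  traj <- simulate_bubble_flow(ph, 3.0, 600, 500, seed = 1)
  tracks <- structure(lapply(split(traj, traj$bubble), function(d)
    data.frame(frame = d$frame, x_um = d$x_um, y_um = d$y_um, intensity = 1)),
    class = "ulm_tracks")
  tracks <- structure(tracks[vapply(tracks, nrow, 1L) >= 15],
                      class = "ulm_tracks")
  maps <- accumulate_maps(tracks, ph$grid, 500, 4L)
  mask <- binarize_density(maps$density, list(method = "count", k = 2),
                           close_radius = 2, min_size = 30)
  dice <- segmentation_dice(mask, phantom_vessel_mask(ph, 4L), 4L)
  expect_gte(dice, 0.7)
})
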