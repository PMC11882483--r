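#' Binarize a super-resolution density map into a vessel mask
#'
#' Deterministic segmentation: the `count` rule keeps pixels with at least
#' `k` accumulated localizations (default 2), then applies morphological
#' closing (disc radius `close_radius`) and removes 8-connected components
#' smaller than `min_size` pixels. An `adaptive` rule (local-mean offset
#' threshold over a square window) is provided as an alternative.
#'
#' @param density non-negative numeric matrix.
#' @param rule list: `list(method = "count", k = 2)` or
#'   `list(method = "adaptive", window = 31, offset = 0)`.
#' @param close_radius disc radius (px) of the morphological closing.
#' @param min_size minimum component size in pixels.
#' @return logical matrix (class retains attribute `rule` for provenance).
#' @export
binarize_density <- function(density, rule = list(method = "count", k = 2),
                             close_radius = 1L, min_size = 20L) {
  stopifnot(all(density >= 0))
  if (!any(density > 0)) {
    return(structure(matrix(FALSE, nrow(density), ncol(density)), rule = rule))
  }
  mask <- switch(rule$method %||% "count",
    count = density >= (rule$k %||% 2),
    adaptive = {
      win <- rule$window %||% 31L
      local_mean <- EBImage::filter2(density,
        matrix(1 / win^2, win, win))
      density > local_mean + (rule$offset %||% 0)
    },
    stop("unknown binarization rule: ", rule$method)
  )
  if (close_radius > 0L && any(mask)) {
    brush <- EBImage::makeBrush(2L * as.integer(close_radius) + 1L, shape = "disc")
    mask <- EBImage::closing(matrix(as.numeric(mask), nrow(mask)), brush) > 0.5
  }
  mask <- remove_small_components(mask, min_size)
  structure(mask, rule = rule)
}

# one Zhang-Suen subiteration; returns the updated padded logical matrix
zs_pass <- function(p, first) {
  H <- nrow(p) - 2L; W <- ncol(p) - 2L
  ri <- 2:(H + 1L); ci <- 2:(W + 1L)
  P <- p[ri, ci]
  n2 <- p[ri - 1L, ci];      n3 <- p[ri - 1L, ci + 1L]
  n4 <- p[ri, ci + 1L];      n5 <- p[ri + 1L, ci + 1L]
  n6 <- p[ri + 1L, ci];      n7 <- p[ri + 1L, ci - 1L]
  n8 <- p[ri, ci - 1L];      n9 <- p[ri - 1L, ci - 1L]
  B <- n2 + n3 + n4 + n5 + n6 + n7 + n8 + n9
  A <- (!n2 & n3) + (!n3 & n4) + (!n4 & n5) + (!n5 & n6) +
       (!n6 & n7) + (!n7 & n8) + (!n8 & n9) + (!n9 & n2)
  if (first) {
    cond <- P & B >= 2 & B <= 6 & A == 1 & !(n2 & n4 & n6) & !(n4 & n6 & n8)
  } else {
    cond <- P & B >= 2 & B <= 6 & A == 1 & !(n2 & n4 & n8) & !(n2 & n6 & n8)
  }
  p[ri, ci][cond] <- FALSE
  p
}

#' Skeletonize a binary vessel mask (Zhang-Suen thinning)
#'
#' Iterative two-subpass thinning to a 1-px-wide, topology-preserving medial
#' representation; the skeleton is always a subset of the mask.
#'
#' @param mask logical matrix.
#' @return logical matrix of the same size.
#' @export
skeletonize_mask <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  p <- matrix(FALSE, H + 2L, W + 2L)
  p[2:(H + 1L), 2:(W + 1L)] <- mask != 0
  repeat {
    before <- p
    p <- zs_pass(p, first = TRUE)
    p <- zs_pass(p, first = FALSE)
    if (identical(p, before)) break
  }
  p[2:(H + 1L), 2:(W + 1L)]
}

# moving-average smoothing of an n x 2 polyline, endpoints fixed; suppresses
# the digital staircase so arc length converges to the continuous one
smooth_polyline <- function(p, half = 2L) {
  n <- nrow(p)
  if (n <= 2L * half + 1L) return(p)
  out <- p * 1.0
  cx <- cumsum(p[, 1]); cy <- cumsum(p[, 2])
  i <- (half + 1L):(n - half)
  out[i, 1] <- (cx[i + half] - c(0, cx)[i - half]) / (2 * half + 1)
  out[i, 2] <- (cy[i + half] - c(0, cy)[i - half]) / (2 * half + 1)
  out
}

# 8-neighbor offsets in (drow, dcol)
.nb8 <- cbind(dr = c(-1, -1, -1, 0, 0, 1, 1, 1),
              dc = c(-1, 0, 1, -1, 1, -1, 0, 1))

#' Extract a measurable vessel graph from a skeleton
#'
#' Branch points are 8-connected clusters of skeleton pixels with 3 or more
#' skeleton neighbors, merged into a single node each (thick junctions would
#' otherwise double-count); endpoints are pixels with exactly one neighbor.
#' Segments are maximal skeleton paths between nodes, with path length `Lc`
#' (sum of 1 and sqrt(2) pixel steps) and chord length `L` (Euclidean
#' end-to-end distance), both in micrometers. Endpoint-attached spurs
#' shorter than `prune_px` skeleton pixels are pruned. Isolated cycles are
#' kept as self-loop segments; a self-loop whose attachment pixels coincide
#' gets `L = 0` and is excluded from curvature statistics downstream.
#'
#' @param skeleton logical matrix (1-px-wide skeleton).
#' @param pixel_size_um pixel size of the skeleton grid in micrometers.
#' @param prune_px prune endpoint spurs shorter than this many pixels
#'   (default 3).
#' @return object of class `vessel_graph`: `nodes` data frame (`id`, `x_um`,
#'   `y_um`, `kind`), `segments` list (`id`, `node_a`, `node_b`, `pixels`
#'   n x 2 (row, col), `path_um` n x 2 (x_um, y_um), `lc_um`, `l_um`), and
#'   `pixel_size_um`.
#' @export
extract_graph <- function(skeleton, pixel_size_um, prune_px = 3L) {
  skel <- skeleton != 0
  H <- nrow(skel); W <- ncol(skel)
  nbc <- neighbor_count(skel)
  nbc[!skel] <- 0L
  node_px <- skel & nbc >= 3L
  end_px <- skel & nbc == 1L
  iso_px <- skel & nbc == 0L

  # cluster adjacent branch pixels into single nodes
  node_lab <- label_components(node_px)
  n_bp <- max(node_lab)
  nodes <- data.frame(id = integer(0), x_um = numeric(0), y_um = numeric(0),
                      kind = character(0), stringsAsFactors = FALSE)
  px_node <- matrix(0L, H, W)   # node id covering each pixel, 0 = none
  if (n_bp > 0L) {
    for (k in seq_len(n_bp)) {
      w <- which(node_lab == k, arr.ind = TRUE)
      nodes <- rbind(nodes, data.frame(
        id = k, x_um = (mean(w[, 2]) - 1) * pixel_size_um,
        y_um = (mean(w[, 1]) - 1) * pixel_size_um, kind = "branch_point"))
      px_node[w] <- k
    }
  }
  ep <- which(end_px | iso_px, arr.ind = TRUE)
  for (i in seq_len(nrow(ep))) {
    id <- nrow(nodes) + 1L
    nodes <- rbind(nodes, data.frame(
      id = id, x_um = (ep[i, 2] - 1) * pixel_size_um,
      y_um = (ep[i, 1] - 1) * pixel_size_um, kind = "endpoint"))
    px_node[ep[i, 1], ep[i, 2]] <- id
  }

  visited <- matrix(FALSE, H, W)   # visited non-node skeleton pixels
  segments <- list()
  add_segment <- function(path_px, node_a, node_b) {
    steps <- if (nrow(path_px) > 1L) diff(path_px) else
      matrix(0, 0, 2)
    # raw 8-connected chain length overestimates the continuous path length
    # (staircase bias); arc length is measured on a lightly smoothed polyline
    sm <- smooth_polyline(path_px)
    lc <- segment_pathlen(sm) * pixel_size_um
    l <- sqrt(sum((path_px[nrow(path_px), ] - path_px[1L, ])^2)) * pixel_size_um
    segments[[length(segments) + 1L]] <<- list(
      id = length(segments) + 1L, node_a = node_a, node_b = node_b,
      pixels = path_px,
      path_um = cbind(x_um = (path_px[, 2] - 1) * pixel_size_um,
                      y_um = (path_px[, 1] - 1) * pixel_size_um),
      lc_chain_um = sum(sqrt(rowSums(steps^2))) * pixel_size_um,
      lc_um = lc, l_um = l)
  }

  neighbors_of <- function(r, c) {
    rr <- r + .nb8[, 1]; cc <- c + .nb8[, 2]
    ok <- rr >= 1L & rr <= H & cc >= 1L & cc <= W
    cbind(rr[ok], cc[ok])[skel[cbind(rr[ok], cc[ok])], , drop = FALSE]
  }

  # walk from every node pixel into each unvisited non-node neighbor
  start_px <- which(px_node > 0L, arr.ind = TRUE)
  for (i in seq_len(nrow(start_px))) {
    r0 <- start_px[i, 1]; c0 <- start_px[i, 2]
    a <- px_node[r0, c0]
    for (j in seq_len(8L)) {
      r <- r0 + .nb8[j, 1]; c <- c0 + .nb8[j, 2]
      if (r < 1L || r > H || c < 1L || c > W) next
      if (!skel[r, c]) next
      if (px_node[r, c] > 0L) {
        # direct node-to-node adjacency: record once (a <= b and ordered)
        b <- px_node[r, c]
        if (a < b || (a == b && (r0 < r || (r0 == r && c0 < c)))) {
          if (a != b) add_segment(rbind(c(r0, c0), c(r, c)), a, b)
        }
        next
      }
      if (visited[r, c]) next
      # trace until the next node pixel
      path <- rbind(c(r0, c0), c(r, c))
      visited[r, c] <- TRUE
      prev <- c(r0, c0); cur <- c(r, c)
      repeat {
        nb <- neighbors_of(cur[1], cur[2])
        nb <- nb[!(nb[, 1] == prev[1] & nb[, 2] == prev[2]), , drop = FALSE]
        nd <- nb[px_node[nb] > 0L, , drop = FALSE]
        if (nrow(nd) > 0L) {
          path <- rbind(path, nd[1L, ])
          add_segment(path, a, px_node[nd[1L, 1], nd[1L, 2]])
          break
        }
        nxt <- nb[!visited[nb] & px_node[nb] == 0L, , drop = FALSE]
        if (nrow(nxt) == 0L) {  # dead end without an endpoint marker (rare)
          add_segment(path, a, a)
          break
        }
        prev <- cur; cur <- nxt[1L, ]
        visited[cur[1], cur[2]] <- TRUE
        path <- rbind(path, cur)
      }
    }
  }

  # isolated cycles: unvisited degree-2 pixels with no node anywhere
  left <- which(skel & !visited & px_node == 0L, arr.ind = TRUE)
  done <- matrix(FALSE, H, W)
  for (i in seq_len(nrow(left))) {
    r0 <- left[i, 1]; c0 <- left[i, 2]
    if (done[r0, c0] || visited[r0, c0]) next
    path <- rbind(c(r0, c0))
    visited[r0, c0] <- TRUE; done[r0, c0] <- TRUE
    prev <- c(NA, NA); cur <- c(r0, c0)
    repeat {
      nb <- neighbors_of(cur[1], cur[2])
      if (!is.na(prev[1]))
        nb <- nb[!(nb[, 1] == prev[1] & nb[, 2] == prev[2]), , drop = FALSE]
      nxt <- nb[!visited[nb], , drop = FALSE]
      if (nrow(nxt) == 0L) break
      prev <- cur; cur <- nxt[1L, ]
      visited[cur[1], cur[2]] <- TRUE; done[cur[1], cur[2]] <- TRUE
      path <- rbind(path, cur)
    }
    if (nrow(path) >= 3L) {
      path <- rbind(path, path[1L, ])  # close the loop
      id <- nrow(nodes) + 1L
      nodes <- rbind(nodes, data.frame(
        id = id, x_um = (path[1, 2] - 1) * pixel_size_um,
        y_um = (path[1, 1] - 1) * pixel_size_um, kind = "branch_point"))
      add_segment(path, id, id)
    }
  }

  g <- structure(list(nodes = nodes, segments = segments,
                      pixel_size_um = pixel_size_um, skeleton = skel),
                 class = "vessel_graph")
  prune_graph(g, prune_px)
}

# drop endpoint-attached spurs shorter than prune_px pixels
prune_graph <- function(g, prune_px) {
  if (prune_px <= 0L || length(g$segments) == 0L) return(g)
  end_ids <- g$nodes$id[g$nodes$kind == "endpoint"]
  keep <- vapply(g$segments, function(s) {
    spur <- xor(s$node_a %in% end_ids, s$node_b %in% end_ids)
    !(spur && nrow(s$pixels) < prune_px)
  }, logical(1))
  g$segments <- g$segments[keep]
  for (i in seq_along(g$segments)) g$segments[[i]]$id <- i
  used <- unique(unlist(lapply(g$segments, function(s) c(s$node_a, s$node_b))))
  g$nodes <- g$nodes[g$nodes$id %in% used, , drop = FALSE]
  g
}

#' @export
print.vessel_graph <- function(x, ...) {
  cat(sprintf("vessel_graph: %d segments, %d branch points, %d endpoints\n",
              length(x$segments), sum(x$nodes$kind == "branch_point"),
              sum(x$nodes$kind == "endpoint")))
  invisible(x)
}

#' Attach per-point radii and segment diameters from the vessel mask
#'
#' The radius at each centerline point is the Euclidean distance transform
#' of the mask at that point minus half a pixel (the transform measures to
#' the nearest background pixel center); the segment diameter is twice the
#' median radius along the segment.
#'
#' @param mask logical vessel mask on the same grid as the graph.
#' @param graph a `vessel_graph` whose skeleton lies inside the mask.
#' @return the graph with `radii_um` (per point) and `diameter_um` added to
#'   every segment.
#' @export
estimate_diameters <- function(mask, graph) {
  dt <- EBImage::distmap(matrix(as.numeric(mask != 0), nrow(mask)))
  ps <- graph$pixel_size_um
  for (i in seq_along(graph$segments)) {
    px <- graph$segments[[i]]$pixels
    d <- dt[px]
    if (any(d <= 0)) stop("skeleton point outside mask: invariant violation")
    r <- pmax(d - 0.5, 0.5) * ps
    graph$segments[[i]]$radii_um <- r
    graph$segments[[i]]$diameter_um <- 2 * stats::median(r)
  }
  graph
}

#' Tidy data frame of graph segments
#'
#' @param graph a `vessel_graph` (after [estimate_diameters()] for the
#'   diameter column).
#' @return data frame: `id`, `node_a`, `node_b`, `lc_um`, `l_um`,
#'   `diameter_um`, `n_px`, `mid_x_um`, `mid_y_um` (segment midpoint).
#' @export
segments_df <- function(graph) {
  if (length(graph$segments) == 0L)
    return(data.frame(id = integer(0), node_a = integer(0), node_b = integer(0),
                      lc_um = numeric(0), l_um = numeric(0),
                      diameter_um = numeric(0), n_px = integer(0),
                      mid_x_um = numeric(0), mid_y_um = numeric(0)))
  do.call(rbind, lapply(graph$segments, function(s) {
    mid <- s$path_um[ceiling(nrow(s$path_um) / 2), ]
    data.frame(id = s$id, node_a = s$node_a, node_b = s$node_b,
               lc_um = s$lc_um, l_um = s$l_um,
               diameter_um = s$diameter_um %||% NA_real_,
               n_px = nrow(s$pixels), mid_x_um = mid[1], mid_y_um = mid[2])
  }))
}
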