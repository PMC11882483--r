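#' Wrap angles into (-pi, pi]
#'
#' @param theta numeric vector of angles in radians.
#' @return angles wrapped into the interval (-pi, pi].
#' @export
wrap_angle <- function(theta) {
  w <- (theta + pi) %% (2 * pi) - pi
  # %% maps pi to -pi; keep the convention open at -pi, closed at pi
  w[w == -pi] <- pi
  w
}

#' Circular mean of a set of angles
#'
#' @param theta angles in radians.
#' @param w optional non-negative weights.
#' @return mean direction in (-pi, pi].
#' @export
circular_mean <- function(theta, w = NULL) {
  if (length(theta) == 0L) stop("cannot take the circular mean of zero angles")
  if (is.null(w)) w <- rep(1, length(theta))
  atan2(sum(w * sin(theta)), sum(w * cos(theta)))
}

# 8-connected component labeling of a logical matrix via the pixel adjacency
# graph (EBImage::bwlabel is 4-connected, which splits diagonal skeleton runs).
# Returns an integer matrix, 0 = background, components numbered from 1.
label_components <- function(mask) {
  mask <- mask != 0
  lab <- matrix(0L, nrow(mask), ncol(mask))
  idx <- which(mask)
  if (length(idx) == 0L) return(lab)
  H <- nrow(mask)
  pos <- match(idx, idx)  # 1..n in pixel order
  edges <- integer(0)
  for (off in c(-1L, H - 1L, H, H + 1L)) {  # N, NE(E-1), E, SE: half the 8-neighborhood
    nb <- idx + off
    row <- (idx - 1L) %% H + 1L
    ok <- nb >= 1L & nb <= length(mask)
    # forbid wrap-around across matrix columns
    if (off == -1L) ok <- ok & row > 1L
    if (off == H - 1L) ok <- ok & row > 1L
    if (off == H + 1L) ok <- ok & row < H
    nb_pos <- match(nb[ok], idx)
    keep <- !is.na(nb_pos)
    edges <- c(edges, rbind(pos[ok][keep], nb_pos[keep]))
  }
  g <- igraph::make_graph(edges = edges, n = length(idx), directed = FALSE)
  lab[idx] <- as.integer(igraph::components(g)$membership)
  lab
}

# Remove 8-connected components smaller than min_size pixels.
remove_small_components <- function(mask, min_size) {
  if (min_size <= 1L || !any(mask)) return(mask != 0)
  lab <- label_components(mask)
  keep <- which(tabulate(lab[lab > 0L]) >= min_size)
  matrix(lab %in% keep, nrow(mask), ncol(mask))
}

# Count of 8-neighbors that are TRUE, for each pixel of a logical matrix.
neighbor_count <- function(mask) {
  m <- matrix(0L, nrow(mask) + 2L, ncol(mask) + 2L)
  m[2:(nrow(mask) + 1L), 2:(ncol(mask) + 1L)] <- as.integer(mask != 0)
  H <- nrow(mask); W <- ncol(mask)
  out <- matrix(0L, H, W)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0L && dc == 0L) next
    out <- out + m[(2:(H + 1L)) + dr, (2:(W + 1L)) + dc]
  }
  out
}

# Deterministic per-stage child seed derived from the global seed, < 2^31.
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + h * 104729 + 1) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
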