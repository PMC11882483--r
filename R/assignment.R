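#' Solve the linear assignment problem (Hungarian / Jonker-Volgenant)
#'
#' Shortest-augmenting-path implementation with dual potentials, O(n^3), for
#' a square cost matrix. Forbidden pairings may be encoded as `Inf`; they are
#' replaced internally by a large finite cost and an assignment using one is
#' reported as unmatched by callers that pad the matrix accordingly.
#'
#' @param cost square numeric matrix; `Inf` allowed for forbidden pairs.
#' @return integer vector `a` with `a[i]` = column assigned to row `i`.
#' @export
solve_assignment <- function(cost) {
  n <- nrow(cost)
  stopifnot(ncol(cost) == n)
  if (n == 0L) return(integer(0))
  big <- max(cost[is.finite(cost)], 0) * n + 1
  cost[!is.finite(cost)] <- big * 2
  u <- numeric(n)
  v <- numeric(n + 1L)            # v[n+1] is the virtual column's potential
  p <- integer(n + 1L)            # p[j] = row matched to column j (0 = none)
  way <- integer(n)
  for (i in seq_len(n)) {
    p[n + 1L] <- i
    j0 <- n + 1L
    minv <- rep(Inf, n)
    used <- logical(n + 1L)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]
      free <- which(!used[seq_len(n)])
      cur <- cost[i0, free] - u[i0] - v[free]
      upd <- cur < minv[free]
      if (any(upd)) {
        minv[free[upd]] <- cur[upd]
        way[free[upd]] <- j0
      }
      jmin <- free[which.min(minv[free])]
      delta <- minv[jmin]
      usedj <- which(used)
      rows <- p[usedj]
      u[rows] <- u[rows] + delta
      v[usedj] <- v[usedj] - delta
      minv[free] <- minv[free] - delta
      j0 <- jmin
      if (p[j0] == 0L) break
    }
    # augment along the alternating tree
    repeat {
      j1 <- way[j0]
      p[j0] <- if (j1 == n + 1L) i else p[j1]
      if (j1 == n + 1L) break
      j0 <- j1
    }
  }
  a <- integer(n)
  a[p[seq_len(n)]] <- seq_len(n)
  a
}

#' Gated minimum-cost matching between two detection sets
#'
#' Builds the standard padded square matrix: matching a detection to a dummy
#' (birth/death) costs `gate_cost`, pairings beyond the gate are forbidden,
#' and the total cost (sum of matched costs plus `gate_cost` per unmatched
#' detection) is minimized by [solve_assignment()].
#'
#' @param cost `na x nb` matrix of pairing costs with `Inf` beyond the gate.
#' @param gate_cost cost of leaving one detection unmatched (the squared
#'   gate distance for squared-Euclidean costs).
#' @return integer vector of length `na`: matched column in `b` or `NA`.
#' @export
match_gated <- function(cost, gate_cost) {
  na <- nrow(cost); nb <- ncol(cost)
  if (na == 0L) return(integer(0))
  if (nb == 0L) return(rep(NA_integer_, na))
  n <- na + nb
  big <- Inf
  full <- matrix(big, n, n)
  full[seq_len(na), seq_len(nb)] <- cost
  for (i in seq_len(na)) full[i, nb + i] <- gate_cost       # a_i unmatched
  for (j in seq_len(nb)) full[na + j, j] <- gate_cost       # b_j unmatched
  full[(na + 1L):n, (nb + 1L):n] <- 0                       # dummy-dummy
  a <- solve_assignment(full)
  out <- rep(NA_integer_, na)
  for (i in seq_len(na)) {
    if (a[i] <= nb && is.finite(cost[i, a[i]])) out[i] <- a[i]
  }
  out
}
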