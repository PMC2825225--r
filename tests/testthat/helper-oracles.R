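# Independent oracles used against the package's own code paths.

# Floyd-Warshall all-pairs distances (deliberately not BFS-based).
fw_distances <- function(net) {
  n <- length(net$nodes)
  D <- matrix(Inf, n, n, dimnames = list(net$nodes, net$nodes))
  diag(D) <- 0
  for (r in seq_len(nrow(net$edges))) {
    i <- match(net$edges[r, 1L], net$nodes)
    j <- match(net$edges[r, 2L], net$nodes)
    D[i, j] <- D[j, i] <- 1
  }
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
      }
    }
  }
  D[is.infinite(D)] <- NA
  storage.mode(D) <- "integer"
  D
}

# Full cost recomputation in plain R.
full_cost_r <- function(coords, W) {
  n <- nrow(coords)
  total <- 0
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      d <- abs(coords[i, 1L] - coords[j, 1L]) + abs(coords[i, 2L] - coords[j, 2L])
      total <- total + W[i, j] * d
    }
  }
  unname(total)
}

moore_offsets <- cbind(dx = c(0, 1, 1, 1, 0, -1, -1, -1),
                       dy = c(1, 1, 0, -1, -1, -1, 0, 1))

# Exhaustive single-move local-minimum certificate by full recomputation.
is_single_move_local_min <- function(layout, W) {
  co <- layout$coords
  n <- nrow(co)
  base <- full_cost_r(co, W)
  occupied <- paste(co[, 1L], co[, 2L])
  for (i in seq_len(n)) {
    for (t in seq_len(8L)) {
      nx <- co[i, 1L] + moore_offsets[t, 1L]
      ny <- co[i, 2L] + moore_offsets[t, 2L]
      if (nx < 0 || nx >= layout$width || ny < 0 || ny >= layout$height) next
      if (paste(nx, ny) %in% occupied) next
      cand <- co
      cand[i, ] <- c(nx, ny)
      if (full_cost_r(cand, W) < base) return(FALSE)
    }
  }
  TRUE
}

# Exhaustive enumeration of all placements of n nodes on a small grid,
# returning the global minimum cost.
enumerate_min_cost <- function(W, width, height) {
  n <- nrow(W)
  cells <- as.matrix(expand.grid(x = 0:(width - 1L), y = 0:(height - 1L)))
  best <- Inf
  place <- integer(n)
  recurse <- function(depth, used) {
    for (c_idx in seq_len(nrow(cells))) {
      if (used[c_idx]) next
      place[depth] <<- c_idx
      if (depth == n) {
        cost <- full_cost_r(cells[place, , drop = FALSE], W)
        if (cost < best) best <<- cost
      } else {
        used[c_idx] <- TRUE
        recurse(depth + 1L, used)
        used[c_idx] <- FALSE
      }
    }
  }
  recurse(1L, logical(nrow(cells)))
  best
}

# Erdos-Renyi test network with optional extra isolated nodes.
random_network <- function(n, p = 0.3, isolated = 0L) {
  ids <- sprintf("v%02d", seq_len(n + isolated))
  pair <- which(upper.tri(matrix(0L, n, n)), arr.ind = TRUE)
  keep <- stats::runif(nrow(pair)) < p
  netgrid_network(cbind(ids[pair[keep, 1L]], ids[pair[keep, 2L]]),
                  nodes = ids)
}

layout_invariants_hold <- function(layout) {
  co <- layout$coords
  all(co[, 1L] >= 0L, co[, 1L] < layout$width,
      co[, 2L] >= 0L, co[, 2L] < layout$height) &&
    !anyDuplicated(co[, 2L] * layout$width + co[, 1L])
}
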