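# Brute-force oracles, deliberately independent of the implementation paths
# they check.

# Largest connected node set by breadth-first flood fill over a raw edge
# list (character labels).  Ties broken towards the component containing
# the earliest label in `nodes`.
oracle_largest_component <- function(nodes, el) {
  adj <- split(c(el[, 2], el[, 1]), c(el[, 1], el[, 2]))
  seen <- character(0)
  best <- character(0)
  for (start in nodes) {
    if (start %in% seen) next
    comp <- start
    frontier <- start
    while (length(frontier) > 0) {
      nxt <- setdiff(unique(unlist(adj[frontier], use.names = FALSE)), comp)
      comp <- c(comp, nxt)
      frontier <- nxt
    }
    seen <- c(seen, comp)
    if (length(comp) > length(best)) best <- comp
  }
  sort(best)
}

# Pairwise intersection sizes of membership sets: the projection oracle.
oracle_projection <- function(memberships) {
  sets <- split(memberships$group, memberships$primary)
  prim <- names(sets)
  out <- list()
  if (length(prim) >= 2) {
    for (a in seq_len(length(prim) - 1)) {
      for (b in seq(a + 1, length(prim))) {
        shared <- length(intersect(sets[[prim[a]]], sets[[prim[b]]]))
        if (shared > 0) {
          out[[length(out) + 1]] <- data.frame(
            i = prim[a], j = prim[b], w = shared)
        }
      }
    }
  }
  if (length(out) == 0) return(data.frame(i = character(), j = character(), w = numeric()))
  do.call(rbind, out)
}

# Spearman by explicit average-rank-then-Pearson arithmetic.
oracle_rank <- function(x) {
  o <- order(x)
  r <- numeric(length(x))
  r[o] <- seq_along(x)
  for (ux in unique(x)) {
    idx <- which(x == ux)
    if (length(idx) > 1) r[idx] <- mean(r[idx])
  }
  r
}

oracle_spearman <- function(x, y) {
  a <- oracle_rank(x) - mean(oracle_rank(x))
  b <- oracle_rank(y) - mean(oracle_rank(y))
  sum(a * b) / sqrt(sum(a^2) * sum(b^2))
}

# Per-sample linear scan over all bins; half-open [lo, hi), top bin closed.
oracle_bin_counts <- function(x, y, x_edges, y_edges) {
  nx <- length(x_edges) - 1
  ny <- length(y_edges) - 1
  counts <- matrix(0L, nx, ny)
  locate <- function(val, edges, nb) {
    for (b in seq_len(nb)) {
      hi_ok <- if (b == nb) val <= edges[b + 1] else val < edges[b + 1]
      if (val >= edges[b] && hi_ok) return(b)
    }
    NA_integer_
  }
  for (s in seq_along(x)) {
    bx <- locate(x[s], x_edges, nx)
    by <- locate(y[s], y_edges, ny)
    if (!is.na(bx) && !is.na(by)) counts[bx, by] <- counts[bx, by] + 1L
  }
  counts
}

# Random weighted test networks (largest component of a G(n, p) draw with
# weights drawn as small integers, like co-occurrence counts).
random_weighted_graph <- function(n, p, seed, max_w = 20) {
  g <- tieprof:::with_seed(seed, {
    g <- igraph::sample_gnp(n, p)
    igraph::E(g)$weight <- sample.int(max_w, igraph::ecount(g), replace = TRUE)
    g
  })
  igraph::V(g)$name <- as.character(seq_len(igraph::vcount(g)))
  largest_component(g)
}

# The two connected-pair configurations used throughout the docs: nodes l
# and r joined by an edge, sharing `shared` neighbours, padded with private
# neighbours to reach the requested degrees.
two_node_configuration <- function(k_l, k_r, shared) {
  stopifnot(shared <= min(k_l, k_r) - 1)
  com <- if (shared > 0) paste0("c", seq_len(shared)) else character(0)
  pl <- k_l - 1 - shared
  pr <- k_r - 1 - shared
  edges <- rbind(
    data.frame(src = "l", dst = "r"),
    if (shared > 0) data.frame(src = rep(c("l", "r"), each = shared),
                               dst = rep(com, 2)),
    if (pl > 0) data.frame(src = "l", dst = paste0("xl", seq_len(pl))),
    if (pr > 0) data.frame(src = "r", dst = paste0("xr", seq_len(pr)))
  )
  edges$weight <- 1
  weighted_network(edges)
}
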