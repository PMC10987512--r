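# Canonical edge order: sort undirected edges by (low endpoint, high
# endpoint) internal index.  Shuffles permute the weight multiset in this
# order so the realization depends only on (topology, seed), not on the
# order edges happened to be inserted.
canonical_edge_order <- function(g) {
  el <- igraph::as_edgelist(g, names = FALSE)
  order(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2]))
}

#' Shuffle edge weights, keeping topology fixed
#'
#' Draws a uniformly random permutation of the observed weight multiset
#' over the (canonically ordered) edge list. Degrees, common-neighbour
#' counts and hence all overlaps are untouched; node strengths generally
#' change. This is the elementary move of the null model: any correlation
#' between weight and topology that survives shuffling is structural, not a
#' property of where the weights were placed.
#'
#' @param g a weighted network with at least one edge.
#' @param seed integer seed; `NULL` uses the current RNG stream.
#' @return the same network with permuted weights.
#' @export
shuffle_weights <- function(g, seed = NULL) {
  validate_network(g)
  ne <- igraph::ecount(g)
  if (ne < 1) stop_empty("network has no edges to shuffle")
  ord <- canonical_edge_order(g)
  w <- igraph::E(g)$weight[ord]
  perm <- with_seed(seed, sample.int(ne))
  wshuf <- numeric(ne)
  wshuf[ord] <- w[perm]
  igraph::set_edge_attr(g, "weight", value = wshuf)
}

#' Build a seeded null-model ensemble
#'
#' A `null_ensemble` is a recipe for `realizations` weight-shuffled copies
#' of one network. Realizations are generated lazily by [realization()]
#' and are a pure function of `(base_seed, index)`: the base seed is
#' expanded into one sub-seed per realization, so realization `r` is
#' reproducible in isolation.
#'
#' @param g the observed weighted network.
#' @param realizations number of shuffled copies (default 100).
#' @param base_seed integer seed for the whole ensemble.
#' @return an object of class `null_ensemble`.
#' @export
build_ensemble <- function(g, realizations = 100, base_seed = 1L) {
  validate_network(g)
  if (realizations < 1) stop_validation("need at least one realization")
  seeds <- with_seed(base_seed, sample.int(.Machine$integer.max - 1L, realizations))
  structure(
    list(network = g, realizations = as.integer(realizations),
         base_seed = as.integer(base_seed), seeds = seeds),
    class = "null_ensemble"
  )
}

#' Materialise one realization of a null ensemble
#'
#' @param ensemble a `null_ensemble`.
#' @param r realization index in `1:realizations`.
#' @return the reference network with that realization's shuffled weights.
#' @export
realization <- function(ensemble, r) {
  stopifnot(inherits(ensemble, "null_ensemble"))
  if (r < 1 || r > ensemble$realizations) stop_validation("realization index out of range")
  shuffle_weights(ensemble$network, seed = ensemble$seeds[[r]])
}

# Weight vector (in igraph edge order) of realization r, without building
# the graph object; used by the profile code, which only needs weights.
realization_weights <- function(ensemble, r) {
  g <- ensemble$network
  ord <- canonical_edge_order(g)
  w <- igraph::E(g)$weight[ord]
  perm <- with_seed(ensemble$seeds[[r]], sample.int(length(w)))
  out <- numeric(length(w))
  out[ord] <- w[perm]
  out
}

#' @export
print.null_ensemble <- function(x, ...) {
  cat("Null ensemble: ", x$realizations, " weight-shuffled realizations\n",
      "  reference network: ", igraph::vcount(x$network), " nodes, ",
      igraph::ecount(x$network), " edges\n",
      "  base seed: ", x$base_seed, "\n", sep = "")
  invisible(x)
}
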