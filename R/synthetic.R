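#' Two cliques joined by a single bridge
#'
#' The textbook weak-ties configuration: two fully connected clusters of
#' `n` nodes each, every within-cluster tie strong, plus one weak bridge
#' between the clusters. The bridge endpoints share no neighbours (overlap
#' 0) while deep-clique edges have overlap 1, so the network has a perfect
#' weight-overlap coupling by construction.
#'
#' @param n clique size (>= 3).
#' @param w_strong intra-clique weight.
#' @param w_weak bridge weight; must satisfy `w_strong > w_weak > 0`.
#' @return a weighted network with `2n` nodes and `n(n-1) + 1` edges.
#' @export
two_clique_toy <- function(n, w_strong = 5, w_weak = 1) {
  if (n < 3) stop_validation("clique size must be at least 3")
  if (!(w_strong > w_weak && w_weak > 0)) {
    stop_validation("need w_strong > w_weak > 0")
  }
  pairs <- t(utils::combn(n, 2))
  edges <- data.frame(
    src = c(pairs[, 1], pairs[, 1] + n, n),
    dst = c(pairs[, 2], pairs[, 2] + n, n + 1),
    weight = c(rep(w_strong, 2 * nrow(pairs)), w_weak)
  )
  weighted_network(edges)
}

#' Network with a planted weight-overlap coupling
#'
#' Generates a topology from the requested family and then assigns integer
#' weights coupled to the symmetric overlap of each edge:
#' `w = ceiling(c * (O + eps0)^beta * eta)`, with `eta` a log-normal noise
#' multiplier and `c = scale / mean((O + eps0)^beta)` a normalising
#' constant that keeps the typical weight at `scale` for every `beta`. `beta = 0` decouples weights from topology entirely
#' (pure noise — the null model's own world); larger `beta` plants a
#' progressively stronger "stronger ties inside denser neighbourhoods"
#' signal. The coupling acts on the symmetric overlap `O`, a property of
#' the tie rather than of either directed view. Weights are integers
#' (ceiling), like co-occurrence counts.
#'
#' @param n node count.
#' @param family `"scale-free"` (preferential attachment, the
#'   heterogeneous-degree regime), `"random"` (Erdos-Renyi, restricted to
#'   its largest component) or `"two-clique"` (two `n/2`-cliques plus a
#'   bridge).
#' @param beta coupling exponent (>= 0).
#' @param noise_sd log-scale standard deviation of the noise multiplier.
#' @param eps0 overlap offset so zero-overlap edges still draw positive
#'   weights.
#' @param scale weight scale before the ceiling.
#' @param pa_m edges attached per step in the scale-free family (mean
#'   degree about `2 * pa_m`).
#' @param gnp_p edge probability of the random family; default gives mean
#'   degree `2 * pa_m`.
#' @param seed integer seed; the same spec and seed reproduce the network
#'   exactly.
#' @return a weighted network.
#' @export
planted_granovetter <- function(n = 1000,
                                family = c("scale-free", "random", "two-clique"),
                                beta = 1, noise_sd = 0.5, eps0 = 0.01,
                                scale = 50, pa_m = 5, gnp_p = NULL,
                                seed = NULL) {
  family <- match.arg(family)
  if (beta < 0) stop_validation("beta must be nonnegative")
  with_seed(seed, {
    g <- switch(family,
      "scale-free" = igraph::sample_pa(n, m = pa_m, directed = FALSE),
      "random" = largest_component(
        igraph::sample_gnp(n, gnp_p %||% min(1, 2 * pa_m / (n - 1)))),
      "two-clique" = two_clique_toy(max(3, n %/% 2))
    )
    igraph::V(g)$name <- as.character(seq_len(igraph::vcount(g)))
    el <- igraph::as_edgelist(g, names = FALSE)
    A <- igraph::as_adjacency_matrix(g, sparse = TRUE)
    if (!is.null(igraph::E(g)$weight)) A@x[] <- 1
    n_e <- as.numeric((A %*% A)[cbind(el[, 1], el[, 2])])
    deg <- igraph::degree(g)
    O <- symmetric_overlap(n_e, deg[el[, 1]], deg[el[, 2]])
    eta <- rlnorm(nrow(el), 0, noise_sd)
    # coupling kernel normalised to unit mean so `scale` sets the typical
    # weight for every beta; otherwise large beta would crush all weights
    # onto the integer floor and erase the planted signal
    kern <- (O + eps0)^beta
    w <- ceiling(scale * kern / mean(kern) * eta)
    igraph::set_edge_attr(g, "weight", value = pmax(w, 1))
  })
}

#' Random bipartite membership graph
#'
#' Each (primary node, group) membership is present independently with
#' probability `p` — the bipartite analogue of an Erdos-Renyi graph.
#' Isolated primary nodes are permitted. Useful as a no-sociology control
#' for projections: any weight-overlap relation its projection shows is
#' produced by the projection itself.
#'
#' @param n_primary,n_groups side sizes.
#' @param p membership probability in (0, 1].
#' @param seed integer seed.
#' @return a bipartite network (see [bipartite_network()]).
#' @export
random_bipartite <- function(n_primary, n_groups, p, seed = NULL) {
  if (n_primary < 1 || n_groups < 1) stop_validation("side sizes must be >= 1")
  if (!(p > 0 && p <= 1)) stop_validation("membership probability must be in (0, 1]")
  with_seed(seed, {
    inc <- matrix(rbinom(n_primary * n_groups, 1, p), n_primary, n_groups)
    idx <- which(inc == 1, arr.ind = TRUE)
    memberships <- data.frame(primary = paste0("p", idx[, 1]),
                              group = paste0("g", idx[, 2]))
    all_nodes <- data.frame(
      name = c(paste0("p", seq_len(n_primary)), paste0("g", seq_len(n_groups))),
      type = c(rep(FALSE, n_primary), rep(TRUE, n_groups))
    )
    igraph::graph_from_data_frame(memberships, directed = FALSE,
                                  vertices = all_nodes)
  })
}
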