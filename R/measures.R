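#' Number of common neighbours of two connected nodes
#'
#' Counts `|N(i) intersect N(j)|` on the binary (unweighted) adjacency;
#' endpoints are never counted because the graph is simple. Internally the
#' count is the `(i, j)` entry of the squared adjacency matrix.
#'
#' @param g a weighted network.
#' @param i,j node labels (or vertex indices).
#' @return integer count `n_ij`.
#' @export
common_neighbors <- function(g, i, j) {
  vi <- tryCatch(igraph::V(g)[i], error = function(e) NULL)
  vj <- tryCatch(igraph::V(g)[j], error = function(e) NULL)
  if (is.null(vi) || is.null(vj)) stop_validation("unknown node label")
  if (as.integer(vi) == as.integer(vj)) stop_validation("common_neighbors needs two distinct nodes")
  length(intersect(igraph::neighbors(g, vi), igraph::neighbors(g, vj)))
}

#' Symmetric neighbourhood overlap
#'
#' `O_ij = n_ij / ((k_i - 1) + (k_j - 1) - n_ij)`: the Jaccard-like fraction
#' of shared neighbours among all neighbours of either endpoint other than
#' the endpoints themselves. Symmetric in i and j, bounded in \[0, 1\].
#' When the denominator is zero (two connected degree-1 nodes, forcing
#' `n = 0`) the overlap is 0.
#'
#' @param n common-neighbour count(s).
#' @param k_i,k_j endpoint degrees.
#' @return overlap value(s) in \[0, 1\]; vectorised.
#' @examples
#' symmetric_overlap(2, 4, 4)   # 0.5
#' symmetric_overlap(2, 4, 16)  # 0.125
#' @export
symmetric_overlap <- function(n, k_i, k_j) {
  check_overlap_args(n, k_i, k_j)
  denom <- (k_i - 1) + (k_j - 1) - n
  ifelse(denom == 0, 0, n / denom)
}

#' Asymmetric neighbourhood overlap
#'
#' `Q_ij = n_ij / (k_i - 1)`: the shared neighbours as a fraction of the
#' source node's other neighbours. Each directed view of an edge gets its
#' own value, so `Q_ij != Q_ji` in general. For a degree-1 source the
#' measure is undefined (division by zero) and `NA` is returned; downstream
#' profile and correlation code excludes such samples and reports the
#' excluded fraction.
#'
#' @param n common-neighbour count(s).
#' @param k_i source-node degree(s).
#' @return value(s) in \[0, 1\], `NA` where `k_i == 1`; vectorised.
#' @examples
#' asymmetric_overlap(2, 4)   # 2/3
#' asymmetric_overlap(2, 16)  # 2/15
#' @export
asymmetric_overlap <- function(n, k_i) {
  check_overlap_args(n, k_i, k_i)
  ifelse(k_i == 1, NA_real_, n / (k_i - 1))
}

check_overlap_args <- function(n, k_i, k_j) {
  if (any(n < 0) || any(k_i < 1) || any(k_j < 1)) {
    stop_validation("need n >= 0 and degrees >= 1")
  }
  both <- k_i > 1 & k_j > 1
  if (any(n[both] > pmin(k_i[both], k_j[both]) - 1)) {
    stop_validation("n exceeds min(k_i, k_j) - 1: impossible on a simple graph")
  }
  invisible(NULL)
}

#' Asymmetric weight, strength-normalised
#'
#' `v_ij = w_ij / s_i` with `s_i = sum_j w_ij` the source node's strength.
#' Values lie in (0, 1\] and sum to 1 over each node's incident edges.
#' This is the package's default asymmetric weight: it applies uniformly to
#' any weighted network, including symmetrised directed ones.
#'
#' @param w symmetric edge weight(s).
#' @param s_i source-node strength(s); must be at least `w`.
#' @return value(s) in (0, 1\]; vectorised.
#' @export
asymmetric_weight_strength <- function(w, s_i) {
  if (any(w <= 0)) stop_validation("weights must be positive")
  if (any(s_i < w)) stop_validation("strength below edge weight: s_i must include w_ij")
  w / s_i
}

#' Asymmetric weight, membership-normalised (bipartite networks)
#'
#' `v_ij = w_ij / m_i` where `m_i` is the source node's number of group
#' memberships in the bipartite representation (papers published, films
#' appeared in, reactions joined). Since two nodes cannot co-occur more
#' often than either participates, `w <= m_i` and the value lies in
#' (0, 1\].
#'
#' @param w co-occurrence weight(s).
#' @param m_i source-node membership count(s).
#' @return value(s) in (0, 1\]; vectorised.
#' @export
asymmetric_weight_bipartite <- function(w, m_i) {
  if (any(w <= 0)) stop_validation("weights must be positive")
  if (any(m_i < w)) stop_validation("membership count below shared count: impossible projection")
  w / m_i
}

#' Enumerate directed edge samples with all tie measures
#'
#' Every undirected edge yields two samples, one per direction. Each sample
#' carries the topological quantities (common-neighbour count `n`, degrees
#' `k_i`, `k_j`), the weights (`w`, source strength `s_i`, membership count
#' `m_i` where available) and the derived measures: symmetric overlap `O`
#' (identical in the two views of an edge), asymmetric overlap `Q` (`NA`
#' when the source has degree 1) and asymmetric weight `v` (`w/s_i` or
#' `w/m_i` depending on `weight_mode`). Undefined values are flagged as
#' `NA`, never dropped here.
#'
#' @param g a weighted network.
#' @param weight_mode `"strength"` (default, `v = w/s_i`) or `"bipartite"`
#'   (`v = w/m_i`; requires the `m` vertex attribute set by
#'   [project_bipartite()]).
#' @return data.frame with one row per directed sample: columns `i`, `j`,
#'   `n`, `k_i`, `k_j`, `w`, `s_i`, `m_i`, `O`, `Q`, `v` and `edge` (the
#'   undirected edge id shared by the two views).
#' @export
edge_samples <- function(g, weight_mode = c("strength", "bipartite")) {
  weight_mode <- match.arg(weight_mode)
  validate_network(g)
  if (igraph::is_directed(g)) stop_config("edge_samples() expects an undirected network")
  if (igraph::ecount(g) == 0) stop_empty("network has no edges")

  el <- igraph::as_edgelist(g, names = FALSE)
  w <- igraph::E(g)$weight
  A <- igraph::as_adjacency_matrix(g, sparse = TRUE)
  n_e <- as.numeric((A %*% A)[cbind(el[, 1], el[, 2])])
  deg <- igraph::degree(g)
  s <- igraph::strength(g)
  labs <- igraph::V(g)$name %||% as.character(seq_len(igraph::vcount(g)))
  m <- igraph::V(g)$m
  if (weight_mode == "bipartite" && (is.null(m) || anyNA(m))) {
    stop_config("weight_mode = 'bipartite' needs the m vertex attribute on every node")
  }

  src <- c(el[, 1], el[, 2])
  dst <- c(el[, 2], el[, 1])
  n2 <- rep(n_e, 2)
  w2 <- rep(w, 2)
  v <- if (weight_mode == "strength") {
    asymmetric_weight_strength(w2, s[src])
  } else {
    asymmetric_weight_bipartite(w2, m[src])
  }
  data.frame(
    i = labs[src], j = labs[dst],
    n = n2, k_i = deg[src], k_j = deg[dst],
    w = w2, s_i = s[src],
    m_i = if (is.null(m)) NA_real_ else m[src],
    O = symmetric_overlap(n2, deg[src], deg[dst]),
    Q = asymmetric_overlap(n2, deg[src]),
    v = v,
    edge = rep(seq_along(w), 2),
    row.names = NULL
  )
}

#' Write an edge-sample table as TSV
#'
#' @param samples result of [edge_samples()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_edge_samples <- function(samples, path) {
  write.table(samples, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
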