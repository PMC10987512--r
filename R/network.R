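#' Build a weighted undirected network from an edge table
#'
#' The package's central object is a simple undirected [igraph] graph with a
#' positive `weight` attribute on every edge. This constructor takes an edge
#' table (three columns: source label, target label, weight), drops
#' self-loops, merges duplicate edges by summing their weights, and
#' validates the result. Duplicate merging by summation matches the
#' co-occurrence interpretation of weights (two records of the same pair add
#' up).
#'
#' @param edges data.frame-like with columns source, target, weight
#'   (weight optional, defaults to 1).
#' @param directed build a directed network (weights are the per-direction
#'   weights `V_ij`; duplicates of the same ordered pair are summed).
#' @return an igraph graph with `E(g)$weight`; undirected unless `directed`.
#' @examples
#' g <- weighted_network(data.frame(i = c("a", "b", "a"),
#'                                  j = c("b", "c", "c"),
#'                                  w = c(2, 1, 1)))
#' igraph::ecount(g)
#' @export
weighted_network <- function(edges, directed = FALSE) {
  edges <- as.data.frame(edges)
  if (ncol(edges) == 2) edges$weight <- 1
  if (ncol(edges) < 3) stop_validation("edge table needs source, target[, weight] columns")
  names(edges)[1:3] <- c("src", "dst", "weight")
  edges$src <- as.character(edges$src)
  edges$dst <- as.character(edges$dst)
  edges$weight <- as.numeric(edges$weight)
  if (anyNA(edges$weight)) stop_validation("non-numeric edge weight")
  if (any(edges$weight <= 0)) stop_validation("all edge weights must be positive")

  loops <- edges$src == edges$dst
  if (any(loops)) {
    message(sum(loops), " self-loop(s) dropped")
    edges <- edges[!loops, , drop = FALSE]
  }
  if (nrow(edges) == 0) stop_empty("no edges after removing self-loops")

  key <- if (directed) {
    paste(edges$src, edges$dst, sep = "\r")
  } else {
    paste(pmin(edges$src, edges$dst), pmax(edges$src, edges$dst), sep = "\r")
  }
  if (anyDuplicated(key)) {
    message(sum(duplicated(key)), " duplicate edge record(s) merged by summing weights")
    w <- rowsum(edges$weight, key)
    first <- !duplicated(key)
    edges <- edges[first, , drop = FALSE]
    edges$weight <- w[match(key[first], rownames(w)), 1]
  }

  g <- igraph::graph_from_data_frame(edges, directed = directed)
  validate_network(g)
  g
}

#' Validate a network object
#'
#' Checks the invariants every network in this package must satisfy:
#' a simple graph (no self-loops, no parallel edges) with a strictly
#' positive `weight` on every edge. For undirected networks this also
#' guarantees the bookkeeping identity that the node strengths sum to twice
#' the total edge weight.
#'
#' @param g an igraph graph.
#' @return `g`, invisibly; throws a validation error otherwise.
#' @export
validate_network <- function(g) {
  if (!igraph::is_igraph(g)) stop_validation("not an igraph object")
  if (any(igraph::which_loop(g))) stop_validation("network contains self-loops")
  if (any(igraph::which_multiple(g))) stop_validation("network contains parallel edges")
  w <- igraph::E(g)$weight
  if (igraph::ecount(g) > 0 && (is.null(w) || any(!is.finite(w)) || any(w <= 0))) {
    stop_validation("every edge must carry a finite positive weight")
  }
  invisible(g)
}

#' Read a network from an edge-list file
#'
#' Supported dialects:
#' \describe{
#'   \item{`edgelist`}{whitespace-separated `src dst [weight]`; missing
#'     weight means 1; lines starting with `#` or `%` are comments.}
#'   \item{`konect`}{konect `out.*` files: `%` comments; 2 columns imply
#'     weight 1; a 3rd column is the weight; a 4th (timestamp) is ignored.}
#'   \item{`bipartite`}{two columns `primary_node group_node`; returns a
#'     bipartite membership graph (see [project_bipartite()]).}
#' }
#' Self-loops are dropped and duplicate edges merged by summing weights,
#' with counts reported via [message()].
#'
#' @param path file path.
#' @param format one of `"edgelist"`, `"konect"`, `"bipartite"`.
#' @param directed read as a directed network (ignored for bipartite).
#' @return an igraph graph; bipartite graphs carry a logical `type` vertex
#'   attribute (`FALSE` = primary node, `TRUE` = group node).
#' @export
load_network <- function(path, format = c("edgelist", "konect", "bipartite"),
                         directed = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_config(paste0("input file not found: ", path))
  lines <- readLines(path, warn = FALSE)
  comment_chars <- if (format == "konect") "%" else c("#", "%")

  rows <- vector("list", length(lines))
  for (ln in seq_along(lines)) {
    line <- trimws(lines[[ln]])
    if (!nzchar(line) || substr(line, 1, 1) %in% comment_chars) next
    tok <- strsplit(line, "[ \t]+")[[1]]
    if (length(tok) < 2) {
      stop_parse(paste0("line ", ln, ": expected at least 2 fields, got ", length(tok)))
    }
    if (format == "bipartite") {
      rows[[ln]] <- data.frame(src = tok[1], dst = tok[2], weight = 1)
    } else {
      w <- if (length(tok) >= 3) suppressWarnings(as.numeric(tok[3])) else 1
      if (is.na(w)) stop_parse(paste0("line ", ln, ": non-numeric weight '", tok[3], "'"))
      if (w <= 0) stop_validation(paste0("line ", ln, ": non-positive weight ", w))
      rows[[ln]] <- data.frame(src = tok[1], dst = tok[2], weight = w)
    }
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0) stop_empty(paste0("no edges in ", path))
  edges <- do.call(rbind, rows)

  if (format == "bipartite") {
    return(bipartite_network(edges[, c("src", "dst")]))
  }
  weighted_network(edges, directed = directed)
}

#' Build a bipartite membership network
#'
#' @param memberships data.frame with columns primary node, group node.
#'   Duplicate membership records are dropped.
#' @return an igraph bipartite graph; `V(g)$type` is `FALSE` for primary
#'   nodes and `TRUE` for group nodes.
#' @export
bipartite_network <- function(memberships) {
  memberships <- as.data.frame(memberships)
  names(memberships)[1:2] <- c("primary", "group")
  memberships$primary <- as.character(memberships$primary)
  memberships$group <- as.character(memberships$group)
  dup <- duplicated(paste(memberships$primary, memberships$group, sep = "\r"))
  if (any(dup)) {
    message(sum(dup), " duplicate membership record(s) dropped")
    memberships <- memberships[!dup, , drop = FALSE]
  }
  primaries <- unique(memberships$primary)
  groups <- unique(memberships$group)
  clash <- intersect(primaries, groups)
  if (length(clash) > 0) {
    stop_validation(paste0("label(s) appear as both primary and group node: ",
                           paste(utils::head(clash, 3), collapse = ", ")))
  }
  g <- igraph::graph_from_data_frame(
    memberships,
    directed = FALSE,
    vertices = data.frame(name = c(primaries, groups),
                          type = c(rep(FALSE, length(primaries)),
                                   rep(TRUE, length(groups))))
  )
  g
}

#' Symmetrise a directed weighted network
#'
#' Converts each reciprocal pair of directed weights into one undirected
#' edge with weight `(V_ij + V_ji) / 2`. An edge present in only one
#' direction contributes with the missing direction counted as zero, so the
#' undirected edge exists whenever either direction does.
#'
#' @param g a directed igraph graph with `E(g)$weight`.
#' @return an undirected weighted network.
#' @examples
#' d <- weighted_network(data.frame(i = c("a", "b"), j = c("b", "a"),
#'                                  w = c(3, 1)), directed = TRUE)
#' igraph::E(symmetrize(d))$weight  # 2
#' @export
symmetrize <- function(g) {
  if (!igraph::is_directed(g)) stop_config("symmetrize() expects a directed network")
  validate_network(g)
  el <- igraph::as_edgelist(g, names = TRUE)
  key <- paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2]), sep = "\r")
  half <- rowsum(igraph::E(g)$weight / 2, key)
  first <- !duplicated(key)
  edges <- data.frame(src = pmin(el[, 1], el[, 2])[first],
                      dst = pmax(el[, 1], el[, 2])[first],
                      weight = half[match(key[first], rownames(half)), 1])
  weighted_network(edges)
}

#' Project a bipartite membership network onto its primary nodes
#'
#' Two primary nodes are connected when they share at least one group; the
#' edge weight is the number of shared groups (the co-occurrence count).
#' Each primary node keeps its membership count as vertex attribute `m`
#' (its degree in the bipartite graph), which feeds the bipartite
#' asymmetric-weight definition `v_ij = w_ij / m_i`.
#'
#' @param g a bipartite graph from [load_network()] / [bipartite_network()].
#' @return an undirected weighted network over the primary nodes, with
#'   `V(g)$m` set.
#' @export
project_bipartite <- function(g) {
  if (is.null(igraph::V(g)$type)) stop_config("not a bipartite network (no type attribute)")
  proj <- igraph::bipartite_projection(g, multiplicity = TRUE, which = "false")
  if (igraph::ecount(proj) == 0) stop_empty("projection has no edges (no group shared by 2 primary nodes)")
  m <- igraph::degree(g)[!igraph::V(g)$type]
  igraph::V(proj)$m <- as.numeric(m[match(igraph::V(proj)$name, names(m))])
  validate_network(proj)
  proj
}

#' Restrict a network to its largest connected component
#'
#' Ties between equally large components are broken towards the component
#' containing the lowest-index vertex, so the result is deterministic.
#'
#' @param g a network.
#' @return the induced subgraph on the largest component (vertex attributes
#'   such as `m` are retained).
#' @export
largest_component <- function(g) {
  if (igraph::vcount(g) == 0) stop_empty("empty network")
  comps <- igraph::components(g)
  biggest <- which(comps$csize == max(comps$csize))
  pick <- biggest[which.min(vapply(biggest, function(cid) min(which(comps$membership == cid)), 1))]
  igraph::induced_subgraph(g, which(comps$membership == pick))
}

#' Write a network as a TSV edge list
#'
#' @param g a weighted network.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_edgelist <- function(g, path) {
  el <- igraph::as_edgelist(g, names = TRUE)
  df <- data.frame(src = el[, 1], dst = el[, 2], weight = igraph::E(g)$weight)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
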