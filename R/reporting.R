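# Matrix writer with bin-edge headers: output stays inspectable without
# the package.
write_grid_tsv <- function(mat, x_edges, y_edges, what, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste0("# ", what, "; rows = weight bins, cols = overlap bins"),
    paste0("# x_edges\t", paste(format(x_edges, digits = 10), collapse = "\t")),
    paste0("# y_edges\t", paste(format(y_edges, digits = 10), collapse = "\t"))
  ), con)
  write.table(mat, con, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Run the full profiling pipeline and write its outputs
#'
#' Loads a network, applies the requested preprocessing (symmetrisation for
#' directed input, bipartite projection, largest-component restriction),
#' builds the null ensemble, and writes the correlation profile, trend
#' curve, rank-correlation summary and a JSON run manifest. The manifest
#' records every input, mode, seed and exclusion tally needed to reproduce
#' the numeric outputs bit for bit.
#'
#' @param input path to the input file.
#' @param format input dialect, see [load_network()].
#' @param out_prefix prefix for output files
#'   (`<prefix>_{counts,R,Z,trend}.tsv`, `<prefix>_summary.txt`,
#'   `<prefix>_manifest.json`).
#' @param directed input is a directed edge list (symmetrised before
#'   measuring).
#' @param measure,weight_def,bins_x,bins_y,realizations,seed passed to
#'   [correlation_profile()]. `weight_def` defaults to `"bipartite"` for
#'   bipartite input and `"strength"` otherwise.
#' @param lcc restrict to the largest connected component (default TRUE).
#' @return invisibly, a list with the profile, summary and output paths.
#' @export
run_profile <- function(input, format = c("edgelist", "konect", "bipartite"),
                        out_prefix, directed = FALSE,
                        measure = c("asymmetric", "symmetric"),
                        weight_def = NULL,
                        bins_x = 25, bins_y = 25,
                        realizations = 100, seed = 1L, lcc = TRUE) {
  format <- match.arg(format)
  measure <- match.arg(measure)
  if (format != "bipartite" && identical(weight_def, "bipartite")) {
    stop_config("weight_def = 'bipartite' requires bipartite input")
  }
  weight_def <- weight_def %||% if (format == "bipartite") "bipartite" else "strength"

  g <- load_network(input, format, directed = directed)
  steps <- character(0)
  if (format == "bipartite") {
    g <- project_bipartite(g)
    steps <- c(steps, "projected")
  }
  if (igraph::is_directed(g)) {
    g <- symmetrize(g)
    steps <- c(steps, "symmetrized")
  }
  if (lcc) {
    g <- largest_component(g)
    steps <- c(steps, "largest_component")
  }

  ensemble <- build_ensemble(g, realizations, seed)
  prof <- correlation_profile(g, ensemble, measure = measure,
                              weight_def = weight_def,
                              bins_x = bins_x, bins_y = bins_y)
  summ <- correlation_summary(g, ensemble, measure = measure,
                              weight_def = weight_def)
  trend <- trend_curve(prof)

  paths <- paste0(out_prefix, c("_counts.tsv", "_R.tsv", "_Z.tsv",
                                "_trend.tsv", "_summary.txt",
                                "_manifest.json"))
  names(paths) <- c("counts", "R", "Z", "trend", "summary", "manifest")
  write_grid_tsv(prof$N, prof$x_edges, prof$y_edges, "observed counts N(p)",
                 paths[["counts"]])
  write_grid_tsv(round(prof$R, 6), prof$x_edges, prof$y_edges,
                 "enrichment ratio R(p) = N/<N_r>", paths[["R"]])
  write_grid_tsv(round(prof$Z, 6), prof$x_edges, prof$y_edges,
                 "Z score (N - <N_r>)/sd(N_r)", paths[["Z"]])
  write.table(trend, paths[["trend"]], sep = "\t", quote = FALSE,
              row.names = FALSE)
  writeLines(c(
    utils::capture.output(print(prof)),
    "",
    utils::capture.output(print(summ))
  ), paths[["summary"]])

  manifest <- list(
    input = input, format = format, directed = directed,
    preprocessing = steps,
    measure = measure, weight_def = weight_def,
    bins_x = bins_x, bins_y = bins_y,
    realizations = realizations, base_seed = seed,
    nodes = igraph::vcount(g), edges = igraph::ecount(g),
    admitted_samples = prof$n_admitted,
    exclusions = as.list(prof$exclusions),
    spearman_observed = summ$observed,
    spearman_null_mean = summ$null_mean,
    spearman_null_sd = summ$null_sd,
    outputs = as.list(paths),
    package_version = as.character(packageVersion("tieprof"))
  )
  jsonlite::write_json(manifest, paths[["manifest"]], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(list(profile = prof, summary = summ, trend = trend,
                 network = g, paths = paths))
}

#' Generate a synthetic network and write it as an edge list
#'
#' @param family `"two-clique"`, `"scale-free"`, `"random"` or
#'   `"bipartite"` (the latter writes a bipartite membership TSV).
#' @param out output path (TSV edge list).
#' @param n node count (primary-side count for bipartite).
#' @param beta,seed passed to [planted_granovetter()] /
#'   [random_bipartite()].
#' @param ... further generator arguments.
#' @return `out`, invisibly.
#' @export
run_simulate <- function(family = c("two-clique", "scale-free", "random",
                                    "bipartite"),
                         out, n = 1000, beta = 1, seed = 1L, ...) {
  family <- match.arg(family)
  if (family == "bipartite") {
    g <- random_bipartite(n_primary = n, n_groups = max(1, n %/% 2), p = 0.05,
                          seed = seed, ...)
    el <- igraph::as_edgelist(g, names = TRUE)
    write.table(el, out, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  } else if (family == "two-clique") {
    write_edgelist(two_clique_toy(max(3, n %/% 2)), out)
  } else {
    write_edgelist(planted_granovetter(n, family = family, beta = beta,
                                       seed = seed, ...), out)
  }
  invisible(out)
}

#' Dump the edge-sample table of a network file
#'
#' @inheritParams run_profile
#' @param out output TSV path.
#' @return `out`, invisibly.
#' @export
run_measures <- function(input, format = c("edgelist", "konect", "bipartite"),
                         out, directed = FALSE, weight_def = NULL,
                         lcc = TRUE) {
  format <- match.arg(format)
  weight_def <- weight_def %||% if (format == "bipartite") "bipartite" else "strength"
  g <- load_network(input, format, directed = directed)
  if (format == "bipartite") g <- project_bipartite(g)
  if (igraph::is_directed(g)) g <- symmetrize(g)
  if (lcc) g <- largest_component(g)
  write_edge_samples(edge_samples(g, weight_mode = weight_def), out)
  invisible(out)
}
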