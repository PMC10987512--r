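#' Log-spaced 2D bin grid
#'
#' Builds geometrically spaced bin edges on the (weight, overlap) plane.
#' With the default pooled policy the range spans the positive values of
#' the supplied vectors (observed network plus, in [correlation_profile()],
#' every realization), so each sample lands in some bin; explicit limits
#' may be given instead, in which case out-of-range samples are tallied as
#' overflow by [bin_counts()]. A degenerate axis (one distinct value) is
#' padded to one decade around that value, with a warning.
#'
#' @param x,y positive sample coordinates (weight-like and overlap-like).
#' @param bins_x,bins_y bin counts per axis (default 25).
#' @param xlim,ylim optional explicit ranges `c(lo, hi)`.
#' @return a `profile_grid_axes` list with `x_edges`, `y_edges`.
#' @export
make_grid <- function(x, y, bins_x = 25, bins_y = 25, xlim = NULL, ylim = NULL) {
  x <- x[is.finite(x) & x > 0]
  y <- y[is.finite(y) & y > 0]
  if (length(x) == 0 || length(y) == 0) stop_empty("no admitted samples with positive coordinates")
  structure(list(x_edges = log_edges(xlim %||% range(x), bins_x, "x"),
                 y_edges = log_edges(ylim %||% range(y), bins_y, "y")),
            class = "profile_grid_axes")
}

log_edges <- function(lim, bins, axis) {
  if (any(lim <= 0)) stop_validation("log-scale axis limits must be positive")
  if (lim[1] == lim[2]) {
    warning("degenerate ", axis, " range: padding to one decade around ", lim[1])
    lim <- lim[1] * c(1 / sqrt(10), sqrt(10))
  }
  edges <- exp(seq(log(lim[1]), log(lim[2]), length.out = bins + 1))
  # pin endpoints so range extremes cannot fall off the grid to rounding
  edges[1] <- lim[1]
  edges[bins + 1] <- lim[2]
  edges
}

# Half-open bin assignment [lo, hi); top edge closed.  A value exactly on
# an interior edge goes to the bin whose lower edge it is (the upper bin).
# Returns 0 / bins+1 for out-of-range values.
bin_index <- function(x, edges) {
  findInterval(x, edges, rightmost.closed = TRUE)
}

#' Count samples per grid bin
#'
#' @param x,y sample coordinates.
#' @param grid axes from [make_grid()].
#' @return list with `counts` (matrix, rows = x bins, cols = y bins) and
#'   `overflow`, the number of samples outside the grid (warned about when
#'   positive — only possible with explicit limits).
#' @export
bin_counts <- function(x, y, grid) {
  nx <- length(grid$x_edges) - 1
  ny <- length(grid$y_edges) - 1
  ix <- bin_index(x, grid$x_edges)
  iy <- bin_index(y, grid$y_edges)
  ok <- ix >= 1 & ix <= nx & iy >= 1 & iy <= ny
  overflow <- sum(!ok)
  if (overflow > 0) warning(overflow, " sample(s) outside the explicit grid range")
  counts <- matrix(tabulate(ix[ok] + (iy[ok] - 1) * nx, nbins = nx * ny), nx, ny)
  list(counts = counts, overflow = overflow)
}

#' Per-bin enrichment ratio R
#'
#' `R(p) = N(p) / <N_r(p)>`: the observed count in a bin over the
#' null-ensemble mean. `R` near 1 means the bin is explained by topology
#' alone; `R > 1` means the observed weight placement concentrates samples
#' there. An empty bin in both (N = 0, mean 0) is undefined (`NA`);
#' observed samples where the null has none give `Inf`.
#'
#' @param N observed count(s).
#' @param mean_Nr ensemble mean count(s).
#' @return ratio(s); vectorised.
#' @examples
#' compute_R(1, 4)  # 0.25
#' @export
compute_R <- function(N, mean_Nr) {
  if (any(N < 0, na.rm = TRUE) || any(mean_Nr < 0, na.rm = TRUE)) {
    stop_validation("counts must be nonnegative")
  }
  ifelse(mean_Nr == 0, ifelse(N == 0, NA_real_, Inf), N / mean_Nr)
}

#' Per-bin Z score
#'
#' `Z(p) = (N(p) - <N_r(p)>) / sd(N_r(p))`: how many ensemble standard
#' deviations the observed count sits from the null mean. A degenerate
#' ensemble (zero spread) gives `NA`.
#'
#' @param N observed count(s).
#' @param mean_Nr,sd_Nr ensemble mean and standard deviation.
#' @return z value(s); vectorised.
#' @export
compute_Z <- function(N, mean_Nr, sd_Nr) {
  if (any(sd_Nr < 0, na.rm = TRUE)) stop_validation("sd must be nonnegative")
  ifelse(sd_Nr == 0, NA_real_, (N - mean_Nr) / sd_Nr)
}

# Admitted samples and (x, y) coordinates for one measure mode.
# Admission depends only on topology-side quantities (n > 0, and k_i > 1 in
# asymmetric mode), so the admitted set is identical across realizations.
profile_coords <- function(samples, measure) {
  if (measure == "asymmetric") {
    admit <- samples$n > 0 & samples$k_i > 1
    excl <- c(zero_overlap = sum(samples$n == 0),
              undefined_Q = sum(samples$n > 0 & samples$k_i == 1))
    list(admit = admit, x = samples$v[admit], y = samples$Q[admit], excl = excl)
  } else {
    admit <- samples$n > 0
    excl <- c(zero_overlap = sum(samples$n == 0), undefined_Q = 0L)
    list(admit = admit, x = samples$w[admit], y = samples$O[admit], excl = excl)
  }
}

#' Correlation profile of a network against its null ensemble
#'
#' Enumerates the two directed samples of every edge, places them on the
#' log-log (weight, overlap) plane — (`v`, `Q`) in asymmetric mode, (`w`,
#' `O`) in symmetric mode — and compares per-bin counts in the observed
#' network with the weight-shuffled ensemble: the enrichment ratio
#' `R = N / <N_r>` and the Z score per bin. The same realizations are used
#' for every bin. Samples with zero overlap (no logarithm) or an undefined
#' asymmetric measure (degree-1 source) are excluded and tallied; the
#' admission rule depends only on topology, so every realization has the
#' same admitted-sample count.
#'
#' Overlaps never change under shuffling, so only the weight coordinate
#' moves between realizations; the grid range is pooled over the observed
#' network and the whole ensemble so all of them share one grid.
#'
#' @param g the observed weighted network.
#' @param ensemble a [build_ensemble()] object on the same topology, or
#'   `NULL` to build one here from `realizations` and `seed`.
#' @param measure `"asymmetric"` (`Q` vs `v`, default) or `"symmetric"`
#'   (`O` vs `w`).
#' @param weight_def asymmetric-weight definition passed to
#'   [edge_samples()]: `"strength"` or `"bipartite"`.
#' @param bins_x,bins_y grid resolution (default 25 x 25).
#' @param realizations,seed used only when `ensemble` is `NULL`.
#' @return a `correlation_profile` object: bin edges, per-bin `N`,
#'   `mean_Nr`, `sd_Nr`, `R`, `Z` (matrices, rows = weight bins, cols =
#'   overlap bins; undefined entries `NA`), the per-realization bin-count
#'   matrix `null_counts`, admitted coordinates `x`, `y`, exclusion
#'   tallies, and the ensemble metadata.
#' @export
correlation_profile <- function(g, ensemble = NULL,
                                measure = c("asymmetric", "symmetric"),
                                weight_def = c("strength", "bipartite"),
                                bins_x = 25, bins_y = 25,
                                realizations = 100, seed = 1L) {
  measure <- match.arg(measure)
  weight_def <- match.arg(weight_def)
  if (is.null(ensemble)) ensemble <- build_ensemble(g, realizations, seed)
  if (!identical(igraph::as_edgelist(g), igraph::as_edgelist(ensemble$network))) {
    stop_config("ensemble topology does not match the network")
  }

  samples <- edge_samples(g, weight_mode = weight_def)
  co <- profile_coords(samples, measure)
  if (length(co$x) == 0) stop_empty("no admitted samples")

  nreal <- ensemble$realizations
  el <- igraph::as_edgelist(g, names = FALSE)
  src <- c(el[, 1], el[, 2])[co$admit]
  edge_id <- samples$edge[co$admit]
  m_i <- samples$m_i[co$admit]
  nv <- igraph::vcount(g)

  # Weight coordinates of every realization (overlaps are invariant).
  xr <- matrix(0, length(co$x), nreal)
  for (r in seq_len(nreal)) {
    wr <- realization_weights(ensemble, r)
    xr[, r] <- if (measure == "symmetric") {
      wr[edge_id]
    } else if (weight_def == "strength") {
      wr[edge_id] / node_strengths(nv, el, wr)[src]
    } else {
      wr[edge_id] / m_i
    }
  }

  grid <- make_grid(c(co$x, xr), co$y, bins_x, bins_y)
  obs <- bin_counts(co$x, co$y, grid)
  nbins <- length(obs$counts)
  null_counts <- matrix(0L, nreal, nbins)
  for (r in seq_len(nreal)) {
    null_counts[r, ] <- as.vector(bin_counts(xr[, r], co$y, grid)$counts)
  }
  mean_Nr <- matrix(colMeans(null_counts), nrow(obs$counts))
  sd_Nr <- matrix(apply(null_counts, 2, sd), nrow(obs$counts))

  structure(
    list(x_edges = grid$x_edges, y_edges = grid$y_edges,
         N = obs$counts, mean_Nr = mean_Nr, sd_Nr = sd_Nr,
         R = compute_R(obs$counts, mean_Nr),
         Z = compute_Z(obs$counts, mean_Nr, sd_Nr),
         null_counts = null_counts,
         x = co$x, y = co$y,
         n_admitted = length(co$x),
         exclusions = co$excl,
         total_samples = nrow(samples),
         measure = measure, weight_def = weight_def,
         realizations = nreal, base_seed = ensemble$base_seed),
    class = "correlation_profile"
  )
}

node_strengths <- function(nv, el, w) {
  s <- numeric(nv)
  agg <- rowsum(c(w, w), c(el[, 1], el[, 2]))
  s[as.integer(rownames(agg))] <- agg[, 1]
  s
}

#' @export
print.correlation_profile <- function(x, ...) {
  cat("Correlation profile (", x$measure, " measures, weight_def = ",
      x$weight_def, ")\n", sep = "")
  cat("  grid: ", nrow(x$N), " x ", ncol(x$N), " log-log bins; ",
      x$realizations, " realizations (base seed ", x$base_seed, ")\n", sep = "")
  cat("  admitted samples: ", x$n_admitted, " of ", x$total_samples,
      " (excluded: ", paste(names(x$exclusions), x$exclusions,
                            sep = " = ", collapse = ", "), ")\n", sep = "")
  well <- x$mean_Nr >= 10
  if (any(well)) {
    cat("  well-populated bins (<N_r> >= 10): ", sum(well),
        "; mean R there ", round(mean(x$R[well]), 3),
        "; share with |Z| > 2: ",
        round(100 * mean(abs(x$Z[well]) > 2, na.rm = TRUE), 1), "%\n", sep = "")
  }
  invisible(x)
}

#' Quadrant summary of a correlation profile
#'
#' Splits the plane into four quadrants at the medians of the observed
#' admitted coordinates and pools counts within each: the quadrant ratio is
#' `sum(N) / sum(<N_r>)` — a count-weighted R that is stable where
#' individual bins are sparse — and the quadrant Z uses the exact
#' per-realization quadrant totals. A planted positive weight-overlap
#' coupling shows up as ratio > 1 in the (high weight, high overlap)
#' quadrant and < 1 at (high weight, low overlap).
#'
#' @param p a [correlation_profile()].
#' @return data.frame with one row per quadrant: `x_side`, `y_side`, `N`,
#'   `mean_Nr`, `sd_Nr`, `R`, `Z`.
#' @export
quadrant_summary <- function(p) {
  stopifnot(inherits(p, "correlation_profile"))
  nx <- nrow(p$N); ny <- ncol(p$N)
  cx <- sqrt(p$x_edges[-1] * p$x_edges[-(nx + 1)])
  cy <- sqrt(p$y_edges[-1] * p$y_edges[-(ny + 1)])
  hi_x <- cx > median(p$x)
  hi_y <- cy > median(p$y)
  out <- expand.grid(x_side = c("low", "high"), y_side = c("low", "high"),
                     stringsAsFactors = FALSE)
  out$N <- out$mean_Nr <- out$sd_Nr <- out$R <- out$Z <- NA_real_
  sel_mat <- outer(hi_x, hi_y, function(a, b) a + 2 * b)  # 0..3 per bin
  for (q in seq_len(4)) {
    bins <- which(as.vector(sel_mat) == q - 1)
    if (length(bins) == 0) next
    N <- sum(p$N[bins])
    null_tot <- rowSums(p$null_counts[, bins, drop = FALSE])
    out$N[q] <- N
    out$mean_Nr[q] <- mean(null_tot)
    out$sd_Nr[q] <- sd(null_tot)
    out$R[q] <- compute_R(N, mean(null_tot))
    out$Z[q] <- compute_Z(N, mean(null_tot), sd(null_tot))
  }
  out
}

#' Average overlap per weight bin (trend curve)
#'
#' The curve overlaid on the profile heatmaps: one average overlap value
#' per weight bin, arithmetic or geometric, with its sample count. Empty
#' bins are omitted.
#'
#' @param x,y sample coordinates (or pass a `correlation_profile` as `x`
#'   and leave `y`/`grid` missing to reuse its samples and grid).
#' @param grid axes from [make_grid()].
#' @param average `"geometric"` (default; natural on a log axis) or
#'   `"arithmetic"`.
#' @return data.frame with `bin`, `x_lo`, `x_hi`, `x_mid` (geometric
#'   centre), `overlap`, `count`.
#' @export
trend_curve <- function(x, y = NULL, grid = NULL,
                        average = c("geometric", "arithmetic")) {
  average <- match.arg(average)
  if (inherits(x, "correlation_profile")) {
    grid <- list(x_edges = x$x_edges, y_edges = x$y_edges)
    y <- x$y
    x <- x$x
  }
  ix <- bin_index(x, grid$x_edges)
  nx <- length(grid$x_edges) - 1
  keep <- ix >= 1 & ix <= nx
  ix <- ix[keep]; yv <- y[keep]
  avg <- function(v) if (average == "geometric") exp(mean(log(v))) else mean(v)
  bins <- sort(unique(ix))
  data.frame(
    bin = bins,
    x_lo = grid$x_edges[bins],
    x_hi = grid$x_edges[bins + 1],
    x_mid = sqrt(grid$x_edges[bins] * grid$x_edges[bins + 1]),
    overlap = vapply(bins, function(b) avg(yv[ix == b]), 1),
    count = vapply(bins, function(b) sum(ix == b), 1L)
  )
}

#' Rank-correlation summary: observed network vs null ensemble
#'
#' Spearman correlation between log overlap and log weight over the
#' admitted samples (positive overlap, defined asymmetric measures), for
#' the observed network and for every realization of the ensemble. Ranks
#' are invariant under the logarithm, but the statistic is computed on logs
#' to mirror how the profiles are binned. A genuinely weight-coupled
#' network shows an observed correlation above the ensemble mean; the
#' ensemble mean itself is typically positive — that is the structural
#' correlation the profiles are designed to filter out.
#'
#' @inheritParams correlation_profile
#' @return a `profile_summary` object: `observed`, `null_rho` (vector),
#'   `null_mean`, `null_sd`, `n_samples`, `realizations`, `base_seed`,
#'   exclusion tallies.
#' @export
correlation_summary <- function(g, ensemble = NULL,
                                measure = c("asymmetric", "symmetric"),
                                weight_def = c("strength", "bipartite"),
                                realizations = 100, seed = 1L) {
  measure <- match.arg(measure)
  weight_def <- match.arg(weight_def)
  if (is.null(ensemble)) ensemble <- build_ensemble(g, realizations, seed)

  samples <- edge_samples(g, weight_mode = weight_def)
  co <- profile_coords(samples, measure)
  if (length(co$x) < 3) stop_empty("fewer than 3 admitted samples")

  rho <- function(x, y) cor(log(x), log(y), method = "spearman")
  nreal <- ensemble$realizations
  el <- igraph::as_edgelist(g, names = FALSE)
  src <- c(el[, 1], el[, 2])[co$admit]
  edge_id <- samples$edge[co$admit]
  m_i <- samples$m_i[co$admit]
  nv <- igraph::vcount(g)

  null_rho <- vapply(seq_len(nreal), function(r) {
    wr <- realization_weights(ensemble, r)
    xr <- if (measure == "symmetric") {
      wr[edge_id]
    } else if (weight_def == "strength") {
      wr[edge_id] / node_strengths(nv, el, wr)[src]
    } else {
      wr[edge_id] / m_i
    }
    rho(xr, co$y)
  }, 1)

  structure(
    list(observed = rho(co$x, co$y),
         null_rho = null_rho,
         null_mean = mean(null_rho), null_sd = sd(null_rho),
         n_samples = length(co$x), exclusions = co$excl,
         measure = measure, weight_def = weight_def,
         realizations = nreal, base_seed = ensemble$base_seed),
    class = "profile_summary"
  )
}

#' @export
print.profile_summary <- function(x, ...) {
  cat("Spearman(", if (x$measure == "asymmetric") "log Q, log v" else "log O, log w",
      ") over ", x$n_samples, " directed samples\n", sep = "")
  cat("  observed: ", round(x$observed, 4), "\n", sep = "")
  cat("  null ensemble (", x$realizations, " realizations): ",
      round(x$null_mean, 4), " +/- ", round(x$null_sd, 4), "\n", sep = "")
  ex <- (x$observed - x$null_mean) / x$null_sd
  cat("  observed exceeds null mean by ", round(ex, 2),
      " ensemble standard deviations\n", sep = "")
  invisible(x)
}
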