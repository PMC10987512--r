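---
title: "Separating structural from genuine weight-topology correlations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Separating structural from genuine weight-topology correlations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tieprof)
```

## The question and the model

In a weighted network the weight `w_ij` of an edge is read as the strength
of the relationship it represents. The hypothesis under test is that
stronger ties live inside densely overlapping neighbourhoods: edge weight
should increase with the neighbourhood overlap of its endpoints, and the
weak edges should be the bridges between otherwise separate clusters.

`tieprof` works with four edge-level measures. For an edge (i, j) with
`n_ij` common neighbours and endpoint degrees `k_i`, `k_j`:

* symmetric overlap `O_ij = n_ij / ((k_i - 1) + (k_j - 1) - n_ij)`,
* asymmetric overlap `Q_ij = n_ij / (k_i - 1)`,
* asymmetric weight `v_ij = w_ij / s_i` with strength `s_i = sum_j w_ij`
  (default), or `v_ij = w_ij / m_i` with `m_i` the bipartite membership
  count, for networks that are projections of memberships,
* and the raw symmetric weight `w_ij` itself.

The symmetric pair (`w`, `O`) describes homogeneous networks well but
misrepresents edges joining nodes of very different degree: two shared
neighbours are a large fraction of a degree-4 node's world
(`Q = 2/3`) and a negligible one for a degree-16 node (`Q = 2/15`),
while the symmetric overlap flattens both views to `O = 1/8`. Heavy-tailed
degree distributions therefore call for the asymmetric pair (`v`, `Q`),
evaluated twice per edge — once from each endpoint.

Asymmetry has a price. Both `Q` and `v` carry the source's degree (or
strength, which is proportional to degree on average) in the denominator,
so they are positively correlated *by construction*: with all weights set
to 1, `v_ij = 1/k_i` exactly while `Q_ij` scales like `1/k_i`. This
structural correlation survives any rearrangement of the weights and must
not be mistaken for evidence about weight placement.

## The null model and the profile

The baseline is the observed topology with the observed weight multiset
randomly permuted over the edges. Everything weight-independent (degrees,
common-neighbour counts, all overlaps) is exactly conserved; only the
weight coordinate of each sample moves. Whatever correlation remains in
this ensemble is structural; whatever the observed network shows *beyond*
it reflects how the weights were actually placed.

The comparison is binned. Directed samples are placed on the (`v`, `Q`)
plane (or (`w`, `O`) in symmetric mode), the plane is divided into
log-log bins of equal size (the measures span several decades), and each
bin p is scored by

* the enrichment ratio `R(p) = N(p) / <N_r(p)>`, observed count over
  ensemble mean, and
* the significance `Z(p) = (N(p) - <N_r(p)>) / sd(N_r(p))`.

The same realizations are used for every bin. A complementary scalar
summary is the Spearman correlation of log overlap against log weight,
reported for the observed network alongside its ensemble mean and spread;
ranks are invariant under the logarithm, so the log transform changes
nothing and is kept purely for symmetry with the binned view.

## Parameters that matter

* **Grid resolution** (`bins_x`, `bins_y`, default 25 x 25): a
  presentation/variance trade-off with no canonical value. Coarser grids
  give better-populated bins on small networks; the package's own tests
  use 10-15 bins per axis on networks of a few thousand samples.
* **Range policy**: by default the grid spans the pooled positive range of
  the observed network *and* every realization, so all of them share one
  grid — required for `R` to compare like with like. Explicit limits are
  accepted; samples falling outside are counted in an overflow tally with
  a warning, never silently lost.
* **Realizations** (default 100): enough to estimate per-bin means and
  standard deviations; the ensemble spread of the Spearman summary also
  comes from it. Each realization is a pure function of
  `(base_seed, index)`, so ensembles are reproducible piecewise.
* **Weight definition** (`strength` vs `bipartite`): strength
  normalisation is the default because it applies to every weighted
  network; membership normalisation requires the `m` attribute that only
  bipartite projections carry.

## Numerical and edge-case choices

* **Zero-overlap samples** (`n_ij = 0`) have no logarithm and are excluded
  from the grid and the Spearman summary, with the excluded fraction
  tallied and printed. Admission depends only on topology, never on
  weights, so the admitted count is identical in the observed network and
  every realization — a conservation the tests assert.
* **Degree-1 sources** make `Q` undefined (division by zero); such samples
  are flagged `NA` and excluded the same way rather than being assigned an
  invented value.
* **Degenerate denominators** in `O` (two connected degree-1 nodes) force
  `n = 0`; the overlap is reported as 0.
* **Bin boundaries** are half-open `[lo, hi)` with the top edge closed,
  and the extreme grid edges are pinned exactly to the pooled range so
  floating-point rounding cannot push extreme samples off the grid.
* **Undefined ratios** propagate as `NA` (`R` with an empty bin in both
  observed and null; `Z` with a zero-spread ensemble), never as numbers.
* **Two samples per edge** enter the profiles and the Spearman summary —
  the asymmetric measures are defined per directed view, and both views
  carry information when degrees differ.
* **Directed inputs** are symmetrised first, `w_ij = (V_ij + V_ji) / 2`,
  with a missing direction counted as zero; asymmetry is then
  reintroduced through strength normalisation. This treats directed,
  undirected and bipartite inputs uniformly.
* **Duplicate edge records** are merged by summing weights, matching the
  co-occurrence reading of weights; self-loops are dropped and counted.
* **Largest component**: analyses restrict to it by default (small
  fragments are usually data-incompleteness artefacts); ties between
  equal-sized components break towards the lowest vertex index.

## Quadrant summary

For a scalar answer to "is the enrichment where the theory says", the
plane is split at the medians of the observed admitted coordinates and
counts are pooled within each quadrant: the quadrant ratio is
`sum(N) / sum(<N_r>)` rather than an average of per-bin `R` values,
because sparse bins make individual ratios noisy while the pooled count is
stable, and the per-realization quadrant totals give that ratio an exact
null spread (and hence an honest `Z`). A planted positive coupling shows
ratio > 1 at (high `v`, high `Q`) and < 1 at (high `v`, low `Q`).

## What the synthetic generators emulate

`planted_granovetter()` draws a topology (preferential attachment for the
heterogeneous regime, Erdos-Renyi for a homogeneous control, or the
two-clique-plus-bridge toy) and assigns integer weights
`w = ceiling(c * (O + eps0)^beta * eta)`, `eta` log-normal with scale
`noise_sd`. The coupling acts on the symmetric overlap `O` because the
mechanism being emulated concerns the tie itself, not either directed
view; `eps0 = 0.01` keeps zero-overlap edges at positive weight, and the
ceiling mimics co-occurrence counts. The constant
`c = scale / mean((O + eps0)^beta)` is normalised per network so that
`scale` (default 50) sets the typical weight for every `beta`; without
this, large `beta` on a low-overlap topology pushes the kernel below 1 and
the integer ceiling collapses nearly all weights to the floor value,
destroying the very coupling the generator exists to plant. `beta = 0` is
exactly the null model's world: weights independent of topology.

Defaults (n = 1000 nodes, attachment parameter `pa_m = 5`, so mean degree
near 10; `noise_sd = 0.5`, about a factor-of-1.6 multiplicative scatter)
are chosen as typical of the empirical co-occurrence networks this kind of
analysis targets.

What the generator does *not* emulate: degree-overlap correlations beyond
what preferential attachment produces, community structure, weight
distributions with heavier tails than log-normal-of-a-power, or temporal
accumulation of weights. Passing tests on these fixtures therefore show
the machinery is correct and calibrated, not that any particular empirical
network obeys the theory.

`random_bipartite()` gives a membership graph with i.i.d. memberships; its
projection is a control in which any weight-overlap relation is produced
by the projection itself.

## Calibration and the problem sizes used

Two properties anchor the test suite:

* **Self-null calibration**: profiling a network whose weights were
  themselves assigned by a shuffle against a fresh 100-realization
  ensemble must give mean `R` near 1 on well-populated bins
  (`<N_r> >= 10`) and an `|Z| > 2` rate near the nominal
  `2 * pnorm(-2) = 4.55%` (binomial band; the rate runs slightly high of
  nominal because each `Z` uses an estimated standard deviation and counts
  are discrete). The suite checks this on a 1200-node scale-free network
  with a 15 x 15 grid.
* **Planted-signal recovery**: at `beta = 2` (800 nodes, 100
  realizations) the observed Spearman exceeds the null mean by far more
  than 3 ensemble standard deviations and the high-high quadrant ratio is
  well above 1; at `beta = 0` neither happens. Enrichment strength grows
  monotonically over `beta` in {0, 1, 2} (averaged over 10 seeds at 250
  nodes).

These sizes keep the whole suite under a minute while leaving the
statistical bands comfortably non-trivial.

## Limitations

* The null model permutes weights only; it does not rewire topology, so
  it cannot separate effects that live in the topology itself (degree
  mixing, clustering) — by design: those are exactly what it conditions
  on.
* No multiple-testing correction is applied across bins; `Z` maps are
  meant to be read as fields, not as independent hypothesis tests.
* Bin counts and axis ranges are analysis choices; profiles of the same
  network at different resolutions agree qualitatively, not bin-for-bin.
* Spearman ties (heavily quantised integer weights) are handled by
  average ranks; with extreme quantisation the summary loses resolution
  even though the profile does not.
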