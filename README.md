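# tieprof

Does the strength of a tie track the topology around it? In many weighted
networks — collaboration graphs, mention networks, flight networks, even
metabolic and neural wiring — one expects strong edges inside densely
overlapping neighbourhoods and weak edges bridging them (the classic
"strength of weak ties" picture). `tieprof` measures that relationship and,
crucially, separates the part of it that is genuinely about *where the
weights were placed* from the part that is baked into the measures
themselves by the network's topology.

It is aimed at anyone analysing a weighted network — social, biological or
infrastructural — who wants a null-model-controlled answer rather than a
raw correlation.

## The measures and the method

For an edge between nodes *i* and *j* with `n_ij` common neighbours and
degrees `k_i`, `k_j`:

- **Symmetric overlap** `O_ij = n_ij / ((k_i - 1) + (k_j - 1) - n_ij)`,
  a Jaccard-like score in [0, 1], identical from both ends.
- **Asymmetric overlap** `Q_ij = n_ij / (k_i - 1)`: the shared
  neighbourhood as seen from *i* alone; `Q_ij != Q_ji` when degrees differ,
  which is exactly what heterogeneous (scale-free) networks need.
- **Asymmetric weight** `v_ij = w_ij / s_i` (weight over source strength
  `s_i = sum_j w_ij`), or `v_ij = w_ij / m_i` for bipartite projections,
  with `m_i` the source's membership count.

Each edge contributes two directed samples `(v, Q)`. The catch: `Q` and `v`
both scale like `1/k_i`, so they correlate even when weights are placed at
random — a purely structural correlation. `tieprof` filters it out with a
**correlation profile**: shuffle the weights over the fixed topology many
times, bin the samples on a log-log `(v, Q)` grid, and compare per-bin
counts,

```
R(p) = N(p) / <N_r(p)>,    Z(p) = (N(p) - <N_r(p)>) / sd(N_r(p)).
```

`R > 1` in the high-`v`/high-`Q` corner — observed samples concentrated
where the null puts few — is the signature of a genuine weight–topology
coupling; `R ≈ 1` everywhere means topology explains it all.

## Worked example

Generate a scale-free network whose weights are deliberately coupled to
overlap (`beta = 2`), then profile it against 100 weight shuffles:

```r
library(tieprof)
g    <- planted_granovetter(n = 500, family = "scale-free", beta = 2, seed = 42)
ens  <- build_ensemble(g, realizations = 100, base_seed = 1)
prof <- correlation_profile(g, ens, bins_x = 12, bins_y = 12)
prof
#> Correlation profile (asymmetric measures, weight_def = strength)
#>   grid: 12 x 12 log-log bins; 100 realizations (base seed 1)
#>   admitted samples: 2174 of 4970 (excluded: zero_overlap = 2796, undefined_Q = 0)
#>   well-populated bins (<N_r> >= 10): 71; mean R there 1.082; share with |Z| > 2: 88.7%

correlation_summary(g, ens)
#> Spearman(log Q, log v) over 2174 directed samples
#>   observed: 0.7043
#>   null ensemble (100 realizations): 0.3706 +/- 0.0158
#>   observed exceeds null mean by 21.06 ensemble standard deviations

quadrant_summary(prof)
#>   x_side y_side         Z         R    sd_Nr mean_Nr   N
#> 1    low    low -10.62469 0.8517813 12.74202  913.38 778
#> 2   high    low  10.62469 1.6027068 12.74202  224.62 360
#> 3    low   high -30.61020 0.2734460 15.19036  639.98 175
#> 4   high   high  30.61020 2.1741326 15.19036  396.02 861
```

Reading the numbers: roughly half the directed samples sit on edges with
zero overlap and are excluded from the log-log grid (tallied, never
silently dropped). The null model itself shows a strong structural
rank correlation (0.37) between `Q` and `v` — that is the artefact of the
asymmetric definitions. The observed network's 0.70 exceeds it by 21
ensemble standard deviations, and the quadrant table shows the excess is
where it should be: samples are 2.2x enriched at high weight *and* high
overlap, 3.7x depleted at high overlap but low weight. For a `beta = 0`
network (weights independent of topology) the same pipeline reports an
excess within noise and quadrant ratios near 1.

Per-measure building blocks are exported too:

```r
symmetric_overlap(2, 4, 4)    # 0.5   two degree-4 nodes sharing 2 neighbours
symmetric_overlap(2, 4, 16)   # 0.125 same share, one high-degree endpoint
asymmetric_overlap(2, 4)      # 2/3   ... as seen from the degree-4 node
asymmetric_overlap(2, 16)     # 2/15  ... as seen from the degree-16 node
```

## Command line

```sh
Rscript inst/cli/tieprof.R simulate --family scale-free --n 1000 --beta 2 --seed 1 --out net.tsv
Rscript inst/cli/tieprof.R profile  --input net.tsv --format edgelist \
    --bins 25 --realizations 100 --seed 1 --out results/run
Rscript inst/cli/tieprof.R measures --input net.tsv --out samples.tsv
```

`profile` writes TSV grids (`counts`, `R`, `Z`), the trend curve, a text
summary and a JSON manifest recording every seed, mode and exclusion tally
needed to reproduce the outputs exactly.

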