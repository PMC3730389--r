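---
title: "Methods: acupoint co-occurrence networks from incidence data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: acupoint co-occurrence networks from incidence data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(acunet)
```

## The model

The data are an `m × p` binary incidence matrix: `m` clinical studies in
rows, `p` acupoints in columns, with a 1 wherever a study's acupuncture
prescription used an acupoint. Acupoints used in at most 5% of studies are
dropped before analysis (`filter_by_frequency()`, strict `>`), mirroring
the curation of the low back pain corpus this package was built around
(53 trials, 33 retained acupoints).

Each acupoint pair is scored by a pointwise mutual-information statistic,

$$\mathrm{MI}(x,y) \;=\; P(x,y)\,\ln\frac{P(x,y)}{P(x)\,P(y)},$$

with all probabilities estimated as count fractions: `P(x) = n_x/m`,
`P(x,y) = n_xy/m`. Two deliberate conventions:

* **It is a single PMI term**, weighted by the co-usage frequency — not the
  Shannon mutual information of the full 2×2 contingency table. A pair must
  be *both* over-represented relative to independence *and* frequently
  co-used to score high.
* `0 · ln 0` is taken as 0, so never-co-used pairs score 0; pairs co-used
  *less* than independence predicts score negative. Negative values are kept
  in the matrix — any positive binarization threshold removes them.
* The natural logarithm is used throughout; values are in nats.

The `p × p` MI matrix is symmetric with a zero diagonal (a self-pair
carries no combination information).

## Binarization: threshold scan, connectivity, density band

The MI matrix is thresholded over the grid `R = 0.001, 0.002, …, 0.999`
(an edge iff `MI > R`, strict — "exceeding" the threshold). Grid values are
generated from scaled integers so that the reported maximal connected
threshold is an exact 3-decimal value rather than a float artifact.

Raising `R` only removes edges, so edge count, density, and connectivity
are all monotone along the grid; `scan_thresholds()` exploits the
monotonicity of connectivity (binary search) but its per-threshold records
are identical to direct evaluation, which the test suite verifies.
"Fully connected" means a *single connected component*, not a complete
graph — the constraint exists to keep the network analysable as one object
rather than fragments.

The analysis network is selected inside an edge-density band, by default
`[0.39, 0.50]` with target 0.40: among fully connected grid networks in the
band, the one with density nearest the target wins, ties going to the
larger threshold (the sparser, stronger-edge network). These defaults are
the published procedure's: the band retains "possibly strong edges only"
while preserving connectivity, and the published analysis reports the
density-0.40 network.

`connectivity = "prefer"` relaxes the connectivity requirement with a
warning when *no* connected in-band network exists, falling back to the
nearest in-band network. This matters for planted synthetic data (below):
with a strong planted signal, between-module pairs co-occur *below*
independence, their MI is negative, and no positive threshold yields a
connected graph — the thresholded network is a disjoint union of module
cliques at every grid point. The published-data defaults
(`"require"`, band 0.39–0.50) are untouched by this option.

## Centralities and modules

Degree is the row sum of the adjacency matrix. Betweenness centrality is
computed by Brandes' dependency accumulation over unweighted BFS shortest
paths; the raw per-pair counts are divided by `(p−1)(p−2)/2` so the score
is the fraction of other-pair geodesics through the node, and the middle
node of a 3-node path scores exactly 1. The published table's normalization
convention is not stated, so both raw and normalized scores are emitted
(`centrality_table()`).

Modularity uses the standard Newman–Girvan form

$$Q \;=\; \frac{1}{2l}\sum_{ij}\Bigl(a_{ij}-\frac{k_ik_j}{2l}\Bigr)\delta_{ij},$$

under which the one-module partition of any graph scores exactly 0 and two
disjoint triangles split by component score 0.5 — closed forms the tests
pin down. A `prefactor = "quarter"` flag recomputes with a `1/(4l)`
prefactor (exactly half the standard value), a convention that appears in
some method descriptions; since it is a positive rescaling it cannot change
which partition is optimal, and the standard form is the default because it
is the one with testable textbook identities.

`detect_modules()` maximizes Q by greedy agglomeration (repeatedly merging
the connected module pair with the best gain) alternated with
Kernighan–Lin refinement: rounds of tentative single-node moves in which
the globally best move is applied *even when its gain is negative*, each
node moving at most once per round, and the round then rolled back to its
best prefix. This escapes the single-move local optima that plain greedy
sweeps stall in. The search restarts from seeded random coarse partitions
(`restarts` times, first restart from singletons); everything is
deterministic given `(seed, restarts)`, with ties broken by input node
order then module id. `exact_best_partition()` enumerates all set
partitions (restricted-growth-string order, ≤ 12 nodes) as the oracle: on
random graphs of up to 10 nodes the detector must never exceed and almost
always attain the exhaustive optimum (the suite requires ≥ 95 of 100
instances; the implementation attains 99–100 in practice).

## The synthetic-data generator

`generate_planted()` draws, per study, one prescription module by the
mixing weights, then includes each in-module acupoint with probability
`p_within` and every other acupoint with `p_background`. It emulates the
qualitative finding that prescriptions cluster into a few recurring
point-combination styles. The recovery benchmark uses `m = 300` studies,
three 11-point modules (mirroring the 33-acupoint corpus), `p_within =
0.9`, `p_background = 0.05`, uniform mixing — a strong, clean signal. The
full pipeline must recover the planted modules with adjusted Rand index
≥ 0.9 over 20 seeded replicates (it attains 1.0).

What the planted model does *not* emulate: heterogeneous study sizes or
prescription lengths, correlated background selection (e.g. anatomically
adjacent points co-selected regardless of module), overlapping modules, and
marginal frequency gradients within a module. Passing the recovery
benchmark therefore shows the machinery is correct on well-separated
structure, not that real corpora are this clean.

## The reconstructed reference fixture

The corpus behind the published analysis was never deposited; only summary
tables were printed. `lbp_fixture()` reconstructs a dataset consistent with
everything printed:

* **Marginals.** Usage counts are `n_x = round(pct · 53/100)`; all 33
  reconstructed counts round-trip to the printed one-decimal percentages
  (rounding half-up), which is also the build's own assertion.
* **Pair counts.** For each of the 13 printed high-MI pairs, the co-usage
  count is recovered by enumerating every feasible integer in the Fréchet
  interval `[max(0, n_x+n_y−m), min(n_x, n_y)]` and keeping the one whose
  MI rounds to the printed 4-decimal value (`infer_pair_count()`). The
  build errors unless the match is unique; for all 13 pairs it is.
* **Completion.** `build_fixture()` places the constrained acupoints by a
  deterministic backtracking search: within a constraint component,
  acupoints are placed one at a time; rows are partitioned into membership
  cells over the already-placed sets; cells are grouped by their pattern
  over the acupoint's constrained neighbours; feasible group allocations
  are enumerated exhaustively (with pruning) and each group's quota is then
  spread over member cells depth-first. Each constraint component gets its
  own seeded row shuffle so that acupoints in *different* components
  overlap near independence instead of packing into the same rows.
  Unconstrained acupoints are filled by seeded sampling. The result is
  re-tallied against every constraint before being returned, and is
  bit-reproducible; the shipped CSV
  (`inst/extdata/lbp_fixture_synthetic.csv`) is asserted identical to the
  in-code reconstruction.

Only the marginals and the 13 anchored pairs are guaranteed. All other
co-usages are an arbitrary consistent completion, so the fixture's degrees,
betweenness values, module composition, and its exact maximal connected
threshold do **not** reproduce the published network-level numbers (which
depend on the unprinted off-table MI values), and one or two unanchored
pairs may exceed the 0.17 cut by chance. The published maximal connected
threshold itself is reported inconsistently at two places in the source
(0.022 vs 0.031) and is treated as context, not a target.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `min_freq` | 0.05 | usage-frequency filter (strict `>`), dimensionless fraction |
| `grid` | 0.001–0.999 by 0.001 | binarization thresholds (nats) |
| `density_band` | [0.39, 0.50] | admissible edge densities for the analysis network |
| `target_density` | 0.40 | preferred density within the band |
| `connectivity` | `"require"` | whether the analysis network must be one component |
| `mi_cut` | 0.17 | reported high-MI pair threshold (nats) |
| `seed`, `restarts` | 1, 10 | module-detection reproducibility and search width |
| `local_set` | 15 lumbar/gluteal points | L/D tagging of high-MI pairs |

The default `local_set` is the published local-acupoints module (14 lumbar
Bladder-meridian and Governing-vessel points) plus GB30: GB30 sits on the
gluteal region, and the published pair table tags its combinations with
lumbar points as local, which a Bladder/Governing-only set cannot
reproduce. A pair is local iff *both* members are local. The set is
anatomical knowledge, not something inferable from incidence data, and is
fully overridable.

## Numerical choices and degenerate inputs

* Percentages render by rounding *half-up* to one decimal (base R's
  `round()` is half-to-even and would print 50.85 as 50.8).
* MI is reported at 4 decimals, frequencies at 1, betweenness at 5,
  matching the published tables' precision; underlying values are kept at
  full precision.
* An all-zero acupoint column makes `P(x) = 0` and the statistic undefined;
  `mi_matrix()` refuses it and points to the frequency filter.
* Zero-edge graphs are refused by modularity and detection (Q undefined);
  graphs with < 3 nodes are refused by betweenness (normalization
  undefined).
* Floating-point tie tolerance in the detector is `1e-12`; improvement must
  exceed it, so cycling is impossible.
* The fixture search is budgeted (~2·10⁵ backtracking states) and errors
  with a diagnostic rather than hanging on pathological constraint systems.

## Problem sizes in the test suite

The suite validates betweenness against an exhaustive path-count oracle on
200 random graphs of up to 8 nodes, the module detector against exhaustive
search on 100 random graphs of up to 10 nodes, threshold monotonicity and
edge-set nesting on 50 random matrices, and pipeline recovery on 20 planted
replicates of 300 studies — sizes chosen so the whole suite runs in about a
minute while each property is still exercised across its meaningful range.

## Known limitations

* One row per study: corpora where a study contributes several distinct
  prescriptions must be expanded to one row per prescription upstream.
* No significance testing of MI values or of Q; the statistic is
  descriptive, and high-MI lists are threshold cuts, not tests.
* Unweighted analysis only: all metrics run on the binarized network, as in
  the published procedure; weighted variants are out of scope.
* The PMI statistic is biased upward for rare pairs at small `m`; with 53
  studies, counts below ~3 make MI values fragile to single-study changes.
* Layout/visualization beyond GraphML export is delegated to Cytoscape or
  igraph plotting.
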