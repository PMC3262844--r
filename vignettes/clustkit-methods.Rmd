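---
title: "Methods and design notes for clustkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes for clustkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clustkit)
options(clustkit.verbose = FALSE)
```

clustkit bundles the clustering algorithms most often applied to biological
networks and expression matrices behind one set of containers
(`weighted_network`, `attribute_matrix`, `cluster_assignment`, base-R
`hclust` trees) and one deterministic ordering convention.  This vignette
explains the models, the tunable parameters, the numerical choices, and what
the synthetic benchmarks do and do not demonstrate.

## Containers and determinism

Every partition is stored size-descending with ties broken by the
lexicographically smallest member id, and all tie-breaking anywhere in the
package (merge order in hierarchical clustering, edge selection in
Girvan-Newman, attractor ties in MCL, node scan order in transitivity
clustering) uses C-locale lexicographic order of node ids.  Two consequences
worth knowing: results are independent of input row order, and repeated runs
with the same seed are byte-identical, which the test suite asserts.

Networks are undirected; directed input is symmetrized and duplicate
unordered pairs collapse to a single edge keeping the **maximum** weight.
The maximum is the conservative choice under similarity semantics (an
interaction supported by either direction is kept at its strongest
evidence); the collapse is reported via a message.

## Edge-weight preprocessing

Raw edge attributes are frequently "smaller is better" scores.
`convert_weights()` provides `neg_log10` (the BLAST e-value convention:
1e-6 becomes 6), `reciprocal` and `log10`.  Zero e-values are clamped to
the smallest positive double rather than erroring, because truncated
e-value output is routine in real BLAST tables.

`heuristic_cutoff()` implements a histogram-valley rule: counts are smoothed
with a centered moving average of window 3, and the cutoff is the left edge
of the first local minimum after the global maximum, with runs of equal
smoothed counts compressed so that a shelf of empty bins between the noise
peak and the signal mass counts as a single valley.  When the smoothed
profile is monotone there is no interior valley and the rule falls back to
the weight at which the cumulative edge count reaches 90%.  The function is
one numeric in, one numeric out, so alternative heuristics can be swapped in
trivially.  Bin count matters: for a few hundred edges, 10-20 bins keep the
histogram smooth enough for the valley to be real rather than shot noise;
the default 100 bins suit the tens of thousands of edges in an all-vs-all
similarity network.

`apply_cutoff()` keeps edges with weight >= cutoff.  Raising the cutoff can
only shrink the edge set and can only increase the connected-component
count; both monotonicity properties are exercised in the tests.

## Distance metrics and missing data

`compute_distance()` supports euclidean, cityblock, and the correlation
family (pearson, uncentered, spearman, kendall, each with an absolute-value
variant); correlation distances are `1 - r`, hence in [0, 2].  Uncentered
correlation — the cosine of the raw profiles — is the conventional metric for
EMAP-style genetic-interaction matrices, where the zero point is meaningful.

Missing values follow pairwise-complete semantics: each pair of profiles
uses only the columns observed in both, and euclidean/cityblock sums are
rescaled by `p/m` (profile length over shared observations) so sparsely
observed pairs are not systematically closer.  Degenerate cases are defined,
not crashed: a zero-variance profile under pearson gets `r = 0` (distance
1), a correlation pair with fewer than two shared observations gets the
maximal distance 2 with a warning, and rows with no data at all are carried
through ingest but excluded from clustering and reported as unassigned.

## Network clustering

**MCL** iterates expansion (matrix squaring) and inflation (entrywise power
with column renormalization) on a column-stochastic matrix built from the
adjacency plus self-loops.  Self-loops default to each node's maximum
incident weight (unit for isolated nodes), which damps oscillation on
bipartite-ish structures; a `unit` policy is available.  Entries below
`pruning_threshold` are zeroed each round.  Iteration stops when the
residual (maximum column L1 change) reaches `max_residual` (default 1e-6)
or after `max_iterations` rounds (default 16, a protocol value adequate for
dense protein-interaction networks; raise it for slowly converging inputs —
the returned diagnostics expose the residual trajectory).  Clusters are read
from the limit matrix: nodes with positive diagonal are attractors,
attractors with overlapping row supports merge, and every node joins the
attractor holding its largest limit value, ties to the smallest id.
Vanilla MCL can emit overlapping clusters; this resolution makes the output
a partition, which the rest of the toolkit expects.  The inflation exponent
is the granularity control: on sparse graphs (mean within-cluster degree
below ~6) inflation 2 visibly fragments true modules and values near 1.4-1.8
are more faithful, a behavior shared by reference MCL implementations and
visible in the planted-partition benchmark below.

**Affinity propagation** is the standard responsibility/availability
message-passing scheme with damping (default 0.9) and a stability window on
the exemplar set.  The shared preference defaults to the median off-diagonal
similarity.  On *exactly* symmetric inputs AP has no way to break ties and
can collapse or oscillate — a property of the algorithm, not the
implementation — so benchmark fixtures carry a seeded symmetric jitter of
negligible magnitude.

**MCODE** ignores weights and works purely on topology.  Vertex weight =
(highest k-core number of the closed neighborhood) x (density of that
core).  Complexes grow from the highest-weight unseen seed, admitting
neighbors whose weight is within `vertex_weight_percentage` of the seed's.
Post-processing order is fluff (optional, may create overlap) then haircut
(removes members with fewer than two in-complex connections), then a filter
discarding complexes without a 2-core (`k_core` configurable).  Defaults
(vwp 0.2, haircut on, fluff off, max depth 100) are the original MCODE
defaults.  MCODE deliberately leaves background nodes unassigned.

**Girvan-Newman** removes the highest-betweenness edge (recomputed each
step, ties by smallest edge id), records the component partition at every
distinct component count, and returns the level maximizing modularity
`Q = sum_c (e_c/m - (d_c/2m)^2)` computed on the original graph.  Edge
betweenness itself comes from igraph; the level bookkeeping and Q selection
are what this package adds.  The cost is O(E^2 V), fine up to a few
thousand edges.

**Transitivity clustering** minimizes the weighted cluster-editing cost:
pairs above the similarity threshold that are separated pay `s - t`, pairs
below it that are co-clustered pay `t - s`.  Instances up to `exact_limit`
(default 8, where the 4140 partitions of 8 elements enumerate instantly)
are solved exactly; larger instances start from the single-linkage
components above the threshold and apply best-improvement single-node moves
(to any cluster or a new singleton) until no move lowers the cost.  The
exact mode doubles as the oracle for the heuristic in the tests: the
heuristic can never report a cost below the exhaustive optimum.  When the
input is a 0/1 adjacency from a random-graph model with known densities,
the natural threshold is between the between-group and within-group edge
probabilities; the benchmark uses their midpoint.

**SCPS-style spectral clustering** degree-normalizes the similarity matrix
(`D^-1/2 S D^-1/2`), embeds nodes in the top-k eigenvector space,
row-normalizes, and runs seeded k-means restarts.  With `n_clusters =
"auto"` the number of clusters is the position of the largest eigengap,
excluding the trivial leading eigenvalue; if no non-trivial gap exceeds
1e-8 the matrix is effectively one block and a single cluster is returned.
The eigengap rule is sharp on near-block-diagonal similarities and fragile
on sparse graphs, where the spectrum has no clean shelf — for such inputs
pass an explicit k.  Zero-degree nodes cannot be normalized and are split
off as singletons first.

## Attribute clustering and model selection

Hierarchical clustering is plain O(n^3) agglomeration with four linkages.
Centroid linkage recomputes each cluster centroid (column means over
non-missing entries) and re-evaluates the metric between centroids —
Cluster 3.0 behavior — rather than the Lance-Williams median update, and can
therefore produce height inversions, which are reported and rendered as-is.
`cut_tree()` slices by height or group count, applying merges in increasing
height order.

k-means assigns rows to the nearest center under the chosen metric and
updates centers as arithmetic means over non-missing entries, even for
correlation metrics (again Cluster 3.0 behavior).  Restart selection uses
the total within-cluster distance.  A subtlety the tests make explicit: the
mean update minimizes the within-cluster sum of *squared* euclidean
distances, so that energy (`history_sq` on the result) is the monotone
Lloyd quantity; the plain distance sum can tick up transiently.  Empty
clusters are repaired by reseeding with the row farthest from its center.
k-medoid replaces means with the member minimizing the summed distance to
its cluster, ties to the smallest id.

`select_k()` runs the partitioner for each k in range under a shared seed
and picks the k maximizing the mean silhouette `s = (b - a)/max(a, b)`,
ties to the smaller k.  Singletons score 0, as do points with `a = b = 0`.
The silhouette is evaluated in the clustering metric throughout (not a
fixed euclidean), so model selection and clustering see the same geometry.

## Derived networks and export

`build_cluster_network()` returns exactly the input edges whose endpoints
co-cluster, optionally restoring inter-cluster edges labeled `inter`; it
never invents edges.  `ensemble_cocluster()` re-runs any seeded algorithm
over `seed .. seed + n_runs - 1`, weights node pairs by co-clustering
frequency, and takes the consensus as the components of pairs with
frequency > 0.5 — majority vote, chosen so the consensus is insensitive to a
minority of discordant runs.  The fuzzy network is truncated to the
highest-frequency `max_edges` pairs for display.

`write_treeview()` emits the Cluster 3.0 / Java TreeView CDT/GTR/ATR
triplet.  TreeView's tree files expect a correlation-like score, so
correlation-family trees write `1 - height`; other metrics write `-height`
and note it in a header comment.  Data cells carry 6 significant digits,
and `read_matrix()` on the CDT restores them exactly at that precision (the
round trip is asserted in the tests).  Heat-map tables order rows by
cluster, keep input order within a cluster, and use a symmetric diverging
scale anchored at zero (yellow/cyan by convention for EMAPs).

## Synthetic benchmarks: what they show

The generators are pure functions of their arguments including the seed.
`planted_partition()` is a stochastic block model; the benchmark condition
used throughout (4 blocks x 15 nodes, p_in 0.3, p_out 0.01) gives a mean
within-block degree of ~4.2 — deliberately sparse, the regime of real
interaction data.  Girvan-Newman, spectral clustering, ensemble consensus,
and transitivity clustering (midpoint threshold) recover the blocks at
adjusted Rand index >= 0.9 there; MCL at inflation 2 fragments them (ARI
~0.66, 8 clusters), exactly as reference MCL implementations do, and
reaches ARI 1.0 only at inflation ~1.4.  `synthetic_expression()` plants
matched gene/array groups with means of +/- effect size, Gaussian noise, an
optional Bernoulli missing mask, and row median-centering; silhouette-based
`select_k` recovers the planted block count noise-free and at a
noise-to-effect ratio of 1/3.

These fixtures emulate block structure, noise and missingness — not the
heavy-tailed degree distributions, hub proteins, overlapping complexes or
batch effects of real data sets.  Passing them shows the algorithms and
their plumbing are correct; it does not certify recovery rates on real
interactomes.

Problem sizes in the routine test suite are kept small (n <= 60 networks,
<= 100-row matrices, 50 random 8x3 matrices for the hierarchical oracle
sweep) — large enough to exercise every code path and tie-break, small
enough that the whole suite runs in well under a minute.

## Command-line interface

`inst/cli/clustkit.R` is a thin wrapper over `run_pipeline()` with
subcommands `cluster`, `cutoff`, `fixtures` and `describe`; exit code 2
flags configuration errors and 1 data errors, and `--quiet` silences the
provenance log.  Configuration files use YAML (a format with a reader in
every scientific R stack), with command-line flags taking precedence; all
defaults are printable via `describe`.  Nothing prompts interactively, so
every pipeline stage is scriptable.
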