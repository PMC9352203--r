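---
title: "Methods: correlation graphs, transforms, clustering and layout"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: correlation graphs, transforms, clustering and layout}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(corgraph)
```

This vignette records how the package's methods are defined, which knobs
matter, and where a design was genuinely open and a choice had to be made.

## The correlation-graph model

A `data_matrix` holds entities as rows and observations as columns; the
entity axis is what gets correlated, and `transpose_matrix()` switches it
(e.g. from individuals to the variants measured on them). For rows
*x*, *y* the package computes Pearson's *r*, or Spearman's rank variant
(Pearson on within-row average ranks), via `stats::cor`. The graph has one
node per row and an edge wherever the correlation passes the threshold,
weighted by the signed correlation.

Assumptions and conventions worth stating explicitly:

- **Strict threshold by default.** Thresholds are conventionally quoted as
  "r > 0.85", so the default comparison is strict; `inclusive = TRUE` is a
  flag. At `r_min = 1` the strict rule admits no edges and warns rather
  than erroring, since it is a legal (if degenerate) configuration.
- **Positive polarity by default.** How negative correlations should enter
  a similarity graph is application-dependent; the default keeps only
  positive correlations, and `polarity = "absolute"` admits strong
  anticorrelations while preserving the sign in the weight.
- **Missing data are pairwise-excluded, never imputed.** Zero is a
  meaningful value in expression data, so missing cells stay missing.
  Pairs with fewer than 3 shared observations get no edge: two shared
  points always give |r| = 1 and would flood the graph with spurious
  edges. Rows that are more than half missing are dropped on read, with a
  warning.
- **Constant rows are removed first** (variance below 1e-12), because
  Pearson is undefined at zero variance.
- **Blocked computation.** `build_correlation_graph()` correlates row
  tiles (default 512 rows) pairwise, so memory follows the block size and
  the thresholded edge list, never the full n × n matrix. A test pins the
  blocked path to the unblocked result.

## The graph model and transforms

Graphs are undirected, simple and weighted, with opaque string node ids
and typed attribute tables (numeric / categorical / text; missing values
are explicit). Directed or duplicate edges met on import are folded to one
undirected edge keeping the **maximum** weight — the folding rule is a
convention, chosen because correlation-style weights are similarities and
the strongest observed relation is the defensible summary. Self-loops are
rejected in construction and dropped (with a warning) on import.

All transforms are pure functions; predicates are one-sided formulas over
the attribute table (`~ weight >= 0.85`, `~ n >= 3`, `~ !(r_max < 0.85 &
Degree < 10)`), evaluated against values captured before any removal, so
one application never cascades.

- **k-NN pruning** uses the union rule: an edge survives iff it is among
  the top-k weights of *either* endpoint. This matches the usual k-NN
  graph construction, guarantees no node is isolated by pruning, and makes
  the transform idempotent. Mutual (intersection) k-NN is available as an
  option. Weight ties are broken by lexicographic edge identity so results
  are deterministic.
- **Edge contraction** is the quotient over connected subgraphs of
  matching edges: chains of matching edges collapse to a single node named
  after the lexicographically smallest member, carrying `members` and
  `n_members` attributes. Parallel edges arising from the quotient keep
  the maximum weight; numeric attributes declared `additive` are summed
  (for count-like columns), everything else inherits from the smallest-id
  member. Total membership is conserved.
- **Component removal** deletes whole components below a size floor and
  provably leaves surviving components untouched.

## Clustering and the granularity knob

Both algorithms expose one knob named *granularity*; the mapping is the
standard single parameter of each algorithm, which is a documented
assumption rather than a published definition:

- **Louvain**: granularity = the resolution γ in
  Q(γ) = Σ_c [e_c/m − γ(d_c/2m)²]. Local moves run to a gain threshold of
  1e-9, then clusters aggregate into super-nodes (intra-cluster weight
  kept as self-loops) and the process repeats until no level improves.
  The visiting order is shuffled from an integer seed; a fixed seed is
  bit-reproducible. Moves happen only on strictly positive gain, which
  rules out tie-induced oscillation.
- **MCL**: granularity = the inflation exponent (> 1). The weighted
  adjacency gets self-loops equal to each node's maximum incident weight
  (standard practice to damp odd-cycle parity effects; isolated nodes get
  a unit loop), is column-normalised, and then expansion (matrix square)
  alternates with inflation (entrywise power, renormalise). Entries below
  1e-5 are pruned after inflation; iteration stops when the largest
  absolute column change drops below 1e-8, capped at 100 rounds (reaching
  the cap warns and interprets the current matrix). Clusters are the
  connected components of the limit's nonzero structure; if a node ever
  sat in two attractor systems it would join the larger cluster (tie:
  smaller member id), keeping the partition hard.

Cluster names are `Cluster 1..N` in descending size order, ties broken by
smallest member id, so labels are stable across runs.

One empirical caveat the tests surface deliberately: on sparse planted
partitions (four 20-node blocks with within-block edge probability 0.3),
inflation 2.0 over-fragments the blocks — this is intrinsic MCL behaviour
at that edge density, reproduced identically by an independent dense
implementation, while inflations around 1.4–1.7 recover the blocks
exactly. The acceptance suite pins both observations rather than hiding
the first.

## Metrics

- **PageRank**: power iteration with uniform teleportation (damping 0.85
  by default), undirected edges treated as bidirectional and weights used
  as transition proportions; dangling (isolated) nodes redistribute their
  mass uniformly, so the result sums to 1. Convergence is an L1 change
  below 1e-10; failing to converge within 200 iterations is an error that
  reports the residual.
- **Betweenness** (nodes and edges): Brandes accumulation over unweighted
  hop-count shortest paths, per component, reported as raw unordered-pair
  counts with endpoints excluded from node scores. Hop counts rather than
  inverse-weight distances are deliberate: correlation weights are
  similarities, not metric distances, and treating them as lengths would
  quietly change the semantics.
- **Eccentricity**: maximum hop distance within the node's own component;
  isolated nodes score 0. The edge value is defined as the maximum of the
  endpoint values — a convention, flagged as such, since edge eccentricity
  has no canonical definition.

## Layout

Each component is laid out independently by a Fruchterman–Reingold spring
embedder: repulsion k²/d between all pairs (Barnes–Hut octree, opening
angle θ = 0.8), attraction w·d²/k along edges, displacement capped by a
step limit that cools geometrically (factor 0.95 per iteration from an
initial 0.1·√n·k). The ideal edge length k is the layout unit (default 1).
Iteration stops when the mean per-node displacement falls below
tol·k (default tol = 1e-3) or at `max_iter`; the `converged` flag reports
which. Initial positions are drawn uniformly in the unit cube from the
seed, and everything downstream is deterministic, so a seed pins the
coordinates bit-for-bit. Coincident points receive a tiny deterministic
separation kick instead of a random one, preserving reproducibility.

The layout is run-to-convergence rather than continuously animated — the
iteration cap is exposed so a caller can step it incrementally if they
want progressive refinement. Components are then arranged concentrically:
the largest at the origin, the rest on rings of increasing radius in rank
order, advancing to a wider ring when the current one fills. Neighbouring
bounding spheres are padded by 10% of the larger radius, and ring radii
always clear the extent of everything already placed, so bounding volumes
never overlap (a property the tests check on 50-component forests).
Force constants and the cooling schedule are package choices, documented
here precisely because only contract-level properties (determinism,
separation, disjointness) are externally testable.

## Visual encodings

Categorical attributes map to a 20-colour maximally-distinct palette in
frequency order (most common value gets the first colour; ties
lexicographic), cycling with a warning past 20 values; missing values are
neutral grey. Numeric attributes rescale affinely between the observed
minimum and maximum — t = (v − min)/(max − min), with t = 0.5 throughout
for a constant attribute — and map to a linear sRGB ramp (white → red by
default) and a size range [0.5, 2.0]. Min–max rather than percentile
rescaling is a deliberate, simpler choice; outlier-robust scaling can be
done upstream on the attribute itself. Encodings serialise as `colour`
and `size` attributes so any renderer can consume them from GraphML/JSON.

## Synthetic data: what it emulates, what it does not

- `planted_module_matrix()`: each module has a latent Gaussian profile;
  rows are profile + independent noise with variance (1 − ρ)/ρ, giving an
  expected within-module Pearson correlation of ρ (cross-module ≈ 0). This
  reproduces the *shape* of co-varying feature blocks — coexpressed gene
  modules, correlated dosage profiles — but none of the distributional
  texture of real data: no counts, no dropout, no library-size or batch
  effects, no heavy tails. Passing tests therefore demonstrate the
  machinery (thresholding, clustering, recovery), not robustness to
  real-data noise.
- `planted_partition_graph()`: stochastic block model with edge
  probabilities p_in/p_out and weight ranges per regime (defaults
  [0.7, 1] within, [0.1, 0.4] across, chosen so within-block edges look
  like strong correlations and cross-block edges like weak ones). The
  recovery benchmarks use four 20-node blocks at p_in = 0.3,
  p_out = 0.02.
- `dosage_matrix()`: 0/1/2 integers from block-specific allele
  frequencies — population-structured genotype shape, no linkage or
  coalescent realism.
- `toy_tree()`: balanced trees for taxonomy-shaped graphs.

All generators restore the caller's RNG state and are bit-reproducible
per seed.

## Problem sizes

The test and acceptance workloads are sized for quick, repeated runs on a
single core: 200 random 20×10 matrices for the correlation oracle, 100
random graphs of up to 12 nodes for exact betweenness enumeration, up to
50 nodes for PageRank linear solves, 20 seeds for each stochastic
recovery benchmark, 50-component forests and 30-node two-clique fixtures
for layout. These sizes are the package's own trade-off between coverage
and turnaround; the algorithms themselves have no such limits, and the
blocked correlation path is specifically there for matrices far larger
than anything in the tests.

## Known limitations

- Graphs are simple and undirected; no multigraphs, no directed
  analytics.
- Betweenness is unweighted by design (see above); closeness, HITS and
  weighted-path variants are out of scope.
- GML attribute keys must be alphanumeric, so other characters are
  sanitised to underscores with a warning — GraphML or JSON preserve
  arbitrary names and are the lossless round-trip formats.
- BioPAX, CX/CX2, Excel, MATLAB and DOT inputs are deliberately not
  parsed; asking for them produces a clear unsupported-format error.
- The Louvain granularity↔resolution and MCL granularity↔inflation
  mappings are the standard single knobs of each algorithm; other tools
  may scale their granularity differently, so numeric values are not
  necessarily portable across implementations.
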