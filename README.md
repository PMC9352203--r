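# corgraph

Correlation graphs, transform stacks, clustering and layout for tabular
data — a headless R toolkit for graph-based exploration of numeric matrices.

## What problem this solves

Much of systems biology reduces to the same move: take a numeric table —
genes × samples, cells × principal components, individuals × SNV dosages —
and ask which rows behave alike. `corgraph` turns that table into a
*correlation graph*: one node per row, an edge wherever the pairwise
correlation passes a threshold, weighted by the correlation itself. The
graph is then sharpened with composable transforms (k-nearest-neighbour
edge pruning, attribute filters, small-component removal, edge
contraction), partitioned with Markov (MCL) or Louvain clustering,
annotated with analytics (PageRank, betweenness, eccentricity, degree),
laid out in 2D or 3D with a seeded force-directed embedder, and styled by
mapping attributes to colour and size — everything a renderer or a
downstream analysis needs, with no GUI in the loop.

The core quantities, in standard notation:

- **Pearson correlation** between rows *x*, *y*:
  *r* = Σ(xᵢ−x̄)(yᵢ−ȳ) / √(Σ(xᵢ−x̄)² Σ(yᵢ−ȳ)²); Spearman is Pearson on
  within-row ranks. An edge (i, j) exists iff *r*ᵢⱼ > *r*min (strict by
  default, matching thresholds quoted as "r > 0.85"; inclusive and
  absolute-value variants are flags). Missing values are pairwise-excluded
  and pairs with < 3 shared observations get no edge.
- **k-NN pruning** keeps an edge iff it ranks in the top *k* weights of at
  least one endpoint (union rule), so pruning never isolates a node and
  each node keeps its strongest edge.
- **Louvain** maximises modularity
  *Q*(γ) = Σ_c [ e_c/m − γ (d_c/2m)² ] greedily over local moves and
  aggregation; the *granularity* knob is the resolution γ.
- **MCL** alternates expansion (squaring) and inflation (entrywise power)
  of the column-stochastic transition matrix; *granularity* is the
  inflation exponent. Larger granularity gives finer clusters for both.
- **Layout** is a Fruchterman–Reingold spring embedder (repulsion k²/d via
  a Barnes–Hut octree, attraction w·d²/k) run per component, with
  components arranged concentrically, largest at the centre.

## Worked example

Five planted modules of 20 rows each, recovered end to end:

```r
library(corgraph)

pm <- planted_module_matrix(n_modules = 5, rows_per_module = 20,
                            n_cols = 30, rho = 0.95, seed = 1)
pm$matrix
#> <data_matrix> 100 rows x 30 cols; 1 annotation column(s): Module

g <- build_correlation_graph(pm$matrix, r_min = 0.85)
g
#> <cgraph> 100 nodes, 950 edges, 5 components
#>   node attributes: Module

cl <- mcl_cluster(g, granularity = 1.7)
cl
#> <cluster_assignment> 5 clusters over 100 nodes
#> Sizes: 20 20 20 20 20

g <- set_cluster_attr(g, cl, "MCL Cluster")
g <- annotate_metrics(g, c("degree", "pagerank"))
head(g$node_attrs, 3)
#>           Module MCL Cluster Degree   PageRank
#> M01_R01 module_1   Cluster 1     19 0.01007928
#> M01_R02 module_1   Cluster 1     19 0.01002218
#> M01_R03 module_1   Cluster 1     19 0.01008668

lay <- force_layout(g, dims = 3, seed = 1)
lay
#> <layout_result> 100 nodes in 3D; converged after 120 iterations
```

The thresholded graph splits into exactly the five planted components
(every row correlates at r > 0.85 only with its own module), MCL at
granularity 1.7 recovers them perfectly, and the cross-tabulation of
cluster against truth is diagonal:

```r
table(get_node_attr(g, "MCL Cluster"), pm$labels[g$nodes])
#>             module_1 module_2 module_3 module_4 module_5
#>   Cluster 1       20        0        0        0        0
#>   Cluster 2        0       20        0        0        0
#>   Cluster 3        0        0       20        0        0
#>   Cluster 4        0        0        0       20        0
#>   Cluster 5        0        0        0        0       20
```

Styled graphs and coordinates serialise to GraphML/GML/JSON graph and TSV
(`write_graph_file()`, `write_layout()`), and `run_pipeline()` drives the
whole chain from a YAML config. A command-line wrapper with the same verbs
(`correlate`, `transform`, `cluster`, `metrics`, `layout`, `encode`,
`convert`, `fixtures`, `pipeline`) ships in `inst/cli/corgraph`:

```sh
CLI=$(Rscript -e 'cat(system.file("cli/corgraph", package = "corgraph"))')
Rscript $CLI correlate matrix.csv --min-r 0.85 --out graph.graphml
Rscript $CLI cluster graph.graphml --algorithm louvain --granularity 0.8 --out clustered.graphml
```

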