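# synkit

Represent, compare and cluster synthetic chemical routes in R.

Computer-aided synthesis planning (CASP) tools and reaction-network
databases both produce synthetic routes — but in mutually incompatible
formats and graph data models, which makes it hard to combine, compare
and rank routes for the same target across sources. `synkit` gives
computational and synthetic chemists a common in-memory model for routes
and the operations that make a route collection analyzable: descriptor
calculation, chemistry-aware distance, and clustering.

## The model

**Molecules and chemical equations are value objects.** A `molecule`'s
identity (`uid`) is a hash of its canonicalized structure under a
configurable policy (canonical isomeric SMILES by default; no-stereo
SMILES or InChIKey to merge stereoisomers or tautomers). A
`chemical_equation`'s identity is a hash of its sorted reactant and
product uids only — reagents, conditions and the order molecules were
written in never affect it, so the same transformation reported by two
CASP tools compares equal.

**Routes are SynGraphs.** A `syngraph` is an adjacency mapping from each
node to its set of children, directed in the synthetic direction
(starting materials toward target), in one of three data models:
bipartite (molecules and equations), monopartite reactions, or
monopartite molecules. A `synroute` is the single-root case: the
necessary-and-sufficient step set assembling one target. Graphs support
equality, union (`merge_syngraphs()`), proper-subset testing
(`is_subset()`), model conversion (`convert_data_model()`) and route
enumeration from a merged catalog (`extract_routes()`).

**Route descriptors** (computed on the monopartite-reactions
projection): number of steps, longest linear sequence (LLS), number of
branches, convergence = LLS / steps, and average branching factor =
non-root nodes / non-leaf nodes. The descriptor factory is extensible via
`register_route_descriptor()`.

**Route distance** is an exact graph edit distance (branch-and-bound over
node mappings, roots pinned for routes) where substituting same-kind
nodes costs `1 − Tanimoto(fingerprints)` — circular (ECFP) fingerprints
for molecules, a product-minus-reactant difference fingerprint for
reactions — and insertions, deletions and cross-kind swaps cost 1.
Distance matrices feed **clustering**: silhouette-optimized agglomerative
clustering (default below 15 routes) or a density-based method with noise
labels (default at 15 and above), with medoid representatives.

## Worked example

```r
library(synkit)

# a seeded synthetic fixture: 3-step main chain, 2-step branch into step 3
rt <- generate_route(route_spec(depth = 3, branch_points = list(c(3, 2)),
                                seed = 11))
rt$route
#> <synroute> bipartite: 12 molecules, 5 chemical equations, 16 edges  [fixture_seed11]

compute_route_descriptors(rt$route)
#> # A tibble: 5 × 3
#>   route_id       descriptor              value
#>   <chr>          <chr>                   <dbl>
#> 1 fixture_seed11 avg_branching_factor     1.33
#> 2 fixture_seed11 convergence              0.6
#> 3 fixture_seed11 longest_linear_sequence  3
#> 4 fixture_seed11 n_branches               1
#> 5 fixture_seed11 n_steps                  5
```

Five reactions overall, of which at most three lie on any single
starting-material-to-target path, so the route is convergent
(convergence 0.6 < 1) with one departure from linearity.

```r
routes <- lapply(1:6, function(s) {
  generate_route(route_spec(2 + s %% 3, seed = s))$route
})
dm <- route_distance_matrix(routes)   # pairwise chemistry-weighted GED
cl <- cluster_routes(dm, routes = routes)
cl
#> <route_cluster_result> method: agglomerative, 3 cluster(s), silhouette 0.396
cl$summary
#> # A tibble: 3 × 4
#>   cluster n_routes mean_steps mean_branches
#>     <int>    <int>      <dbl>         <dbl>
#> 1       1        2          3             0
#> 2       2        2          4             0
#> 3       3        2          2             0
```

The six linear routes of depths 2, 3 and 4 fall into three clusters by
size, as the silhouette scan over k picks the partition separating the
depth groups; each cluster's medoid is one of its own members.

For file-based batches, `process_routes()` reads CASP tree JSON or
node/edge JSON files (`{"file.json" = "tool_name"}`), writes the routes
in the requested format and data model (bipartite node/edge JSON by
default), and runs the requested functionalities (`compute_descriptors`
writes `descriptors.csv`; `clustering` writes `clusters.csv` and
`cluster_summary.csv`). `route_helper()` prints every option and its
default, and `inst/cli/routes.R` exposes the same pipeline as a shell
command.

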