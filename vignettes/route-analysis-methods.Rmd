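---
title: "Models and methods for synthetic-route analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for synthetic-route analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(synkit)
```

This vignette explains the scientific model behind `synkit`, the choices
made where the design was genuinely open, and what the package's tests
do and do not establish.

## Value objects and the identity layer

The package treats molecules and chemical equations as *value objects*:
their identity is entirely determined by immutable, structure-derived
properties, never by object identity or provenance. This is what makes
routes from different CASP tools comparable at all — two tools that
predict the same transformation must produce nodes that compare equal.

A `molecule`'s uid hashes its canonical structure under one of three
policies:

| policy | identity string | effect |
|---|---|---|
| `canonical-isomeric-smiles` (default) | canonical SMILES with stereo | stereoisomers distinct |
| `canonical-smiles-no-stereo` | canonical SMILES, stereo removed | stereoisomers merge |
| `inchikey` | InChIKey | tautomer-insensitive merging |

Coarser policies can only merge nodes, never split a uid-equal pair, so
switching policy is monotone in the partition-refinement sense. The
no-stereo policy is implemented by deleting stereo tokens (`@`, `/`,
`\`) from the input before canonicalization, which is equivalent to the
backend's own stereo-free output.

A `chemical_equation`'s uid hashes the *sorted reactant uids* and
*sorted product uids* only. Three consequences define the identity
layer: molecule order within a role is irrelevant; anything confined to
the reagent role is invisible; and stoichiometric multiplicities are
recorded but excluded. Role attribution assigns agent-block molecules to
the reagent role and also reassigns any molecule whose uid appears
verbatim on both sides (a spectator at this level of description). We do
not attempt mapping-based role detection: without atom mapping there is
no principled way to decide that a consumed molecule "really" acted as a
reagent, so the rule is deliberately syntactic and documented as such.

Chemistry — validation aside — is delegated to OpenBabel (via
ChemmineR/ChemmineOB): canonical SMILES, InChIKey, and ECFP circular
fingerprints. OpenBabel accepts some malformed SMILES silently, so a
lexical validator (token legality, balanced brackets, paired ring
bonds) runs first and raises an invalid-structure error naming the
offending string.

## The SynGraph model

A `syngraph` stores the graph as a mapping from each node to its
duplicate-free child set; edges are implicit and always point in the
synthetic direction (precursors toward target), so the target is the
unique sink of a route. The direction is a convention — the opposite one
would work — but it makes "root" coincide with the target and keeps the
descriptor definitions below readable. Child sets are kept sorted by uid
so that serialization and DOT export are deterministic; every node is a
key (possibly with an empty child set), which keeps root/leaf queries
total.

Three data models coexist. The bipartite model holds molecule and
equation nodes with role edges; the monopartite-reactions model keeps
equations only (an edge means a product of one step is a reactant of the
next); the monopartite-molecules model keeps molecules only and is
*lossy*, because the equations are implicit — conversions out of it are
refused rather than guessed. One representational decision deserves
emphasis: **reagent molecules are not graph nodes** in the bipartite
model; they live only in the equation's role map. Since graph equality
compares the adjacency dictionaries, this is precisely what makes two
routes that differ only in reagents compare equal, and it makes the
bipartite ⇄ monopartite-reactions round trip exact.

Equality is dictionary equality under node uids; subset testing is
containment of key-value pairs with equality excluded (proper subset),
implemented directly on the mapping with no isomorphism search; merging
is key-wise union, under which uid-equal nodes collapse — that is how a
route catalog (SynTree) is built from routes predicted by different
tools. Route extraction walks the catalog from the target: at every
molecule with more than one producing reaction it commits to one
producer, recursively, and returns the closure of each choice
combination; the number of distinct routes is the product of the
alternative counts. Cyclic graphs are refused — route extraction over
cycles has no agreed semantics, and guessing one silently would be worse
than an error.

## Route descriptors

All descriptors are defined on the monopartite-reactions projection and
are therefore invariant to the representation the route arrived in:

* `n_steps` — unique reaction nodes.
* `longest_linear_sequence` — the maximum number of reactions on any
  starting-material → target path (computed by memoized DFS on the DAG).
* `n_branches` — departures from linearity, counted as
  $\sum_c \max(0, \mathrm{indeg}(c) - 1)$: 0 for a linear route, 1 per
  binary convergence. A defensible alternative reading counts every
  *parent* feeding a convergent step; that convention is exposed as
  `n_branches(route, convention = "parents")` rather than silently
  chosen, because published descriptions are ambiguous between the two
  and no printed ground truth pins them apart.
* `convergence` — LLS / steps, in $(0, 1]$, equal to 1 exactly for
  linear routes.
* `avg_branching_factor` — (nodes − 1) / (nodes with indegree ≥ 1). For
  a single-step route the denominator is zero; the scalar function
  raises an undefined-descriptor error, while the tabular
  `compute_route_descriptors()` reports `NA` so one degenerate route
  cannot abort a batch.

The descriptor module is a factory: `register_route_descriptor()` adds a
named calculator that immediately becomes available to the table
builder, the facade and the helper, without modifying existing code.

## Graph edit distance

Route distance is the minimum-cost edit path transforming one graph into
an isomorph of the other. Costs: node insertion and deletion 1;
substitution of same-kind nodes `1 − similarity`; substitution across
kinds 1 (equivalent to a delete-insert pair); each inserted or deleted
edge 1, preserved edges free. The edge costs are a design decision the
route-comparison literature usually leaves implicit; unit edge costs
match the common GED convention and make the distance sensitive to
topology, not only node content. Similarity uses ECFP4-style circular
fingerprints (radius 2) and Tanimoto for molecules. For reactions we use
a difference fingerprint: stoichiometry-weighted product counts minus
reactant counts, split into its positive and negative parts and compared
with the min/max (generalized) Tanimoto — the split keeps the vectors
non-negative so the similarity stays in $[0, 1]$ with value 1 exactly
for identity-equal reactions. A structural (concatenated reactant/product
bit-union) variant is selectable.

The default search is exact: depth-first branch-and-bound over node
mappings with an admissible remaining-cost bound, candidate ordering by
substitution cost, and — for routes — the roots pinned onto each other
(`use_roots = TRUE`). Pinning is part of the distance's definition here,
not merely a speed-up: it encodes that two routes are compared as plans
for *their targets*, and it restricts the mapping space accordingly. The
test suite verifies the search against exhaustive enumeration over all
node mappings in both the pinned and unpinned modes. An `approximate`
beam-search mode (width 5 by default) is available for larger graphs and
is documented as an upper bound; it is never used in tests that assert
exact values. Distances default to the monopartite-reactions projection,
where the comparison concentrates on the chemistry of the steps;
fingerprints are computed once per node and cached because the
$O(n^2)$ pair loop dominates the matrix computation. The parallel path
farms out independent pairs and is bit-identical to the serial one.

## Clustering

The agglomerative path fits `hclust` (single linkage by default, the
usual choice when distances are edit-like and clusters may be chained)
on the precomputed matrix, scans $k \in [2, n-1]$ — the full range in
which a silhouette is defined, since no narrower scan range is obviously
right — and keeps the $k$ with the highest mean silhouette, breaking
ties toward smaller $k$ (parsimony). The density path is a DBSCAN on the
distance matrix; when `eps` is not given it is chosen by the same
silhouette scan over distance quantiles, with noise points contributing
zero width to the scanned score so that labelings explaining more routes
win over equally tight ones that discard routes as noise (the *reported*
silhouette excludes noise). The default method switches from
agglomerative to density at 15 routes. At least 3 routes are required
(a silhouette needs $2 \le k < n$); an all-zero matrix — all routes
equivalent — is returned as a single flagged degenerate cluster rather
than an error. Medoids minimize summed intra-cluster distance with ties
broken by position, and per-cluster summaries report route counts and
mean step/branch descriptors, with noise (−1) as its own row.

## The synthetic-route generator

Tests and the acceptance script run on seeded synthetic routes, not on
downloaded CASP output. The generator builds chains of "concatenation
reactions" over a 20-codeword alphabet of small amine/ether SMILES, each
codeword an `N` followed by one to four C/O atoms. Because no codeword
contains a second `N`, concatenations are uniquely decodable, and
because they never end in `N`, two different chains cannot collide by
being read in reverse — so distinct construction paths are guaranteed to
produce distinct molecules, and the descriptor values implied by the
construction (tracked as chain arithmetic while building, not measured
on the finished graph) are exact ground truth. Branch positions, branch
depths and seeds are explicit; the same spec and seed reproduce the same
route bit for bit, and no global RNG state leaks (`withr::with_seed`).

What the generator emulates: the *shape* of CASP output — single-target
DAGs with convergent branches, shared starting materials, alternative
producers in merged catalogs — with fully valid, canonicalizable
chemistry. What it does not emulate: chemical plausibility (the toy
reactions have no mechanism, realistic reagents, or balanced atoms),
molecule sizes typical of medicinal chemistry, stereochemistry-rich
structures, or CASP-specific metadata. Consequently, passing tests
establish the correctness of the graph, identity, descriptor, distance
and clustering machinery — they do not validate any chemical judgment
about real routes, which the package deliberately does not attempt.

Problem sizes used by the shipped suites — 50 graphs of at most 4
reaction nodes for the exhaustive-oracle sweep, 200 specs for descriptor
ground truth, 100 trials for identity invariances and round trips, 8
routes per distance matrix — were chosen so the whole suite exercises
every property at meaningful multiplicity while remaining comfortable to
run repeatedly during development.

## Numerical and degenerate-input choices

* Floating-point comparisons in the search use a `1e-9` slack; silhouette
  ties use `1e-12` (first maximum wins, favoring smaller $k$ and smaller
  `eps`).
* Distance matrices must be symmetric within `1e-9` and have a zero
  diagonal; violations raise an invalid-matrix error rather than being
  symmetrized silently.
* Empty graphs error on root/leaf queries; `merge_syngraphs(list())` is
  an error, not an empty graph, because the data model of the result
  would be undefined.
* Reading a node/edge document recomputes every uid from the structure
  strings; file uids only resolve edges, so a document produced under a
  different uid scheme still round-trips to an equal graph.

## Known limitations

* No atom mapping: role attribution is syntactic, and reaction
  similarity ignores atom-level correspondence.
* Cyclic reaction networks (full NOC subgraphs) are out of scope; only
  DAGs are accepted where routes are extracted.
* Exact GED is exponential in the worst case; it is intended for
  route-sized graphs (tens of nodes at most), with the beam mode as the
  documented escape hatch.
* The monopartite-molecules model cannot be converted back to richer
  models.
* In-memory adapters to third-party graph objects are an extension
  point of the format registry, not a shipped feature; DOT export is
  presentation-only.
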