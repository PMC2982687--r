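---
title: "Compression-based comparison of node-labeled networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Compression-based comparison of node-labeled networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netzip)
```

## The problem

Comparing the global structure of two large biological networks — say the
metabolic networks of two organisms, with compounds as vertices and
reactions as edges — is hard: subgraph isomorphism is intractable, and
alignment-style methods return interesting subnetworks rather than a
single similarity value. netzip takes the data-compression route instead:
compress each network, compress the two networks concatenated, and read
the similarity off the compression sizes. The crucial requirement is that
the compressor be *deterministic up to isomorphism* — two isomorphic
inputs must compress to identical rule sets and sizes, regardless of how
their vertices happen to be numbered in the input file. Matching-based
contraction schemes do not have this property; the two compressors
implemented here do.

## The compression model

A network is an undirected multigraph whose vertices carry labels from a
totally ordered set. Parallel edges are distinct members of the edge
multiset and self-loops are allowed; both arise during contraction, and
both count toward the edge total. Original labels are ordered numerically
when they all parse as integers (the Morgan-index case) and byte-wise
lexicographically otherwise; every label created during compression ranks
above all labels existing at its creation.

**CompressEdge** repeatedly partitions the non-self-loop edges by their
unordered endpoint-label pair. A class is *eligible* only if no two of its
edges share a vertex — in particular, a class containing parallel copies
of one vertex pair is ineligible, and self-loops are never candidates
(contracting an edge needs two distinct endpoints). Among eligible classes
the largest is contracted; every member edge is replaced by a fresh vertex
carrying a new label, edges incident to the removed endpoints re-attach to
the new vertex, and a former parallel edge between the two endpoints
becomes a self-loop and is retained. Each step removes at least one edge,
so the procedure terminates; it stops early when no class is eligible.

Ties between equally large classes are resolved by *label bags*: each
label `l` expands to a multiset `s(l)` of original labels (`s(l) = {l}`
for originals, the multiset union of the parts for derived labels). Bags
are compared after sorting in descending label order, position by
position, a strict prefix counting as smaller; remaining ties fall back to
the smaller label pair. Because distinct classes have distinct pairs, the
selection is always unique — this is what pins the whole run down.

The result is a grammar: an ordered rule list `R` (each rule
`l_n <- (l1, l2)`) plus the residual graph, and the compression size

```
C(G) = |R| + |Ec|
```

(rule count plus residual edge count, with multiplicity), which stands in
for the Kolmogorov complexity of the graph. The compression is lossy — the
original network cannot be rebuilt from `R` and the residual — but that
does not matter for similarity measurement.

**CompressVertices(M)** generalizes the unit of contraction from an edge
to a *connected vertex subset* of size `m = 2, ..., M`. Subsets are
canonicalized by their **dl-sequence**: the non-increasing sequence of
(degree, label) pairs, with degrees computed within the subset's induced
edge multiset, not the whole graph. Subsets with equal dl-sequences form a
class; a class is eligible when its members are pairwise disjoint. Each
outer iteration tries `m = 2` first and only moves to larger `m` when no
smaller class is eligible, and `m` restarts at 2 after every contraction.
Selection among the largest eligible classes uses the label bag of the
subset's labels, then the smaller dl-sequence. Contracting a member
removes its vertices and *all* induced edges — no self-loop is left
behind, unlike single-edge contraction — and re-attaches external edges to
the fresh vertex.

The dl-sequence is a deliberate surrogate for subgraph isomorphism: it is
cheap to compute and totally ordered, at the price that non-isomorphic
subsets can share a dl-sequence from size 4 upward (for example, the
4-vertex paths a-b-a-b and a-a-b-b). Such subsets are contracted under one
label; for three vertices the dl-sequence determines the subgraph.

## The similarity measure

The universal similarity metric expresses the distance between two objects
through conditional Kolmogorov complexities of each given the other.
Kolmogorov complexity is uncomputable, so `K(G)` is approximated by
`C(G)`, and the conditional complexity by `K(G1|G2) ~ C(G1 U G2) - C(G2)`,
where `G1 U G2` is the *disjoint* concatenation (same-labeled vertices
stay distinct vertices). Substituting into the max-form of the metric
gives the quantity computed by `gusm()`:

```
GUSM(G1, G2) = (C(G1 U G2) - min(C1, C2)) / max(C1, C2)
```

The shortest-program symbols of the underlying theory have no runtime
representation; only the three compression sizes are ever computed. Two
degenerate anchors are exact identities of the implementation, not
approximations:

* if `G` compresses completely (`|Ec| = 0`), `GUSM(G, G) = 0`;
* if no edge of `G` can be contracted (all equal-labeled edges overlap,
  as in a star with identically labeled leaves), `C(G) = |E|`,
  `C(G U G) = 2|E|`, and `GUSM(G, G) = 1`.

More generally the doubled graph compresses in lockstep with the single
one — same rule sequence, doubled class sizes — so
`C(G U G) = |R| + 2|Ec|` and `GUSM(G, G) = |Ec| / C(G)` for both
compressors. When both graphs are empty the distance is defined as 0
(identical objects). GUSM is symmetric and isomorphism-invariant, but the
greedy compressor carries no subadditivity guarantee, so values are not
certified to stay within [0, 1]; the package asserts only the identities
above.

## Morgan relabeling

Real metabolic networks label every vertex with a distinct compound, so
every edge class has one member and `C(G) = |E|`: nothing compresses.
Replacing labels with the **Morgan index** exposes structural regularity:
start from 1 everywhere and repeatedly assign each vertex the sum of its
neighbors' values (parallel edges with multiplicity). One iteration gives
the vertex degree; `morgan_original()` iterates until the number of
distinct values stops increasing and returns the last strictly refining
labeling — the pre-halt labeling is the finest one accepted. Isolated
vertices keep the value 0. Morgan values are graph invariants and never
cross components on a disjoint union, so relabeling before or after
concatenation is equivalent; each graph of a collection is relabeled on
its own. The iteration count `k` is a run-level parameter (`morgan:K` or
`morgan:auto` on the command line): small `k` leaves many equal labels and
overlapping classes, large `k` approaches the all-distinct regime, and
useful comparisons sit between the two.

## Clustering and the baseline

`distance_matrix()` computes all pairwise GUSM values (each single-graph
size computed once), `single_linkage()` builds the nearest-neighbor
dendrogram, and `to_newick()` exports it. Single linkage is implemented
in-package because run-reproducibility requires a documented tie-break:
among equally close cluster pairs, the pair whose first members have the
smallest name indices is merged. The tree is returned as a standard
`hclust` object; the Newick export places each node at half its merge
height, so leaf-to-leaf path lengths equal merge heights, and
`stats::hclust(method = "single")` serves as an independent cross-check in
the test suite.

`graphitour_compress()` is the comparison baseline: it picks the most
frequent label-pair class outright and contracts a *maximum cardinality
matching* of it, stopping when every class has fewer than two edges (a
rule must pay for itself; whether the historical tool contracted singleton
classes is not documented, and we choose not to). Maximum matchings are
generally not unique, so the result can depend on the order in which
vertices are presented — the flaw the deterministic compressors fix. The
implementation makes this explicit: an exact branch-and-bound matcher
prefers edges ranked by a caller-supplied `vertex_order`, and the result
records a per-step fingerprint trace, because on symmetric inputs
different orders can pass through different intermediate graphs yet
converge to one final graph. `size_distance()` (absolute node- or
edge-count difference) is the second, deliberately naive baseline.

## Synthetic data

All tests run on generated inputs; nothing is downloaded.
`random_labeled_graph(n, m, alphabet, seed)` draws a uniform simple graph
with uniform labels — edges are sampled without replacement from all
vertex pairs, so there are no parallel edges or loops at generation time
(contraction introduces them later). `permuted_copy()` renames vertices by
a seeded permutation and shuffles record order, which is how isomorphism
invariance is exercised. The two fixed fixtures are *constrained
reconstructions*: 7-vertex, 8-edge graphs reproducing the documented
edge-label counts, degree sequence (3, 3, 3, 2, 2, 2, 1), class overlap
structure and selection behavior of the compressors' worked examples;
tests assert that behavior, never a particular drawing.
`incompressible_star(k)` and `compressible_matching(k)` realize the two
compressibility extremes anchoring the GUSM identities. All generators are
seed-deterministic bit-for-bit, and restore the caller's RNG state.

Property tests draw from a fixed family — up to 30 vertices, up to 60
edges, alphabets of 2–4 labels, 50 graphs per property — chosen to be
dense enough that classes overlap, parallel edges appear during
contraction, and both compressors are exercised past their trivial paths,
while keeping the full suite within a couple of minutes. What passing
these tests shows is that the algorithmic invariants (determinism,
isomorphism invariance, lockstep self-similarity, oracle agreement) hold
on adversarially labeled random graphs; it does not show that GUSM
recovers phylogeny on real metabolic networks, which requires curated
pathway data outside the package's scope.

## Numerical and design choices

* **Label order for originals.** The total order on labels is required but
  its construction for original labels is free. We order numerically when
  every label parses as an integer, else byte-wise (`radix`)
  lexicographically — locale-independent, hence reproducible across
  systems.
* **Bag comparison on unequal sizes.** The element-wise rule is silent
  when one sorted bag exhausts first; a strict prefix compares as smaller,
  which keeps the order total.
* **Derived label display.** A derived label prints as the concatenation
  of its bag in ascending order (`'a','a','b'` → `"aab"`); displays are
  derived from bags only, so they are isomorphism-invariant.
* **Disjointness over distinct pairs.** A member set trivially intersects
  itself; the pairwise-disjointness condition on a class is read over
  distinct member pairs.
* **Bag of a vertex-set rule.** The update of `s(l_n)` for subset
  contraction is defined as the multiset union of the member labels' bags,
  by direct analogy with the edge case.
* **Self-loop policy.** Edge contraction retains a former parallel edge as
  a self-loop; subset contraction removes all induced edges including
  loops. Self-loops count in `|E|` and `|Ec|` but are never contraction
  candidates and add 2 to their vertex's degree.
* **Enumeration guard.** Connected subsets are enumerated by recursive
  growth from each anchor vertex (each subset emitted exactly once);
  complexity grows quickly with `M`, so the practical range is `M <= 5`
  and the default is `M = 3`.
* **Concatenation ids.** If the two inputs share vertex ids, ids are
  prefixed `1:`/`2:`; algorithms never read ids, only labels and
  structure, so this is invisible to the results.
* **When the edge loop stalls.** CompressEdge returns as soon as no class
  is eligible even though edges remain; there is deliberately no fallback
  to subset contraction inside it.
* **Edge multiplicity in files.** The TSV reader preserves exactly the
  edge multiset the file declares; whether a source network should be
  deduplicated is the caller's decision.

## Known limitations

* **CompressVertices(2) is not exactly CompressEdge on multigraphs.** The
  two coincide as long as the working graph stays simple (for example,
  throughout any run on a labeled tree, since contracting tree edges never
  creates parallels — the test suite asserts equivalence there). But once
  contraction creates parallel edges they can part ways: a doubled vertex
  pair forms its own dl-class (degrees 2,2) that subset contraction may
  contract, while the corresponding edge class contains both parallel
  copies and is permanently ineligible. On the first worked fixture the
  edge compressor finishes at size 7 with four residual edges, while
  subset contraction at `M = 2` continues through the doubled pairs down
  to size 4. On random graphs from the test family the two disagree on a
  sizable minority of inputs (21 of the 50 graphs drawn in the acceptance
  suite). The acceptance suite states the equivalence in its classical
  form and records the divergence honestly rather than weakening either
  procedure.
* GUSM is not a metric and not certified to lie in [0, 1]; it is a
  similarity score whose anchors (0 and 1 for the two self-distance
  extremes) are exact.
* The compression is lossy, and directed graphs and edge labels are out of
  scope.
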