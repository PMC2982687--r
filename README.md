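# netzip — compression-based comparison of node-labeled networks

netzip measures the similarity of biological networks (e.g. metabolic
networks with compounds as vertices and reactions as edges) by *graph
compression*. Each network is compressed by iteratively contracting
identical pieces; the similarity of two networks is read off the
compression sizes of the individual networks and of their concatenation.
The compressors are deterministic up to isomorphism — two isomorphic
inputs always yield identical rule sequences and sizes, regardless of
vertex numbering or file order — which is the property that makes the
resulting distances meaningful.

## The method in brief

A network is an undirected multigraph `G(V, E)` with vertex labels from a
totally ordered set. Two compressors produce a grammar (an ordered rule
list `R`) and a residual graph `Gc`:

* **CompressEdge** — contract, at each step, the uniquely selected class of
  identically labeled edges whose members are pairwise vertex-disjoint
  (largest class first; ties by the smaller label bag `s(l1) ∪ s(l2)`,
  then the smaller label pair).
* **CompressVertices(M)** — generalize the unit of contraction to connected
  vertex subsets of size `m = 2, …, M`, canonicalized by their
  *dl-sequence* (the non-increasing sequence of within-subset
  (degree, label) pairs), restarting at `m = 2` after every contraction.

The compression size `C(G) = |R| + |Ec|` stands in for the Kolmogorov
complexity `K(G)`, and the universal similarity metric is approximated by

    GUSM(G1, G2) = (C(G1 ∪ G2) − min(C1, C2)) / max(C1, C2)

where `G1 ∪ G2` is the disjoint concatenation. Two exact anchors: a fully
compressible graph has self-distance 0, and a graph none of whose edges
can be contracted (all equal-labeled edges overlap) has self-distance 1.

Around the core sit Morgan-index relabeling (`morgan_iterate()`,
`morgan_original()`, `morgan_relabel()`) to expose structure in networks
whose labels are all distinct, single-linkage clustering with Newick
export (`single_linkage()`, `to_newick()`), a matching-based baseline
compressor (`graphitour_compress()`) whose order-dependence motivates the
deterministic design, and seeded synthetic generators (`fig1_like()`,
`fig2_like()`, `random_labeled_graph()`, …) so every claim is testable
without external data. See the vignette
(`vignettes/network-compression.Rmd`) for the full model, parameter
guidance, design choices and known limitations.

## Worked example

```r
library(netzip)

g <- fig1_like()              # 7 vertices, 8 edges, labels a/b/c
degree_sequence(g)
#> [1] 3 3 3 2 2 2 1
res <- compress_edge(g)
res
#> compression_result (edge): 3 rules + 4 residual edges = size 7
sapply(res$rules, function(r) paste0(r$new, " <- (", paste(r$body, collapse = ", "), ")"))
#> [1] "aa <- (a, a)"   "bb <- (b, b)"   "aac <- (aa, c)"
```

The four (a,b) edges overlap pairwise, so they are never contracted; the
two disjoint (a,a) edges go first, and the run stops at size
`C(G) = 3 + 4 = 7`. The self-distance anchors are exact:

```r
star <- incompressible_star(3);  gusm(star, star)            # all edges overlap
#> [1] 1
matching <- compressible_matching(2);  gusm(matching, matching)
#> [1] 0
```

A small collection — two isomorphic sparse networks and an unrelated one —
clusters as it should:

```r
g1 <- random_labeled_graph(24, 18, c("a", "b"), seed = 11)
g2 <- permuted_copy(g1, seed = 99)        # isomorphic copy of g1
g3 <- random_labeled_graph(24, 18, c("a", "b"), seed = 12)
d <- distance_matrix(list(net1 = g1, net1_iso = g2, net2 = g3), method = "edge")
round(d, 3)
#>           net1 net1_iso  net2
#> net1     0.000    0.938 1.176
#> net1_iso 0.938    0.000 1.176
#> net2     1.176    1.176 0.000
to_newick(single_linkage(d))
#> [1] "((net1:0.46875,net1_iso:0.46875):0.1194852941,net2:0.5882352941);"
```

The isomorphic pair is closest (its distance, 15/16 = 0.938, equals
`|Ec|/C(G)` — the residue the greedy compressor cannot remove even from
two identical graphs), and the unrelated network joins last.

A command-line wrapper covering `compress`, `gusm`, `matrix`, `cluster`
and `synth` ships in `inst/scripts/netzip.R`:

```sh
Rscript inst/scripts/netzip.R synth --kind matching --k 4 --out m4.tsv
Rscript inst/scripts/netzip.R compress --method edge m4.tsv
# method=edge rules=1 residual_edges=0 size=1
```

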