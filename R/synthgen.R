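#' Seeded random labeled graph
#'
#' Simple graph (no parallel edges, no self-loops) with `n` vertices, `m`
#' edges drawn uniformly among vertex pairs, and labels drawn uniformly from
#' `alphabet`. The same `seed` always yields the same graph; the caller's
#' RNG state is left untouched.
#'
#' @param n Number of vertices.
#' @param m Number of edges, at most `n * (n - 1) / 2`.
#' @param alphabet Non-empty character vector of labels.
#' @param seed Integer seed.
#' @return A [labeled_graph] with ids `v1, ..., vn`.
#' @examples
#' g <- random_labeled_graph(10, 15, c("a", "b"), seed = 1)
#' c(n_vertices(g), n_edges(g))
#' @export
random_labeled_graph <- function(n, m, alphabet = c("a", "b"), seed = 1) {
  stopifnot(n >= 1, length(alphabet) >= 1)
  if (m > n * (n - 1) / 2) stop("`m` exceeds the number of vertex pairs")
  withr::with_seed(as.integer(seed), {
    ids <- paste0("v", seq_len(n))
    labs <- sample(as.character(alphabet), n, replace = TRUE)
    if (m > 0) {
      pairs <- which(upper.tri(matrix(0L, n, n)), arr.ind = TRUE)
      pick <- pairs[sample.int(nrow(pairs), m), , drop = FALSE]
      edges <- data.frame(from = ids[pick[, 1]], to = ids[pick[, 2]],
                          stringsAsFactors = FALSE)
    } else {
      edges <- NULL
    }
    labeled_graph(stats::setNames(labs, ids), edges)
  })
}

#' Isomorphic permuted copy of a graph
#'
#' Renames the vertex ids by a seeded random permutation of the id set and
#' shuffles the vertex and edge record order (and edge endpoint order). The
#' result is isomorphic to the input; compressing it must give identical
#' rule sequences and sizes.
#'
#' @param g A [labeled_graph].
#' @param seed Integer seed.
#' @return A [labeled_graph].
#' @export
permuted_copy <- function(g, seed = 1) {
  stopifnot(inherits(g, "labeled_graph"))
  withr::with_seed(as.integer(seed), {
    ids <- g$vertices$id
    new_ids <- stats::setNames(sample(ids), ids)
    v <- data.frame(id = unname(new_ids[ids]), label = g$vertices$label,
                    stringsAsFactors = FALSE)
    v <- v[sample.int(nrow(v)), , drop = FALSE]
    e <- g$edges
    if (nrow(e)) {
      from <- unname(new_ids[e$from]); to <- unname(new_ids[e$to])
      swap <- sample(c(TRUE, FALSE), length(from), replace = TRUE)
      e <- data.frame(from = ifelse(swap, to, from), to = ifelse(swap, from, to),
                      stringsAsFactors = FALSE)
      e <- e[sample.int(nrow(e)), , drop = FALSE]
    }
    rownames(v) <- rownames(e) <- NULL
    labeled_graph(v, e)
  })
}

#' Worked-example fixtures
#'
#' Two fixed 7-vertex, 8-edge graphs that exercise the selection rules of
#' the compressors.
#'
#' `fig1_like()` carries 4 edges labeled (a,b), 2 edges (a,a), 1 edge (b,b)
#' and 1 edge (a,c); its degree sequence is (3, 3, 3, 2, 2, 2, 1). The (a,b)
#' class overlaps and is ineligible, so edge compression starts by
#' contracting the two disjoint (a,a) edges.
#'
#' `fig2_like()` carries 4 edges (a,b), 2 edges (a,c) and 2 edges (b,c);
#' every edge class overlaps, so no pair can be contracted. At subset size 3
#' the two overlapping (a,b,c) triangles are ineligible and the two disjoint
#' b-a-b paths -- label set (a,b,b), dl-sequence ((2,a),(1,b),(1,b)) -- are
#' contracted first.
#'
#' @return A [labeled_graph].
#' @examples
#' degree_sequence(fig1_like())
#' select_vertices(fig2_like(), 3)$dl
#' @export
fig1_like <- function() {
  labeled_graph(
    c(a1 = "a", a2 = "a", a3 = "a", a4 = "a", b1 = "b", b2 = "b", c1 = "c"),
    data.frame(
      from = c("a1", "a3", "b1", "a1", "a2", "a3", "a4", "a1"),
      to   = c("a2", "a4", "b2", "b1", "b1", "b2", "b2", "c1"),
      stringsAsFactors = FALSE
    )
  )
}

#' @rdname fig1_like
#' @export
fig2_like <- function() {
  labeled_graph(
    c(a1 = "a", a2 = "a", b1 = "b", b2 = "b", b3 = "b", b4 = "b", c1 = "c"),
    data.frame(
      from = c("a1", "a1", "a2", "a2", "a1", "a2", "b2", "b3"),
      to   = c("b1", "b2", "b3", "b4", "c1", "c1", "c1", "c1"),
      stringsAsFactors = FALSE
    )
  )
}

#' Compressibility extremes
#'
#' `incompressible_star(k)` is a star with center labeled `"a"` and `k`
#' leaves labeled `"b"`: all equally labeled edges share the center, no
#' class is eligible, and `C(G) = k`; its GUSM self-distance under edge
#' compression is 1. `compressible_matching(k)` is `k` pairwise-disjoint
#' a-b edges: one rule contracts everything, `C(G) = 1`, and the GUSM
#' self-distance is 0.
#'
#' @param k Number of leaves / edges, at least 2.
#' @return A [labeled_graph].
#' @examples
#' compression_size(incompressible_star(4)) # 4
#' compression_size(compressible_matching(4)) # 1
#' @export
incompressible_star <- function(k) {
  stopifnot(k >= 2)
  ids <- c("hub", paste0("leaf", seq_len(k)))
  labeled_graph(
    stats::setNames(c("a", rep("b", k)), ids),
    data.frame(from = rep("hub", k), to = ids[-1], stringsAsFactors = FALSE)
  )
}

#' @rdname incompressible_star
#' @export
compressible_matching <- function(k) {
  stopifnot(k >= 2)
  labeled_graph(
    stats::setNames(rep(c("a", "b"), k), paste0(rep(c("u", "w"), k), rep(seq_len(k), each = 2))),
    data.frame(
      from = paste0("u", seq_len(k)), to = paste0("w", seq_len(k)),
      stringsAsFactors = FALSE
    )
  )
}
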