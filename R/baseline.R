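#' Matching-based baseline compressor
#'
#' Reimplementation of the GRAPHITOUR-style contraction scheme used as a
#' comparison baseline: at each step the most frequent endpoint-label-pair
#' class is chosen (ties by the smaller label pair), a *maximum cardinality
#' matching* is computed among that class's edges, and the matched edges are
#' contracted under one new label. Compression stops once every class has
#' fewer than 2 edges, so a rule always pays for itself.
#'
#' When a class's edges overlap, the maximum matching is generally not
#' unique; ties are resolved through `vertex_order`, which makes the
#' dependence of the result on the input's vertex ordering explicit and
#' reproducible. That dependence is exactly what the deterministic
#' compressors [compress_edge()] and [compress_vertices()] eliminate.
#'
#' @param g A [labeled_graph].
#' @param vertex_order Character vector: a permutation of all vertex ids of
#'   `g`, used to rank edges when several maximum matchings exist.
#' @return A `compression_result` with `method = "graphitour"` and an extra
#'   component `trace`: one label-level fingerprint of the working graph per
#'   contraction step, so that order-dependent intermediate results are
#'   observable even when runs converge to the same final graph.
#' @examples
#' r <- graphitour_compress(compressible_matching(3))
#' r$size # 1, same as compress_edge on a disjoint matching
#' @export
graphitour_compress <- function(g, vertex_order = g$vertices$id) {
  stopifnot(inherits(g, "labeled_graph"))
  vertex_order <- as.character(vertex_order)
  if (anyDuplicated(vertex_order) || !setequal(vertex_order, g$vertices$id) ||
      length(vertex_order) != nrow(g$vertices)) {
    stop("`vertex_order` must be a permutation of all vertex ids")
  }
  state <- new_compress_state(g)
  vrank <- match(state$ids, vertex_order)
  rules <- list()
  trace <- character()
  repeat {
    classes <- edge_class_partition(state)
    if (!length(classes)) break
    cnt <- vapply(classes, function(cl) length(cl$rows), integer(1))
    if (max(cnt) < 2) break
    cand <- classes[cnt == max(cnt)]
    best <- cand[[1]]
    for (cl in cand[-1]) {
      if (cl$l1 < best$l1 || (cl$l1 == best$l1 && cl$l2 < best$l2)) best <- cl
    }
    e <- state$edges
    rows <- best$rows
    r1 <- pmin(vrank[e[rows, 1]], vrank[e[rows, 2]])
    r2 <- pmax(vrank[e[rows, 1]], vrank[e[rows, 2]])
    pref <- rows[order(r1, r2, rows)]
    matched <- max_matching_pref(e, pref, length(state$vlab))
    step <- contract_edge_class_state(
      state, list(l1 = best$l1, l2 = best$l2, rows = matched)
    )
    state <- step$state
    vrank <- c(vrank, max(vrank, 0L) + seq_along(matched))
    rules[[length(rules) + 1L]] <- step$rule
    trace <- c(trace, graph_label_fingerprint(state_to_graph(state)))
  }
  res <- new_compression_result(rules, state_to_graph(state), method = "graphitour")
  res$trace <- trace
  res
}

# Exact maximum cardinality matching over the given edge rows, found by
# branch and bound that prefers taking edges in `pref` order; among equal
# maxima the preference-first one is kept, which pins the result to the
# vertex order.
max_matching_pref <- function(edges, pref, n_vertices) {
  k <- length(pref)
  best <- integer(0)
  used <- logical(n_vertices)
  rec <- function(i, chosen) {
    if (length(chosen) + (k - i + 1L) <= length(best)) return(invisible())
    if (i > k) {
      if (length(chosen) > length(best)) best <<- chosen
      return(invisible())
    }
    r <- pref[[i]]
    a <- edges[r, 1]; b <- edges[r, 2]
    if (!used[[a]] && !used[[b]]) {
      used[[a]] <<- TRUE; used[[b]] <<- TRUE
      rec(i + 1L, c(chosen, r))
      used[[a]] <<- FALSE; used[[b]] <<- FALSE
    }
    rec(i + 1L, chosen)
  }
  rec(1L, integer(0))
  best
}

#' Node- or edge-count distance between two graphs
#'
#' The naive baseline the compression distance is compared against: the
#' absolute difference of vertex counts or of edge counts.
#'
#' @param g1,g2 [labeled_graph] objects.
#' @param mode `"nodes"` or `"edges"`.
#' @return A non-negative number.
#' @examples
#' size_distance(incompressible_star(3), compressible_matching(3), "nodes") # 2
#' @export
size_distance <- function(g1, g2, mode = c("nodes", "edges")) {
  mode <- match.arg(mode)
  switch(mode,
    nodes = abs(n_vertices(g1) - n_vertices(g2)),
    edges = abs(n_edges(g1) - n_edges(g2))
  )
}
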