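#' @title Iterative contraction of identical edges (CompressEdge)
#' @description
#' Compresses a node-labeled multigraph by repeatedly contracting the
#' uniquely selected class of identically labeled edges. In each round the
#' edges are partitioned by their (unordered) endpoint-label pair; a class is
#' *eligible* only when no two of its edges share a vertex (self-loops are
#' never candidates), which is what makes the result independent of vertex
#' ids and input order. Among eligible classes the algorithm picks the most
#' frequent one, breaking ties first by the smaller label bag
#' ([label_bag_less()]) and then by the smaller descending-sorted label pair.
#' Every member edge is replaced by one fresh vertex carrying a new label
#' that ranks above all existing labels; edges incident to the removed
#' endpoints are re-attached to the new vertex, and a former parallel edge
#' between the two endpoints becomes a self-loop and is retained.
#'
#' The returned compression size `C(G) = |R| + |E_c|` (rule count plus
#' residual edge count) is the package's stand-in for the Kolmogorov
#' complexity of the graph; see [gusm()].
#'
#' @param g A [labeled_graph].
#' @return A `compression_result`: list with components `rules` (list of
#'   rules in extraction order, each with `new`, `kind = "edge"` and `body`,
#'   the label pair `(l1, l2)` with `l1 >= l2`), `residual` (the compressed
#'   [labeled_graph]), `size` and `method`.
#' @examples
#' compress_edge(fig1_like())$rules[[1]]$body # c("a", "a")
#' compress_edge(compressible_matching(4))$size # 1
#' @export
compress_edge <- function(g) {
  stopifnot(inherits(g, "labeled_graph"))
  state <- new_compress_state(g)
  rules <- list()
  while (nrow(state$edges) > 0) {
    cl <- select_edge_class_state(state)
    if (is.null(cl)) break
    step <- contract_edge_class_state(state, cl)
    state <- step$state
    rules[[length(rules) + 1L]] <- step$rule
  }
  new_compression_result(rules, state_to_graph(state), method = "edge")
}

new_compression_result <- function(rules, residual, method) {
  structure(
    list(
      rules = rules,
      residual = residual,
      size = length(rules) + nrow(residual$edges),
      method = method
    ),
    class = "compression_result"
  )
}

#' @export
print.compression_result <- function(x, ...) {
  cat(sprintf(
    "compression_result (%s): %d rules + %d residual edges = size %d\n",
    x$method, length(x$rules), nrow(x$residual$edges), x$size
  ))
  invisible(x)
}

## ---- internal steps over the compression state ----------------------------

# Partition non-self-loop edges by sorted endpoint-label pair. Each class
# records the label ordinals (l1 >= l2), the member edge rows, and whether
# the members are pairwise vertex-disjoint (which includes excluding classes
# containing parallel copies of one vertex pair).
edge_class_partition <- function(state) {
  e <- state$edges
  if (!nrow(e)) return(list())
  nonloop <- which(e[, 1] != e[, 2])
  if (!length(nonloop)) return(list())
  la <- state$vlab[e[nonloop, 1]]
  lb <- state$vlab[e[nonloop, 2]]
  l1 <- pmax(la, lb); l2 <- pmin(la, lb)
  groups <- split(seq_along(nonloop), paste(l1, l2))
  lapply(groups, function(ix) {
    rows <- nonloop[ix]
    list(
      l1 = l1[ix[[1]]], l2 = l2[ix[[1]]], rows = rows,
      eligible = anyDuplicated(as.vector(e[rows, , drop = FALSE])) == 0L
    )
  })
}

# Deterministic unique selection: maximum cardinality among eligible
# classes, then smallest merged label bag, then smallest label pair.
select_edge_class_state <- function(state, classes = edge_class_partition(state)) {
  elig <- Filter(function(cl) cl$eligible, classes)
  if (!length(elig)) return(NULL)
  cnt <- vapply(elig, function(cl) length(cl$rows), integer(1))
  cand <- elig[cnt == max(cnt)]
  best <- cand[[1]]
  if (length(cand) > 1) {
    best_bag <- merge_bags(state$reg, best$l1, best$l2)
    for (cl in cand[-1]) {
      bag <- merge_bags(state$reg, cl$l1, cl$l2)
      if (rank_bag_less(bag, best_bag)) {
        best <- cl; best_bag <- bag
      } else if (!rank_bag_less(best_bag, bag)) {
        if (cl$l1 < best$l1 || (cl$l1 == best$l1 && cl$l2 < best$l2)) {
          best <- cl; best_bag <- bag
        }
      }
    }
  }
  best
}

# Contracts every member edge of the class to a fresh vertex labeled with a
# new top-ranked label whose bag is s(l1) U s(l2).
contract_edge_class_state <- function(state, cl) {
  nl <- state_new_label(state, merge_bags(state$reg, cl$l1, cl$l2))
  state <- nl$state
  rule <- list(
    new = nl$display,
    kind = "edge",
    body = c(state$reg$display[[cl$l1]], state$reg$display[[cl$l2]])
  )
  e <- state$edges
  newv <- integer(length(cl$rows))
  for (k in seq_along(cl$rows)) {
    av <- state_add_vertex(state, nl$ordinal)
    state <- av$state
    newv[[k]] <- av$vertex
  }
  map <- seq_along(state$vlab)
  v1 <- e[cl$rows, 1]; v2 <- e[cl$rows, 2]
  map[v1] <- newv; map[v2] <- newv
  state$vlab[c(v1, v2)] <- NA_integer_
  keep <- setdiff(seq_len(nrow(e)), cl$rows)
  state$edges <- cbind(map[e[keep, 1]], map[e[keep, 2]])
  list(state = state, rule = rule)
}

## ---- public single-step interface -----------------------------------------

# Converts an internal class to its public face on the original graph.
class_public <- function(state, g, cl) {
  list(
    label_pair = c(state$reg$display[[cl$l1]], state$reg$display[[cl$l2]]),
    edges = g$edges[cl$rows, , drop = FALSE]
  )
}

#' Eligible edge classes of a graph
#'
#' Partitions the non-self-loop edges by sorted endpoint-label pair and
#' returns the *eligible* classes: those whose member edges are pairwise
#' vertex-disjoint (a class containing parallel copies of one vertex pair is
#' therefore excluded).
#'
#' @param g A [labeled_graph].
#' @return A list of classes, each a list with `label_pair` (character
#'   `(l1, l2)`, `l1 >= l2`) and `edges` (the member rows of `g$edges`),
#'   ordered by descending class size and then by label pair.
#' @examples
#' length(build_edge_classes(fig1_like())) # the overlapping (b,a) class is absent
#' @export
build_edge_classes <- function(g) {
  stopifnot(inherits(g, "labeled_graph"))
  state <- new_compress_state(g)
  elig <- Filter(function(cl) cl$eligible, edge_class_partition(state))
  if (!length(elig)) return(list())
  o <- order(
    -vapply(elig, function(cl) length(cl$rows), integer(1)),
    vapply(elig, function(cl) cl$l1, integer(1)),
    vapply(elig, function(cl) cl$l2, integer(1))
  )
  unname(lapply(elig[o], function(cl) class_public(state, g, cl)))
}

#' Select the edge class to contract next
#'
#' Applies the deterministic selection rule (largest eligible class, ties by
#' smaller label bag, then smaller label pair) to a graph.
#'
#' @param g A [labeled_graph].
#' @return The chosen class in the format of [build_edge_classes()], or
#'   `NULL` when no class is eligible.
#' @examples
#' select_edge_class(fig1_like())$label_pair # c("a", "a")
#' @export
select_edge_class <- function(g) {
  stopifnot(inherits(g, "labeled_graph"))
  state <- new_compress_state(g)
  cl <- select_edge_class_state(state)
  if (is.null(cl)) return(NULL)
  class_public(state, g, cl)
}

#' Contract one edge class
#'
#' Performs a single contraction step on `g` for the class with the given
#' endpoint-label pair, which must be eligible. Intended for stepping through
#' a compression by hand; full runs ([compress_edge()]) maintain the derived
#' label order internally.
#'
#' @param g A [labeled_graph].
#' @param label_pair Character vector of the two endpoint labels (in either
#'   order).
#' @return A list with the emitted `rule` and the contracted `graph`.
#' @examples
#' step <- contract_edge_class(fig1_like(), c("a", "a"))
#' n_vertices(step$graph) # 5
#' @export
contract_edge_class <- function(g, label_pair) {
  stopifnot(inherits(g, "labeled_graph"), length(label_pair) == 2)
  state <- new_compress_state(g)
  classes <- edge_class_partition(state)
  want <- sort(as.character(label_pair))
  hit <- NULL
  for (cl in classes) {
    have <- sort(c(state$reg$display[[cl$l1]], state$reg$display[[cl$l2]]))
    if (identical(have, want)) { hit <- cl; break }
  }
  if (is.null(hit)) {
    stop("no edge class with endpoint labels (", paste(label_pair, collapse = ", "), ")")
  }
  if (!hit$eligible) {
    stop("edge class (", paste(label_pair, collapse = ", "), ") is not eligible: members share a vertex")
  }
  step <- contract_edge_class_state(state, hit)
  list(rule = step$rule, graph = state_to_graph(step$state))
}
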