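#' Node-labeled undirected multigraph
#'
#' The central container of the package: an undirected multigraph whose
#' vertices carry labels (e.g. chemical compound names or Morgan indices).
#' Edges form a multiset, so parallel edges are distinct members and
#' self-loops are representable; both arise naturally during contraction and
#' both count towards the edge total.
#'
#' @param vertices Either a data frame with character columns `id` and
#'   `label`, or a named character vector (names are vertex ids, values are
#'   labels).
#' @param edges A data frame (or two-column matrix) whose first two columns
#'   hold the endpoint ids of each edge, or `NULL` for an edgeless graph.
#'   Row order and duplicate rows are preserved.
#' @return An object of class `labeled_graph`: a list with data-frame
#'   components `vertices` (`id`, `label`) and `edges` (`from`, `to`).
#' @examples
#' g <- labeled_graph(c(v1 = "a", v2 = "b"), data.frame(from = "v1", to = "v2"))
#' n_edges(g)
#' @export
labeled_graph <- function(vertices, edges = NULL) {
  if (is.character(vertices)) {
    if (is.null(names(vertices)) && length(vertices) > 0) {
      stop("character `vertices` must be named (names are vertex ids)")
    }
    vertices <- data.frame(
      id = if (length(vertices)) names(vertices) else character(),
      label = unname(vertices),
      stringsAsFactors = FALSE
    )
  }
  if (!is.data.frame(vertices) || !all(c("id", "label") %in% names(vertices))) {
    stop("`vertices` must be a data frame with columns `id` and `label`")
  }
  v <- data.frame(
    id = as.character(vertices$id),
    label = as.character(vertices$label),
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(v$id)) {
    stop("duplicate vertex ids: ", paste(unique(v$id[duplicated(v$id)]), collapse = ", "))
  }
  if (is.null(edges)) {
    e <- data.frame(from = character(), to = character(), stringsAsFactors = FALSE)
  } else {
    if (is.matrix(edges)) edges <- as.data.frame(edges, stringsAsFactors = FALSE)
    if (!is.data.frame(edges) || ncol(edges) < 2) {
      stop("`edges` must be a data frame or matrix with two columns")
    }
    e <- data.frame(
      from = as.character(edges[[1]]),
      to = as.character(edges[[2]]),
      stringsAsFactors = FALSE
    )
  }
  unknown <- setdiff(unique(c(e$from, e$to)), v$id)
  if (length(unknown)) {
    stop("edge endpoint(s) not declared as vertices: ", paste(unknown, collapse = ", "))
  }
  structure(list(vertices = v, edges = e), class = "labeled_graph")
}

#' @export
print.labeled_graph <- function(x, ...) {
  cat(sprintf(
    "labeled_graph: %d vertices, %d edges, %d distinct labels\n",
    nrow(x$vertices), nrow(x$edges), length(unique(x$vertices$label))
  ))
  invisible(x)
}

#' Vertex and edge counts
#'
#' Edges are counted with multiplicity (parallel edges and self-loops each
#' count once per multiset member).
#'
#' @param g A [labeled_graph].
#' @return An integer count.
#' @export
n_vertices <- function(g) nrow(g$vertices)

#' @rdname n_vertices
#' @export
n_edges <- function(g) nrow(g$edges)

#' Disjoint union (concatenation) of two labeled graphs
#'
#' Concatenates two graphs for joint compression: every vertex and edge of
#' both inputs is kept, and vertices with identical labels remain distinct
#' vertices. When the two graphs share vertex ids, ids are prefixed with
#' `"1:"` / `"2:"` to keep them distinct; labels are never altered.
#'
#' @param g1,g2 [labeled_graph] objects.
#' @return A [labeled_graph] with `n_vertices(g1) + n_vertices(g2)` vertices
#'   and `n_edges(g1) + n_edges(g2)` edges.
#' @examples
#' g <- labeled_graph(c(v1 = "a", v2 = "b"), data.frame(from = "v1", to = "v2"))
#' n_vertices(concatenate(g, g))
#' @export
concatenate <- function(g1, g2) {
  stopifnot(inherits(g1, "labeled_graph"), inherits(g2, "labeled_graph"))
  v1 <- g1$vertices; e1 <- g1$edges
  v2 <- g2$vertices; e2 <- g2$edges
  if (length(intersect(v1$id, v2$id))) {
    v1$id <- paste0("1:", v1$id)
    v2$id <- paste0("2:", v2$id)
    if (nrow(e1)) { e1$from <- paste0("1:", e1$from); e1$to <- paste0("1:", e1$to) }
    if (nrow(e2)) { e2$from <- paste0("2:", e2$from); e2$to <- paste0("2:", e2$to) }
  }
  labeled_graph(rbind(v1, v2), rbind(e1, e2))
}

#' Degree sequence of a labeled graph
#'
#' @param g A [labeled_graph].
#' @return The non-increasing integer sequence of vertex degrees. Parallel
#'   edges count with multiplicity and a self-loop adds 2 to its vertex.
#' @examples
#' degree_sequence(fig1_like())
#' @export
degree_sequence <- function(g) {
  stopifnot(inherits(g, "labeled_graph"))
  unname(sort(vertex_degrees(g), decreasing = TRUE))
}

# Named per-vertex degrees (self-loop adds 2), in vertex order.
vertex_degrees <- function(g) {
  deg <- integer(nrow(g$vertices))
  names(deg) <- g$vertices$id
  if (nrow(g$edges)) {
    tab <- table(factor(c(g$edges$from, g$edges$to), levels = g$vertices$id))
    deg[] <- as.integer(tab)
  }
  deg
}

# Edge multiset as a sorted character vector of canonical "u|v" keys
# (endpoints sorted within each edge); used for multiset equality in tests
# and for graph comparison.
edge_multiset <- function(g) {
  if (!nrow(g$edges)) return(character())
  sort(paste(pmin(g$edges$from, g$edges$to), pmax(g$edges$from, g$edges$to), sep = "|"))
}

# Canonical label-level fingerprint of a graph: multiset of vertex labels
# plus multiset of endpoint-label pairs. Invariant under vertex renaming.
graph_label_fingerprint <- function(g) {
  lab <- stats::setNames(g$vertices$label, g$vertices$id)
  vpart <- paste(sort(g$vertices$label), collapse = ",")
  if (nrow(g$edges)) {
    a <- lab[g$edges$from]; b <- lab[g$edges$to]
    epart <- paste(sort(paste(pmin(a, b), pmax(a, b), sep = "|")), collapse = ",")
  } else {
    epart <- ""
  }
  paste(vpart, epart, sep = " / ")
}
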