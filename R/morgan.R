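#' Morgan index relabeling
#'
#' The Morgan index assigns 1 to every vertex and then repeatedly replaces
#' each vertex's value by the sum of its neighbors' values (parallel edges
#' counted with multiplicity). One iteration yields the vertex degree.
#' Because networks whose vertices all carry distinct labels (e.g. compounds
#' in a metabolic network) are incompressible by label-class contraction,
#' replacing labels with Morgan indices exposes structural regularity to the
#' compressors while remaining a graph invariant.
#'
#' `morgan_original()` iterates until the number of distinct values stops
#' increasing and returns the last strictly refining labeling (the
#' "original" Morgan index).
#'
#' @param g A [labeled_graph] without self-loops.
#' @param k Number of iterations, at least 1.
#' @return A `morgan_labeling`: list with `values` (named numeric vector,
#'   one entry per vertex) and `iteration` (the iteration that produced the
#'   values).
#' @examples
#' p3 <- labeled_graph(c(v1 = "x", v2 = "x", v3 = "x"),
#'                     data.frame(from = c("v1", "v2"), to = c("v2", "v3")))
#' morgan_iterate(p3, 1)$values # degrees: 1, 2, 1
#' @export
morgan_iterate <- function(g, k) {
  stopifnot(inherits(g, "labeled_graph"))
  if (!is.numeric(k) || length(k) != 1 || k < 1) stop("`k` must be at least 1")
  if (nrow(g$edges) && any(g$edges$from == g$edges$to)) {
    stop("Morgan indices are defined for graphs without self-loops")
  }
  val <- morgan_run(g, as.integer(k))
  structure(list(values = val, iteration = as.integer(k)), class = "morgan_labeling")
}

# k sweeps of neighbor-sum starting from all ones; doubles to keep exactness
# for the value ranges reached at practical iteration counts.
morgan_run <- function(g, k, start = NULL) {
  ids <- g$vertices$id
  n <- length(ids)
  val <- if (is.null(start)) rep(1, n) else start
  e1 <- match(g$edges$from, ids)
  e2 <- match(g$edges$to, ids)
  for (t in seq_len(k)) {
    nxt <- numeric(n)
    if (length(e1)) {
      s <- rowsum(c(val[e2], val[e1]), group = c(e1, e2))
      nxt[as.integer(rownames(s))] <- s[, 1]
    }
    val <- nxt
  }
  stats::setNames(val, ids)
}

#' @rdname morgan_iterate
#' @export
morgan_original <- function(g) {
  stopifnot(inherits(g, "labeled_graph"))
  if (nrow(g$edges) && any(g$edges$from == g$edges$to)) {
    stop("Morgan indices are defined for graphs without self-loops")
  }
  t <- 1L
  cur <- morgan_run(g, 1L)
  repeat {
    nxt <- morgan_run(g, 1L, start = unname(cur))
    nxt <- stats::setNames(nxt, names(cur))
    if (length(unique(nxt)) <= length(unique(cur))) {
      return(structure(list(values = cur, iteration = t), class = "morgan_labeling"))
    }
    cur <- nxt
    t <- t + 1L
  }
}

#' @export
print.morgan_labeling <- function(x, ...) {
  cat(sprintf(
    "morgan_labeling: iteration %d, %d vertices, %d distinct values\n",
    x$iteration, length(x$values), length(unique(x$values))
  ))
  invisible(x)
}

#' Relabel a graph with Morgan indices
#'
#' Replaces every vertex label by the decimal rendering of its Morgan value;
#' topology is untouched. The resulting all-integer labels are ordered
#' numerically by the compressors.
#'
#' @param g A [labeled_graph].
#' @param labeling A `morgan_labeling` covering all vertices of `g`; by
#'   default [morgan_original()] of `g`.
#' @return A [labeled_graph].
#' @examples
#' p3 <- labeled_graph(c(v1 = "x", v2 = "x", v3 = "x"),
#'                     data.frame(from = c("v1", "v2"), to = c("v2", "v3")))
#' morgan_relabel(p3, morgan_iterate(p3, 1))$vertices$label # "1" "2" "1"
#' @export
morgan_relabel <- function(g, labeling = morgan_original(g)) {
  stopifnot(inherits(g, "labeled_graph"), inherits(labeling, "morgan_labeling"))
  miss <- setdiff(g$vertices$id, names(labeling$values))
  if (length(miss)) {
    stop("labeling does not cover vertex id(s): ", paste(miss, collapse = ", "))
  }
  v <- g$vertices
  v$label <- format(labeling$values[v$id], scientific = FALSE, trim = TRUE)
  labeled_graph(v, g$edges)
}
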