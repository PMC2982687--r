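#' Compression size of a graph
#'
#' `C(G) = |R| + |E_c|`: the number of contraction rules plus the number of
#' residual edges (with multiplicity). This quantity approximates the
#' Kolmogorov complexity of the graph and is the raw material of the GUSM
#' distance.
#'
#' @param g A [labeled_graph].
#' @param method `"edge"` for [compress_edge()], `"vertices"` for
#'   [compress_vertices()].
#' @param M Maximum subset size when `method = "vertices"`.
#' @return A non-negative integer.
#' @examples
#' compression_size(incompressible_star(3)) # 3: nothing contracts
#' compression_size(compressible_matching(5)) # 1: one rule, no residue
#' @export
compression_size <- function(g, method = c("edge", "vertices"), M = 3) {
  method <- match.arg(method)
  run_compressor(g, method, M)$size
}

run_compressor <- function(g, method, M) {
  switch(method,
    edge = compress_edge(g),
    vertices = compress_vertices(g, M)
  )
}

#' GUSM: compression-based similarity of two graphs
#'
#' Approximates the universal similarity metric by graph compression. With
#' `C1 = C(G1)`, `C2 = C(G2)` and `C12 = C(G1 U G2)` (the disjoint
#' concatenation, [concatenate()]), the conditional complexity of one graph
#' given the other is approximated by `C12 - C(other)`, giving
#'
#' `GUSM(G1, G2) = (C12 - min(C1, C2)) / max(C1, C2)`.
#'
#' Two copies of a fully compressible graph have distance 0; two copies of a
#' graph none of whose edges can be contracted have distance 1. When both
#' graphs are empty the distance is defined as 0. The value is symmetric and
#' invariant under vertex renaming, but the greedy compressor carries no
#' subadditivity guarantee, so GUSM is not certified to stay within [0, 1]
#' in general.
#'
#' @param g1,g2 [labeled_graph] objects.
#' @inheritParams compression_size
#' @return A numeric distance.
#' @examples
#' s <- incompressible_star(3)
#' gusm(s, s) # 1
#' m <- compressible_matching(2)
#' gusm(m, m) # 0
#' @export
gusm <- function(g1, g2, method = c("edge", "vertices"), M = 3) {
  method <- match.arg(method)
  c1 <- compression_size(g1, method, M)
  c2 <- compression_size(g2, method, M)
  c12 <- compression_size(concatenate(g1, g2), method, M)
  den <- max(c1, c2)
  if (den == 0) return(0)
  (c12 - min(c1, c2)) / den
}

#' Pairwise GUSM distance matrix over a graph collection
#'
#' Computes all pairwise GUSM values; each single-graph compression size is
#' computed once and reused across pairs.
#'
#' @param graphs A named list of [labeled_graph] objects (at least 2, names
#'   unique).
#' @inheritParams compression_size
#' @return A symmetric numeric matrix with zero diagonal and the graph names
#'   as dimnames.
#' @examples
#' gs <- list(a = incompressible_star(3), b = compressible_matching(3))
#' distance_matrix(gs)
#' @export
distance_matrix <- function(graphs, method = c("edge", "vertices"), M = 3) {
  method <- match.arg(method)
  if (!is.list(graphs) || length(graphs) < 2) stop("need a list of at least 2 graphs")
  nms <- names(graphs)
  if (is.null(nms) || any(!nzchar(nms))) stop("`graphs` must be a fully named list")
  if (anyDuplicated(nms)) {
    stop("duplicate graph names: ", paste(unique(nms[duplicated(nms)]), collapse = ", "))
  }
  n <- length(graphs)
  sizes <- vapply(graphs, compression_size, numeric(1), method = method, M = M)
  d <- matrix(0, n, n, dimnames = list(nms, nms))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      c12 <- compression_size(concatenate(graphs[[i]], graphs[[j]]), method, M)
      den <- max(sizes[[i]], sizes[[j]])
      d[i, j] <- d[j, i] <- if (den == 0) 0 else (c12 - min(sizes[[i]], sizes[[j]])) / den
    }
  }
  d
}

#' Read and write distance matrices as TSV
#'
#' Full symmetric matrix with a leading header row and a name column.
#'
#' @param d A symmetric numeric matrix with dimnames.
#' @param path File path.
#' @return `write_distance_matrix()` returns `path` invisibly;
#'   `read_distance_matrix()` returns the matrix.
#' @export
write_distance_matrix <- function(d, path) {
  stopifnot(is.matrix(d), !is.null(rownames(d)))
  tab <- cbind(name = rownames(d), as.data.frame(d, check.names = FALSE))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_distance_matrix
#' @export
read_distance_matrix <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                           stringsAsFactors = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- tab[[1]]
  storage.mode(m) <- "double"
  m
}
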