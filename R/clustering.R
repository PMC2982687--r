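#' Single-linkage clustering of a distance matrix
#'
#' Agglomerative nearest-neighbor clustering: the pair of clusters with the
#' smallest minimum inter-cluster distance is merged at each step. Ties are
#' broken deterministically by the smaller index (position in the matrix's
#' names) of each cluster's first member, so identical inputs always yield
#' identical trees. Merge heights are non-decreasing, as single linkage
#' guarantees.
#'
#' @param d A symmetric numeric matrix with dimnames (e.g. from
#'   [distance_matrix()]), or a [stats::dist] object.
#' @return An object of class `hclust` (method `"single"`), so the standard
#'   `plot()`, `cutree()` and conversion tooling apply.
#' @examples
#' d <- matrix(c(0, .1, .9, .1, 0, .9, .9, .9, 0), 3,
#'             dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
#' single_linkage(d)$height # 0.1 0.9
#' @export
single_linkage <- function(d) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  stopifnot(is.matrix(d), nrow(d) == ncol(d))
  if (nrow(d) < 2) stop("need at least 2 items")
  if (!isTRUE(all.equal(d, t(d), check.attributes = FALSE))) {
    stop("distance matrix must be symmetric")
  }
  labels <- rownames(d)
  if (is.null(labels)) labels <- paste0("V", seq_len(nrow(d)))
  n <- nrow(d)
  cd <- d
  diag(cd) <- Inf
  members <- as.list(seq_len(n))     # leaf indices per active cluster
  code <- -seq_len(n)                # hclust coding: -leaf or +merge step
  first <- seq_len(n)                # tie-break key: smallest leaf index
  active <- rep(TRUE, n + (n - 1))
  # grow cd/members/code/first as merges append new clusters
  merge <- matrix(0L, n - 1, 2)
  height <- numeric(n - 1)
  cd <- rbind(cbind(cd, matrix(Inf, n, n - 1)), matrix(Inf, n - 1, 2 * n - 1))
  for (step in seq_len(n - 1)) {
    act <- which(active[seq_len(n + step - 1)])
    best <- NULL
    for (i in act) {
      for (j in act) {
        if (j <= i) next
        a <- min(first[i], first[j]); b <- max(first[i], first[j])
        if (is.null(best) ||
            cd[i, j] < best$h ||
            (cd[i, j] == best$h && (a < best$a || (a == best$a && b < best$b)))) {
          best <- list(i = i, j = j, h = cd[i, j], a = a, b = b)
        }
      }
    }
    i <- best$i; j <- best$j
    new <- n + step
    # left child is the cluster containing the earlier-indexed leaf
    merge[step, ] <- if (first[i] <= first[j]) c(code[i], code[j]) else c(code[j], code[i])
    height[step] <- best$h
    members[[new]] <- c(members[[i]], members[[j]])
    code[new] <- step
    first[new] <- min(first[i], first[j])
    active[c(i, j)] <- FALSE
    active[new] <- TRUE
    for (k in which(active[seq_len(new - 1)])) {
      cd[k, new] <- cd[new, k] <- min(cd[i, k], cd[j, k])
    }
  }
  structure(
    list(
      merge = merge, height = height,
      order = dendro_order(merge, n),
      labels = labels, method = "single",
      call = match.call(), dist.method = "GUSM"
    ),
    class = "hclust"
  )
}

# Leaf ordering by left-to-right traversal of the merge tree.
dendro_order <- function(merge, n) {
  rec <- function(node) {
    if (node < 0) return(-node)
    c(rec(merge[node, 1]), rec(merge[node, 2]))
  }
  rec(n - 1)
}

#' Export a dendrogram as a Newick string
#'
#' Writes an `hclust` tree (typically from [single_linkage()]) as an
#' ultrametric Newick tree. Each node is placed at half its merge height, so
#' the two leaves of a cluster merged at height `h` sit at depth `h / 2` --
#' leaf-to-leaf path lengths then equal the merge heights. Labels containing
#' Newick metacharacters or spaces are single-quoted.
#'
#' @param h An `hclust` object.
#' @param digits Significant digits for branch lengths.
#' @return A Newick string ending in `";"`.
#' @examples
#' d <- matrix(c(0, 1, 1, 0), 2, dimnames = list(c("A", "B"), c("A", "B")))
#' to_newick(single_linkage(d)) # "(A:0.5,B:0.5);"
#' @export
to_newick <- function(h, digits = 10) {
  stopifnot(inherits(h, "hclust"))
  quote_label <- function(x) {
    if (grepl("[][ ():,;']", x)) paste0("'", gsub("'", "''", x), "'") else x
  }
  fmt <- function(x) sprintf(paste0("%.", digits, "g"), x)
  rec <- function(node, parent_height) {
    if (node < 0) {
      return(paste0(quote_label(h$labels[[-node]]), ":", fmt(parent_height / 2)))
    }
    hh <- h$height[[node]]
    paste0(
      "(", rec(h$merge[node, 1], hh), ",", rec(h$merge[node, 2], hh), ")",
      if (!is.na(parent_height)) paste0(":", fmt((parent_height - hh) / 2)) else ""
    )
  }
  n <- length(h$height)
  paste0(rec(n, NA_real_), ";")
}
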