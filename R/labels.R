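#' Ordering machinery for labels, label bags and dl-sequences
#'
#' Compression requires a strict total order on labels. Original labels are
#' ordered numerically when every label parses as an integer (the Morgan
#' index case) and byte-wise lexicographically otherwise; every label derived
#' during compression ranks above all labels existing at its creation. Each
#' label `l` carries a bag `s(l)` of original labels: `s(l) = {l}` for an
#' original label, and the multiset union of the constituents' bags for a
#' derived one. Bags drive tie-breaking between equally frequent contraction
#' candidates.
#'
#' @name label-order
NULL

# Unique displays in ascending label order: numeric if all parse as
# integers, else byte-wise (radix) lexicographic -- locale-independent.
order_label_displays <- function(labs) {
  u <- unique(as.character(labs))
  if (length(u) && all(grepl("^-?[0-9]+$", u))) {
    u[order(as.numeric(u))]
  } else {
    sort(u, method = "radix")
  }
}

#' Compare two label bags
#'
#' Sorts each bag's labels in descending label order and compares
#' position-wise: the bag with the smaller label at the first differing
#' position is the smaller bag; a strict prefix compares as smaller. This is
#' the tie-break applied between equally frequent contraction candidates.
#'
#' @param s1,s2 Character vectors of (original) labels, multiplicity given by
#'   repetition.
#' @param labels Optional character vector giving the ascending label order
#'   explicitly; by default the order is inferred from the labels present
#'   (numeric when all parse as integers, lexicographic otherwise).
#' @return `TRUE` iff `s1` sorts strictly before `s2`.
#' @examples
#' label_bag_less(c("a", "a", "b"), c("b", "b")) # (b,a,a) < (b,b)
#' @export
label_bag_less <- function(s1, s2, labels = NULL) {
  if (is.null(labels)) labels <- order_label_displays(c(s1, s2))
  r1 <- match(as.character(s1), labels)
  r2 <- match(as.character(s2), labels)
  if (anyNA(r1) || anyNA(r2)) stop("bag contains labels absent from `labels`")
  rank_bag_less(sort(r1, decreasing = TRUE), sort(r2, decreasing = TRUE))
}

# Core comparison on descending-sorted integer rank vectors.
rank_bag_less <- function(r1, r2) {
  r1 <- unname(r1); r2 <- unname(r2)
  n <- min(length(r1), length(r2))
  if (n > 0) {
    d <- which(r1[seq_len(n)] != r2[seq_len(n)])
    if (length(d)) return(r1[d[[1]]] < r2[d[[1]]])
  }
  length(r1) < length(r2)
}

#' dl-sequence of a connected vertex subset
#'
#' Canonicalizes a connected vertex subset as the non-increasing sequence of
#' (degree, label) pairs, where each degree is computed within the subset's
#' induced edge multiset -- not the whole graph. Parallel induced edges count
#' with multiplicity and an induced self-loop adds 2. Pairs are ordered by
#' `(d1, l1) > (d2, l2)` iff `d1 > d2`, or `d1 == d2` and `l1 > l2`.
#'
#' @param g A [labeled_graph].
#' @param subset Character vector of vertex ids inducing a connected
#'   subgraph.
#' @return A data frame with columns `degree` (integer) and `label`
#'   (character), rows sorted non-increasingly.
#' @examples
#' g <- labeled_graph(c(u = "a", v = "a", w = "b"),
#'                    data.frame(from = c("u", "v"), to = c("v", "w")))
#' dl_sequence(g, c("u", "v", "w")) # ((2,'a'), (1,'b'), (1,'a'))
#' @export
dl_sequence <- function(g, subset) {
  stopifnot(inherits(g, "labeled_graph"))
  subset <- as.character(subset)
  if (anyDuplicated(subset)) stop("`subset` has duplicate ids")
  miss <- setdiff(subset, g$vertices$id)
  if (length(miss)) stop("unknown vertex id(s): ", paste(miss, collapse = ", "))
  keep <- g$edges$from %in% subset & g$edges$to %in% subset
  ind <- g$edges[keep, , drop = FALSE]
  if (!induced_connected(subset, ind)) stop("`subset` does not induce a connected subgraph")
  deg <- table(factor(c(ind$from, ind$to), levels = subset))
  labs <- g$vertices$label[match(subset, g$vertices$id)]
  ord_labels <- order_label_displays(g$vertices$label)
  rk <- match(labs, ord_labels)
  o <- order(-as.integer(deg), -rk)
  data.frame(
    degree = as.integer(deg)[o], label = labs[o],
    stringsAsFactors = FALSE, row.names = NULL
  )
}

# Connectivity of a vertex set under a given induced edge list.
induced_connected <- function(subset, ind_edges) {
  n <- length(subset)
  if (n <= 1) return(TRUE)
  comp <- seq_len(n)
  find <- function(i) { while (comp[i] != i) { comp[i] <<- comp[comp[i]]; i <- comp[i] }; i }
  a <- match(ind_edges$from, subset); b <- match(ind_edges$to, subset)
  for (k in seq_along(a)) {
    ra <- find(a[[k]]); rb <- find(b[[k]])
    if (ra != rb) comp[ra] <- rb
  }
  length(unique(vapply(seq_len(n), find, integer(1)))) == 1L
}

#' Compare two dl-sequences
#'
#' Strict element-wise first-difference comparison of two equal-length
#' dl-sequences under the (degree, label) pair order.
#'
#' @param a,b dl-sequences as returned by [dl_sequence()]: data frames with
#'   columns `degree` and `label`, of equal length.
#' @param labels Optional explicit ascending label order (see
#'   [label_bag_less()]).
#' @return `TRUE` iff `a` sorts strictly before `b`.
#' @export
dl_less <- function(a, b, labels = NULL) {
  if (nrow(a) != nrow(b)) stop("dl-sequences must have equal length")
  if (is.null(labels)) labels <- order_label_displays(c(a$label, b$label))
  ra <- match(a$label, labels); rb <- match(b$label, labels)
  if (anyNA(ra) || anyNA(rb)) stop("dl-sequence contains labels absent from `labels`")
  dl_rank_less(cbind(a$degree, ra), cbind(b$degree, rb))
}

# a, b: m x 2 matrices of (degree, label rank) rows, already sorted.
dl_rank_less <- function(a, b) {
  for (i in seq_len(nrow(a))) {
    if (a[i, 1] != b[i, 1]) return(unname(a[i, 1] < b[i, 1]))
    if (a[i, 2] != b[i, 2]) return(unname(a[i, 2] < b[i, 2]))
  }
  FALSE
}

## ---- internal compression state -------------------------------------------

# The state carries: a label registry (display strings, origin, bags as
# descending-sorted integer vectors of original-label ordinals), per-vertex
# label ordinals (NA = contracted away), the edge multiset as an integer
# matrix of vertex indices, and the original id strings for surviving
# vertices.
new_compress_state <- function(g) {
  ids <- g$vertices$id
  labs <- g$vertices$label
  displays <- order_label_displays(labs)
  nl <- length(displays)
  reg <- list(
    display = displays,
    origin = rep("original", nl),
    bags = lapply(seq_len(nl), function(i) i)
  )
  e <- cbind(
    match(g$edges$from, ids),
    match(g$edges$to, ids)
  )
  if (!nrow(g$edges)) e <- matrix(integer(), ncol = 2)
  list(
    reg = reg,
    vlab = match(labs, displays),
    edges = e,
    ids = ids,
    derived_count = 0L
  )
}

# Adds a derived label whose bag is the multiset union given by `bag`
# (integer ordinals of original labels). Its display is the concatenation of
# the bag's original displays in ascending label order ('a','a','b' -> "aab").
state_new_label <- function(state, bag) {
  ord <- length(state$reg$display) + 1L
  display <- paste(state$reg$display[sort(bag)], collapse = "")
  state$reg$display <- c(state$reg$display, display)
  state$reg$origin <- c(state$reg$origin, "derived")
  state$reg$bags <- c(state$reg$bags, list(sort(bag, decreasing = TRUE)))
  list(state = state, ordinal = ord, display = display)
}

# Appends one vertex carrying label ordinal `lab`; returns its index.
state_add_vertex <- function(state, lab) {
  state$vlab <- c(state$vlab, lab)
  state$ids <- c(state$ids, NA_character_)
  list(state = state, vertex = length(state$vlab))
}

# Rebuilds a labeled_graph from the surviving vertices. Derived vertices get
# fresh ids c1, c2, ... disambiguated against the original id set.
state_to_graph <- function(state) {
  alive <- which(!is.na(state$vlab))
  ids <- state$ids[alive]
  need <- which(is.na(ids))
  if (length(need)) {
    taken <- c(stats::na.omit(state$ids))
    k <- 0L
    for (i in need) {
      repeat {
        k <- k + 1L
        cand <- paste0("c", k)
        if (!cand %in% taken) break
      }
      ids[[i]] <- cand
      taken <- c(taken, cand)
    }
  }
  idx <- integer(length(state$vlab))
  idx[alive] <- seq_along(alive)
  e <- state$edges
  labeled_graph(
    data.frame(id = ids, label = state$reg$display[state$vlab[alive]], stringsAsFactors = FALSE),
    data.frame(from = ids[idx[e[, 1]]], to = ids[idx[e[, 2]]], stringsAsFactors = FALSE)
  )
}

# Multiset-union bag of two labels (ordinals), descending-sorted.
merge_bags <- function(reg, l1, l2) {
  sort(c(reg$bags[[l1]], reg$bags[[l2]]), decreasing = TRUE)
}
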