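#' @title Iterative contraction of identical connected vertex sets
#' @description
#' Generalizes [compress_edge()] by contracting identical *connected vertex
#' subsets* of size `m = 2, ..., M` instead of single edges. Subsets are
#' canonicalized by their dl-sequence (the non-increasing sequence of
#' within-subset degree / label pairs, [dl_sequence()]), which stands in for
#' subgraph isomorphism: subsets with equal dl-sequences form one class. In
#' each round the smallest subset size with an eligible class wins (`m`
#' restarts at 2 after every contraction); a class is eligible when its
#' member subsets are pairwise disjoint. Among the largest eligible classes
#' ties are broken by the smaller label bag and then by the smaller
#' dl-sequence. Contracting a member removes its vertices and *all* induced
#' edges -- no self-loop is left behind -- and re-attaches external edges to
#' the fresh vertex.
#'
#' Because classes are keyed by dl-sequence, non-isomorphic subsets with
#' equal dl-sequences (possible from size 4 upward) are deliberately merged
#' under one label; for three vertices the dl-sequence determines the
#' subgraph.
#'
#' @param g A [labeled_graph].
#' @param M Maximum subset size to try (`>= 2`). `M = 2` mirrors
#'   [compress_edge()] on graphs that stay simple throughout the run; see the
#'   package vignette for where the two procedures part ways on multigraphs.
#' @return A `compression_result` (see [compress_edge()]); vertex-set rules
#'   have `kind = "vertex_set"` and `body` equal to the class dl-sequence (a
#'   data frame with columns `degree`, `label`).
#' @examples
#' compress_vertices(fig2_like(), 3)$rules[[1]]$body
#' @export
compress_vertices <- function(g, M = 3) {
  stopifnot(inherits(g, "labeled_graph"))
  if (!is.numeric(M) || length(M) != 1 || M < 2) {
    stop("`M` must be at least 2: a single vertex cannot be contracted")
  }
  M <- as.integer(M)
  state <- new_compress_state(g)
  rules <- list()
  while (nrow(state$edges) > 0) {
    sel <- NULL
    for (m in 2:M) {
      sel <- select_vertices_state(state, m)
      if (!is.null(sel)) break
    }
    if (is.null(sel)) break
    step <- contract_subset_class_state(state, sel)
    state <- step$state
    rules[[length(rules) + 1L]] <- step$rule
  }
  new_compression_result(rules, state_to_graph(state), method = "vertices")
}

## ---- internal: subset enumeration and class selection ---------------------

# Adjacency over active vertices (unique neighbors, self-loops dropped).
state_adjacency <- function(state) {
  n <- length(state$vlab)
  adj <- rep(list(integer()), n)
  e <- state$edges
  if (nrow(e)) {
    nl <- e[, 1] != e[, 2]
    a <- e[nl, 1]; b <- e[nl, 2]
    nb <- split(c(b, a), c(a, b))
    for (k in names(nb)) adj[[as.integer(k)]] <- sort(unique(nb[[k]]))
  }
  adj
}

# Connected m-subset enumeration (each subset exactly once) by recursive
# growth from each anchor vertex, only ever adding ids larger than the
# anchor and never re-adding a vertex already reachable at an earlier branch.
connected_subsets_state <- function(state, m) {
  e <- state$edges
  if (m == 2L) {
    if (!nrow(e)) return(list())
    nl <- e[, 1] != e[, 2]
    if (!any(nl)) return(list())
    u <- pmin(e[nl, 1], e[nl, 2]); v <- pmax(e[nl, 1], e[nl, 2])
    keys <- !duplicated(paste(u, v))
    return(mapply(function(a, b) c(a, b), u[keys], v[keys], SIMPLIFY = FALSE))
  }
  adj <- state_adjacency(state)
  active <- which(!is.na(state$vlab))
  out <- vector("list", 64L)
  cnt <- 0L
  emit <- function(s) {
    cnt <<- cnt + 1L
    if (cnt > length(out)) length(out) <<- 2L * cnt
    out[[cnt]] <<- s
  }
  anchor <- 0L
  extend <- function(sub, ext, seen) {
    if (length(sub) == m) { emit(sub); return(invisible()) }
    while (length(ext)) {
      w <- ext[[1L]]
      ext <- ext[-1L]
      nw <- adj[[w]]
      cand <- nw[nw > anchor & !seen[nw]]
      seen2 <- seen
      seen2[nw] <- TRUE
      extend(c(sub, w), c(ext, cand), seen2)
    }
    invisible()
  }
  nmax <- length(adj)
  for (v in active) {
    if (!length(adj[[v]])) next
    anchor <- v
    seen <- logical(nmax)
    seen[v] <- TRUE
    seen[adj[[v]]] <- TRUE
    extend(v, adj[[v]][adj[[v]] > v], seen)
  }
  if (cnt == 0L) list() else out[seq_len(cnt)]
}

# dl-sequence of a subset (integer vertex indices) as an m x 2 matrix of
# (within-subset degree, label ordinal) rows, sorted non-increasingly.
subset_dl_state <- function(state, sub, inc) {
  e <- state$edges
  rows <- unique(unlist(inc[sub], use.names = FALSE))
  if (length(rows)) {
    keep <- rows[e[rows, 1] %in% sub & e[rows, 2] %in% sub]
  } else {
    keep <- integer()
  }
  deg <- integer(length(sub))
  if (length(keep)) {
    ends <- c(e[keep, 1], e[keep, 2])
    t <- tabulate(match(ends, sub), nbins = length(sub))
    deg <- t
  }
  lab <- state$vlab[sub]
  o <- order(-deg, -lab)
  cbind(deg[o], lab[o])
}

# Incidence list: vertex index -> edge row indices.
state_incidence <- function(state) {
  e <- state$edges
  inc <- rep(list(integer()), length(state$vlab))
  if (nrow(e)) {
    sp <- split(rep(seq_len(nrow(e)), 2L), c(e[, 1], e[, 2]))
    for (k in names(sp)) inc[[as.integer(k)]] <- unique(sp[[k]])
  }
  inc
}

# One SelectVertices(m) pass: group connected m-subsets by dl-sequence, keep
# classes whose members are pairwise disjoint, and pick the unique winner.
# Returns NULL or list(members, dl (matrix), bag, ordinal-free rule pieces).
select_vertices_state <- function(state, m) {
  subs <- connected_subsets_state(state, m)
  if (!length(subs)) return(NULL)
  inc <- state_incidence(state)
  dls <- lapply(subs, function(s) subset_dl_state(state, s, inc))
  keys <- vapply(dls, function(d) paste(d[, 1], d[, 2], sep = ":", collapse = ","), character(1))
  groups <- split(seq_along(subs), keys)
  elig <- Filter(
    function(ix) anyDuplicated(unlist(subs[ix], use.names = FALSE)) == 0L,
    groups
  )
  if (!length(elig)) return(NULL)
  cnt <- lengths(elig)
  cand <- elig[cnt == max(cnt)]
  pick <- cand[[1]]
  if (length(cand) > 1) {
    class_bag <- function(ix) {
      sort(unlist(state$reg$bags[state$vlab[subs[[ix[[1]]]]]], use.names = FALSE),
           decreasing = TRUE)
    }
    best_bag <- class_bag(pick)
    best_dl <- dls[[pick[[1]]]]
    for (ix in cand[-1]) {
      bag <- class_bag(ix)
      dl <- dls[[ix[[1]]]]
      if (rank_bag_less(bag, best_bag) ||
          (!rank_bag_less(best_bag, bag) && dl_rank_less(dl, best_dl))) {
        pick <- ix; best_bag <- bag; best_dl <- dl
      }
    }
  }
  list(
    members = subs[pick],
    dl = dls[[pick[[1]]]],
    bag = sort(unlist(state$reg$bags[state$vlab[subs[[pick[[1]]]]]], use.names = FALSE),
               decreasing = TRUE)
  )
}

# Contracts every member subset of the selected class: a fresh top-ranked
# label, removal of all induced edges (loops included), re-attachment of
# external edges.
contract_subset_class_state <- function(state, sel) {
  dl_labels <- state$reg$display[sel$dl[, 2]]
  nl <- state_new_label(state, sel$bag)
  state <- nl$state
  rule <- list(
    new = nl$display,
    kind = "vertex_set",
    body = data.frame(
      degree = as.integer(sel$dl[, 1]), label = dl_labels,
      stringsAsFactors = FALSE, row.names = NULL
    )
  )
  e <- state$edges
  memb <- integer(length(state$vlab))
  for (j in seq_along(sel$members)) memb[sel$members[[j]]] <- j
  newv <- integer(length(sel$members))
  for (j in seq_along(sel$members)) {
    av <- state_add_vertex(state, nl$ordinal)
    state <- av$state
    newv[[j]] <- av$vertex
  }
  memb <- c(memb, integer(length(newv)))
  m1 <- memb[e[, 1]]; m2 <- memb[e[, 2]]
  drop <- m1 > 0L & m1 == m2
  map <- seq_along(state$vlab)
  for (j in seq_along(sel$members)) map[sel$members[[j]]] <- newv[[j]]
  state$vlab[unlist(sel$members, use.names = FALSE)] <- NA_integer_
  keep <- which(!drop)
  state$edges <- cbind(map[e[keep, 1]], map[e[keep, 2]])
  list(state = state, rule = rule)
}

## ---- public single-step interface -----------------------------------------

#' Enumerate connected vertex subsets
#'
#' All size-`m` vertex subsets of `g` whose induced subgraph is connected,
#' each exactly once.
#'
#' @param g A [labeled_graph].
#' @param m Subset size, at least 2.
#' @return A list of character vectors of vertex ids.
#' @examples
#' g <- fig2_like()
#' length(enumerate_connected_subsets(g, 2)) # one per adjacent vertex pair
#' @export
enumerate_connected_subsets <- function(g, m) {
  stopifnot(inherits(g, "labeled_graph"))
  if (!is.numeric(m) || length(m) != 1 || m < 2) stop("`m` must be at least 2")
  state <- new_compress_state(g)
  subs <- connected_subsets_state(state, as.integer(m))
  lapply(subs, function(s) g$vertices$id[sort(s)])
}

#' Select the vertex-subset class to contract next
#'
#' Runs one SelectVertices pass at subset size `m`: connected subsets are
#' grouped by dl-sequence, classes with overlapping members are discarded,
#' and the winner among the largest remaining classes is chosen by smallest
#' label bag, then smallest dl-sequence.
#'
#' @param g A [labeled_graph].
#' @param m Subset size, at least 2.
#' @return `NULL` when no class is eligible, otherwise a list with `dl` (the
#'   class dl-sequence as a data frame) and `members` (list of id vectors).
#' @examples
#' select_vertices(fig2_like(), 2) # NULL: every pair class overlaps
#' select_vertices(fig2_like(), 3)$dl
#' @export
select_vertices <- function(g, m) {
  stopifnot(inherits(g, "labeled_graph"))
  if (!is.numeric(m) || length(m) != 1 || m < 2) stop("`m` must be at least 2")
  state <- new_compress_state(g)
  sel <- select_vertices_state(state, as.integer(m))
  if (is.null(sel)) return(NULL)
  list(
    dl = data.frame(
      degree = as.integer(sel$dl[, 1]),
      label = state$reg$display[sel$dl[, 2]],
      stringsAsFactors = FALSE, row.names = NULL
    ),
    members = lapply(sel$members, function(s) g$vertices$id[sort(s)])
  )
}

#' Contract one class of identical connected vertex subsets
#'
#' Single-step counterpart of [compress_vertices()]: contracts the given
#' pairwise-disjoint member subsets, which must share one dl-sequence, each
#' to a fresh vertex. All induced edges (including internal parallels and
#' self-loops) are removed.
#'
#' @param g A [labeled_graph].
#' @param members A list of character vectors of vertex ids.
#' @return A list with the emitted `rule` and the contracted `graph`.
#' @export
contract_subset_class <- function(g, members) {
  stopifnot(inherits(g, "labeled_graph"), is.list(members), length(members) >= 1)
  state <- new_compress_state(g)
  ids <- g$vertices$id
  subs <- lapply(members, function(s) {
    ix <- match(as.character(s), ids)
    if (anyNA(ix)) stop("unknown vertex id(s): ", paste(s[is.na(ix)], collapse = ", "))
    sort(ix)
  })
  if (anyDuplicated(unlist(subs))) stop("member subsets are not pairwise disjoint")
  inc <- state_incidence(state)
  dls <- lapply(subs, function(s) subset_dl_state(state, s, inc))
  keys <- vapply(dls, function(d) paste(d[, 1], d[, 2], sep = ":", collapse = ","), character(1))
  if (length(unique(keys)) != 1) stop("member subsets do not share one dl-sequence")
  for (s in subs) {
    keep <- state$edges[, 1] %in% s & state$edges[, 2] %in% s
    ind <- data.frame(from = as.character(state$edges[keep, 1]),
                      to = as.character(state$edges[keep, 2]))
    if (!induced_connected(as.character(s), ind)) {
      stop("a member subset does not induce a connected subgraph")
    }
  }
  sel <- list(
    members = subs,
    dl = dls[[1]],
    bag = sort(unlist(state$reg$bags[state$vlab[subs[[1]]]], use.names = FALSE),
               decreasing = TRUE)
  )
  step <- contract_subset_class_state(state, sel)
  list(rule = step$rule, graph = state_to_graph(step$state))
}
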