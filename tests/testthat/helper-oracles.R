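# Shared fixtures and independent oracles for the test suite.

# Quick constructor: labels is a named character vector (id -> label).
lg <- function(labels, from = character(), to = character()) {
  labeled_graph(labels, data.frame(from = from, to = to, stringsAsFactors = FALSE))
}

empty_graph <- function() labeled_graph(character())

# Path with the given labels on v1, v2, ...
path_graph <- function(labels) {
  n <- length(labels)
  ids <- paste0("v", seq_len(n))
  lg(stats::setNames(labels, ids),
     from = ids[-n], to = ids[-1])
}

triangle_graph <- function(labels = c("a", "b", "c")) {
  lg(stats::setNames(labels, c("x", "y", "z")),
     from = c("x", "y", "z"), to = c("y", "z", "x"))
}

# Serializes a compression result's rule sequence for run-to-run comparison.
rule_key <- function(res) {
  paste(vapply(res$rules, function(x) {
    if (x$kind == "edge") {
      paste0("E(", paste(x$body, collapse = ","), ")")
    } else {
      paste0("V(", paste(x$body$degree, x$body$label, sep = ":", collapse = ","), ")")
    }
  }, character(1)), collapse = ";")
}

# Maps length-2 vertex-set rule bodies onto edge rule bodies so the two
# compressors' rule sequences can be compared directly.
v2_as_edge_key <- function(res) {
  gsub("V\\(1:([^,]+),1:([^)]+)\\)", "E(\\1,\\2)", rule_key(res))
}

as_igraph <- function(g) {
  igraph::graph_from_data_frame(
    g$edges, directed = FALSE,
    vertices = data.frame(name = g$vertices$id, stringsAsFactors = FALSE)
  )
}

# Brute-force oracle: all size-m vertex subsets whose induced subgraph is
# connected, via exhaustive filtering with igraph.
brute_connected_subsets <- function(g, m) {
  subs <- utils::combn(g$vertices$id, m, simplify = FALSE)
  ig <- as_igraph(g)
  keep <- Filter(
    function(s) igraph::is_connected(igraph::induced_subgraph(ig, s)),
    subs
  )
  sort(vapply(keep, function(s) paste(sort(s), collapse = ","), character(1)))
}

subset_keys <- function(subsets) {
  sort(vapply(subsets, function(s) paste(sort(s), collapse = ","), character(1)))
}

# Study-condition random graph used across property tests: n <= 30,
# m <= 60, alphabet of at most 4 labels, drawn deterministically from `s`.
study_graph <- function(s) {
  withr::with_seed(7000 + s, {
    n <- sample(5:30, 1)
    m <- sample(0:min(60, n * (n - 1) / 2), 1)
    a <- letters[seq_len(sample(2:4, 1))]
    list(n = n, m = m, alphabet = a)
  }) -> p
  random_labeled_graph(p$n, p$m, p$alphabet, seed = 7500 + s)
}

# Uniform random labeled tree: contraction of tree edges never creates
# parallel edges, so runs stay simple throughout.
random_tree <- function(n, alphabet, seed) {
  withr::with_seed(seed, {
    ids <- paste0("v", seq_len(n))
    parent <- c(NA, vapply(2:n, function(i) sample.int(i - 1, 1), integer(1)))
    labeled_graph(
      stats::setNames(sample(alphabet, n, replace = TRUE), ids),
      data.frame(from = ids[parent[-1]], to = ids[-1], stringsAsFactors = FALSE)
    )
  })
}
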