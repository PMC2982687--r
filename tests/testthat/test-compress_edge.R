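test_that("edge classes exclude overlapping classes and the selection is the worked one", {
  cls <- build_edge_classes(fig1_like())
  pairs <- vapply(cls, function(cl) paste(cl$label_pair, collapse = ","), character(1))
  sizes <- vapply(cls, function(cl) nrow(cl$edges), integer(1))
  expect_false("b,a" %in% pairs) # the 4 (a,b) edges overlap: not eligible
  expect_setequal(pairs, c("a,a", "b,b", "c,a"))
  expect_equal(sizes[pairs == "a,a"], 2L)
  expect_equal(select_edge_class(fig1_like())$label_pair, c("a", "a"))

  # all three star edges share the center: nothing is eligible
  expect_length(build_edge_classes(incompressible_star(3)), 0)
  expect_null(select_edge_class(incompressible_star(3)))

  # a perfect matching is one class of size k
  cls <- build_edge_classes(compressible_matching(4))
  expect_length(cls, 1)
  expect_equal(nrow(cls[[1]]$edges), 4)

  # parallel copies of one vertex pair make their class ineligible
  para <- lg(c(u = "a", w = "b"), from = c("u", "u"), to = c("w", "w"))
  expect_length(build_edge_classes(para), 0)
})

test_that("derived-label bags drive the tie-break between equally frequent classes", {
  # after contracting (a,a) into 'aa', classes ('aa','b') and ('b','b') are
  # tied in count; s('aa') U s('b') = {a,a,b} sorts before {b,b}
  g <- lg(c(a1 = "a", a2 = "a", b1 = "b", b2 = "b", b3 = "b"),
          from = c("a1", "a1", "b2"), to = c("a2", "b1", "b3"))
  res <- compress_edge(g)
  expect_equal(res$rules[[1]]$body, c("a", "a"))
  expect_equal(res$rules[[2]]$body, c("aa", "b"))
  expect_equal(res$rules[[2]]$new, "aab")
  expect_equal(res$rules[[3]]$body, c("b", "b"))
  expect_equal(res$size, 3)
})

test_that("contracting an edge class rewires incident edges and keeps parallels", {
  step <- contract_edge_class(lg(c(u = "a", w = "b"), from = "u", to = "w"), c("a", "b"))
  expect_equal(n_vertices(step$graph), 1)
  expect_equal(n_edges(step$graph), 0)
  expect_equal(step$rule$body, c("b", "a"))

  step <- contract_edge_class(fig1_like(), c("a", "a"))
  expect_equal(n_vertices(step$graph), 5)
  expect_equal(n_edges(step$graph), 6)
  expect_equal(sum(step$graph$vertices$label == "aa"), 2)

  # triangle: contracting the (c,a) singleton leaves parallel edges to 'b'
  step <- contract_edge_class(triangle_graph(), c("c", "a"))
  expect_equal(n_vertices(step$graph), 2)
  expect_equal(n_edges(step$graph), 2)
  labs <- stats::setNames(step$graph$vertices$label, step$graph$vertices$id)
  ends <- sort(unname(c(labs[step$graph$edges$from[1]], labs[step$graph$edges$to[1]])))
  expect_equal(ends, c("ac", "b"))

  expect_error(contract_edge_class(fig1_like(), c("a", "b")), "not eligible")
  expect_error(contract_edge_class(fig1_like(), c("a", "z")), "no edge class")
})

test_that("full edge compression matches closed-form sizes", {
  # all-distinct labels: each class holds one edge and C(G) = |E|
  g <- triangle_graph(c("a", "b", "c"))
  expect_equal(compress_edge(g)$size, 3)
  dist7 <- random_labeled_graph(7, 10, letters[1:7], seed = 5)
  dist7$vertices$label <- letters[1:7] # force all-distinct
  expect_equal(compress_edge(dist7)$size, n_edges(dist7))

  star <- compress_edge(incompressible_star(3))
  expect_length(star$rules, 0)
  expect_equal(star$size, 3)

  matching <- compress_edge(compressible_matching(5))
  expect_length(matching$rules, 1)
  expect_equal(matching$size, 1)

  fig1 <- compress_edge(fig1_like())
  expect_equal(rule_key(fig1), "E(a,a);E(b,b);E(aa,c)")
  expect_equal(fig1$size, 7)
})

test_that("edge compression is invariant under vertex permutation and input reordering", {
  for (s in 1:10) {
    g <- study_graph(s)
    ref <- compress_edge(g)
    expect_lte(ref$size, n_edges(g))
    for (p in 1:3) {
      perm <- permuted_copy(g, seed = 100 * s + p)
      got <- compress_edge(perm)
      expect_identical(rule_key(got), rule_key(ref))
      expect_identical(got$size, ref$size)
    }
  }
})

test_that("compressing a doubled graph proceeds in lockstep with the single graph", {
  for (s in 1:8) {
    g <- study_graph(s)
    one <- compress_edge(g)
    two <- compress_edge(concatenate(g, g))
    expect_equal(two$size, length(one$rules) + 2 * nrow(one$residual$edges))
    expect_identical(rule_key(two), rule_key(one))
  }
})
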