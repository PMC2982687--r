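test_that("connected-subset enumeration matches exhaustive filtering", {
  tri <- triangle_graph()
  expect_length(enumerate_connected_subsets(tri, 2), 3)
  expect_length(enumerate_connected_subsets(tri, 3), 1)
  expect_error(enumerate_connected_subsets(tri, 1), "at least 2")
  for (s in 1:6) {
    g <- withr::with_seed(s, random_labeled_graph(10, sample(5:20, 1), c("a", "b"), seed = s))
    for (m in 2:4) {
      expect_identical(
        subset_keys(enumerate_connected_subsets(g, m)),
        brute_connected_subsets(g, m)
      )
    }
  }
})

test_that("subset selection reproduces the overlapping-triangle example", {
  g <- fig2_like()
  # every pair class overlaps: no eligible class at m = 2
  expect_null(select_vertices(g, 2))
  sel <- select_vertices(g, 3)
  expect_equal(sel$dl, data.frame(degree = c(2L, 1L, 1L), label = c("a", "b", "b")))
  expect_length(sel$members, 2)
  expect_true(all(vapply(sel$members, length, integer(1)) == 3))
  # the two members are the disjoint b-a-b paths, not the overlapping triangles
  expect_false("c1" %in% unlist(sel$members))

  # a single-edge graph has exactly its one pair class
  one <- lg(c(u = "a", w = "b"), from = "u", to = "w")
  sel1 <- select_vertices(one, 2)
  expect_equal(sel1$members, list(c("u", "w")))
})

test_that("subset contraction removes all induced edges and leaves no self-loop", {
  # two disjoint a-a-b triangles inside the fig1-like fixture -> two 'aab'
  step <- contract_subset_class(fig1_like(), list(c("a1", "a2", "b1"), c("a3", "a4", "b2")))
  expect_equal(step$rule$kind, "vertex_set")
  expect_equal(sum(step$graph$vertices$label == "aab"), 2)
  expect_equal(n_vertices(step$graph), 3)
  expect_equal(n_edges(step$graph), 2)
  expect_false(any(step$graph$edges$from == step$graph$edges$to))

  # fig2: contracting the two b-a-b paths gives two 'abb' vertices
  sel <- select_vertices(fig2_like(), 3)
  step <- contract_subset_class(fig2_like(), sel$members)
  expect_equal(sum(step$graph$vertices$label == "abb"), 2)
  expect_equal(n_vertices(step$graph), 3)
  expect_equal(n_edges(step$graph), 4)

  # whole triangle as one subset -> a single vertex, no edges
  step <- contract_subset_class(triangle_graph(), list(c("x", "y", "z")))
  expect_equal(n_vertices(step$graph), 1)
  expect_equal(n_edges(step$graph), 0)

  expect_error(contract_subset_class(fig1_like(), list(c("a2", "c1"))), "connected")
  expect_error(
    contract_subset_class(fig1_like(), list(c("a1", "a2"), c("a1", "b1"))),
    "disjoint"
  )
})

test_that("vertex-set compression restarts at m = 2 and matches worked runs", {
  expect_error(compress_vertices(fig1_like(), 1), "at least 2")
  res <- compress_vertices(fig2_like(), 3)
  expect_equal(
    res$rules[[1]]$body,
    data.frame(degree = c(2L, 1L, 1L), label = c("a", "b", "b"))
  )
  expect_equal(res$rules[[1]]$new, "abb")
  expect_equal(res$size, 2)

  # star with 3 identical leaves: only the whole size-4 subset is contractible
  star <- compress_vertices(incompressible_star(3), 4)
  expect_length(star$rules, 1)
  expect_equal(star$size, 1)
  expect_equal(nrow(star$rules[[1]]$body), 4)
  # with M = 3 the star stays incompressible (all subsets share the hub)
  expect_equal(compress_vertices(incompressible_star(3), 3)$size, 3)
})

test_that("CompressVertices(2) mirrors CompressEdge while runs stay simple", {
  # tree contraction never creates parallel edges, so the equivalence the
  # procedures share on simple graphs holds exactly on labeled trees
  for (s in 1:12) {
    g <- random_tree(4 + (s * 5) %% 16, letters[1:3], seed = 300 + s)
    e <- compress_edge(g)
    v <- compress_vertices(g, 2)
    expect_equal(v$size, e$size)
    expect_identical(v2_as_edge_key(v), rule_key(e))
  }
  # fixtures
  expect_equal(compress_vertices(compressible_matching(4), 2)$size, 1)
  expect_equal(compress_vertices(incompressible_star(4), 2)$size, 4)
})

test_that("vertex-set compression is isomorphism-invariant and terminates", {
  for (s in 1:6) {
    g <- study_graph(s + 20)
    ref <- compress_vertices(g, 3)
    expect_lte(ref$size, max(n_edges(g), 0))
    for (p in 1:2) {
      got <- compress_vertices(permuted_copy(g, seed = 200 * s + p), 3)
      expect_identical(rule_key(got), rule_key(ref))
      expect_identical(got$size, ref$size)
    }
  }
})

test_that("doubled-graph lockstep holds for vertex-set compression", {
  for (s in 1:6) {
    g <- study_graph(s + 40)
    one <- compress_vertices(g, 3)
    two <- compress_vertices(concatenate(g, g), 3)
    expect_equal(two$size, length(one$rules) + 2 * nrow(one$residual$edges))
    expect_identical(rule_key(two), rule_key(one))
  }
})
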