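test_that("label-bag comparison reproduces the worked orderings", {
  # {l1,l3} vs {l3,l2} under l1 < l2 < l3: sorted (l3,l1) and (l3,l2)
  expect_true(label_bag_less(c("l1", "l3"), c("l3", "l2"),
                             labels = c("l1", "l2", "l3")))
  expect_false(label_bag_less(c("l3", "l2"), c("l1", "l3"),
                              labels = c("l1", "l2", "l3")))
  # {'a','a','b'} vs {'b','b'}: sorted (b,a,a) and (b,b)
  expect_true(label_bag_less(c("a", "a", "b"), c("b", "b")))
  expect_false(label_bag_less(c("b", "b"), c("a", "a", "b")))
  # irreflexive
  expect_false(label_bag_less(c("a", "b"), c("b", "a")))
  # strict prefix compares as smaller
  expect_true(label_bag_less(c("b"), c("b", "a")))
  expect_false(label_bag_less(c("b", "a"), c("b")))
})

test_that("label-bag order is a strict total order on random bags", {
  alphabet <- c("a", "b", "c")
  withr::with_seed(11, {
    for (i in 1:200) {
      s1 <- sample(alphabet, sample(0:4, 1), replace = TRUE)
      s2 <- sample(alphabet, sample(0:4, 1), replace = TRUE)
      lt <- label_bag_less(s1, s2, alphabet)
      gt <- label_bag_less(s2, s1, alphabet)
      eq <- identical(sort(s1), sort(s2))
      expect_equal(lt + gt + eq, 1) # exactly one of <, >, = holds
    }
  })
})

test_that("integer labels are ordered numerically, others lexicographically", {
  # Morgan-index style labels: 10 ranks above 9
  expect_true(label_bag_less(c("9"), c("10")))
  expect_false(label_bag_less(c("10"), c("9")))
  # plain strings: byte order
  expect_true(label_bag_less(c("ab"), c("b")))
})

test_that("dl-sequence matches the worked examples and ignores outside edges", {
  aab <- lg(c(u = "a", v = "a", w = "b"), from = c("u", "v"), to = c("v", "w"))
  expect_equal(
    dl_sequence(aab, c("u", "v", "w")),
    data.frame(degree = c(2L, 1L, 1L), label = c("a", "b", "a"))
  )
  ab <- lg(c(u = "a", w = "b"), from = "u", to = "w")
  expect_equal(
    dl_sequence(ab, c("u", "w")),
    data.frame(degree = c(1L, 1L), label = c("b", "a"))
  )
  # degrees are induced: the hub's outside edges do not count
  star <- incompressible_star(3)
  expect_equal(
    dl_sequence(star, c("hub", "leaf1")),
    data.frame(degree = c(1L, 1L), label = c("b", "a"))
  )
  # a-b-a-b and a-a-b-b paths share one dl-sequence
  p1 <- path_graph(c("a", "b", "a", "b"))
  p2 <- path_graph(c("a", "a", "b", "b"))
  want <- data.frame(degree = c(2L, 2L, 1L, 1L), label = c("b", "a", "b", "a"))
  expect_equal(dl_sequence(p1, paste0("v", 1:4)), want)
  expect_equal(dl_sequence(p2, paste0("v", 1:4)), want)
  expect_error(dl_sequence(compressible_matching(2), c("u1", "u2")), "connected")
})

test_that("dl-sequence order is strict, total and length-checked", {
  a <- data.frame(degree = c(2L, 1L, 1L), label = c("a", "b", "a"))
  b <- data.frame(degree = c(2L, 1L, 1L), label = c("a", "b", "b"))
  expect_true(dl_less(a, b))
  expect_false(dl_less(b, a))
  expect_false(dl_less(a, a))
  expect_error(dl_less(a, a[1:2, ]), "equal length")
  # exhaustive small-alphabet enumeration: exactly one of <, >, = holds
  pairs <- expand.grid(d1 = 1:2, l1 = c("a", "b"), d2 = 1:2, l2 = c("a", "b"),
                       stringsAsFactors = FALSE)
  seqs <- lapply(seq_len(nrow(pairs)), function(i) {
    s <- data.frame(degree = c(pairs$d1[i], pairs$d2[i]),
                    label = c(pairs$l1[i], pairs$l2[i]))
    s[order(-s$degree, -rank(match(s$label, c("a", "b")))), ]
  })
  for (x in seqs) for (y in seqs) {
    lt <- dl_less(x, y, labels = c("a", "b"))
    gt <- dl_less(y, x, labels = c("a", "b"))
    eq <- identical(unname(as.matrix(x)), unname(as.matrix(y)))
    expect_equal(lt + gt + eq, 1)
  }
})
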