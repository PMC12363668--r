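test_that("complete graphs have the full Cartesian (or loop-free) edge set", {
  g <- make_complete(3, self_loops = TRUE)
  expect_equal(nrow(g$edges), 9L)
  expect_equal(degree_out(g), rep(3L, 3))
  expect_true(is_regular(g) && is_strongly_connected(g))

  h <- make_complete(3, self_loops = FALSE)
  expect_equal(nrow(h$edges), 6L)
  expect_equal(degree_out(h), rep(2L, 3))

  k1 <- make_complete(1, self_loops = TRUE)
  expect_equal(nrow(k1$edges), 1L)
  expect_equal(degree_out(k1), 1L)
  expect_true(is_strongly_connected(k1))

  expect_error(make_complete(0), "N >= 1")
})

test_that("cycles and paths have the expected degrees and edge counts", {
  g <- make_cycle(10)
  expect_equal(nrow(g$edges), 20L)  # 10 undirected edges
  expect_equal(degree_undirected(g), rep(2L, 10))
  expect_true(is_regular(g))

  p <- make_path(3)
  expect_equal(sort(degree_undirected(p)), c(1L, 1L, 2L))
  expect_equal(sum(degree_undirected(make_path(7)) == 1L), 2L)

  expect_identical(edge_key(make_cycle(3)),
                   edge_key(make_complete(3, self_loops = FALSE)))

  expect_error(make_cycle(2), "N >= 3")
  expect_error(make_path(1), "N >= 2")
})

test_that("stars and double stars split leaves as specified", {
  s <- make_star(4)
  expect_equal(sort(degree_undirected(s), decreasing = TRUE), c(3L, 1L, 1L, 1L))

  d6 <- make_double_star(6)
  expect_equal(sort(degree_undirected(d6), decreasing = TRUE),
               c(3L, 3L, 1L, 1L, 1L, 1L))
  # hubs adjacent
  expect_true(any(d6$edges[, 1L] == 1L & d6$edges[, 2L] == 2L))

  # odd N: leaf counts differ by one, extra leaf on hub 1
  d7 <- make_double_star(7)
  deg <- degree_undirected(d7)
  expect_equal(sort(deg[1:2] - 1L), c(2L, 3L))
  expect_equal(deg[1L] - 1L, 3L)

  expect_error(make_star(1), "N >= 2")
  expect_error(make_double_star(3), "N >= 4")
})

test_that("barbell attaches each path endpoint to one clique vertex", {
  b7 <- make_barbell(7)
  expect_equal(b7$n, 21L)

  b2 <- make_barbell(2)
  expect_equal(sort(degree_undirected(b2), decreasing = TRUE),
               c(2L, 2L, 2L, 2L, 1L, 1L))

  b3 <- make_barbell(3)
  deg <- degree_undirected(b3)
  expect_equal(deg[4L], 2L)  # path endpoints
  expect_equal(deg[6L], 2L)
  expect_equal(deg[1L], 3L)  # clique attachment vertices: (n-1) + 1
  expect_equal(deg[7L], 3L)

  expect_error(make_barbell(1), "n >= 2")
})

test_that("contracting star has the stated directed structure", {
  g <- make_contracting_star(9, b = 2)
  expect_equal(nrow(g$edges), 22L)
  expect_false(is_undirected(g))
  expect_true(is_strongly_connected(g))

  g13 <- make_contracting_star(13, b = 3)
  expect_equal(g13$n, 13L)
  expect_true(is_strongly_connected(g13))
  # blade length (N-1)/b = 4: outermost blade vertex has 3 outgoing
  # contracting/path edges inward plus none outward
  expect_equal(degree_out(g13)[5L], 3L)  # vertex 5 = outermost of blade 1

  # center receives no long-range contracting edges: in-neighbors of the
  # center are exactly the b innermost blade vertices
  inn <- sort(g13$edges[g13$edges[, 2L] == 1L, 1L])
  expect_equal(inn, c(2L, 6L, 10L))

  expect_error(make_contracting_star(9, b = 3), "divide")
})

test_that("family constructors yield strongly connected graphs; regularity is as expected", {
  gs <- list(make_complete(5), make_complete(5, FALSE), make_cycle(5),
             make_path(5), make_star(5), make_double_star(6),
             make_barbell(3), make_contracting_star(7, 2))
  for (g in gs) expect_true(is_strongly_connected(g), info = g$name)
  expect_true(all(vapply(gs[1:3], is_regular, logical(1))))
  expect_false(any(vapply(gs[5:8], is_regular, logical(1))))
})

test_that("degree entropy is 1 for regular graphs and matches the star value", {
  expect_equal(degree_entropy(make_cycle(6)), 1.0)
  expect_equal(degree_entropy(make_complete(5, FALSE)), 1.0)
  expect_equal(degree_entropy(make_path(2)), 1.0)

  # direct evaluation for the star on 8 vertices: degrees (7, 1 x 7)
  p <- c(7, rep(1, 7)) / 14
  expect_equal(degree_entropy(make_star(8)), -sum(p * log(p)) / log(8))
  expect_equal(degree_entropy(make_star(8)), 0.8012, tolerance = 1e-4)

  expect_error(degree_entropy(make_contracting_star(7, 2)), "undirected")
})

test_that("evograph validates its invariants", {
  expect_error(evograph(3, rbind(c(1, 4))), "vertex indices")
  expect_error(evograph(3, rbind(c(1, 2), c(1, 2))), "duplicate")
  g <- evograph(2, rbind(c(1, 2), c(2, 1)))
  expect_true(is_undirected(g))
  expect_false(has_self_loops(g))
  expect_true(has_self_loops(make_complete(2, TRUE)))
})
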