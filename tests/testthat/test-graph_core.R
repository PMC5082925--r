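test_that("degrees follow the handshake identity and reversal swaps them", {
  g <- tiny_graph(c(1L, 1L, 2L), c(2L, 3L, 3L))
  deg <- degrees(g)
  expect_identical(deg$in_degree, c(0L, 1L, 2L))
  expect_identical(deg$out_degree, c(2L, 1L, 0L))

  for (seed in 1:10) {
    g <- er_directed(30, 70, seed = seed)
    deg <- degrees(g)
    expect_identical(sum(deg$in_degree), n_edges(g))
    expect_identical(sum(deg$out_degree), n_edges(g))
    rev_deg <- degrees(reverse_graph(g))
    expect_identical(rev_deg$in_degree, deg$out_degree)
    expect_identical(rev_deg$out_degree, deg$in_degree)
  }
})

test_that("BFS distances are exact, directed, and use an explicit sentinel", {
  g <- tiny_graph(c(1L, 2L, 3L), c(2L, 3L, 4L))  # path A->B->C->D
  d <- bfs_distances(g, 1L)
  expect_identical(unname(d$distances), c(0L, 1L, 2L, 3L))
  d4 <- bfs_distances(g, 4L)
  expect_identical(unname(d4$distances), c(NA, NA, NA, 0L))
  expect_error(bfs_distances(g, 99L), class = "cld_unknown_id_error")

  # matrix-power walk oracle on random graphs
  for (seed in 1:8) {
    g <- er_directed(30, 60, seed = seed)
    D <- oracle_distances(g)
    for (s in c(1L, 7L, 30L)) {
      got <- bfs_distances(g, g$ids[s])$distances
      expect_identical(unname(got), unname(D[s, ]))
    }
  }
})

test_that("finite BFS distances satisfy the triangle inequality", {
  for (seed in 1:5) {
    g <- er_directed(20, 45, seed = 100 + seed)
    D <- sapply(g$ids, function(s) bfs_distances(g, s)$distances)
    D <- t(D)  # D[a, b] = dist a -> b
    # vectorized check over all (a, b, c): d(a,c) <= d(a,b) + d(b,c)
    for (b in 1:20) {
      via <- outer(D[, b], D[b, ], `+`)   # a -> b -> c
      comp <- !is.na(via) & !is.na(D)
      expect_true(all(D[comp] <= via[comp]))
    }
  }
})

test_that("shortest_path is valid, minimal, and breaks ties lexicographically", {
  g <- tiny_graph(c(1L, 2L), c(2L, 3L))
  expect_identical(shortest_path(g, 1L, 3L), c(1L, 2L, 3L))

  # two equal-length routes: pick the one through the smaller intermediate
  g2 <- tiny_graph(c(1L, 1L, 2L, 3L), c(2L, 3L, 4L, 4L))
  expect_identical(shortest_path(g2, 1L, 4L), c(1L, 2L, 4L))

  for (seed in 1:10) {
    g <- er_directed(12, 26, seed = seed)
    D <- oracle_distances(g)
    A <- adj_matrix_of(g)
    for (s in 1:12) for (t in 1:12) {
      if (s == t) next
      p <- shortest_path(g, g$ids[s], g$ids[t])
      if (is.na(D[s, t])) {
        expect_identical(p, NA_integer_)
      } else {
        expect_identical(length(p) - 1L, as.integer(D[s, t]))
        idx <- match(p, g$ids)
        expect_true(all(A[cbind(idx[-length(idx)], idx[-1L])] > 0))
      }
    }
  }
})

test_that("feedback-loop enumeration matches exhaustive search on small graphs", {
  g3 <- tiny_graph(c(1L, 2L, 3L), c(2L, 3L, 1L))
  loops <- find_feedback_loops(g3, max_length = 3)
  expect_identical(loops, list(c(1L, 2L, 3L)))

  # a DAG has no cycles
  dag <- tiny_graph(c(1L, 1L, 2L, 3L, 4L), c(2L, 3L, 4L, 4L, 5L), n = 10L)
  expect_identical(find_feedback_loops(dag, max_length = 8), list())

  set.seed(7)
  for (rep in 1:20) {
    n <- sample(4:7, 1)
    m <- sample(n:(2 * n), 1)
    g <- er_directed(n, m, seed = 500 + rep)
    got <- find_feedback_loops(g, max_length = 7)
    want <- oracle_cycles(g, maxlen = 7)
    key <- function(l) sort(vapply(l, paste, character(1), collapse = "-"))
    expect_identical(key(got), key(want))
  }
})

test_that("loop options behave: through filter, cap guard, canonical start", {
  # two cycles sharing node 2: 1->2->1 and 2->3->4->2
  g <- tiny_graph(c(1L, 2L, 2L, 3L, 4L), c(2L, 1L, 3L, 4L, 2L))
  all_loops <- find_feedback_loops(g, max_length = 4)
  expect_identical(length(all_loops), 2L)
  expect_true(all(vapply(all_loops, function(l) l[1L] == min(l), logical(1))))
  thru4 <- find_feedback_loops(g, max_length = 4, through = 4L)
  expect_identical(thru4, list(c(2L, 3L, 4L)))

  expect_error(find_feedback_loops(g, max_length = 9),
               class = "cld_loop_cap_error")
  expect_identical(length(find_feedback_loops(g, max_length = 9, cap = 9)), 2L)
  expect_error(find_feedback_loops(g, max_length = 1),
               class = "cld_argument_error")
})
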