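test_that("density counts ordered pairs and includes isolates", {
  complete3 <- tiny_graph(c(1L, 1L, 2L, 2L, 3L, 3L), c(2L, 3L, 1L, 3L, 1L, 2L))
  expect_identical(edge_density(complete3), 1)
  expect_identical(edge_density(tiny_graph(integer(), integer(), n = 5L)), 0)
  expect_error(edge_density(tiny_graph(integer(), integer(), n = 1L)),
               class = "cld_undefined_metric_error")
  # at study scale the sparse map rounds to 0.016
  expect_identical(round(edge_density(er_directed(114, 209, seed = 1)), 3),
                   0.016)
})

test_that("density is invariant under node relabelling", {
  g <- er_directed(25, 60, seed = 3)
  perm <- with(list(), {set.seed(9); sample(25)})
  vars <- data.frame(id = perm[match(g$ids, g$ids)], name = g$names)
  links <- data.frame(source = perm[match(g$edges$source, g$ids)],
                      target = perm[match(g$edges$target, g$ids)])
  g_rel <- build_graph(vars, links)
  expect_equal(edge_density(g_rel), edge_density(g))
})

test_that("degree distributions tally every node and edge", {
  g3 <- tiny_graph(c(1L, 2L, 3L), c(2L, 3L, 1L))
  dd <- degree_distribution(g3, "in")
  expect_identical(dd$histogram, data.frame(degree = 1L, count = 3L))
  for (direction in c("in", "out")) {
    g <- er_directed(40, 100, seed = 11)
    dd <- degree_distribution(g, direction)
    expect_identical(sum(dd$histogram$count), n_nodes(g))
    expect_identical(sum(dd$histogram$degree * dd$histogram$count),
                     n_edges(g))
  }
})

test_that("average path length uses the reachable-ordered-pairs convention", {
  cyc <- tiny_graph(c(1L, 2L, 3L), c(2L, 3L, 1L))
  apl <- average_path_length(cyc)
  expect_identical(apl$avg, 1.5)
  expect_identical(apl$n_reachable_pairs, 6L)

  path3 <- tiny_graph(c(1L, 2L), c(2L, 3L))
  expect_equal(average_path_length(path3)$avg, 4 / 3)

  # an isolate removes pairs from numerator and denominator, not the mean
  path3_iso <- tiny_graph(c(1L, 2L), c(2L, 3L), n = 4L)
  expect_equal(average_path_length(path3_iso)$avg, 4 / 3)

  expect_error(average_path_length(tiny_graph(integer(), integer(), n = 3L)),
               class = "cld_undefined_metric_error")
})

test_that("diameter matches the all-sources BFS maximum with smallest tie pair", {
  cyc <- tiny_graph(c(1L, 2L, 3L), c(2L, 3L, 1L))
  expect_identical(diameter(cyc)$d, 2L)
  expect_identical(diameter(cyc)$endpoints, c(1L, 3L))

  for (seed in 1:8) {
    g <- er_directed(25, 55, seed = 40 + seed)
    D <- oracle_distances(g)
    diag(D) <- NA_integer_
    got <- diameter(g)
    expect_identical(got$d, as.integer(max(D, na.rm = TRUE)))
    # the reported pair achieves the diameter
    expect_identical(
      as.integer(D[match(got$endpoints[1], g$ids),
                   match(got$endpoints[2], g$ids)]),
      got$d)
    # oracle APL as well
    expect_equal(average_path_length(g)$avg, mean(D[!is.na(D)]))
  }
})

test_that("adding a shortcut between already-connected nodes never raises APL", {
  for (seed in 1:6) {
    g <- er_directed(20, 50, seed = 60 + seed)
    D <- oracle_distances(g)
    diag(D) <- NA_integer_
    cand <- which(!is.na(D) & D >= 2, arr.ind = TRUE)
    if (!nrow(cand)) next
    pick <- cand[1L, ]
    before <- average_path_length(g)
    g2 <- build_graph(
      data.frame(id = g$ids, name = g$names),
      rbind(g$edges[, c("source", "target")],
            data.frame(source = g$ids[pick[1L]], target = g$ids[pick[2L]])))
    after <- average_path_length(g2)
    expect_identical(after$n_reachable_pairs, before$n_reachable_pairs)
    expect_lte(after$avg, before$avg)
  }
})

test_that("global_report agrees with its component operations field by field", {
  g <- er_directed(40, 90, seed = 77)
  rep1 <- global_report(g, seed = 5, restarts = 5)
  expect_identical(rep1$n_nodes, n_nodes(g))
  expect_identical(rep1$n_edges, n_edges(g))
  expect_identical(rep1$density, edge_density(g))
  expect_identical(rep1$avg_path_length, average_path_length(g)$avg)
  expect_identical(rep1$diameter, diameter(g)$d)
  expect_identical(rep1$n_isolates, length(isolates(g)))
  expect_identical(rep1$modularity,
                   louvain(g, seed = 5, restarts = 5)$modularity)
  # regenerating the report reproduces it exactly
  rep2 <- global_report(g, seed = 5, restarts = 5)
  expect_identical(format_global_report(rep1), format_global_report(rep2))

  two_cycle <- tiny_graph(c(1L, 2L), c(2L, 1L))
  r <- global_report(two_cycle, restarts = 2)
  expect_identical(
    unlist(format_global_report(r)[c("nodes", "edges", "density",
                                     "avg_path_length", "diameter",
                                     "n_isolates")], use.names = FALSE),
    c(2, 2, 1, 1, 1, 0))
})
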