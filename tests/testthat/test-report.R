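make_bundle <- function(seed = 7, config = list(restarts = 5)) {
  g <- er_directed(30, 70, seed = seed)
  files <- write_cld_files(g)
  analyze_cld(files$key, files$edges,
              config = c(config, list(polarity_col = "polarity")))
}

test_that("analyze_cld assembles a bundle consistent with the stage functions", {
  g <- cld_like(seed = 12)
  files <- write_cld_files(g)
  bundle <- analyze_cld(files$key, files$edges,
                        config = list(seed = 3, restarts = 5,
                                      polarity_col = "polarity"))
  expect_s3_class(bundle, "cld_analysis")
  expect_identical(bundle$global$n_nodes, 114L)
  expect_identical(bundle$global$n_edges, 209L)
  expect_identical(bundle$global$density, edge_density(g))
  expect_identical(bundle$centrality, centrality_table(g))
  expect_identical(bundle$partition$modularity,
                   louvain(g, seed = 3, restarts = 5)$modularity)
  expect_identical(bundle$loops, find_feedback_loops(g, max_length = 3))
  expect_null(bundle$baseline)
  expect_identical(bundle$provenance$config$seed, 3)
  expect_match(bundle$provenance$key_md5, "^[a-f0-9]{32}$")
})

test_that("analyze_cld writes a deterministic bundle directory", {
  g <- er_directed(25, 60, seed = 9)
  files <- write_cld_files(g)
  out1 <- tempfile("out1")
  out2 <- tempfile("out2")
  cfg <- list(seed = 11, restarts = 4, polarity_col = "polarity",
              baseline_replicates = 10)
  b1 <- analyze_cld(files$key, files$edges, config = cfg, out_dir = out1)
  b2 <- analyze_cld(files$key, files$edges, config = cfg, out_dir = out2)
  expect_true(!is.null(b1$baseline))
  for (f in c("global.csv", "centrality.csv", "partition.csv",
              "bundle.json", "graph.graphml")) {
    expect_identical(readLines(file.path(out1, f)),
                     readLines(file.path(out2, f)))
  }
  # rendered numbers carry the declared reporting precision
  glob <- utils::read.csv(file.path(out1, "global.csv"))
  expect_identical(glob$density, round(b1$global$density, 3))
  expect_identical(glob$avg_path_length, round(b1$global$avg_path_length, 2))
  cent <- utils::read.csv(file.path(out1, "centrality.csv"))
  expect_identical(cent$betweenness, round(b1$centrality$betweenness, 1))
})

test_that("analyze_cld fails cleanly without partial outputs", {
  g <- er_directed(10, 20, seed = 2)
  files <- write_cld_files(g)
  out <- tempfile("never")
  expect_error(
    analyze_cld(files$key, file.path(files$dir, "missing.csv"),
                out_dir = out),
    class = "cld_file_error")
  expect_false(dir.exists(out))
})

test_that("a bundle compared with itself yields zero deltas and perfect rank correlation", {
  b <- make_bundle()
  cmp <- compare_clds(b, b)
  expect_true(all(abs(unlist(cmp$deltas[-1L])) < 1e-12))
  expect_equal(cmp$rank_correlation$spearman,
               rep(1, nrow(cmp$rank_correlation)), tolerance = 1e-12)
  expect_identical(length(cmp$shared_names), n_nodes(b$graph))
  expect_identical(unname(lengths(cmp$unmatched)), c(0L, 0L))
})

test_that("comparison matches variables by normalized name and reports mismatches", {
  b1 <- make_bundle(seed = 7)
  # same graph, but half the names perturbed in case/punctuation only and
  # the rest genuinely different
  g <- b1$graph
  vars <- data.frame(id = g$ids, name = g$names)
  vars$name[1:10] <- toupper(gsub("-", "  ", vars$name[1:10]))
  vars$name[11:15] <- paste0("other thing ", 1:5)
  files <- write_cld_files(build_graph(vars, g$edges))
  b2 <- analyze_cld(files$key, files$edges,
                    config = list(restarts = 5, polarity_col = "polarity"))
  cmp <- compare_clds(b1, b2)
  expect_identical(length(cmp$shared_names), 25L)
  expect_identical(lengths(cmp$unmatched), c(cld1 = 5L, cld2 = 5L))
  # matched variables still correlate perfectly (same underlying graph)
  expect_equal(cmp$rank_correlation$spearman,
               rep(1, nrow(cmp$rank_correlation)), tolerance = 1e-12)

  expect_error(compare_clds(b1), class = "cld_argument_error")
  # disjoint auto-named graphs share nothing
  b3 <- make_bundle(seed = 8)
  expect_error(compare_clds(b1, b3), class = "cld_no_match_error")
})
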