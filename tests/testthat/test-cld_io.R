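test_that("variable key parsing accepts well-formed files and preserves order", {
  path <- write_lines_file(c("id,name", "3,Exercise", "1,Diet", "2,Screen Time"))
  vars <- read_variable_key(path)
  expect_identical(vars$id, c(3L, 1L, 2L))
  expect_identical(vars$name, c("Exercise", "Diet", "Screen Time"))

  # headerless, alternative delimiter, explicit column positions
  path2 <- write_lines_file(c("10\tWalking", "11\tCycling"), ext = ".tsv")
  vars2 <- read_variable_key(path2, sep = "\t", header = FALSE)
  expect_identical(vars2$id, c(10L, 11L))
})

test_that("malformed variable keys raise distinct typed errors", {
  expect_error(read_variable_key(tempfile("nope")), class = "cld_file_error")
  expect_error(
    read_variable_key(write_lines_file(c("id,name", "1,A", "1,B"))),
    class = "cld_duplicate_id_error")
  expect_error(
    read_variable_key(write_lines_file(c("id,name", "x,A"))),
    class = "cld_id_parse_error")
  expect_error(
    read_variable_key(write_lines_file(c("id,name", "1,A", "2,"))),
    class = "cld_empty_name_error")
  expect_error(
    read_variable_key(write_lines_file(c("id,name", "1,A  B", "2,A B"))),
    class = "cld_duplicate_name_error")
})

test_that("edge lists deduplicate, reject self-loops, and parse polarity", {
  path <- write_lines_file(c("source,target", "1,2", "1,2", "2,3"))
  expect_warning(links <- read_edge_list(path),
                 class = "cld_duplicate_edge_warning")
  expect_identical(nrow(links), 2L)
  expect_identical(links$polarity, c("unknown", "unknown"))

  expect_error(
    read_edge_list(write_lines_file(c("source,target", "3,3"))),
    class = "cld_self_loop_error")
  expect_error(
    read_edge_list(write_lines_file(c("source,target", "1,b"))),
    class = "cld_id_parse_error")

  pol_path <- write_lines_file(c("source,target,sign",
                                 "1,2,+", "2,3,-", "3,4,positive", "4,5,maybe"))
  expect_warning(pol <- read_edge_list(pol_path, polarity_col = "sign"),
                 class = "cld_polarity_warning")
  expect_identical(pol$polarity,
                   c("positive", "negative", "positive", "unknown"))
  # same file read without the polarity column configured
  no_pol <- read_edge_list(pol_path)
  expect_true(all(no_pol$polarity == "unknown"))
})

test_that("build_graph keeps isolates and patches unlabelled endpoints", {
  vars <- data.frame(id = 1:3, name = c("A", "B", "C"))
  g <- build_graph(vars, data.frame(source = 1L, target = 2L))
  expect_identical(n_nodes(g), 3L)
  expect_identical(n_edges(g), 1L)
  expect_identical(isolates(g), 3L)

  expect_warning(
    g2 <- build_graph(vars, data.frame(source = c(1L, 999L),
                                       target = c(2L, 1L))),
    class = "cld_unlabelled_node_warning")
  expect_true(999L %in% g2$ids)
  expect_identical(unname(node_names(g2)["999"]), "unlabelled-999")

  expect_error(build_graph(vars[0, ], NULL), class = "cld_empty_graph_error")
})

test_that("exports serialize correctly and unknown formats fail", {
  g <- tiny_graph(1L, 2L, n = 2L)
  csv <- export_graph(g, "edge-csv")
  expect_identical(length(strsplit(csv, "\n")[[1]]), 2L)  # header + 1 row

  gml <- export_graph(g, "graphml")
  expect_identical(lengths(regmatches(gml, gregexpr("<node ", gml))), 2L)
  expect_match(gml, "edgedefault=\"directed\"")

  dot <- export_graph(g, "dot")
  expect_match(dot, "n1 -> n2")

  expect_error(export_graph(g, "gexf"), class = "cld_format_error")
})

test_that("edge-csv export/import round-trips the link set of generated graphs", {
  for (seed in 1:5) {
    g <- er_directed(50, 120, seed = seed)
    path <- tempfile(fileext = ".csv")
    export_graph(g, "edge-csv", file = path)
    links <- read_edge_list(path, polarity_col = "polarity")
    expect_identical(links[order(links$source, links$target), ],
                     g$edges[order(g$edges$source, g$edges$target), ],
                     ignore_attr = TRUE)
  }
  # full two-file round trip preserves names and isolates too
  g <- tiny_graph(c(1L, 2L), c(2L, 3L), n = 4L)
  files <- write_cld_files(g)
  g2 <- build_graph(read_variable_key(files$key),
                    read_edge_list(files$edges, polarity_col = "polarity"))
  expect_identical(g2$ids, g$ids)
  expect_identical(g2$names, g$names)
  expect_identical(g2$edges, g$edges)
})
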