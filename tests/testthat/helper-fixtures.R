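# In-code fixture builders shared across test files.

# Small graph from parallel source/target vectors; nodes 1..n named A, B, ...
tiny_graph <- function(src, tgt, n = max(c(src, tgt))) {
  vars <- data.frame(id = seq_len(n),
                     name = make.unique(rep(LETTERS, length.out = n)))
  links <- if (length(src))
    data.frame(source = src, target = tgt)
  else data.frame(source = integer(), target = integer())
  build_graph(vars, links)
}

# Write a key / edge-list CSV pair for a graph, returning the two paths.
write_cld_files <- function(g, dir = NULL) {
  if (is.null(dir)) {
    dir <- tempfile("cld")
    dir.create(dir)
  }
  key <- file.path(dir, "key.csv")
  edges <- file.path(dir, "edges.csv")
  write_cld(g, key, edges)
  list(key = key, edges = edges, dir = dir)
}

write_lines_file <- function(lines, ext = ".csv") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# Two directed 5-cliques joined by a single edge; communities = cliques.
two_clique_graph <- function() {
  cl <- function(nodes) {
    e <- expand.grid(source = nodes, target = nodes)
    e[e$source != e$target, ]
  }
  links <- rbind(cl(1:5), cl(6:10), data.frame(source = 5, target = 6))
  build_graph(data.frame(id = 1:10, name = paste0("v", 1:10)), links)
}

# Two disjoint directed 3-cycles.
disjoint_cycles_graph <- function() {
  tiny_graph(c(1, 2, 3, 4, 5, 6), c(2, 3, 1, 5, 6, 4))
}
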