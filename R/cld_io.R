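#' Read a variable key (node ID to name mapping)
#'
#' A causal loop diagram (CLD) is distributed as two delimited text files: a
#' variable key mapping integer IDs to human-readable variable names, and an
#' edge list of directed causal links. This function reads and validates the
#' key. Variables that never appear in the edge list (isolates) are kept: the
#' key file is the authoritative node universe.
#'
#' @param path Path to the delimited text file. The ID column must contain
#'   integers; the name column non-empty text.
#' @param sep Field delimiter (default comma).
#' @param header Logical; does the file carry a header row (default `TRUE`)?
#' @param id_col,name_col Column names (when `header = TRUE`) or 1-based
#'   positions of the ID and name fields. Defaults: first and second column.
#' @return A `data.frame` with columns `id` (integer) and `name` (character),
#'   row order preserved from the file.
#' @section Errors: Each malformed input raises a typed condition:
#'   `cld_file_error` (missing file), `cld_id_parse_error` (non-integer ID),
#'   `cld_duplicate_id_error`, `cld_empty_name_error`,
#'   `cld_duplicate_name_error` (names identical after whitespace
#'   normalization).
#' @examples
#' tf <- tempfile(fileext = ".csv")
#' writeLines(c("id,name", "1,Exercise", "2,Diet"), tf)
#' read_variable_key(tf)
#' @seealso [read_edge_list()], [build_graph()]
#' @export
read_variable_key <- function(path, sep = ",", header = TRUE,
                              id_col = NULL, name_col = NULL) {
  tab <- read_delim_file(path, sep, header)
  id_raw <- pick_column(tab, id_col, 1L, "id")
  name_raw <- pick_column(tab, name_col, 2L, "name")

  ids <- parse_integer_ids(id_raw, what = "variable ID")
  names <- trimws(as.character(name_raw))

  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    cld_error("cld_duplicate_id_error",
              sprintf("duplicate variable ID(s) in key: %s",
                      paste(dup, collapse = ", ")))
  if (any(is.na(names) | names == ""))
    cld_error("cld_empty_name_error",
              sprintf("empty variable name at row(s): %s",
                      paste(which(is.na(names) | names == ""),
                            collapse = ", ")))
  norm <- gsub("[[:space:]]+", " ", names)
  if (anyDuplicated(norm))
    cld_error("cld_duplicate_name_error",
              sprintf("duplicate variable name(s) after whitespace normalization: %s",
                      paste(unique(norm[duplicated(norm)]), collapse = "; ")))

  data.frame(id = ids, name = names, stringsAsFactors = FALSE)
}

#' Read a CLD edge list
#'
#' Reads the directed causal links of a CLD from delimited text. Each row is
#' one link `source -> target` between integer variable IDs. The network is
#' unweighted and simple: duplicate rows are collapsed to one link (with a
#' `cld_duplicate_edge_warning`), and self-loops are rejected — a variable
#' "causing itself" has no meaning at the grain of a CLD and would corrupt the
#' density denominator.
#'
#' Link polarity (positive / negative causal orientation) is parsed when
#' `polarity_col` is given and stored for bookkeeping, but no analysis in this
#' package uses it: all metrics treat the CLD as an unsigned directed network.
#'
#' @inheritParams read_variable_key
#' @param source_col,target_col Column names or 1-based positions of the
#'   source and target ID fields. Defaults: first and second column.
#' @param polarity_col Optional column name/position holding link polarity.
#'   Recognized tokens (case-insensitive): `+`, `+1`, `1`, `pos`, `positive`
#'   and `-`, `-1`, `neg`, `negative`; anything else maps to `"unknown"`.
#' @return A `data.frame` with columns `source`, `target` (integer) and
#'   `polarity` (character, one of `"positive"`, `"negative"`, `"unknown"`),
#'   duplicates removed.
#' @section Errors: `cld_file_error`, `cld_id_parse_error` (non-integer
#'   endpoint), `cld_self_loop_error` (message lists offending rows).
#' @examples
#' tf <- tempfile(fileext = ".csv")
#' writeLines(c("source,target", "1,2", "2,3"), tf)
#' read_edge_list(tf)
#' @export
read_edge_list <- function(path, sep = ",", header = TRUE,
                           source_col = NULL, target_col = NULL,
                           polarity_col = NULL) {
  tab <- read_delim_file(path, sep, header)
  src <- parse_integer_ids(pick_column(tab, source_col, 1L, "source"),
                           what = "source ID")
  tgt <- parse_integer_ids(pick_column(tab, target_col, 2L, "target"),
                           what = "target ID")

  self <- which(src == tgt)
  if (length(self))
    cld_error("cld_self_loop_error",
              sprintf("self-loop(s) not allowed; offending data row(s): %s",
                      paste(sprintf("%d (%d->%d)", self, src[self], tgt[self]),
                            collapse = ", ")))

  pol <- rep("unknown", length(src))
  if (!is.null(polarity_col))
    pol <- parse_polarity(pick_column(tab, polarity_col, NULL, "polarity"))

  key <- paste(src, tgt, sep = "->")
  if (anyDuplicated(key)) {
    dups <- unique(key[duplicated(key)])
    cld_warning("cld_duplicate_edge_warning",
                sprintf("%d duplicate link row(s) collapsed: %s",
                        sum(duplicated(key)), paste(dups, collapse = ", ")))
    keep <- !duplicated(key)
    src <- src[keep]; tgt <- tgt[keep]; pol <- pol[keep]
  }

  data.frame(source = src, target = tgt, polarity = pol,
             stringsAsFactors = FALSE)
}

#' Build a CLD graph from variables and links
#'
#' Assembles a directed unweighted network from a variable key and an edge
#' list. The node universe is the union of the key and the link endpoints:
#' the key is authoritative for names, and endpoints absent from the key are
#' added as variables named `"unlabelled-<id>"` with a
#' `cld_unlabelled_node_warning`. Isolates (variables with no links) are
#' retained — they are part of the mapped system.
#'
#' @param variables A `data.frame` with columns `id` and `name`, as returned
#'   by [read_variable_key()].
#' @param links A `data.frame` with columns `source`, `target` and optionally
#'   `polarity`, as returned by [read_edge_list()].
#' @return A `cld_graph` object: a list with elements `ids` (integer node
#'   IDs, key order preserved), `names` (parallel character vector), `edges`
#'   (the link data frame), and derived adjacency lists `adj_out` / `adj_in`
#'   (1-based internal indices).
#' @examples
#' vars <- data.frame(id = 1:3, name = c("A", "B", "C"))
#' links <- data.frame(source = 1L, target = 2L)
#' g <- build_graph(vars, links)
#' n_nodes(g); n_edges(g); isolates(g)
#' @export
build_graph <- function(variables, links) {
  if (is.null(variables) || nrow(variables) == 0L)
    cld_error("cld_empty_graph_error", "variable list must be non-empty")
  stopifnot(all(c("id", "name") %in% names(variables)))
  ids <- as.integer(variables$id)
  nms <- as.character(variables$name)

  if (is.null(links))
    links <- data.frame(source = integer(), target = integer(),
                        polarity = character(), stringsAsFactors = FALSE)
  if (!"polarity" %in% names(links))
    links$polarity <- rep("unknown", nrow(links))
  links <- data.frame(source = as.integer(links$source),
                      target = as.integer(links$target),
                      polarity = as.character(links$polarity),
                      stringsAsFactors = FALSE)

  missing_ids <- sort(unique(setdiff(c(links$source, links$target), ids)))
  if (length(missing_ids)) {
    cld_warning("cld_unlabelled_node_warning",
                sprintf("link endpoint(s) absent from key added as unlabelled: %s",
                        paste(missing_ids, collapse = ", ")))
    ids <- c(ids, missing_ids)
    nms <- c(nms, paste0("unlabelled-", missing_ids))
  }

  g <- structure(list(ids = ids, names = nms, edges = links),
                 class = "cld_graph")
  g <- rebuild_adjacency(g)
  validate_cld_graph(g)
  g
}

# Recompute internal-index adjacency lists from g$edges.
rebuild_adjacency <- function(g) {
  n <- length(g$ids)
  si <- match(g$edges$source, g$ids)
  ti <- match(g$edges$target, g$ids)
  adj_out <- vector("list", n)
  adj_in <- vector("list", n)
  out_split <- split(ti, factor(si, levels = seq_len(n)))
  in_split <- split(si, factor(ti, levels = seq_len(n)))
  for (i in seq_len(n)) {
    adj_out[[i]] <- as.integer(sort(out_split[[i]]))
    adj_in[[i]] <- as.integer(sort(in_split[[i]]))
  }
  g$adj_out <- adj_out
  g$adj_in <- adj_in
  g
}

validate_cld_graph <- function(g) {
  if (anyDuplicated(g$ids))
    cld_error("cld_duplicate_id_error", "duplicate node ids in graph")
  if (any(g$edges$source == g$edges$target))
    cld_error("cld_self_loop_error", "graph contains a self-loop")
  if (anyDuplicated(paste(g$edges$source, g$edges$target)))
    cld_error("cld_duplicate_edge_error", "graph contains duplicate links")
  if (!all(c(g$edges$source, g$edges$target) %in% g$ids))
    cld_error("cld_dangling_edge_error", "link endpoint missing from node set")
  invisible(g)
}

#' @export
print.cld_graph <- function(x, ...) {
  cat(sprintf("<cld_graph> %d variables, %d causal links, %d isolate(s)\n",
              n_nodes(x), n_edges(x), length(isolates(x))))
  invisible(x)
}

#' Basic accessors for a CLD graph
#'
#' `n_nodes()` and `n_edges()` return the node and link counts; `isolates()`
#' the IDs of variables with no links at all; `node_names()` a named character
#' vector mapping ID to variable name.
#'
#' @param g A `cld_graph`.
#' @return See individual descriptions.
#' @export
n_nodes <- function(g) length(g$ids)

#' @rdname n_nodes
#' @export
n_edges <- function(g) nrow(g$edges)

#' @rdname n_nodes
#' @export
isolates <- function(g) {
  touched <- unique(c(g$edges$source, g$edges$target))
  sort(setdiff(g$ids, touched))
}

#' @rdname n_nodes
#' @export
node_names <- function(g) stats::setNames(g$names, g$ids)

#' Export a CLD graph to a standard text format
#'
#' Serializes the graph as GraphML (nodes carry the variable name, edges the
#' polarity), Graphviz DOT, or a plain edge-list CSV. The edge-CSV form
#' round-trips: re-reading it with [read_edge_list()] reproduces the link set
#' exactly (isolates, having no links, need the variable key to survive a
#' round trip).
#'
#' @param g A `cld_graph`.
#' @param format One of `"edge-csv"`, `"graphml"`, `"dot"`.
#' @param file Optional path; when given the text is also written there.
#' @return The serialized text as a single character string, invisibly when
#'   `file` is given.
#' @export
export_graph <- function(g, format = c("edge-csv", "graphml", "dot"),
                         file = NULL) {
  if (length(format) != 1L || !format %in% c("edge-csv", "graphml", "dot"))
    cld_error("cld_format_error",
              sprintf("unknown export format: %s",
                      paste(format, collapse = ", ")))
  txt <- switch(format,
    "edge-csv" = export_edge_csv(g),
    "graphml" = export_graphml(g),
    "dot" = export_dot(g))
  if (!is.null(file)) {
    writeLines(txt, file, sep = "")
    return(invisible(txt))
  }
  txt
}

#' Write a CLD to key + edge-list files
#'
#' Convenience writer producing the same two-file dialect [read_variable_key()]
#' and [read_edge_list()] consume (comma-separated, with header).
#'
#' @param g A `cld_graph`.
#' @param key_path,edges_path Output file paths.
#' @return Invisibly, a list with the two paths.
#' @export
write_cld <- function(g, key_path, edges_path) {
  utils::write.csv(data.frame(id = g$ids, name = g$names),
                   key_path, row.names = FALSE, quote = TRUE)
  utils::write.csv(g$edges, edges_path, row.names = FALSE, quote = TRUE)
  invisible(list(key = key_path, edges = edges_path))
}

export_edge_csv <- function(g) {
  con <- textConnection("out", "w", local = TRUE)
  utils::write.csv(g$edges, con, row.names = FALSE, quote = TRUE)
  close(con)
  paste0(paste(out, collapse = "\n"), "\n")
}

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  x <- gsub("\"", "&quot;", x, fixed = TRUE)
  gsub("'", "&apos;", x, fixed = TRUE)
}

export_graphml <- function(g) {
  head <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<graphml xmlns="http://graphml.graphdrawing.org/xmlns">',
    '  <key id="d0" for="node" attr.name="name" attr.type="string"/>',
    '  <key id="d1" for="edge" attr.name="polarity" attr.type="string"/>',
    '  <graph id="cld" edgedefault="directed">')
  nodes <- sprintf('    <node id="n%d"><data key="d0">%s</data></node>',
                   g$ids, xml_escape(g$names))
  edges <- if (nrow(g$edges)) {
    sprintf('    <edge source="n%d" target="n%d"><data key="d1">%s</data></edge>',
            g$edges$source, g$edges$target, xml_escape(g$edges$polarity))
  } else character()
  paste0(paste(c(head, nodes, edges, "  </graph>", "</graphml>"),
               collapse = "\n"), "\n")
}

export_dot <- function(g) {
  esc <- function(x) gsub("\"", "\\\\\"", x)
  nodes <- sprintf('  n%d [label="%s"];', g$ids, esc(g$names))
  edges <- if (nrow(g$edges)) {
    style <- ifelse(g$edges$polarity == "negative", ' [arrowhead=tee]', '')
    sprintf('  n%d -> n%d%s;', g$edges$source, g$edges$target, style)
  } else character()
  paste0(paste(c("digraph cld {", nodes, edges, "}"), collapse = "\n"), "\n")
}

# ---- low-level parsing helpers ------------------------------------------

read_delim_file <- function(path, sep, header) {
  if (!is.character(path) || length(path) != 1L || !file.exists(path))
    cld_error("cld_file_error", sprintf("file not found: %s", path))
  tab <- utils::read.table(path, sep = sep, header = header,
                           stringsAsFactors = FALSE, colClasses = "character",
                           quote = "\"", comment.char = "", strip.white = TRUE,
                           blank.lines.skip = TRUE)
  if (ncol(tab) < 2L)
    cld_error("cld_file_error",
              sprintf("expected at least 2 columns in %s, found %d",
                      path, ncol(tab)))
  tab
}

pick_column <- function(tab, col, default_pos, what) {
  if (is.null(col)) col <- default_pos
  if (is.character(col)) {
    if (!col %in% names(tab))
      cld_error("cld_file_error",
                sprintf("%s column '%s' not found (columns: %s)",
                        what, col, paste(names(tab), collapse = ", ")))
    return(tab[[col]])
  }
  if (col > ncol(tab))
    cld_error("cld_file_error",
              sprintf("%s column index %d out of range", what, col))
  tab[[col]]
}

parse_integer_ids <- function(x, what) {
  x <- trimws(as.character(x))
  num <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(num) | num != floor(num) | num < 1)
  if (length(bad))
    cld_error("cld_id_parse_error",
              sprintf("non-integer %s at data row(s) %s: %s",
                      what, paste(bad, collapse = ", "),
                      paste(sprintf("'%s'", x[bad]), collapse = ", ")))
  as.integer(num)
}

parse_polarity <- function(x) {
  x <- tolower(trimws(as.character(x)))
  pos <- c("+", "+1", "1", "pos", "positive", "s", "same")
  neg <- c("-", "-1", "neg", "negative", "o", "opposite")
  none <- c("unknown", "na", "?", "")
  out <- rep("unknown", length(x))
  out[x %in% pos] <- "positive"
  out[x %in% neg] <- "negative"
  unknown_tokens <- x[!(x %in% c(pos, neg, none)) & !is.na(x)]
  if (length(unknown_tokens))
    cld_warning("cld_polarity_warning",
                sprintf("unrecognized polarity token(s) treated as unknown: %s",
                        paste(unique(unknown_tokens), collapse = ", ")))
  out
}
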