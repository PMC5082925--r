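#' Node degrees of a CLD graph
#'
#' In-degree counts the causal links pointing at a variable (its perceived
#' causes); out-degree counts the links it emits (the variables it acts on).
#' Isolates report `(0, 0)`. The handshake identity holds:
#' `sum(in_degree) == sum(out_degree) == n_edges(g)`.
#'
#' @param g A `cld_graph`.
#' @return A `data.frame` with columns `id`, `in_degree`, `out_degree`, one
#'   row per variable in node order.
#' @export
degrees <- function(g) {
  n <- n_nodes(g)
  si <- match(g$edges$source, g$ids)
  ti <- match(g$edges$target, g$ids)
  data.frame(id = g$ids,
             in_degree = tabulate(ti, nbins = n),
             out_degree = tabulate(si, nbins = n))
}

#' Reverse every link of a CLD graph
#'
#' @param g A `cld_graph`.
#' @return A `cld_graph` with all links flipped (polarity preserved).
#' @export
reverse_graph <- function(g) {
  e <- g$edges
  g$edges <- data.frame(source = e$target, target = e$source,
                        polarity = e$polarity, stringsAsFactors = FALSE)
  rebuild_adjacency(g)
}

# BFS over internal indices; returns integer distances, NA = unreachable.
bfs_index <- function(adj_out, s, n) {
  dist <- rep(NA_integer_, n)
  dist[s] <- 0L
  frontier <- s
  d <- 0L
  while (length(frontier)) {
    nxt <- unique(unlist(adj_out[frontier], use.names = FALSE))
    nxt <- nxt[is.na(dist[nxt])]
    if (!length(nxt)) break
    d <- d + 1L
    dist[nxt] <- d
    frontier <- nxt
  }
  dist
}

# All-pairs directed hop distances; rows = sources, NA = unreachable.
all_pairs_distances <- function(g) {
  n <- n_nodes(g)
  out <- matrix(NA_integer_, n, n, dimnames = list(g$ids, g$ids))
  for (s in seq_len(n)) out[s, ] <- bfs_index(g$adj_out, s, n)
  out
}

node_index <- function(g, id, what = "variable id") {
  idx <- match(as.integer(id), g$ids)
  if (any(is.na(idx)))
    cld_error("cld_unknown_id_error",
              sprintf("unknown %s: %s", what,
                      paste(id[is.na(idx)], collapse = ", ")))
  idx
}

#' Single-source shortest-path distances (breadth-first search)
#'
#' Hop-count distances from `source` to every variable, following causal
#' arrows strictly in their direction. Distance is the minimum number of
#' links that must be traversed; variables not reachable along directed
#' paths get the explicit sentinel `NA` (never a large stand-in number, so
#' averages cannot silently absorb unreachable pairs).
#'
#' @param g A `cld_graph`.
#' @param source Variable ID to start from.
#' @return An object of class `cld_distances`: list with `source` (the ID)
#'   and `distances` (integer vector named by variable ID; `NA` =
#'   unreachable).
#' @export
bfs_distances <- function(g, source) {
  s <- node_index(g, source, "source id")
  d <- bfs_index(g$adj_out, s, n_nodes(g))
  structure(list(source = as.integer(source),
                 distances = stats::setNames(d, g$ids)),
            class = "cld_distances")
}

#' @export
print.cld_distances <- function(x, ...) {
  fin <- x$distances[!is.na(x$distances)]
  cat(sprintf("<cld_distances> source %d: %d reachable (max %d), %d unreachable\n",
              x$source, length(fin), max(fin),
              sum(is.na(x$distances))))
  invisible(x)
}

#' Extract one shortest directed path between two variables
#'
#' Returns a shortest causal chain from `source` to `target`. When several
#' shortest paths exist the tie is broken deterministically: the
#' lexicographically smallest sequence of variable IDs is returned.
#'
#' @param g A `cld_graph`.
#' @param source,target Variable IDs.
#' @return Integer vector of variable IDs from `source` to `target`
#'   inclusive, or `NA` if `target` is unreachable.
#' @export
shortest_path <- function(g, source, target) {
  s <- node_index(g, source, "source id")
  t <- node_index(g, target, "target id")
  n <- n_nodes(g)
  if (s == t) return(as.integer(source))
  fwd <- bfs_index(g$adj_out, s, n)
  if (is.na(fwd[t])) return(NA_integer_)
  bwd <- bfs_index(g$adj_in, t, n)     # distance *to* target
  total <- fwd[t]
  path <- integer(total + 1L)
  path[1L] <- s
  cur <- s
  for (step in seq_len(total)) {
    cand <- g$adj_out[[cur]]
    cand <- cand[!is.na(bwd[cand]) & fwd[cand] == step &
                 fwd[cand] + bwd[cand] == total]
    cur <- cand[which.min(g$ids[cand])]
    path[step + 1L] <- cur
  }
  g$ids[path]
}

#' Enumerate feedback loops (simple directed cycles)
#'
#' Finds all distinct simple directed cycles of length at most `max_length`.
#' Each cycle is reported once, canonically rotated to start at its smallest
#' variable ID; direction is preserved (cycles are not reflected). Loop
#' enumeration is exponential in `max_length`, so a cap (default 8) guards
#' against accidental blow-ups; systems-mapping practice discourages
#' interpreting long causal chains anyway.
#'
#' @param g A `cld_graph`.
#' @param max_length Maximum cycle length (number of links), >= 2.
#' @param through Optional variable ID; keep only loops containing it.
#' @param cap Upper bound on `max_length`; raise explicitly for deep searches.
#' @return List of integer vectors, each a cycle as variable IDs in traversal
#'   order starting at the smallest ID. Sorted by length then lexicographic
#'   order. Empty list if the graph is acyclic within the bound.
#' @examples
#' vars <- data.frame(id = 1:3, name = c("A", "B", "C"))
#' links <- data.frame(source = c(1, 2, 3), target = c(2, 3, 1))
#' find_feedback_loops(build_graph(vars, links), max_length = 3)
#' @export
find_feedback_loops <- function(g, max_length = 3L, through = NULL, cap = 8L) {
  max_length <- assert_count(max_length, "max_length", min = 2L)
  if (max_length > cap)
    cld_error("cld_loop_cap_error",
              sprintf(paste("max_length %d exceeds cap %d; pass cap = %d to",
                            "override (enumeration is exponential)"),
                      max_length, cap, max_length))
  if (!is.null(through)) node_index(g, through, "through id")

  ids <- g$ids
  adj_out <- g$adj_out
  n <- n_nodes(g)
  res <- list()
  path <- integer(max_length)
  on_path <- logical(n)
  s <- 0L
  dfs <- function(v, depth) {
    path[depth] <<- v
    on_path[v] <<- TRUE
    for (w in adj_out[[v]]) {
      if (w == s) {
        if (depth >= 2L)
          res[[length(res) + 1L]] <<- ids[path[seq_len(depth)]]
      } else if (depth < max_length && ids[w] > ids[s] && !on_path[w]) {
        dfs(w, depth + 1L)
      }
    }
    on_path[v] <<- FALSE
  }
  for (s in order(ids)) dfs(s, 1L)

  if (!is.null(through))
    res <- Filter(function(cyc) as.integer(through) %in% cyc, res)
  if (length(res) > 1L) {
    keys <- vapply(res, function(cyc)
      sprintf("%03d|%s", length(cyc),
              paste(sprintf("%09d", cyc), collapse = ",")), character(1))
    res <- res[order(keys)]
  }
  res
}
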