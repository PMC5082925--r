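#' Directed network density
#'
#' Fraction of realized causal links out of the `N * (N - 1)` possible
#' ordered pairs. Isolates count toward `N`: an unconnected variable is
#' still part of the mapped system and dilutes its density.
#'
#' @param g A `cld_graph`.
#' @return Density in `[0, 1]`, full precision (round only when reporting).
#' @export
edge_density <- function(g) {
  n <- n_nodes(g)
  if (n < 2L)
    cld_error("cld_undefined_metric_error",
              "density undefined for a single-node graph")
  n_edges(g) / (n * (n - 1))
}

#' Degree distribution of a CLD graph
#'
#' Exact histogram of in- or out-degree. In a CLD the right tail is the hub
#' structure: variables perceived to be caused by (in) or to drive (out)
#' many others.
#'
#' @param g A `cld_graph`.
#' @param direction `"in"` or `"out"`.
#' @return A list of class `cld_degree_distribution`: `direction`,
#'   `histogram` (data.frame `degree`, `count` for every occupied degree),
#'   `min`, `max`.
#' @export
degree_distribution <- function(g, direction = c("in", "out")) {
  direction <- match.arg(direction)
  deg <- degrees(g)
  d <- if (direction == "in") deg$in_degree else deg$out_degree
  tab <- table(d)
  structure(list(direction = direction,
                 histogram = data.frame(degree = as.integer(names(tab)),
                                        count = as.integer(tab)),
                 min = min(d), max = max(d)),
            class = "cld_degree_distribution")
}

#' @export
print.cld_degree_distribution <- function(x, ...) {
  cat(sprintf("<cld_degree_distribution> %s-degree, range %d..%d\n",
              x$direction, x$min, x$max))
  print(x$histogram, row.names = FALSE)
  invisible(x)
}

#' Average directed shortest-path length
#'
#' Mean hop distance over all *reachable* ordered pairs `(i, j)`, `i != j`.
#' Unreachable pairs are excluded from both numerator and denominator, so a
#' single isolate does not make the average undefined. This
#' reachable-ordered-pairs convention is the one under which short average
#' paths coexist with isolates in sparse directed systems maps.
#'
#' @param g A `cld_graph`.
#' @return A list with `avg` (mean distance, full precision) and
#'   `n_reachable_pairs` (number of ordered pairs contributing).
#' @export
average_path_length <- function(g) {
  dm <- all_pairs_distances(g)
  diag(dm) <- NA_integer_
  fin <- dm[!is.na(dm)]
  if (!length(fin))
    cld_error("cld_undefined_metric_error",
              "no reachable ordered pairs: average path length undefined")
  list(avg = mean(fin), n_reachable_pairs = length(fin))
}

#' Directed diameter
#'
#' The largest finite directed shortest-path distance in the network, with
#' one ordered pair achieving it. Ties are broken toward the smallest
#' `(source, target)` ID pair for deterministic reporting.
#'
#' @param g A `cld_graph`.
#' @return A list with `d` (integer diameter) and `endpoints` (integer
#'   vector `c(source, target)`).
#' @export
diameter <- function(g) {
  dm <- all_pairs_distances(g)
  diag(dm) <- NA_integer_
  if (all(is.na(dm)))
    cld_error("cld_undefined_metric_error",
              "no reachable ordered pairs: diameter undefined")
  d <- max(dm, na.rm = TRUE)
  hits <- which(dm == d, arr.ind = TRUE)
  src <- g$ids[hits[, 1L]]
  tgt <- g$ids[hits[, 2L]]
  best <- order(src, tgt)[1L]
  list(d = as.integer(d), endpoints = c(src[best], tgt[best]))
}

#' Whole-network structural summary
#'
#' Assembles the standard one-row topology report for a CLD: node and link
#' counts, density, average directed path length over reachable pairs,
#' diameter, isolate count, and best-of-restarts modularity from
#' Louvain-style community detection.
#'
#' @param g A `cld_graph`.
#' @param seed Integer seed for the community-detection restarts.
#' @param restarts Number of Louvain restarts (default 20).
#' @param variant Modularity variant passed to [louvain()].
#' @return An object of class `cld_global_report`: list with fields
#'   `n_nodes`, `n_edges`, `density`, `avg_path_length`,
#'   `n_reachable_pairs`, `diameter`, `diameter_endpoints`, `n_isolates`,
#'   `modularity`, `partition` (the full [louvain()] result). All values
#'   full precision; rounding happens only at serialization
#'   ([format_global_report()]).
#' @export
global_report <- function(g, seed = 1L, restarts = 20L,
                          variant = c("undirected", "directed")) {
  variant <- match.arg(variant)
  apl <- average_path_length(g)
  diam <- diameter(g)
  part <- if (n_edges(g) >= 1L) louvain(g, seed = seed, restarts = restarts,
                                        variant = variant)
  structure(list(
    n_nodes = n_nodes(g),
    n_edges = n_edges(g),
    density = edge_density(g),
    avg_path_length = apl$avg,
    n_reachable_pairs = apl$n_reachable_pairs,
    diameter = diam$d,
    diameter_endpoints = diam$endpoints,
    n_isolates = length(isolates(g)),
    modularity = if (!is.null(part)) part$modularity else NA_real_,
    partition = part
  ), class = "cld_global_report")
}

#' Round and flatten a global report for serialization
#'
#' Applies the reporting precision used throughout the package — density to
#' 3 decimal places, average path length to 2 — and drops the embedded
#' partition object.
#'
#' @param report A `cld_global_report`.
#' @return A one-row `data.frame` in column order Nodes, Edges, Density,
#'   Av. Path Length, Modularity, then the extension columns.
#' @export
format_global_report <- function(report) {
  data.frame(
    nodes = report$n_nodes,
    edges = report$n_edges,
    density = round(report$density, 3),
    avg_path_length = round(report$avg_path_length, 2),
    modularity = if (is.na(report$modularity)) NA
                 else round(report$modularity, 2),
    diameter = report$diameter,
    diameter_source = report$diameter_endpoints[1L],
    diameter_target = report$diameter_endpoints[2L],
    n_isolates = report$n_isolates,
    n_reachable_pairs = report$n_reachable_pairs
  )
}

#' @export
print.cld_global_report <- function(x, ...) {
  cat("<cld_global_report>\n")
  print(format_global_report(x), row.names = FALSE)
  invisible(x)
}
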