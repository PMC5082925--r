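#' Analysis configuration defaults
#'
#' All tunables of the end-to-end pipeline in one place; [analyze_cld()]
#' merges user overrides over these. Fields: delimiter/header handling for
#' both input files (`sep`, `header`, `id_col`, `name_col`, `source_col`,
#' `target_col`, `polarity_col`), `seed`, Louvain `restarts` and `variant`,
#' `loops_max_length` (`NULL` disables loop enumeration),
#' `baseline_replicates` (`0` disables the random-ensemble comparison).
#'
#' @return Named list of defaults.
#' @export
default_config <- function() {
  list(sep = ",", header = TRUE,
       id_col = NULL, name_col = NULL,
       source_col = NULL, target_col = NULL, polarity_col = NULL,
       seed = 1L, restarts = 20L, variant = "undirected",
       loops_max_length = 3L,
       baseline_replicates = 0L)
}

#' Analyze one causal loop diagram end-to-end
#'
#' Reads a variable key and edge list, builds the directed network, and
#' computes the full quantitative summary: global topology report,
#' centrality table with leverage-point ranks, community partition,
#' feedback loops up to a bounded length, and (optionally) the
#' random-baseline topology comparison. All stochastic stages are driven by
#' `config$seed`, so re-running with the same inputs and config reproduces
#' the bundle bit-for-bit.
#'
#' @param key_path Path to the variable key file.
#' @param edges_path Path to the edge-list file.
#' @param config Named list of overrides merged over [default_config()].
#' @param out_dir Optional directory; when given, the bundle is written
#'   there as JSON + CSV files via [write_bundle()] after all computation
#'   succeeds (a failing stage leaves no partial outputs).
#' @return An object of class `cld_analysis`: list with `graph`, `global`
#'   (see [global_report()]), `centrality`, `partition`, `loops`,
#'   `baseline` (or `NULL`), `root_influencers`, and `provenance` (input
#'   paths and md5 hashes, the full effective config, package version).
#' @export
analyze_cld <- function(key_path, edges_path, config = list(),
                        out_dir = NULL) {
  cfg <- utils::modifyList(default_config(), config)
  vars <- read_variable_key(key_path, sep = cfg$sep, header = cfg$header,
                            id_col = cfg$id_col, name_col = cfg$name_col)
  links <- read_edge_list(edges_path, sep = cfg$sep, header = cfg$header,
                          source_col = cfg$source_col,
                          target_col = cfg$target_col,
                          polarity_col = cfg$polarity_col)
  g <- build_graph(vars, links)

  global <- global_report(g, seed = cfg$seed, restarts = cfg$restarts,
                          variant = cfg$variant)
  centrality <- centrality_table(g)
  loops <- if (!is.null(cfg$loops_max_length))
    find_feedback_loops(g, max_length = cfg$loops_max_length)
  baseline <- if (cfg$baseline_replicates >= 10L)
    compare_to_random(g, n_replicates = cfg$baseline_replicates,
                      seed = derive_seed(cfg$seed, 42L))

  bundle <- structure(list(
    graph = g,
    global = global,
    centrality = centrality,
    partition = global$partition,
    loops = loops,
    baseline = baseline,
    root_influencers = root_influencers(g),
    provenance = list(
      key_path = key_path,
      edges_path = edges_path,
      key_md5 = unname(tools::md5sum(key_path)),
      edges_md5 = unname(tools::md5sum(edges_path)),
      config = cfg,
      package_version = as.character(utils::packageVersion("cldnet"))
    )
  ), class = "cld_analysis")

  if (!is.null(out_dir)) write_bundle(bundle, out_dir)
  bundle
}

#' @export
print.cld_analysis <- function(x, ...) {
  cat("<cld_analysis>\n")
  print(x$global)
  cat(sprintf("top betweenness: %s\n",
              paste(utils::head(top_central(x$centrality)$id, 4),
                    collapse = ", ")))
  if (!is.null(x$loops))
    cat(sprintf("%d feedback loop(s) of length <= %d\n", length(x$loops),
                x$provenance$config$loops_max_length))
  invisible(x)
}

#' Write an analysis bundle to disk
#'
#' Emits `global.csv` (one row, rounded for reporting: density 3 d.p.,
#' average path length 2 d.p.), `centrality.csv` (betweenness 1 d.p.),
#' `partition.csv`, `bundle.json` (full precision, machine-readable,
#' timestamp-free so reruns are byte-identical), and `graph.graphml`.
#'
#' @param bundle A `cld_analysis`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the vector of files written.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(global = file.path(dir, "global.csv"),
             centrality = file.path(dir, "centrality.csv"),
             partition = file.path(dir, "partition.csv"),
             json = file.path(dir, "bundle.json"),
             graphml = file.path(dir, "graph.graphml"))

  utils::write.csv(format_global_report(bundle$global), paths["global"],
                   row.names = FALSE)
  cent <- bundle$centrality
  cent$betweenness <- round(cent$betweenness, 1)
  utils::write.csv(cent, paths["centrality"], row.names = FALSE)
  part <- data.frame(id = bundle$graph$ids, name = bundle$graph$names,
                     community = unname(
                       bundle$partition$assignment[
                         as.character(bundle$graph$ids)]))
  utils::write.csv(part, paths["partition"], row.names = FALSE)

  payload <- list(
    global = unclass_report(bundle$global),
    centrality = bundle$centrality,
    partition = list(assignment = as.list(bundle$partition$assignment),
                     n_communities = bundle$partition$n_communities,
                     modularity = bundle$partition$modularity,
                     restarts = bundle$partition$restarts,
                     seed = bundle$partition$seed,
                     variant = bundle$partition$variant),
    loops = bundle$loops,
    baseline = if (!is.null(bundle$baseline)) list(
      observed = as.list(bundle$baseline$observed),
      z_scores = as.list(bundle$baseline$z_scores),
      heavy_tail_in = bundle$baseline$heavy_tail_in,
      heavy_tail_out = bundle$baseline$heavy_tail_out,
      heavy_tail_flag = bundle$baseline$heavy_tail_flag,
      n_replicates = bundle$baseline$n_replicates,
      seed = bundle$baseline$seed),
    root_influencers = bundle$root_influencers,
    provenance = bundle$provenance
  )
  jsonlite::write_json(payload, paths["json"], auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  export_graph(bundle$graph, "graphml", file = paths["graphml"])
  invisible(paths)
}

unclass_report <- function(report) {
  r <- unclass(report)
  r$partition <- NULL
  r
}

#' Compare two or more analyzed CLDs
#'
#' Side-by-side global metrics with deltas against the first bundle, plus
#' Spearman rank correlations of the centrality measures over variables
#' matched by normalized name (lowercase, punctuation stripped, whitespace
#' collapsed; ties in the correlation handled by average ranks). CLDs from
#' different communities name variables differently, so the match report
#' lists shared and unmatched variables explicitly.
#'
#' @param ... Two or more `cld_analysis` bundles (or a single list of them).
#' @return An object of class `cld_comparison`: `global` (one row per
#'   bundle), `deltas` (numeric differences vs the first bundle),
#'   `rank_correlation` (data.frame: pair, measure, spearman, n_matched),
#'   `shared_names`, `unmatched` (per-bundle list of names present only
#'   there).
#' @export
compare_clds <- function(...) {
  bundles <- list(...)
  if (length(bundles) == 1L && !inherits(bundles[[1L]], "cld_analysis"))
    bundles <- bundles[[1L]]
  if (length(bundles) < 2L)
    cld_error("cld_argument_error", "need at least 2 bundles to compare")
  if (!all(vapply(bundles, inherits, logical(1), "cld_analysis")))
    cld_error("cld_argument_error", "all inputs must be cld_analysis bundles")

  labels <- paste0("cld", seq_along(bundles))
  norm <- lapply(bundles, function(b) normalize_name(b$centrality$name))
  shared <- Reduce(intersect, norm)
  if (!length(shared))
    cld_error("cld_no_match_error",
              "no variable names shared between the CLDs after normalization")
  unmatched <- lapply(seq_along(bundles), function(i)
    sort(bundles[[i]]$centrality$name[!norm[[i]] %in% shared]))
  names(unmatched) <- labels

  glob <- do.call(rbind, lapply(bundles, function(b)
    format_global_report(b$global)))
  glob <- cbind(cld = labels, glob)
  num_cols <- vapply(glob, is.numeric, logical(1))
  deltas <- glob[-1L, num_cols, drop = FALSE]
  deltas[] <- lapply(seq_len(ncol(deltas)), function(j)
    deltas[[j]] - glob[1L, num_cols][[j]])
  deltas <- cbind(cld = labels[-1L], deltas)

  measures <- c("betweenness", "in_degree", "out_degree")
  pairs <- utils::combn(length(bundles), 2L)
  rc <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(k) {
    i <- pairs[1L, k]; j <- pairs[2L, k]
    xi <- bundles[[i]]$centrality[match(shared, norm[[i]]), ]
    xj <- bundles[[j]]$centrality[match(shared, norm[[j]]), ]
    data.frame(pair = sprintf("%s~%s", labels[i], labels[j]),
               measure = measures,
               spearman = vapply(measures, function(mm)
                 stats::cor(xi[[mm]], xj[[mm]], method = "spearman"),
                 numeric(1)),
               n_matched = length(shared), row.names = NULL)
  }))

  structure(list(global = glob, deltas = deltas, rank_correlation = rc,
                 shared_names = sort(shared), unmatched = unmatched),
            class = "cld_comparison")
}

#' @export
print.cld_comparison <- function(x, ...) {
  cat(sprintf("<cld_comparison> %d CLDs, %d shared variable(s)\n",
              nrow(x$global), length(x$shared_names)))
  print(x$global, row.names = FALSE)
  print(x$rank_correlation, row.names = FALSE, digits = 3)
  invisible(x)
}
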