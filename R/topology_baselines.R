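#' Compare a CLD against a uniform random-graph ensemble
#'
#' Quantifies the qualitative topology claims commonly made about systems
#' maps — "small-world-like" (sparse yet short average paths) and
#' "scale-free-like" (heavy-tailed degree structure) — by generating an
#' ensemble of uniform directed random graphs with the same node and edge
#' counts ([er_directed()]) and expressing each observed metric as a
#' z-score against the ensemble.
#'
#' The uniform G(N, E) baseline is deliberate: a degree-preserving rewiring
#' null would build the observed hubs into the baseline and erase exactly
#' the heavy-tail signal being tested. The heavy-tail rule — observed
#' maximum degree more than 3 ensemble standard deviations above the
#' ensemble mean — is a declared convention of this package, not a
#' statistical test; no power-law exponent is fitted because maximum
#' degrees around 14 could not support one.
#'
#' @param g A `cld_graph`.
#' @param n_replicates Ensemble size (>= 10).
#' @param seed Integer seed; fixes the whole comparison bit-for-bit.
#' @param modularity_restarts Louvain restarts used for the observed graph
#'   and each replicate (default 5; the ensemble needs stability, not the
#'   global optimum).
#' @return An object of class `cld_baseline_comparison`: `observed` (named
#'   metric vector), `ensemble` (data.frame of per-replicate metrics),
#'   `summary` (mean and sd per metric), `z_scores` (named vector, `NA`
#'   where the ensemble sd is 0), `heavy_tail_in`, `heavy_tail_out`,
#'   `heavy_tail_flag` (either direction), `n_replicates`, `seed`.
#' @export
compare_to_random <- function(g, n_replicates = 20L, seed = 1L,
                              modularity_restarts = 5L) {
  n_replicates <- assert_count(n_replicates, "n_replicates", min = 10L)
  n <- n_nodes(g)
  m <- n_edges(g)
  if (m > n * (n - 1))
    cld_error("cld_argument_error", "edge count exceeds simple-graph maximum")

  metrics_of <- function(gr, sd_seed) {
    apl <- tryCatch(average_path_length(gr), cld_error = function(e) NULL)
    if (is.null(apl)) return(NULL)
    q <- if (n_edges(gr) >= 1L)
      louvain(gr, seed = sd_seed, restarts = modularity_restarts)$modularity
    else NA_real_
    deg <- degrees(gr)
    c(avg_path_length = apl$avg,
      diameter = diameter(gr)$d,
      modularity = q,
      max_in_degree = max(deg$in_degree),
      max_out_degree = max(deg$out_degree))
  }

  observed <- metrics_of(g, derive_seed(seed, 0L))
  if (is.null(observed))
    cld_error("cld_undefined_metric_error",
              "observed graph has no reachable ordered pairs")

  reps <- vector("list", n_replicates)
  skipped <- 0L
  for (r in seq_len(n_replicates)) {
    gr <- er_directed(n, m, seed = derive_seed(seed, r))
    val <- metrics_of(gr, derive_seed(seed, 10000L + r))
    if (is.null(val)) {
      skipped <- skipped + 1L
      cld_warning("cld_degenerate_replicate_warning",
                  sprintf("replicate %d has no reachable pairs; skipped", r))
    } else reps[[r]] <- val
  }
  reps <- do.call(rbind, reps[!vapply(reps, is.null, logical(1))])
  if (is.null(reps) || nrow(reps) < 2L)
    cld_error("cld_degenerate_ensemble_error",
              "fewer than 2 usable ensemble replicates")

  mu <- colMeans(reps)
  sdev <- apply(reps, 2L, stats::sd)
  z <- ifelse(sdev > 0, (observed - mu) / sdev, NA_real_)
  ht_in <- isTRUE(sdev["max_in_degree"] > 0 &&
    observed["max_in_degree"] > mu["max_in_degree"] +
      3 * sdev["max_in_degree"])
  ht_out <- isTRUE(sdev["max_out_degree"] > 0 &&
    observed["max_out_degree"] > mu["max_out_degree"] +
      3 * sdev["max_out_degree"])

  structure(list(
    observed = observed,
    ensemble = as.data.frame(reps),
    summary = data.frame(metric = names(mu), mean = unname(mu),
                         sd = unname(sdev)),
    z_scores = z,
    heavy_tail_in = ht_in,
    heavy_tail_out = ht_out,
    heavy_tail_flag = ht_in || ht_out,
    n_replicates = n_replicates,
    n_skipped = skipped,
    seed = as.integer(seed)
  ), class = "cld_baseline_comparison")
}

#' @export
print.cld_baseline_comparison <- function(x, ...) {
  cat(sprintf("<cld_baseline_comparison> %d replicates (seed %d)\n",
              x$n_replicates, x$seed))
  tab <- data.frame(metric = names(x$observed),
                    observed = unname(x$observed),
                    ensemble_mean = x$summary$mean,
                    ensemble_sd = x$summary$sd,
                    z = unname(x$z_scores))
  print(tab, row.names = FALSE, digits = 4)
  cat(sprintf("heavy tail: in-degree %s, out-degree %s\n",
              x$heavy_tail_in, x$heavy_tail_out))
  invisible(x)
}
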