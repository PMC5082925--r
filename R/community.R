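#' Modularity of a community assignment
#'
#' Scores how strongly a partition of the variables into communities
#' concentrates causal links within communities, relative to a
#' degree-matched random expectation.
#'
#' Two variants are provided. The default `"undirected"` variant first
#' projects the CLD onto a simple undirected graph (symmetrize, drop
#' duplicate arcs) and computes
#' `Q = sum_c [ e_c / m - (d_c / (2 m))^2 ]`,
#' with `e_c` the number of undirected edges inside community `c`, `d_c`
#' the total undirected degree in `c`, and `m` the number of undirected
#' edges. This mirrors how general-purpose network tools score modularity
#' on a directed graph by default. The `"directed"` variant keeps arc
#' direction: `Q = sum_c [ e_c / m - (Kout_c * Kin_c) / m^2 ]` with `m` the
#' number of arcs.
#'
#' @param g A `cld_graph`.
#' @param assignment Community labels: either a vector named by variable ID,
#'   or an unnamed vector aligned with the node order of `g`. Every node
#'   must be labelled.
#' @param variant `"undirected"` (projection, default) or `"directed"`.
#' @return Modularity `Q` in `[-0.5, 1]`, full precision.
#' @export
modularity_score <- function(g, assignment,
                             variant = c("undirected", "directed")) {
  variant <- match.arg(variant)
  com <- align_assignment(g, assignment)
  arcs <- modularity_arcs(g, variant)
  directed_modularity(arcs$s, arcs$t, arcs$w, com)
}

# Align an assignment vector (named by id or positional) to node order.
align_assignment <- function(g, assignment) {
  n <- n_nodes(g)
  if (!is.null(names(assignment))) {
    idx <- match(as.character(g$ids), names(assignment))
    if (any(is.na(idx)))
      cld_error("cld_partial_assignment_error",
                sprintf("assignment missing variable(s): %s",
                        paste(g$ids[is.na(idx)], collapse = ", ")))
    assignment <- assignment[idx]
  }
  if (length(assignment) != n || any(is.na(assignment)))
    cld_error("cld_partial_assignment_error",
              "assignment must label every variable exactly once")
  as.integer(factor(assignment))
}

# Arc representation on internal indices for the modularity formula.
# Undirected projection = symmetrized simple graph encoded as reciprocal
# unit arcs, under which the directed formula reduces to the classic
# undirected Q.
modularity_arcs <- function(g, variant) {
  if (n_edges(g) < 1L)
    cld_error("cld_edgeless_error",
              "modularity undefined for a graph with no links")
  si <- match(g$edges$source, g$ids)
  ti <- match(g$edges$target, g$ids)
  if (variant == "directed")
    return(list(s = si, t = ti, w = rep(1, length(si))))
  a <- pmin(si, ti)
  b <- pmax(si, ti)
  keep <- !duplicated(paste(a, b))
  a <- a[keep]; b <- b[keep]
  list(s = c(a, b), t = c(b, a), w = rep(1, 2L * length(a)))
}

# Q = sum_c [ e_c/m - Kout_c*Kin_c/m^2 ] on weighted arcs (self-arcs allowed).
directed_modularity <- function(s, t, w, com) {
  m <- sum(w)
  ncom <- max(com)
  within <- com[s] == com[t]
  e_c <- vapply(seq_len(ncom), function(c)
    sum(w[within & com[s] == c]), numeric(1))
  k_out <- rowsum_by(w, s, length(com))
  k_in <- rowsum_by(w, t, length(com))
  K_out <- rowsum_by(k_out, com, ncom)
  K_in <- rowsum_by(k_in, com, ncom)
  sum(e_c / m - K_out * K_in / m^2)
}

rowsum_by <- function(w, idx, n) {
  out <- numeric(n)
  agg <- rowsum(w, idx)
  out[as.integer(rownames(agg))] <- agg[, 1L]
  out
}

#' Louvain-style multilevel community detection
#'
#' Greedy modularity optimisation: repeated local-move sweeps (each node is
#' offered to the neighbouring community with the largest modularity gain;
#' ties go to the lower community label; moves require strict improvement),
#' followed by aggregation of communities into super-nodes, until no sweep
#' improves. The whole procedure restarts `restarts` times with different
#' seeded node-visitation orders and returns the best partition found.
#' Deterministic given `(seed, restarts)`; the caller's RNG state is left
#' untouched.
#'
#' @param g A `cld_graph` with at least one link.
#' @param seed Integer seed for the restart shuffles.
#' @param restarts Number of restarts (>= 1).
#' @param variant Modularity variant, see [modularity_score()]. The
#'   undirected projection is the default because that is how
#'   general-purpose network software typically scores a directed graph;
#'   the directed formula is available for methodological completeness.
#' @param resolution Resolution parameter (fixed default 1; values > 1
#'   favour smaller communities).
#' @return An object of class `cld_partition`: list with `assignment`
#'   (integer labels named by variable ID, renumbered 1..k in node order),
#'   `n_communities`, `modularity` (exactly
#'   `modularity_score(g, assignment, variant)`), `restarts`, `seed`,
#'   `variant`, and `q_restarts` (the best Q seen in each restart, for an
#'   honest view of the stochastic spread).
#' @export
louvain <- function(g, seed = 1L, restarts = 20L,
                    variant = c("undirected", "directed"),
                    resolution = 1) {
  variant <- match.arg(variant)
  restarts <- assert_count(restarts, "restarts", min = 1L)
  arcs <- modularity_arcs(g, variant)
  n <- n_nodes(g)

  best <- NULL
  q_restarts <- numeric(restarts)
  for (r in seq_len(restarts)) {
    com <- with_seed(derive_seed(seed, r),
                     louvain_once(arcs$s, arcs$t, arcs$w, n, resolution))
    q <- directed_modularity(arcs$s, arcs$t, arcs$w, com)
    q_restarts[r] <- q
    if (is.null(best) || q > best$q + 1e-12) best <- list(com = com, q = q)
  }

  labels <- as.integer(factor(best$com, levels = unique(best$com)))
  structure(list(
    assignment = stats::setNames(labels, g$ids),
    n_communities = max(labels),
    modularity = directed_modularity(arcs$s, arcs$t, arcs$w, labels),
    restarts = restarts,
    seed = as.integer(seed),
    variant = variant,
    q_restarts = q_restarts
  ), class = "cld_partition")
}

#' @export
print.cld_partition <- function(x, ...) {
  cat(sprintf(
    "<cld_partition> %d communities, Q = %.4f (%s, %d restart(s), seed %d)\n",
    x$n_communities, x$modularity, x$variant, x$restarts, x$seed))
  if (length(x$q_restarts) > 1L)
    cat(sprintf("  restart Q spread: %.4f .. %.4f\n",
                min(x$q_restarts), max(x$q_restarts)))
  invisible(x)
}

# One full multilevel run on arc arrays; returns membership (internal order).
louvain_once <- function(s, t, w, n, resolution) {
  m <- sum(w)
  membership <- seq_len(n)
  n_cur <- n
  repeat {
    res <- local_moves(s, t, w, n_cur, m, resolution)
    com <- res$com
    # map the original nodes through this level
    membership <- com[membership]
    k <- max(com)
    if (!res$moved || k == n_cur) break
    # aggregate arcs by community pair (self-arcs carry internal weight)
    key <- paste(com[s], com[t])
    agg <- rowsum(w, key)
    parts <- strsplit(rownames(agg), " ", fixed = TRUE)
    s <- vapply(parts, function(p) as.integer(p[1L]), integer(1))
    t <- vapply(parts, function(p) as.integer(p[2L]), integer(1))
    w <- agg[, 1L]
    n_cur <- k
  }
  membership
}

# Local-moving phase. Nodes are visited in a shuffled order (RNG assumed
# seeded by the caller); sweeps repeat until a full sweep makes no move.
local_moves <- function(s, t, w, n, m, resolution) {
  com <- seq_len(n)
  k_out <- rowsum_by(w, s, n)
  k_in <- rowsum_by(w, t, n)
  K_out <- k_out
  K_in <- k_in
  out_idx <- split(seq_along(s), factor(s, levels = seq_len(n)))
  in_idx <- split(seq_along(t), factor(t, levels = seq_len(n)))

  perm <- sample.int(n)
  moved_any <- FALSE
  repeat {
    moves <- 0L
    for (i in perm) {
      ci <- com[i]
      oi <- out_idx[[i]]
      ii <- in_idx[[i]]
      nb <- c(t[oi], s[ii])
      wt <- c(w[oi], w[ii])
      keep <- nb != i
      nb <- nb[keep]; wt <- wt[keep]
      if (!length(nb)) next
      # arc weight between i and each candidate community
      wc <- rowsum(wt, com[nb])
      cand <- as.integer(rownames(wc))
      wvec <- wc[, 1L]
      if (!ci %in% cand) { cand <- c(cand, ci); wvec <- c(wvec, 0) }
      # detach i
      K_out[ci] <- K_out[ci] - k_out[i]
      K_in[ci] <- K_in[ci] - k_in[i]
      gain <- wvec / m -
        resolution * (K_out[cand] * k_in[i] + K_in[cand] * k_out[i]) / m^2
      ord <- order(cand)
      cand <- cand[ord]; gain <- gain[ord]
      best <- cand[which.max(gain)]   # first max = lowest label on ties
      cur_gain <- gain[match(ci, cand)]
      target <- if (gain[match(best, cand)] > cur_gain + 1e-12) best else ci
      K_out[target] <- K_out[target] + k_out[i]
      K_in[target] <- K_in[target] + k_in[i]
      if (target != ci) {
        com[i] <- target
        moves <- moves + 1L
      }
    }
    if (moves == 0L) break
    moved_any <- TRUE
  }
  list(com = as.integer(factor(com, levels = sort(unique(com)))),
       moved = moved_any)
}
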