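# Seeded generators of CLD-like directed networks. All generators are pure
# functions of their parameters + seed and never touch the caller's RNG.

make_graph <- function(n, src, tgt, name_fmt = "node-%03d", ids = seq_len(n)) {
  vars <- data.frame(id = ids, name = sprintf(name_fmt, ids),
                     stringsAsFactors = FALSE)
  links <- data.frame(source = ids[src], target = ids[tgt],
                      polarity = rep("unknown", length(src)),
                      stringsAsFactors = FALSE)
  build_graph(vars, links)
}

#' Uniform directed random graph G(n, m)
#'
#' Exactly `m` distinct directed non-self edges drawn uniformly without
#' replacement from the `n * (n - 1)` possible ordered pairs. This is the
#' null model used by [compare_to_random()]: it matches node and edge counts
#' but has no hubs, no communities and no planted structure.
#'
#' @param n Number of nodes (>= 2).
#' @param m Number of edges, `0 <= m <= n * (n - 1)`.
#' @param seed Integer seed; same `(n, m, seed)` always yields the same graph.
#' @return A `cld_graph` with auto-generated node names (the seed is baked
#'   into the names so graphs from different seeds share no variables).
#' @export
er_directed <- function(n, m, seed = 1L) {
  n <- assert_count(n, "n", min = 2L)
  m <- assert_count(m, "m", min = 0L)
  if (m > n * (n - 1))
    cld_error("cld_argument_error",
              sprintf("m = %d exceeds n*(n-1) = %d", m, n * (n - 1)))
  pick <- with_seed(seed, sample(n * (n - 1), m))
  idx <- pick - 1L
  src <- idx %/% (n - 1L) + 1L
  r <- idx %% (n - 1L) + 1L
  tgt <- ifelse(r >= src, r + 1L, r)
  make_graph(n, src, tgt, name_fmt = sprintf("er-s%d-node-%%03d", seed))
}

#' Directed preferential-attachment graph
#'
#' Nodes arrive one at a time; each new node emits `edges_per_node` edges
#' (fewer while the graph is small) to distinct existing nodes chosen with
#' probability proportional to `in_degree + 1`. The `+1` smoothing keeps
#' zero-in-degree nodes reachable as targets. Produces the heavy-tailed
#' in-degree regime characteristic of scale-free-like networks.
#'
#' @param n Number of nodes (>= 3).
#' @param edges_per_node Edges emitted by each arriving node (>= 1).
#' @param seed Integer seed.
#' @return A `cld_graph`.
#' @export
preferential_attachment_directed <- function(n, edges_per_node = 2L,
                                             seed = 1L) {
  n <- assert_count(n, "n", min = 3L)
  edges_per_node <- assert_count(edges_per_node, "edges_per_node", min = 1L)
  with_seed(seed, {
    in_deg <- integer(n)
    src <- integer(0)
    tgt <- integer(0)
    for (v in 2:n) {
      k <- min(edges_per_node, v - 1L)
      existing <- seq_len(v - 1L)
      targets <- if (length(existing) == 1L) existing
                 else sample(existing, k, prob = in_deg[existing] + 1)
      src <- c(src, rep(v, k))
      tgt <- c(tgt, targets)
      in_deg[targets] <- in_deg[targets] + 1L
    }
    make_graph(n, src, tgt, name_fmt = sprintf("pa-s%d-node-%%03d", seed))
  })
}

# ---- CLD-like generator --------------------------------------------------

# Study conditions the generator emulates. One isolate; a 16-hop geodesic
# chain defining the diameter pair; four planted in-hubs and five planted
# out-hubs at fixed IDs; a three-variable reinforcing loop; five modular
# blocks. Average path length and modularity are steered into narrow windows
# around the emulation targets (4.65 and 0.56).
cld_like_spec <- function() {
  list(
    n = 114L, m = 209L,
    isolate = 47L,
    chain_from = 113L, chain_to = 77L, chain_len = 16L,
    in_hubs = c(`66` = 14L, `84` = 13L, `57` = 11L, `26` = 7L),
    out_hubs = c(`8` = 7L, `98` = 6L, `12` = 5L, `40` = 5L, `102` = 5L),
    zero_in = c(8L, 102L),
    cycle = c(64L, 88L, 84L),          # 64 -> 88 -> 84 -> 64
    n_blocks = 5L,
    generic_in_cap = 6L, generic_out_cap = 5L,
    p_within = 0.74,
    apl_target = 4.65, apl_window = c(4.645, 4.655),
    planted_q_window = c(0.495, 0.53),
    louvain_q_window = c(0.535, 0.57)
  )
}

#' Generate a CLD-like synthetic network
#'
#' Produces a 114-variable, 209-link directed network with the structural
#' signature of a community-built childhood-obesity systems map: exactly one
#' isolate (variable 47), heavy-tailed degree structure with planted in-hubs
#' (variable 66 with in-degree 14, 84 with 13, 57 with 11, 26 with 7) and
#' out-hubs (variable 8 with out-degree 7 and in-degree 0, 98 with 6),
#' a planted three-variable feedback loop (64 -> 88 -> 84 -> 64), five
#' modular blocks, a directed diameter of 16 achieved by the pair
#' (113, 77), an average directed path length steered to 4.65, and
#' best-partition modularity near 0.56.
#'
#' Generation is constructive: the skeleton (isolate, chain, hubs, loop,
#' blocks) is planted outright, filler edges are placed mostly within
#' blocks, and a seeded greedy rewiring pass then walks average path length
#' and modularity into their target windows without disturbing the planted
#' degrees. If a draw cannot satisfy all constraints the generator re-draws
#' with a derived seed, up to `max_retries` times, then fails with
#' diagnostics. Deterministic per seed.
#'
#' @param seed Integer seed.
#' @param max_retries Re-draw budget before giving up (default 60).
#' @return A `cld_graph`; attribute `"generator"` records the seed, the
#'   attempt that succeeded, and the achieved average path length and
#'   planted-partition modularity. Attribute `"planted_assignment"` holds
#'   the block partition used during construction.
#' @export
cld_like <- function(seed = 1L, max_retries = 60L) {
  reasons <- character(0)
  for (attempt in seq_len(max_retries)) {
    res <- cld_like_attempt(derive_seed(seed, 7000L + attempt))
    if (is.character(res)) {
      reasons <- c(reasons, sprintf("attempt %d: %s", attempt, res))
      next
    }
    attr(res$graph, "generator") <-
      list(kind = "cld_like", seed = as.integer(seed), attempt = attempt,
           apl = res$apl, planted_q = res$planted_q,
           louvain_q = res$louvain_q)
    attr(res$graph, "planted_assignment") <- res$assignment
    return(res$graph)
  }
  cld_error("cld_generation_error",
            paste0("cld_like could not satisfy its structural constraints ",
                   sprintf("after %d attempts (seed %d). Diagnostics:\n",
                           max_retries, seed),
                   paste(utils::tail(reasons, 8L), collapse = "\n")))
}

# One constructive attempt; returns a list on success or a reason string.
cld_like_attempt <- function(seed) {
  sp <- cld_like_spec()
  with_seed(seed, {
    n <- sp$n
    ids <- seq_len(n)
    in_hub_ids <- as.integer(names(sp$in_hubs))
    out_hub_ids <- as.integer(names(sp$out_hubs))

    # --- roles ---------------------------------------------------------
    reserved <- c(sp$isolate, sp$chain_from, sp$chain_to,
                  in_hub_ids, out_hub_ids, sp$cycle)
    plain <- setdiff(ids, reserved)
    mids <- sort(sample(plain, sp$chain_len - 1L))
    block_nodes <- setdiff(ids, c(sp$isolate, sp$chain_from, mids))
    block_of <- integer(n)                     # 0 = not in a block
    block_of[sample(block_nodes)] <-
      rep(seq_len(sp$n_blocks), length.out = length(block_nodes))

    # --- degree caps ---------------------------------------------------
    in_cap <- rep(sp$generic_in_cap, n)
    out_cap <- rep(sp$generic_out_cap, n)
    in_cap[in_hub_ids] <- sp$in_hubs
    out_cap[out_hub_ids] <- sp$out_hubs
    in_cap[c(sp$zero_in, sp$isolate, sp$chain_from, mids)] <- 0L
    out_cap[c(sp$isolate, sp$chain_to, mids, sp$chain_from)] <- 0L

    in_deg <- integer(n)
    out_deg <- integer(n)
    adj <- matrix(FALSE, n, n)

    add_edge <- function(s, t) {
      adj[s, t] <<- TRUE
      out_deg[s] <<- out_deg[s] + 1L
      in_deg[t] <<- in_deg[t] + 1L
    }
    # --- planted skeleton ---------------------------------------------
    chain <- c(sp$chain_from, mids, sp$chain_to)
    for (i in seq_len(sp$chain_len)) {
      adj[chain[i], chain[i + 1L]] <- TRUE   # chain bypasses cap ledger
    }
    cyc <- sp$cycle
    for (i in seq_along(cyc))
      add_edge(cyc[i], cyc[ifelse(i == length(cyc), 1L, i + 1L)])

    can_target <- function(s, t) {
      s != t & !adj[s, t] & in_deg[t] < in_cap[t]
    }
    draw_target <- function(s) {
      own <- block_of[s]
      pool_in <- block_nodes[block_of[block_nodes] == own]
      pool_out <- block_nodes[block_of[block_nodes] != own]
      pool <- if (stats::runif(1) < sp$p_within) pool_in else pool_out
      ok <- pool[can_target(s, pool)]
      if (!length(ok)) ok <- block_nodes[can_target(s, block_nodes)]
      if (!length(ok)) return(NA_integer_)
      if (length(ok) == 1L) ok else sample(ok, 1L)
    }
    draw_source <- function(t) {
      own <- block_of[t]
      cand <- block_nodes[out_deg[block_nodes] < out_cap[block_nodes]]
      cand <- cand[cand != t & !adj[cand, t]]
      if (!length(cand)) return(NA_integer_)
      pool_in <- cand[block_of[cand] == own]
      pool <- if (stats::runif(1) < sp$p_within && length(pool_in))
        pool_in else cand
      if (length(pool) == 1L) pool else sample(pool, 1L)
    }

    # --- out-hub emissions --------------------------------------------
    for (h in out_hub_ids) {
      guard <- 0L
      while (out_deg[h] < out_cap[h]) {
        t <- draw_target(h)
        if (is.na(t)) return("out-hub emission exhausted targets")
        add_edge(h, t)
        if ((guard <- guard + 1L) > 200L)
          return("out-hub emission stalled")
      }
    }
    # --- in-hub fills --------------------------------------------------
    for (h in in_hub_ids) {
      guard <- 0L
      while (in_deg[h] < in_cap[h]) {
        s <- draw_source(h)
        if (is.na(s)) return("in-hub fill exhausted sources")
        add_edge(s, h)
        if ((guard <- guard + 1L) > 300L)
          return("in-hub fill stalled")
      }
    }
    # --- coverage: the planted isolate must be the only isolate --------
    for (v in block_nodes) {
      if (in_deg[v] + out_deg[v] > 0L) next
      t <- draw_target(v)
      if (!is.na(t) && out_deg[v] < out_cap[v]) {
        add_edge(v, t)
      } else {
        s <- draw_source(v)
        if (is.na(s)) return("coverage: cannot attach degree-0 node")
        add_edge(s, v)
      }
    }
    if (sum(adj) > sp$m) return("coverage overshot edge budget")

    # --- filler edges --------------------------------------------------
    n_current <- function() sum(adj)
    guard <- 0L
    while (n_current() < sp$m) {
      cand <- block_nodes[out_deg[block_nodes] < out_cap[block_nodes]]
      if (!length(cand)) return("filler: no source capacity left")
      s <- if (length(cand) == 1L) cand else sample(cand, 1L)
      t <- draw_target(s)
      if (!is.na(t)) add_edge(s, t)
      if ((guard <- guard + 1L) > 3000L)
        return("filler placement stalled")
    }

    # planted partition: blocks, plus the chain (with its head) and the
    # isolate as their own communities
    assignment <- block_of
    assignment[c(sp$chain_from, mids)] <- sp$n_blocks + 1L
    assignment[sp$isolate] <- sp$n_blocks + 2L
    assignment <- stats::setNames(assignment, ids)

    hub_edge <- adj        # edges whose endpoints' degrees are planted
    hub_edge[,] <- FALSE
    hub_edge[out_hub_ids, ] <- TRUE
    hub_edge[, in_hub_ids] <- TRUE
    fixed <- matrix(FALSE, n, n)
    for (i in seq_len(sp$chain_len)) fixed[chain[i], chain[i + 1L]] <- TRUE
    for (i in seq_along(cyc))
      fixed[cyc[i], cyc[ifelse(i == length(cyc), 1L, i + 1L)]] <- TRUE

    st <- steer_structure(adj, fixed, hub_edge, block_of, block_nodes,
                          in_cap, out_cap, in_deg, out_deg, sp, ids,
                          com_full = unname(assignment))
    if (is.character(st)) return(st)

    g <- graph_from_adj(st$adj, ids)
    if (!identical(isolates(g), sp$isolate))
      return(sprintf("isolate set is {%s}, expected {%d}",
                     paste(isolates(g), collapse = ","), sp$isolate))
    # final stochastic-detection check on the finished graph
    part <- louvain(g, seed = derive_seed(seed, 991L), restarts = 6L)
    if (part$modularity < sp$louvain_q_window[1L] ||
        part$modularity > sp$louvain_q_window[2L])
      return(sprintf("louvain Q %.3f outside window", part$modularity))
    list(graph = g, apl = st$apl, planted_q = st$q,
         louvain_q = part$modularity, assignment = assignment)
  })
}

graph_from_adj <- function(adj, ids) {
  e <- which(adj, arr.ind = TRUE)
  make_graph(nrow(adj), e[, 1L], e[, 2L],
             name_fmt = "synthetic-variable-%03d", ids = ids)
}

# Greedy seeded rewiring of filler edges: first walk the planted-partition
# modularity into its window by trading within-block against between-block
# filler edges, then walk the average path length into its window with
# type-preserving rewires, re-checking the diameter invariant throughout.
steer_structure <- function(adj, fixed, hub_edge, block_of, block_nodes,
                            in_cap, out_cap, in_deg, out_deg, sp, ids,
                            com_full) {
  n <- nrow(adj)
  q_of <- function(a) planted_q(a, com_full)
  filler_edges <- function(a) {
    e <- which(a & !fixed & !hub_edge, arr.ind = TRUE)
    e[block_of[e[, 1L]] > 0L & block_of[e[, 2L]] > 0L, , drop = FALSE]
  }
  apl_diam <- function(a) {
    dm <- adj_dist_matrix(a)
    diag(dm) <- NA_integer_
    fin <- dm[!is.na(dm)]
    dmax <- max(fin)
    hits <- which(dm == dmax, arr.ind = TRUE)
    list(apl = mean(fin),
         diam = dmax,
         unique_pair = nrow(hits) == 1L &&
           hits[1L, 1L] == sp$chain_from && hits[1L, 2L] == sp$chain_to)
  }

  # phase A: modularity window
  q <- q_of(adj)
  for (iter in seq_len(400L)) {
    if (q >= sp$planted_q_window[1L] && q <= sp$planted_q_window[2L]) break
    want_within <- q < sp$planted_q_window[1L]
    fe <- filler_edges(adj)
    same <- block_of[fe[, 1L]] == block_of[fe[, 2L]]
    pool <- fe[if (want_within) !same else same, , drop = FALSE]
    if (!nrow(pool)) return("q-steering: no filler edges of needed type")
    pick <- pool[sample(nrow(pool), 1L), ]
    # remove, then add an edge of the opposite type
    s_old <- pick[1L]; t_old <- pick[2L]
    if (in_deg[s_old] + out_deg[s_old] <= 1L ||
        in_deg[t_old] + out_deg[t_old] <= 1L) next   # would create an isolate
    cand_s <- block_nodes[out_deg[block_nodes] < out_cap[block_nodes] |
                          block_nodes == ids[s_old]]
    repl <- propose_edge(adj, cand_s, block_nodes, block_of, in_cap, in_deg,
                         within = want_within)
    if (is.null(repl)) next
    adj[s_old, t_old] <- FALSE
    out_deg[s_old] <- out_deg[s_old] - 1L; in_deg[t_old] <- in_deg[t_old] - 1L
    adj[repl[1L], repl[2L]] <- TRUE
    out_deg[repl[1L]] <- out_deg[repl[1L]] + 1L
    in_deg[repl[2L]] <- in_deg[repl[2L]] + 1L
    q <- q_of(adj)
  }
  if (q < sp$planted_q_window[1L] || q > sp$planted_q_window[2L])
    return(sprintf("q-steering failed (Q = %.3f)", q))

  # phase B: average path length window (type-preserving rewires)
  cur <- apl_diam(adj)
  if (cur$diam > sp$chain_len) return("main component too deep for diameter")
  best_gap <- abs(cur$apl - sp$apl_target)
  for (iter in seq_len(900L)) {
    if (cur$apl >= sp$apl_window[1L] && cur$apl <= sp$apl_window[2L] &&
        cur$diam == sp$chain_len && cur$unique_pair) break
    fe <- filler_edges(adj)
    pick <- fe[sample(nrow(fe), 1L), ]
    s_old <- pick[1L]; t_old <- pick[2L]
    if (in_deg[s_old] + out_deg[s_old] <= 1L ||
        in_deg[t_old] + out_deg[t_old] <= 1L) next   # would create an isolate
    within <- block_of[s_old] == block_of[t_old]
    cand_s <- block_nodes[out_deg[block_nodes] < out_cap[block_nodes] |
                          block_nodes == ids[s_old]]
    repl <- propose_edge(adj, cand_s, block_nodes, block_of, in_cap, in_deg,
                         within = within)
    if (is.null(repl)) next
    adj2 <- adj
    adj2[s_old, t_old] <- FALSE
    adj2[repl[1L], repl[2L]] <- TRUE
    nxt <- apl_diam(adj2)
    if (nxt$diam > sp$chain_len || !nxt$unique_pair) next
    gap <- abs(nxt$apl - sp$apl_target)
    if (gap < best_gap || !cur$unique_pair) {
      adj <- adj2
      out_deg[s_old] <- out_deg[s_old] - 1L
      in_deg[t_old] <- in_deg[t_old] - 1L
      out_deg[repl[1L]] <- out_deg[repl[1L]] + 1L
      in_deg[repl[2L]] <- in_deg[repl[2L]] + 1L
      cur <- nxt
      best_gap <- gap
    }
  }
  q <- q_of(adj)
  ok <- cur$apl >= sp$apl_window[1L] && cur$apl <= sp$apl_window[2L] &&
    cur$diam == sp$chain_len && cur$unique_pair &&
    q >= sp$planted_q_window[1L] && q <= sp$planted_q_window[2L]
  if (!ok)
    return(sprintf("apl-steering failed (apl %.4f, diam %d, Q %.3f)",
                   cur$apl, cur$diam, q))
  list(adj = adj, apl = cur$apl, q = q)
}

# Candidate replacement edge between block nodes of the requested type.
propose_edge <- function(adj, cand_s, block_nodes, block_of, in_cap, in_deg,
                         within, tries = 30L) {
  for (k in seq_len(tries)) {
    s <- if (length(cand_s) == 1L) cand_s else sample(cand_s, 1L)
    pool <- block_nodes[if (within) block_of[block_nodes] == block_of[s]
                        else block_of[block_nodes] != block_of[s]]
    pool <- pool[pool != s & !adj[s, pool] & in_deg[pool] < in_cap[pool]]
    if (length(pool))
      return(c(s, if (length(pool) == 1L) pool else sample(pool, 1L)))
  }
  NULL
}

# Undirected-projection modularity of the planted partition, directly on an
# adjacency matrix (fast path for the generator's steering loop).
planted_q <- function(adj, com) {
  und <- adj | t(adj)
  e <- which(und & upper.tri(und), arr.ind = TRUE)
  m <- nrow(e)
  within <- com[e[, 1L]] == com[e[, 2L]]
  labs <- sort(unique(com))
  deg <- tabulate(c(com[e[, 1L]], com[e[, 2L]]), nbins = max(labs))
  e_c <- tabulate(com[e[, 1L]][within], nbins = max(labs))
  sum(e_c / m - (deg / (2 * m))^2)
}

# Hop distances from a raw adjacency matrix via sparse-frontier BFS.
adj_dist_matrix <- function(adj) {
  n <- nrow(adj)
  nbr <- apply(adj, 1L, which, simplify = FALSE)
  out <- matrix(NA_integer_, n, n)
  for (s in seq_len(n)) out[s, ] <- bfs_index(nbr, s, n)
  out
}
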