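# Independent oracles used to validate the package's graph algorithms.
# These deliberately take different algorithmic routes than the
# implementation: matrix-power walks instead of BFS, exhaustive path /
# partition / permutation enumeration instead of Brandes or Louvain.

adj_matrix_of <- function(g) {
  n <- n_nodes(g)
  A <- matrix(0, n, n, dimnames = list(g$ids, g$ids))
  if (n_edges(g))
    A[cbind(match(g$edges$source, g$ids), match(g$edges$target, g$ids))] <- 1
  A
}

# Hop distances via boolean matrix powers: the first k with a length-k walk
# is the shortest-path distance.
oracle_distances <- function(g) {
  A <- adj_matrix_of(g)
  n <- nrow(A)
  D <- matrix(NA_integer_, n, n, dimnames = dimnames(A))
  diag(D) <- 0L
  Wk <- diag(n)
  for (k in seq_len(max(n - 1L, 1L))) {
    Wk <- (Wk %*% A) > 0
    D[Wk & is.na(D)] <- k
  }
  D
}

# Betweenness by exhaustive enumeration of every shortest path per ordered
# pair (distance-pruned DFS), splitting credit equally across paths.
oracle_betweenness <- function(g) {
  D <- oracle_distances(g)
  A <- adj_matrix_of(g)
  n <- nrow(A)
  nbrs <- lapply(seq_len(n), function(i) which(A[i, ] > 0))
  cb <- numeric(n)
  for (s in seq_len(n)) {
    for (t in seq_len(n)) {
      if (s == t || is.na(D[s, t])) next
      L <- D[s, t]
      paths <- list()
      walk <- function(v, depth, trail) {
        if (v == t) {
          paths[[length(paths) + 1L]] <<- trail
          return()
        }
        for (w in nbrs[[v]])
          if (!is.na(D[w, t]) && D[w, t] == L - depth - 1L)
            walk(w, depth + 1L, c(trail, w))
      }
      walk(s, 0L, s)
      sigma <- length(paths)
      for (p in paths) {
        interior <- p[-c(1L, length(p))]
        cb[interior] <- cb[interior] + 1 / sigma
      }
    }
  }
  stats::setNames(cb, g$ids)
}

# All simple directed cycles of length <= maxlen by brute force over node
# subsets and permutations, canonically rotated to the smallest ID.
oracle_cycles <- function(g, maxlen) {
  A <- adj_matrix_of(g)
  n <- nrow(A)
  ids <- g$ids
  perms_of <- function(x) {
    if (length(x) <= 1L) return(list(x))
    out <- list()
    for (i in seq_along(x))
      for (p in perms_of(x[-i])) out[[length(out) + 1L]] <- c(x[i], p)
    out
  }
  res <- list()
  for (k in 2:min(maxlen, n)) {
    subs <- utils::combn(seq_len(n), k)
    for (j in seq_len(ncol(subs))) {
      nodes <- subs[, j]
      first <- nodes[which.min(ids[nodes])]
      for (p in perms_of(setdiff(nodes, first))) {
        cyc <- c(first, p)
        edges_ok <- all(A[cbind(cyc, c(cyc[-1L], cyc[1L]))] > 0)
        if (edges_ok) res[[length(res) + 1L]] <- ids[cyc]
      }
    }
  }
  res
}

# All set partitions of n elements as membership vectors (restricted-growth
# enumeration). Bell(8) = 4140, so keep n <= 8.
all_partitions <- function(n) {
  out <- list()
  rec <- function(memb, i, k) {
    if (i > n) {
      out[[length(out) + 1L]] <<- memb
      return()
    }
    for (c in seq_len(k + 1L)) {
      memb[i] <- c
      rec(memb, i + 1L, max(k, c))
    }
  }
  rec(integer(n), 1L, 0L)
  out
}

# Fast undirected-projection modularity on precomputed undirected edges,
# for exhaustive partition sweeps.
make_q_evaluator <- function(g) {
  si <- match(g$edges$source, g$ids)
  ti <- match(g$edges$target, g$ids)
  a <- pmin(si, ti)
  b <- pmax(si, ti)
  keep <- !duplicated(paste(a, b))
  a <- a[keep]
  b <- b[keep]
  m <- length(a)
  n <- n_nodes(g)
  function(memb) {
    within <- memb[a] == memb[b]
    e_c <- tabulate(memb[a][within], nbins = n)
    deg <- tabulate(c(memb[a], memb[b]), nbins = n)
    sum(e_c / m - (deg / (2 * m))^2)
  }
}

oracle_best_modularity <- function(g) {
  qf <- make_q_evaluator(g)
  max(vapply(all_partitions(n_nodes(g)), qf, numeric(1)))
}
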