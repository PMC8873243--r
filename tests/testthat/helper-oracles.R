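# Brute-force graph oracles, written independently of the package's
# centrality code: exhaustive BFS distance matrices, shortest-path counting
# by dynamic programming over the BFS DAG, per-pair packet propagation for
# load, a dense eigendecomposition for eigenvector centrality, and a direct
# linear solve for PageRank. Intended for graphs of a few dozen nodes.

oracle_adjlist <- function(g) {
  n <- igraph::vcount(g)
  el <- igraph::as_edgelist(g, names = FALSE)
  adj <- rep(list(integer(0)), n)
  for (e in seq_len(nrow(el))) {
    a <- el[e, 1]; b <- el[e, 2]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  adj
}

oracle_distances <- function(adj) {
  n <- length(adj)
  D <- matrix(Inf, n, n)
  for (s in seq_len(n)) {
    D[s, s] <- 0
    frontier <- s
    d <- 0
    while (length(frontier)) {
      d <- d + 1
      nxt <- unique(unlist(adj[frontier]))
      nxt <- nxt[!is.finite(D[s, nxt])]
      D[s, nxt] <- d
      frontier <- nxt
    }
  }
  D
}

# number of shortest paths between all pairs, by DP in BFS order
oracle_sigma <- function(adj, D) {
  n <- length(adj)
  S <- matrix(0, n, n)
  for (s in seq_len(n)) {
    S[s, s] <- 1
    reach <- which(is.finite(D[s, ]))
    for (v in reach[order(D[s, reach])]) {
      if (v == s) next
      preds <- adj[[v]][D[s, adj[[v]]] == D[s, v] - 1]
      S[s, v] <- sum(S[s, preds])
    }
  }
  S
}

oracle_betweenness <- function(g) {
  adj <- oracle_adjlist(g)
  n <- length(adj)
  if (n < 3) return(numeric(n))
  D <- oracle_distances(adj)
  S <- oracle_sigma(adj, D)
  bc <- numeric(n)
  for (s in seq_len(n - 1)) for (t in (s + 1):n) {
    if (!is.finite(D[s, t])) next
    for (v in seq_len(n)) {
      if (v == s || v == t) next
      if (is.finite(D[s, v]) && is.finite(D[v, t]) &&
          D[s, v] + D[v, t] == D[s, t]) {
        bc[v] <- bc[v] + S[s, v] * S[v, t] / S[s, t]
      }
    }
  }
  bc / ((n - 1) * (n - 2) / 2)
}

# load: unit packet per ordered pair, equal split over predecessors at each
# hop toward the destination; transit mass summed per intermediate node
oracle_load <- function(g) {
  adj <- oracle_adjlist(g)
  n <- length(adj)
  if (n < 3) return(numeric(n))
  D <- oracle_distances(adj)
  load <- numeric(n)
  for (s in seq_len(n)) for (t in seq_len(n)) {
    if (s == t || !is.finite(D[s, t])) next
    onpath <- which(is.finite(D[s, ]) & is.finite(D[, t]) &
                      D[s, ] + D[, t] == D[s, t])
    frac <- numeric(n)
    frac[s] <- 1
    for (v in onpath[order(D[s, onpath])]) {
      if (v == t || frac[v] == 0) next
      succ <- adj[[v]][D[adj[[v]], t] == D[v, t] - 1]
      frac[succ] <- frac[succ] + frac[v] / length(succ)
    }
    mid <- setdiff(onpath, c(s, t))
    load[mid] <- load[mid] + frac[mid]
  }
  load / ((n - 1) * (n - 2))
}

oracle_closeness <- function(g) {
  adj <- oracle_adjlist(g)
  n <- length(adj)
  D <- oracle_distances(adj)
  vapply(seq_len(n), function(i) {
    di <- D[i, -i]
    di <- di[is.finite(di)]
    r <- length(di) + 1
    if (r == 1 || n == 1) return(0)
    ((r - 1) / (n - 1)) * ((r - 1) / sum(di))
  }, numeric(1))
}

oracle_clustering <- function(g) {
  adj <- oracle_adjlist(g)
  n <- length(adj)
  vapply(seq_len(n), function(v) {
    nb <- adj[[v]]
    k <- length(nb)
    if (k < 2) return(0)
    links <- 0
    for (i in seq_len(k - 1)) for (j in (i + 1):k) {
      if (nb[j] %in% adj[[nb[i]]]) links <- links + 1
    }
    2 * links / (k * (k - 1))
  }, numeric(1))
}

# dominant eigenvector of A via dense eigendecomposition; with degenerate top
# eigenvalues (e.g. several identical components), project the uniform start
# vector onto the top eigenspace, matching the power-iteration limit
oracle_eigenvector <- function(g) {
  n <- igraph::vcount(g)
  if (igraph::ecount(g) == 0) return(numeric(n))
  A <- as.matrix(igraph::as_adjacency_matrix(g))
  e <- eigen(A + diag(n), symmetric = TRUE)
  top <- which(e$values > max(e$values) - 1e-9)
  V <- e$vectors[, top, drop = FALSE]
  x <- V %*% crossprod(V, rep(1 / n, n))
  x <- as.numeric(x)
  x / sqrt(sum(x^2))
}

# PageRank by direct linear solve; degree-0 (dangling) nodes spread their
# mass uniformly over all nodes
oracle_pagerank <- function(g, damping = 0.85) {
  n <- igraph::vcount(g)
  A <- as.matrix(igraph::as_adjacency_matrix(g))
  deg <- rowSums(A)
  M <- matrix(0, n, n)
  for (u in seq_len(n)) {
    if (deg[u] > 0) M[, u] <- A[u, ] / deg[u] else M[, u] <- 1 / n
  }
  as.numeric(solve(diag(n) - damping * M, rep((1 - damping) / n, n)))
}

# seeded random test graph, possibly disconnected, with named vertices
random_test_graph <- function(n, p = 0.2, seed = 1) {
  set.seed(seed)
  g <- igraph::sample_gnp(n, p)
  igraph::V(g)$name <- sprintf("N%02d", seq_len(n))
  g
}

# exhaustive pair-counting auROC (ties count one half)
oracle_auroc <- function(scores, labels) {
  pos <- scores[labels]
  neg <- scores[!labels]
  tot <- 0
  for (x in pos) for (y in neg) {
    tot <- tot + (x > y) + 0.5 * (x == y)
  }
  tot / (length(pos) * length(neg))
}
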