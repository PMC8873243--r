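#' Centrality profile of every protein in a graph
#'
#' Computes the seven protein-level network features used throughout the
#' package: degree (raw neighbour count), betweenness and load centrality
#' (both normalised by (n-1)(n-2)/2), closeness with reachable-set scaling,
#' eigenvector centrality (power iteration, unit Euclidean norm), local
#' clustering coefficient, and PageRank (damping 0.85). All measures are
#' well defined on disconnected graphs; isolated nodes score 0 (PageRank
#' excepted, which always sums to 1 over nodes).
#'
#' @param graph an undirected igraph object with named vertices, or an
#'   `srn_network` (its graph is used).
#' @return a data.frame with one row per vertex (rownames = vertex names) and
#'   columns `degree`, `betweenness`, `closeness`, `eigenvector`,
#'   `clustering`, `load`, `pagerank`.
#' @export
network_centralities <- function(graph) {
  if (inherits(graph, "srn_network")) graph <- graph$graph
  n <- igraph::vcount(graph)
  nm <- igraph::V(graph)$name
  if (is.null(nm)) nm <- as.character(seq_len(n))

  deg <- as.numeric(igraph::degree(graph))
  btw <- if (n > 2) as.numeric(igraph::betweenness(graph, normalized = TRUE))
         else numeric(n)
  clo <- .closeness_wf(graph)
  eig <- .eigenvector_power(graph)
  clu <- igraph::transitivity(graph, type = "local", isolates = "zero")
  lod <- load_centrality(graph)
  pr <- as.numeric(igraph::page_rank(graph, damping = 0.85)$vector)

  out <- data.frame(degree = deg, betweenness = btw, closeness = clo,
                    eigenvector = eig, clustering = as.numeric(clu),
                    load = lod, pagerank = pr, row.names = nm)
  out
}

#' Centrality profile of one protein
#'
#' @param net an `srn_network` or igraph.
#' @param protein vertex name.
#' @return a one-row data.frame (see [network_centralities()]).
#' @export
protein_centralities <- function(net, protein) {
  g <- if (inherits(net, "srn_network")) net$graph else net
  if (!protein %in% igraph::V(g)$name) stop("unknown protein: ", protein)
  network_centralities(g)[protein, , drop = FALSE]
}

# closeness with reachable-set scaling: ((r-1)/(n-1)) * ((r-1)/sum d), where
# r counts the node's component (itself included); isolated nodes -> 0
.closeness_wf <- function(graph) {
  n <- igraph::vcount(graph)
  if (n == 0L) return(numeric(0))
  d <- igraph::distances(graph)
  vapply(seq_len(n), function(i) {
    di <- d[i, -i]
    di <- di[is.finite(di)]
    r <- length(di) + 1L
    if (r == 1L || n == 1L) return(0)
    ((r - 1) / (n - 1)) * ((r - 1) / sum(di))
  }, numeric(1))
}

# eigenvector centrality by power iteration on A + I (the shift damps
# period-2 oscillation on bipartite components); unit L2 norm, uniform start.
# The stopping tolerance is well below the 1e-6 accuracy the downstream
# features are specified to, since the iterate-difference criterion
# overestimates convergence near a small spectral gap.
.eigenvector_power <- function(graph, tol = 1e-10, max_iter = 10000L) {
  n <- igraph::vcount(graph)
  if (n == 0L) return(numeric(0))
  if (igraph::ecount(graph) == 0L) return(numeric(n))
  A <- igraph::as_adjacency_matrix(graph, sparse = TRUE)
  x <- rep(1 / n, n)
  for (it in seq_len(max_iter)) {
    x_new <- x + as.numeric(A %*% x)
    nrm <- sqrt(sum(x_new^2))
    if (nrm == 0) return(numeric(n))
    x_new <- x_new / nrm
    if (sum(abs(x_new - x)) < n * tol) return(x_new)
    x <- x_new
  }
  warning("eigenvector power iteration did not converge in ",
          max_iter, " iterations")
  x
}

#' Load centrality
#'
#' Traffic-model variant of betweenness: a unit packet travels between every
#' ordered node pair along shortest paths, splitting equally over the
#' available predecessors at each hop; a node's load is its total transit
#' mass (endpoints excluded), normalised by (n-1)(n-2)/2 per unordered pair.
#' Equals normalised betweenness on graphs whose shortest paths are unique
#' (e.g. trees).
#'
#' @param graph an undirected igraph object or `srn_network`.
#' @return numeric vector of normalised loads, one per vertex.
#' @export
load_centrality <- function(graph) {
  if (inherits(graph, "srn_network")) graph <- graph$graph
  adj <- igraph::as_adj_list(graph)
  adj <- lapply(adj, function(v) as.integer(v) - 1L)
  as.numeric(load_centrality_cpp(adj))
}
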