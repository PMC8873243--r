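#' Canonical feature column order
#'
#' @param set `"prot"` (7 protein-level), `"res"` (9 residue-level) or
#'   `"net"` (all 16, protein-level first).
#' @return character vector of feature column names.
#' @export
srn_feature_columns <- function(set = c("net", "prot", "res")) {
  set <- match.arg(set)
  prot <- c("degree", "betweenness", "closeness", "eigenvector",
            "clustering", "load", "pagerank")
  res <- c("location_3d", "degree_change", "betweenness_change",
           "closeness_change", "eigenvector_change", "clustering_change",
           "load_change", "pagerank_change", "percent_degree_change")
  switch(set, prot = prot, res = res, net = c(prot, res))
}

#' Edges affected by a missense mutation
#'
#' Maps a mutated residue to the interaction edges it can disrupt: a core
#' mutation destabilises the protein and affects every interaction of the
#' protein; an interface mutation affects exactly the interactions whose
#' interface (on this protein) contains the position; a surface non-interface
#' mutation affects none.
#'
#' @param net an `srn_network`.
#' @param protein,position the mutated residue.
#' @return character vector of partner proteins whose edge with `protein` is
#'   affected (possibly empty), or `NULL` when the residue cannot be scored
#'   (protein absent from the network, position unannotated, or location
#'   ambiguous).
#' @export
affected_edges <- function(net, protein, position) {
  g <- net$graph
  if (!protein %in% igraph::V(g)$name) return(NULL)
  loc <- residue_location(net, protein, position)
  if (is.na(loc) || loc == "unresolved") return(NULL)
  if (loc == "surface") return(character(0))
  partners <- igraph::V(g)$name[as.integer(
    igraph::neighbors(g, protein))]
  if (loc == "core") return(partners)
  # interface: keep partners whose interface set on this protein holds position
  hit <- vapply(partners, function(p) {
    sides <- interface_residues(net, protein, p)
    !is.null(sides[[protein]]) && position %in% sides[[protein]]
  }, logical(1L))
  partners[hit]
}

# perturbed centrality profile of one protein after deleting its edges to
# `partners`; global measures (eigenvector, pagerank, load) are recomputed on
# the whole perturbed graph, path measures only from the protein
.perturbed_row <- function(graph, protein, partners) {
  n <- igraph::vcount(graph)
  if (length(partners)) {
    eids <- igraph::get_edge_ids(graph, rbind(rep(protein, length(partners)),
                                              partners))
    g2 <- igraph::delete_edges(graph, eids[eids > 0])
  } else {
    g2 <- graph
  }
  deg <- as.numeric(igraph::degree(g2, v = protein))
  btw <- if (n > 2)
    as.numeric(igraph::betweenness(g2, v = protein, normalized = TRUE))
  else 0
  d <- igraph::distances(g2, v = protein)[1L, ]
  d <- d[is.finite(d)]
  r <- length(d)                         # includes the protein itself (d=0)
  clo <- if (r <= 1L || n <= 1L) 0 else ((r - 1) / (n - 1)) * ((r - 1) / sum(d))
  eig <- .eigenvector_power(g2)[match(protein, igraph::V(g2)$name)]
  clu <- igraph::transitivity(g2, type = "local", vids = protein,
                              isolates = "zero")
  lod <- load_centrality(g2)[match(protein, igraph::V(g2)$name)]
  pr <- as.numeric(igraph::page_rank(g2, damping = 0.85)$vector[protein])
  c(degree = deg, betweenness = btw, closeness = clo, eigenvector = eig,
    clustering = as.numeric(clu), load = lod, pagerank = pr)
}

#' Residue-level network-perturbation features of one mutation
#'
#' Computes the protein's centrality profile before and after removing the
#' edges the mutation maps to (nodes are never removed, keeping
#' normalisations comparable), and returns the nine residue-level features:
#' the 3D location code (core 0, surface 1, interface 2), the seven
#' original-minus-perturbed centrality changes (positive = centrality loss),
#' and the percent degree change.
#'
#' @param net an `srn_network`.
#' @param protein,position the mutated residue.
#' @param base optional precomputed [network_centralities()] table for `net`.
#' @return one-row data.frame with the columns of
#'   `srn_feature_columns("res")`, or `NULL` if the mutation is unscoreable.
#' @export
perturb_and_diff <- function(net, protein, position, base = NULL) {
  partners <- affected_edges(net, protein, position)
  if (is.null(partners)) return(NULL)
  loc <- residue_location(net, protein, position)
  if (is.null(base)) base <- network_centralities(net$graph)
  orig <- unlist(base[protein, ])
  if (length(partners) == 0L) {
    pert <- orig                          # no edges removed: identical graph
  } else {
    pert <- .perturbed_row(net$graph, protein, partners)
  }
  delta <- orig - pert
  deg0 <- orig[["degree"]]
  pdc <- if (deg0 > 0) 100 * delta[["degree"]] / deg0 else 0
  out <- data.frame(location_3d = unname(.location_codes[loc]),
                    degree_change = delta[["degree"]],
                    betweenness_change = delta[["betweenness"]],
                    closeness_change = delta[["closeness"]],
                    eigenvector_change = delta[["eigenvector"]],
                    clustering_change = delta[["clustering"]],
                    load_change = delta[["load"]],
                    pagerank_change = delta[["pagerank"]],
                    percent_degree_change = pdc)
  rownames(out) <- NULL
  out
}

#' Assemble classifier feature vectors for a set of mutations
#'
#' Builds one row per scoreable mutation: the 7 protein-level centralities of
#' the mutated protein, the 9 residue-level perturbation features of the
#' mutated position and, when an amino-acid feature table is supplied, its 83
#' substitution-level descriptors. Mutations on proteins outside the network
#' or at unannotated/ambiguous positions are skipped and reported through the
#' `coverage` attribute (scoreable / total).
#'
#' Perturbed profiles are cached per distinct (protein, affected-edge-set),
#' so recurrent mutations and shared interfaces cost one recomputation.
#'
#' @param net an `srn_network`.
#' @param mutations data.frame with columns `protein`, `position` and
#'   optionally `ref_aa`, `alt_aa`, `gene` (defaults to `protein`), `label`.
#' @param aa_features optional table keyed by `protein`, `position`, `alt_aa`
#'   with numeric amino-acid feature columns (see [read_aa_features()]).
#' @param mode `"network"` keeps all scoreable mutations with the 16 network
#'   features only; `"full"` additionally requires and appends the amino-acid
#'   block, dropping mutations without one; `"auto"` picks `"full"` when
#'   `aa_features` is supplied.
#' @return a data.frame with key columns (`protein`, `position`, `ref_aa`,
#'   `alt_aa`, `gene`, `label`) followed by the features in
#'   [srn_feature_columns()] order; attribute `coverage` holds the scoreable
#'   fraction (NaN for an empty input).
#' @export
featurize <- function(net, mutations, aa_features = NULL,
                      mode = c("auto", "network", "full")) {
  mode <- match.arg(mode)
  if (mode == "auto") mode <- if (is.null(aa_features)) "network" else "full"
  if (mode == "full" && is.null(aa_features)) {
    stop("mode 'full' requires an amino-acid feature table")
  }
  mutations <- as.data.frame(mutations)
  n_total <- nrow(mutations)
  if (!"gene" %in% names(mutations)) mutations$gene <- mutations$protein
  if (!"label" %in% names(mutations)) mutations$label <- "unknown"
  if (!"ref_aa" %in% names(mutations)) mutations$ref_aa <- NA_character_
  if (!"alt_aa" %in% names(mutations)) mutations$alt_aa <- NA_character_

  if (n_total == 0L) {
    out <- mutations
    attr(out, "coverage") <- NaN
    return(out)
  }

  base <- network_centralities(net$graph)
  cache <- new.env(parent = emptyenv())
  rows <- vector("list", n_total)
  for (i in seq_len(n_total)) {
    p <- as.character(mutations$protein[i])
    pos <- as.integer(mutations$position[i])
    partners <- affected_edges(net, p, pos)
    if (is.null(partners)) next
    loc <- residue_location(net, p, pos)
    ck <- paste(p, paste(sort(partners), collapse = ","), sep = "::")
    if (!exists(ck, envir = cache)) {
      pert <- if (length(partners) == 0L) unlist(base[p, ])
              else .perturbed_row(net$graph, p, partners)
      assign(ck, pert, envir = cache)
    }
    pert <- get(ck, envir = cache)
    orig <- unlist(base[p, ])
    delta <- orig - pert
    deg0 <- orig[["degree"]]
    rows[[i]] <- c(orig, location_3d = unname(.location_codes[loc]),
                   degree_change = delta[["degree"]],
                   betweenness_change = delta[["betweenness"]],
                   closeness_change = delta[["closeness"]],
                   eigenvector_change = delta[["eigenvector"]],
                   clustering_change = delta[["clustering"]],
                   load_change = delta[["load"]],
                   pagerank_change = delta[["pagerank"]],
                   percent_degree_change =
                     if (deg0 > 0) 100 * delta[["degree"]] / deg0 else 0)
  }
  keep <- !vapply(rows, is.null, logical(1L))
  feats <- do.call(rbind, rows[keep])
  keys <- mutations[keep, c("protein", "position", "ref_aa", "alt_aa",
                            "gene", "label"), drop = FALSE]
  out <- cbind(keys, as.data.frame(feats))
  out <- out[, c(names(keys), srn_feature_columns("net"))]
  rownames(out) <- NULL

  if (mode == "full") {
    aa <- as.data.frame(aa_features)
    keycols <- c("protein", "position", "alt_aa")
    miss <- setdiff(keycols, names(aa))
    if (length(miss)) stop("aa_features is missing key column(s): ",
                           paste(miss, collapse = ", "))
    out <- merge(out, aa, by = keycols, sort = FALSE)
    out <- out[, c(names(keys), srn_feature_columns("net"),
                   setdiff(names(aa), keycols))]
  }
  attr(out, "coverage") <- sum(keep) / n_total
  attr(out, "aa_columns") <- if (mode == "full")
    setdiff(names(aa_features), c("protein", "position", "alt_aa")) else character(0)
  out
}
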