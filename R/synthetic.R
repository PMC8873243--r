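#' Planted label model for synthetic mutations
#'
#' Logistic model generating mutation labels from network context:
#' `P(positive) = logistic(beta0 + beta_deg * z(degree) + beta_iface *
#' I(interface) + beta_core * I(core))`, with degree standardised over the
#' network's proteins. Positive coefficients plant the empirically observed
#' signal: disease mutations favour central proteins and interface/core
#' residues.
#'
#' @param beta0 intercept (controls the base positive rate).
#' @param beta_deg coefficient on standardised protein degree.
#' @param beta_iface coefficient on the interface indicator.
#' @param beta_core coefficient on the core indicator.
#' @param seed integer seed used when drawing labels.
#' @return list of class `srn_planted_model`.
#' @export
planted_model <- function(beta0 = -2, beta_deg = 1.5, beta_iface = 2,
                          beta_core = 1, seed = 1L) {
  structure(list(beta0 = beta0, beta_deg = beta_deg, beta_iface = beta_iface,
                 beta_core = beta_core, seed = as.integer(seed)),
            class = "srn_planted_model")
}

# draw m distinct targets uniformly from the multiset `pool`
.distinct_targets <- function(pool, m) {
  targets <- integer(0)
  while (length(targets) < m) {
    cand <- pool[sample.int(length(pool), 1L)]
    if (!cand %in% targets) targets <- c(targets, cand)
  }
  targets
}

#' Generate a synthetic structurally resolved interactome
#'
#' Grows a scale-free graph by preferential attachment (starting from
#' `attachment` isolated seed nodes, each new node wires to `attachment`
#' distinct existing nodes chosen proportionally to degree, giving exactly
#' `(n_proteins - attachment) * attachment` edges), then dresses it with
#' structural annotations: each edge endpoint receives `iface_per_edge`
#' distinct interface positions (disjoint across a protein's edges unless
#' `overlap_interfaces`), and every remaining position gets a per-chain RSA
#' value drawn so that roughly 25% of residues are core, 60% surface and 15%
#' ambiguous.
#'
#' @param n_proteins number of proteins.
#' @param attachment edges added per new node (scale-free exponent knob).
#' @param protein_length residues per protein; must accommodate
#'   `degree * iface_per_edge` interface positions on the hubs.
#' @param iface_per_edge interface residues per edge endpoint (>= 5 so every
#'   edge survives the interface-coverage filter).
#' @param overlap_interfaces allow one position to serve several interfaces
#'   of the same protein.
#' @param seed integer seed.
#' @return list with `network` (`srn_network`), `records` (interface record
#'   table) and `rsa_table`.
#' @export
generate_interactome <- function(n_proteins = 300L, attachment = 2L,
                                 protein_length = 400L, iface_per_edge = 5L,
                                 overlap_interfaces = FALSE, seed = 1L) {
  if (n_proteins <= attachment || attachment < 1L) {
    stop("need n_proteins > attachment >= 1")
  }
  if (iface_per_edge < 5L) stop("iface_per_edge must be >= 5")
  set.seed(seed)
  m <- attachment
  # preferential attachment over a degree-weighted multiset of node ids
  pool <- integer(0)
  edges <- matrix(0L, nrow = (n_proteins - m) * m, ncol = 2L)
  targets <- seq_len(m)
  row <- 1L
  for (v in (m + 1L):n_proteins) {
    for (t in targets) {
      edges[row, ] <- c(v, t)
      row <- row + 1L
    }
    pool <- c(pool, targets, rep.int(v, m))
    if (v < n_proteins) targets <- .distinct_targets(pool, m)
  }
  ids <- sprintf("P%04d", seq_len(n_proteins))

  # interface positions per protein: consume a shuffled position pool
  pos_pool <- lapply(seq_len(n_proteins),
                     function(i) sample.int(protein_length))
  next_free <- rep(1L, n_proteins)
  take_positions <- function(i) {
    used <- if (next_free[i] > 1L) pos_pool[[i]][seq_len(next_free[i] - 1L)]
            else integer(0)
    if (overlap_interfaces && length(used) >= iface_per_edge && runif(1) < 0.3) {
      return(sort(sample(used, iface_per_edge)))
    }
    n_free <- protein_length - next_free[i] + 1L
    if (n_free >= iface_per_edge) {
      out <- pos_pool[[i]][next_free[i]:(next_free[i] + iface_per_edge - 1L)]
      next_free[i] <<- next_free[i] + iface_per_edge
      return(sort(out))
    }
    # hub proteins can exhaust fresh positions; reuse earlier interface
    # residues (real hubs likewise share interface residues among partners)
    if (length(used) + n_free < iface_per_edge) {
      stop("protein_length too small to host ", iface_per_edge,
           " interface residues on node ", i)
    }
    fresh <- if (n_free > 0L) pos_pool[[i]][next_free[i]:protein_length]
             else integer(0)
    next_free[i] <<- protein_length + 1L
    sort(c(fresh, sample(used, iface_per_edge - length(fresh))))
  }
  rec <- vector("list", nrow(edges) * 2L)
  for (e in seq_len(nrow(edges))) {
    a <- edges[e, 1L]; b <- edges[e, 2L]
    pa <- take_positions(a)
    pb <- take_positions(b)
    rec[[2L * e - 1L]] <- data.table(protein_a = ids[a], protein_b = ids[b],
                                     residue_a = pa)
    rec[[2L * e]] <- data.table(protein_a = ids[b], protein_b = ids[a],
                                residue_a = pb)
  }
  records <- rbindlist(rec)

  # RSA for all non-interface positions, one chain per protein
  rsa_rows <- lapply(seq_len(n_proteins), function(i) {
    used <- if (next_free[i] > 1L) pos_pool[[i]][seq_len(next_free[i] - 1L)]
            else integer(0)
    free <- setdiff(seq_len(protein_length), used)
    cls <- sample(c("core", "surface", "unresolved"), length(free),
                  replace = TRUE, prob = c(0.25, 0.60, 0.15))
    rsa <- numeric(length(free))
    rsa[cls == "core"] <- runif(sum(cls == "core"), 0, 4.999)
    rsa[cls == "surface"] <- runif(sum(cls == "surface"), 15.001, 100)
    rsa[cls == "unresolved"] <- runif(sum(cls == "unresolved"), 5, 15)
    data.table(protein = ids[i], chain = "A", position = free, rsa = rsa)
  })
  rsa_table <- rbindlist(rsa_rows)

  net <- suppressWarnings(
    build_network(filter_interactions(records), rsa_table))
  list(network = net, records = records, rsa_table = rsa_table)
}

#' Generate labelled synthetic mutations
#'
#' Samples mutated residues uniformly over the network's unambiguously
#' annotated positions (core, surface or interface) and draws each label from
#' the planted logistic model.
#'
#' @param net an `srn_network`.
#' @param n_mutations number of mutations.
#' @param model an [planted_model()]; its `seed` drives the sampling.
#' @return data.frame of mutations with `protein`, `position`, `ref_aa`,
#'   `alt_aa`, `gene`, `label`.
#' @export
generate_mutations <- function(net, n_mutations = 2000L,
                               model = planted_model()) {
  prots <- ls(net$location_map)
  cand <- rbindlist(lapply(prots, function(p) {
    v <- get(p, envir = net$location_map)
    v <- v[v != "unresolved"]
    if (!length(v)) return(NULL)
    data.table(protein = p, position = as.integer(names(v)),
               location = unname(v))
  }))
  cand <- cand[protein %in% igraph::V(net$graph)$name]
  if (nrow(cand) == 0L) stop("network has no annotated residues")
  set.seed(model$seed)
  pick <- sample.int(nrow(cand), n_mutations, replace = TRUE)
  muts <- cand[pick]

  deg <- igraph::degree(net$graph)
  sdd <- sd(deg)
  zdeg <- if (sdd > 0) (deg - mean(deg)) / sdd else deg * 0
  eta <- model$beta0 +
    model$beta_deg * zdeg[muts$protein] +
    model$beta_iface * (muts$location == "interface") +
    model$beta_core * (muts$location == "core")
  lab <- rbinom(n_mutations, 1L, plogis(eta))

  aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]]
  ref <- sample(aas, n_mutations, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(aas, r), 1L), character(1L))
  data.frame(protein = muts$protein, position = muts$position,
             ref_aa = ref, alt_aa = alt, gene = muts$protein,
             label = ifelse(lab == 1L, "positive", "negative"),
             stringsAsFactors = FALSE)
}

#' Generate a synthetic amino-acid substitution feature table
#'
#' Stands in for substitution-level descriptor databases: `n_informative`
#' columns are drawn as `Normal(effect * I(positive), 1)`, the rest as pure
#' `Normal(0, 1)` noise, keyed identically to the mutation list.
#'
#' @param mutations mutation data.frame (needs `protein`, `position`,
#'   `alt_aa`, `label`).
#' @param n_features number of feature columns (default 83).
#' @param n_informative how many columns carry label signal.
#' @param effect mean shift of informative columns for positives.
#' @param seed integer seed.
#' @return data.frame: key columns plus `aa_01` ... feature columns.
#' @export
generate_aa_features <- function(mutations, n_features = 83L,
                                 n_informative = 0L, effect = 0,
                                 seed = 1L) {
  if (n_informative > n_features) stop("n_informative exceeds n_features")
  set.seed(seed)
  n <- nrow(mutations)
  lab <- as.numeric(mutations$label == "positive")
  cols <- lapply(seq_len(n_features), function(j) {
    if (j <= n_informative) rnorm(n, mean = effect * lab) else rnorm(n)
  })
  names(cols) <- sprintf("aa_%02d", seq_len(n_features))
  cbind(mutations[, c("protein", "position", "alt_aa")],
        as.data.frame(cols))
}

#' Generate a complete synthetic study bundle
#'
#' Convenience wrapper producing every input the analysis pipeline consumes:
#' a structurally resolved network, its RSA table, labelled mutations from a
#' planted model, and an amino-acid feature table.
#'
#' @param n_proteins,attachment,protein_length,iface_per_edge,seed see
#'   [generate_interactome()].
#' @param n_mutations see [generate_mutations()].
#' @param model a [planted_model()] (its seed is derived from `seed` when
#'   left `NULL`).
#' @param n_informative,effect see [generate_aa_features()].
#' @return list of class `srn_bundle`: `network`, `records`, `rsa_table`,
#'   `mutations`, `aa_features`, `truth`.
#' @export
synthetic_bundle <- function(n_proteins = 300L, attachment = 2L,
                             protein_length = 400L, iface_per_edge = 5L,
                             n_mutations = 2000L, model = NULL,
                             n_informative = 10L, effect = 1,
                             seed = 1L) {
  if (is.null(model)) model <- planted_model(seed = seed + 1L)
  inter <- generate_interactome(n_proteins, attachment, protein_length,
                                iface_per_edge, seed = seed)
  muts <- generate_mutations(inter$network, n_mutations, model)
  aa <- generate_aa_features(muts, n_informative = n_informative,
                             effect = effect, seed = seed + 2L)
  structure(list(network = inter$network, records = inter$records,
                 rsa_table = inter$rsa_table, mutations = muts,
                 aa_features = aa, truth = model),
            class = "srn_bundle")
}

#' Write a synthetic bundle as the four standard input files
#'
#' @param bundle an `srn_bundle`.
#' @param dir output directory (created if needed); writes
#'   `interface_residues.tsv`, `rsa.tsv`, `mutations.tsv`,
#'   `aa_features.tsv`.
#' @return invisibly, the four paths.
#' @export
write_bundle <- function(bundle, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, c("interface_residues.tsv", "rsa.tsv",
                            "mutations.tsv", "aa_features.tsv"))
  write_interface_table(bundle$records, paths[1L])
  fwrite(bundle$rsa_table, paths[2L], sep = "\t")
  fwrite(bundle$mutations, paths[3L], sep = "\t")
  fwrite(bundle$aa_features, paths[4L], sep = "\t")
  invisible(paths)
}
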