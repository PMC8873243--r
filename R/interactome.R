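#' Parse an interface-residue table
#'
#' Reads the three-column interface-residue dialect in which each row names
#' one residue at a physical interaction interface: the first two columns are
#' the UniProt accessions of the interacting pair and the third is the 1-based
#' position of an interface residue on the *first* protein. Residues of the
#' partner protein appear on rows with the protein order reversed.
#'
#' @param path path to a TSV (or XLSX) file with a header row containing at
#'   least the columns `Uniprot1`, `Uniprot2`, `Uniprot1_residue`
#'   (case-insensitive; extra columns are ignored).
#' @param dialect `"auto"` (by file extension), `"tsv"` or `"xlsx"`. XLSX
#'   support requires the readxl package.
#' @return a `data.table` with columns `protein_a`, `protein_b`, `residue_a`
#'   (integer), deduplicated on the full triple with the original row order
#'   otherwise preserved.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("Uniprot1\tUniprot2\tUniprot1_residue",
#'              "P1\tP2\t10", "P1\tP2\t12", "P2\tP1\t5"), tf)
#' parse_interface_table(tf)
#' @export
parse_interface_table <- function(path, dialect = c("auto", "tsv", "xlsx")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  if (dialect == "auto") {
    dialect <- if (grepl("\\.xlsx?$", path, ignore.case = TRUE)) "xlsx" else "tsv"
  }
  if (dialect == "xlsx") {
    if (!requireNamespace("readxl", quietly = TRUE)) {
      stop("reading xlsx requires the 'readxl' package")
    }
    tab <- as.data.table(readxl::read_excel(path))
  } else {
    tab <- fread(path, sep = "\t", header = TRUE, colClasses = "character")
  }
  want <- c("uniprot1", "uniprot2", "uniprot1_residue")
  idx <- match(want, tolower(names(tab)))
  if (anyNA(idx)) {
    stop("interface table is missing required column(s): ",
         paste(c("Uniprot1", "Uniprot2", "Uniprot1_residue")[is.na(idx)],
               collapse = ", "))
  }
  out <- tab[, idx, with = FALSE]
  setnames(out, c("protein_a", "protein_b", "residue_a"))
  res <- suppressWarnings(as.numeric(out$residue_a))
  bad <- which(is.na(res) | res != floor(res) | res < 1)
  if (length(bad)) {
    stop("non-integer or out-of-range residue position in row(s): ",
         paste(head(bad, 5L), collapse = ", "))
  }
  out[, residue_a := as.integer(res)]
  out[, protein_a := as.character(protein_a)]
  out[, protein_b := as.character(protein_b)]
  unique(out, by = c("protein_a", "protein_b", "residue_a"))
}

#' Read a per-residue relative solvent accessibility table
#'
#' @param path TSV with header `protein  chain  position  rsa`; one row per
#'   residue per structure chain, RSA in percent.
#' @return a `data.table` with those four columns (`position` integer,
#'   `rsa` numeric).
#' @export
read_rsa_table <- function(path) {
  tab <- fread(path, sep = "\t", header = TRUE)
  need <- c("protein", "chain", "position", "rsa")
  miss <- setdiff(need, tolower(names(tab)))
  if (length(miss)) stop("RSA table is missing column(s): ",
                         paste(miss, collapse = ", "))
  setnames(tab, tolower(names(tab)))
  tab <- tab[, need, with = FALSE]
  tab[, position := as.integer(position)]
  tab[, rsa := as.numeric(rsa)]
  if (any(tab$rsa < 0, na.rm = TRUE)) stop("negative RSA values in table")
  tab[]
}

#' Classify a residue by relative solvent accessibility
#'
#' Residues with RSA below 5% are buried (`core`), above 15% exposed
#' (`surface`); the ambiguous band in between is `unresolved` and excluded
#' from downstream analysis.
#'
#' @param rsa numeric vector of RSA percentages (>= 0).
#' @param core_max,surface_min the two thresholds, in percent.
#' @return character vector of `"core"`, `"surface"`, `"unresolved"`.
#' @export
assign_rsa_location <- function(rsa, core_max = 5, surface_min = 15) {
  if (any(is.na(rsa)) || any(rsa < 0)) stop("RSA must be non-negative")
  ifelse(rsa < core_max, "core",
         ifelse(rsa > surface_min, "surface", "unresolved"))
}

#' Consensus location over multiple structure chains
#'
#' When several chains or structures cover the same residue, the final label
#' is the strict majority among the unambiguous (`core`/`surface`) votes;
#' ties, or all votes ambiguous, give `unresolved`.
#'
#' @param labels character vector of per-chain location labels.
#' @return a single location label.
#' @export
consensus_location <- function(labels) {
  if (length(labels) == 0L) stop("empty label list")
  labels <- labels[labels != "unresolved"]
  if (length(labels) == 0L) return("unresolved")
  n_core <- sum(labels == "core")
  n_surf <- sum(labels == "surface")
  if (n_core > n_surf) "core" else if (n_surf > n_core) "surface" else "unresolved"
}

# canonical undirected edge key: ids sorted within the pair
.edge_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "|")
}

#' Drop interactions with poorly covered interfaces
#'
#' An interaction is kept only if *both* partners contribute at least
#' `min_residues` distinct interface positions; all rows of dropped
#' interactions are removed. Distinct positions (not rows) are counted.
#'
#' @param records interface records as returned by [parse_interface_table()].
#' @param min_residues minimum interface size per partner (default 5).
#' @return the filtered records, original order preserved.
#' @export
filter_interactions <- function(records, min_residues = 5L) {
  records <- as.data.table(records)
  if (nrow(records) == 0L) return(records)
  ekey <- .edge_key(records$protein_a, records$protein_b)
  counts <- data.table(ekey = ekey, protein = records$protein_a,
                       residue = records$residue_a)
  per_side <- counts[, .(n = uniqueN(residue)), by = .(ekey, protein)]
  info <- per_side[, .(nsides = .N, minn = min(n)), by = ekey]
  is_self <- vapply(strsplit(info$ekey, "|", fixed = TRUE),
                    function(p) p[1L] == p[2L], logical(1L))
  # both partners must contribute >= min_residues positions; an interaction
  # with rows for only one side cannot satisfy that (self-loops need one side)
  keep_keys <- info$ekey[info$minn >= min_residues &
                           info$nsides == ifelse(is_self, 1L, 2L)]
  records[which(ekey %in% keep_keys)]
}

#' Build a structurally resolved interaction network
#'
#' Combines filtered interface records with per-chain RSA annotations into an
#' undirected protein graph in which every edge carries, for each endpoint,
#' the set of interface positions mediating the interaction, and every
#' annotated residue has a single 3D location label. Interface membership
#' takes precedence over the RSA-derived core/surface call; remaining residues
#' get the consensus of their per-chain RSA labels.
#'
#' @param records interface records that already pass [filter_interactions()].
#' @param rsa RSA table as returned by [read_rsa_table()] (may be `NULL` for
#'   interface-only networks).
#' @param include_self keep homodimeric self-interactions as self-loops
#'   (default `FALSE`: dropped with a warning, since centrality semantics of
#'   self-loops are not well defined).
#' @return an object of class `srn_network` with components `graph` (igraph),
#'   `interface_map` (per edge key, per endpoint, sorted integer positions)
#'   and `location_map` (per protein, named character vector position ->
#'   location).
#' @export
build_network <- function(records, rsa = NULL, include_self = FALSE) {
  records <- data.table::copy(as.data.table(records))
  if (nrow(records) == 0L) stop("no interface records; cannot build a network")
  self <- records$protein_a == records$protein_b
  if (any(self) && !include_self) {
    warning(sum(self), " self-interaction record(s) dropped")
    records <- records[!self]
  }
  if (nrow(records) == 0L) stop("no inter-protein records left")

  records[, edge_key := .edge_key(protein_a, protein_b)]
  pairs <- unique(records[, .(edge_key)])
  ends <- do.call(rbind, strsplit(pairs$edge_key, "|", fixed = TRUE))
  nodes <- sort(unique(c(ends[, 1L], ends[, 2L])))
  graph <- igraph::graph_from_data_frame(
    data.frame(from = ends[, 1L], to = ends[, 2L], stringsAsFactors = FALSE),
    directed = FALSE, vertices = nodes)

  # interface map: edge key -> endpoint protein -> sorted positions
  by_side <- records[, .(pos = list(sort(unique(residue_a)))),
                     by = .(edge_key, protein_a)]
  interface_map <- new.env(parent = emptyenv())
  for (k in unique(by_side$edge_key)) assign(k, list(), envir = interface_map)
  for (i in seq_len(nrow(by_side))) {
    k <- by_side$edge_key[i]
    cur <- get(k, envir = interface_map)
    cur[[by_side$protein_a[i]]] <- by_side$pos[[i]]
    assign(k, cur, envir = interface_map)
  }

  # residue locations: consensus RSA labels, then interface override
  location_map <- new.env(parent = emptyenv())
  if (!is.null(rsa) && nrow(rsa)) {
    rsa <- as.data.table(rsa)
    rsa[, location := assign_rsa_location(rsa)]
    cons <- rsa[, .(location = consensus_location(location)),
                by = .(protein, position)]
    for (p in unique(cons$protein)) {
      sub <- cons[protein == p]
      v <- sub$location
      names(v) <- as.character(sub$position)
      assign(p, v, envir = location_map)
    }
  }
  for (k in ls(interface_map)) {
    sides <- get(k, envir = interface_map)
    for (p in names(sides)) {
      v <- if (exists(p, envir = location_map)) get(p, envir = location_map)
           else character()
      v[as.character(sides[[p]])] <- "interface"
      assign(p, v, envir = location_map)
    }
  }

  structure(list(graph = graph, interface_map = interface_map,
                 location_map = location_map),
            class = "srn_network")
}

#' @export
print.srn_network <- function(x, ...) {
  cat("Structurally resolved PPI network\n")
  cat("  proteins:    ", igraph::vcount(x$graph), "\n")
  cat("  interactions:", igraph::ecount(x$graph), "\n")
  n_iface <- sum(vapply(ls(x$interface_map), function(k) {
    sum(lengths(get(k, envir = x$interface_map)))
  }, numeric(1)))
  cat("  interface residues:", n_iface, "\n")
  invisible(x)
}

#' Interface positions of an interaction
#'
#' @param net an `srn_network`.
#' @param a,b the two endpoint proteins (order irrelevant).
#' @return named list with one sorted integer vector per endpoint, or `NULL`
#'   if the edge is absent.
#' @export
interface_residues <- function(net, a, b) {
  k <- .edge_key(a, b)
  if (!exists(k, envir = net$interface_map)) return(NULL)
  get(k, envir = net$interface_map)
}

#' 3D location of residues
#'
#' @param net an `srn_network`.
#' @param protein protein identifier.
#' @param position optional integer position(s); if omitted, the full named
#'   location vector for the protein is returned.
#' @return location label(s); `NA` for unannotated positions.
#' @export
residue_location <- function(net, protein, position = NULL) {
  if (!exists(protein, envir = net$location_map)) {
    return(if (is.null(position)) NULL else rep(NA_character_, length(position)))
  }
  v <- get(protein, envir = net$location_map)
  if (is.null(position)) return(v)
  unname(v[as.character(position)])
}

#' Export a network as plain-text tables
#'
#' Writes an edge-list TSV (`protein_a  protein_b  n_iface_a  n_iface_b`) and
#' a residue-annotation TSV (`protein  position  location`).
#'
#' @param net an `srn_network`.
#' @param edges_path,residues_path output file paths.
#' @return invisibly, the two paths.
#' @export
write_network <- function(net, edges_path, residues_path) {
  keys <- sort(ls(net$interface_map))
  el <- do.call(rbind, lapply(keys, function(k) {
    ends <- strsplit(k, "|", fixed = TRUE)[[1L]]
    sides <- get(k, envir = net$interface_map)
    data.frame(protein_a = ends[1L], protein_b = ends[2L],
               n_iface_a = length(sides[[ends[1L]]]),
               n_iface_b = length(sides[[ends[2L]]]))
  }))
  fwrite(el, edges_path, sep = "\t")
  prots <- sort(ls(net$location_map))
  res <- rbindlist(lapply(prots, function(p) {
    v <- get(p, envir = net$location_map)
    data.table(protein = p, position = as.integer(names(v)), location = unname(v))
  }))
  setorder(res, protein, position)
  fwrite(res, residues_path, sep = "\t")
  invisible(c(edges_path, residues_path))
}

#' Serialise interface records back to the three-column dialect
#'
#' @param records interface records.
#' @param path output TSV path.
#' @export
write_interface_table <- function(records, path) {
  out <- data.table(Uniprot1 = records$protein_a,
                    Uniprot2 = records$protein_b,
                    Uniprot1_residue = records$residue_a)
  fwrite(out, path, sep = "\t")
  invisible(path)
}
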