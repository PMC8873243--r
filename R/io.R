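#' Read a mutation table
#'
#' Expects a TSV with header columns `protein` and `position`, and optionally
#' `gene`, `ref_aa`, `alt_aa`, `label`. Labels are normalised to
#' `"positive"` / `"negative"` / `"unknown"` (driver/pathogenic count as
#' positive, passenger/neutral/benign as negative).
#'
#' @param path TSV path.
#' @return data.frame of mutations.
#' @export
read_mutations <- function(path) {
  tab <- fread(path, sep = "\t", header = TRUE)
  setnames(tab, tolower(names(tab)))
  if (!all(c("protein", "position") %in% names(tab))) {
    stop("mutation table needs at least 'protein' and 'position' columns")
  }
  tab[, position := as.integer(position)]
  if (any(tab$position < 1L, na.rm = TRUE)) stop("positions must be >= 1")
  if (!"gene" %in% names(tab)) tab[, gene := protein]
  if ("label" %in% names(tab)) {
    tab[, label := .normalize_label(label)]
  } else {
    tab[, label := "unknown"]
  }
  setDF(tab)
  tab
}

.normalize_label <- function(x) {
  x <- tolower(as.character(x))
  pos <- c("positive", "driver", "pathogenic", "functional", "1", "true")
  neg <- c("negative", "passenger", "neutral", "benign", "0", "false")
  ifelse(x %in% pos, "positive", ifelse(x %in% neg, "negative", "unknown"))
}

#' Read a MAF-lite mutation table
#'
#' Minimal reader for MAF-style files carrying `Hugo_Symbol`,
#' `Protein_position` and `Amino_acids` (`"R/H"` form) columns; an optional
#' `SWISSPROT` column supplies the protein accession (otherwise the gene
#' symbol is used).
#'
#' @param path TSV path.
#' @return data.frame of mutations as in [read_mutations()].
#' @export
read_maf_lite <- function(path) {
  tab <- fread(path, sep = "\t", header = TRUE)
  need <- c("Hugo_Symbol", "Protein_position", "Amino_acids")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("MAF table is missing column(s): ",
                         paste(miss, collapse = ", "))
  aa <- strsplit(as.character(tab$Amino_acids), "/", fixed = TRUE)
  out <- data.frame(
    gene = as.character(tab$Hugo_Symbol),
    protein = if ("SWISSPROT" %in% names(tab)) as.character(tab$SWISSPROT)
              else as.character(tab$Hugo_Symbol),
    position = as.integer(tab$Protein_position),
    ref_aa = vapply(aa, function(v) v[1L], character(1L)),
    alt_aa = vapply(aa, function(v) if (length(v) > 1L) v[2L] else NA_character_,
                    character(1L)),
    stringsAsFactors = FALSE)
  out$label <- if ("label" %in% tolower(names(tab)))
    .normalize_label(tab[[which(tolower(names(tab)) == "label")[1L]]])
  else "unknown"
  out
}

#' Read an amino-acid substitution feature table
#'
#' A TSV keyed by `protein`, `position`, `alt_aa` followed by numeric
#' substitution-level feature columns (conservation scores, biophysical
#' property changes, ...). Column names are preserved verbatim so that
#' feature-importance reports stay interpretable.
#'
#' @param path TSV path.
#' @return data.frame with the key columns and the feature block.
#' @export
read_aa_features <- function(path) {
  tab <- fread(path, sep = "\t", header = TRUE)
  keyidx <- match(c("protein", "position", "alt_aa"), tolower(names(tab)))
  if (anyNA(keyidx)) {
    stop("AA feature table needs 'protein', 'position' and 'alt_aa' columns")
  }
  setnames(tab, keyidx, c("protein", "position", "alt_aa"))
  tab[, position := as.integer(position)]
  setDF(tab)
  tab
}
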