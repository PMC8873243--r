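# in-code fixtures shared across test files

# hub P0 with three partners; P0's interfaces overlap on positions 4 and 5
# (edge to P1 uses 1:5, edge to P2 uses 4:8, edge to P3 uses 11:15)
toy_records_hub <- function() {
  data.frame(
    protein_a = c(rep("P0", 15), rep("P1", 5), rep("P2", 5), rep("P3", 5)),
    protein_b = c(rep("P1", 5), rep("P2", 5), rep("P3", 5),
                  rep("P0", 15)),
    residue_a = c(1:5, 4:8, 11:15, 1:5, 1:5, 1:5),
    stringsAsFactors = FALSE)
}

toy_rsa_hub <- function() {
  data.frame(
    protein = c("P0", "P0", "P0", "P0", "P1"),
    chain = "A",
    position = c(20L, 21L, 22L, 1L, 30L),
    rsa = c(3, 20, 10, 3, 50),   # core, surface, unresolved, iface-override, surface
    stringsAsFactors = FALSE)
}

toy_network_hub <- function() {
  build_network(filter_interactions(toy_records_hub()), toy_rsa_hub())
}

# path A - B - C with structural annotations on B
toy_records_path <- function() {
  data.frame(
    protein_a = c(rep("A", 5), rep("B", 10), rep("C", 5)),
    protein_b = c(rep("B", 5), rep("A", 5), rep("C", 5), rep("B", 5)),
    residue_a = c(1:5, 1:5, 6:10, 1:5),
    stringsAsFactors = FALSE)
}

toy_network_path <- function() {
  rsa <- data.frame(protein = c("B", "B"), chain = "A",
                    position = c(20L, 21L), rsa = c(3, 50),
                    stringsAsFactors = FALSE)
  build_network(filter_interactions(toy_records_path()), rsa)
}

# small labelled dataset with numeric features for ml tests
toy_dataset <- function(n_genes = 10, per_gene = 8, seed = 1) {
  set.seed(seed)
  gene <- rep(sprintf("G%02d", seq_len(n_genes)), each = per_gene)
  n <- length(gene)
  label <- ifelse(runif(n) < 0.4, "positive", "negative")
  x1 <- rnorm(n, mean = 2 * (label == "positive"))
  x2 <- rnorm(n)
  data.frame(protein = gene, position = seq_len(n), ref_aa = "A",
             alt_aa = "V", gene = gene, label = label, x1 = x1, x2 = x2,
             stringsAsFactors = FALSE)
}
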