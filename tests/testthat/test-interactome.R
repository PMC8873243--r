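test_that("interface tables parse, dedup and round-trip", {
  tf <- tempfile(fileext = ".tsv")
  writeLines(c("Uniprot1\tUniprot2\tUniprot1_residue",
               "P1\tP2\t10", "P1\tP2\t12", "P2\tP1\t5", "P1\tP2\t10"), tf)
  rec <- parse_interface_table(tf)
  expect_equal(nrow(rec), 3L)   # duplicate (P1,P2,10) collapsed
  expect_equal(rec$residue_a, c(10L, 12L, 5L))
  expect_equal(rec$protein_a, c("P1", "P1", "P2"))

  # round-trip: serialise and re-parse gives the same record multiset
  tf2 <- tempfile(fileext = ".tsv")
  write_interface_table(rec, tf2)
  rec2 <- parse_interface_table(tf2)
  expect_equal(as.data.frame(rec2), as.data.frame(rec))
})

test_that("parser reports missing columns and bad residues", {
  tf <- tempfile(fileext = ".tsv")
  writeLines(c("Uniprot1\tSomething\tUniprot1_residue", "P1\tP2\t10"), tf)
  expect_error(parse_interface_table(tf), "Uniprot2")

  tf3 <- tempfile(fileext = ".tsv")
  writeLines(c("Uniprot1\tUniprot2\tUniprot1_residue", "P1\tP2\tten"), tf3)
  expect_error(parse_interface_table(tf3), "row")
  expect_error(parse_interface_table(tempfile()), "not found")
})

test_that("RSA thresholds classify residues and reject negatives", {
  expect_equal(assign_rsa_location(c(3, 20, 10)),
               c("core", "surface", "unresolved"))
  expect_equal(assign_rsa_location(5), "unresolved")   # boundary inclusive
  expect_equal(assign_rsa_location(15), "unresolved")
  expect_error(assign_rsa_location(-1), "non-negative")
})

test_that("consensus takes strict majority and resolves ties to unresolved", {
  expect_equal(consensus_location(c("core", "core", "surface")), "core")
  expect_equal(consensus_location(c("surface", "surface")), "surface")
  expect_equal(consensus_location(c("core", "surface")), "unresolved")
  expect_equal(consensus_location(c("unresolved", "unresolved")), "unresolved")
  expect_equal(consensus_location(c("core", "unresolved", "surface", "core")),
               "core")
  expect_error(consensus_location(character(0)), "empty")
})

test_that("interactions need >= 5 interface residues on both partners", {
  rec <- toy_records_hub()
  expect_equal(nrow(filter_interactions(rec)), nrow(rec))

  # 6 residues on one side, 4 on the other: dropped
  rec2 <- data.frame(protein_a = c(rep("X", 6), rep("Y", 4)),
                     protein_b = c(rep("Y", 6), rep("X", 4)),
                     residue_a = c(1:6, 1:4))
  expect_equal(nrow(filter_interactions(rec2)), 0L)
  expect_equal(nrow(filter_interactions(rec2, min_residues = 4)), 10L)

  # rows listed for only one partner cannot pass
  rec3 <- data.frame(protein_a = rep("X", 6), protein_b = rep("Y", 6),
                     residue_a = 1:6)
  expect_equal(nrow(filter_interactions(rec3)), 0L)
  expect_equal(nrow(filter_interactions(rec[0, ])), 0L)
})

test_that("raising the filter threshold never adds edges", {
  set.seed(11)
  syn <- generate_interactome(n_proteins = 30, attachment = 2,
                              protein_length = 120, iface_per_edge = 6,
                              seed = 11)
  n_edges <- function(r) {
    if (nrow(r) == 0) return(0L)
    length(unique(paste(pmin(r$protein_a, r$protein_b),
                        pmax(r$protein_a, r$protein_b))))
  }
  counts <- vapply(3:8, function(k)
    n_edges(filter_interactions(syn$records, min_residues = k)), integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("built networks carry symmetric interface maps and locations", {
  net <- toy_network_hub()
  expect_s3_class(net, "srn_network")
  expect_equal(igraph::vcount(net$graph), 4L)
  expect_equal(igraph::ecount(net$graph), 3L)

  s1 <- interface_residues(net, "P0", "P1")
  s2 <- interface_residues(net, "P1", "P0")
  expect_identical(s1, s2)
  expect_equal(s1$P0, 1:5)
  expect_equal(s1$P1, 1:5)
  expect_equal(interface_residues(net, "P0", "P2")$P0, 4:8)

  # RSA-derived labels and the interface override (P0 pos 1 has core RSA)
  expect_equal(residue_location(net, "P0", c(20, 21, 22, 1)),
               c("core", "surface", "unresolved", "interface"))
  expect_equal(residue_location(net, "P1", 30), "surface")
  expect_true(is.na(residue_location(net, "P1", 999)))
})

test_that("interface labels coincide exactly with interface-map membership", {
  net <- toy_network_hub()
  for (p in ls(net$location_map)) {
    locs <- residue_location(net, p)
    iface_pos <- sort(as.integer(names(locs[locs == "interface"])))
    in_map <- sort(unique(unlist(lapply(ls(net$interface_map), function(k) {
      sides <- get(k, envir = net$interface_map)
      if (p %in% names(sides)) sides[[p]] else integer(0)
    }))))
    expect_equal(iface_pos, in_map)
  }
})

test_that("self-interactions are excluded by default", {
  rec <- rbind(toy_records_hub(),
               data.frame(protein_a = "P9", protein_b = "P9", residue_a = 1:5))
  expect_warning(net <- build_network(rec, toy_rsa_hub()), "self")
  expect_false("P9" %in% igraph::V(net$graph)$name)
})

test_that("network export writes the documented tables", {
  net <- toy_network_hub()
  e <- tempfile(fileext = ".tsv"); r <- tempfile(fileext = ".tsv")
  write_network(net, e, r)
  edges <- read.delim(e)
  expect_setequal(names(edges),
                  c("protein_a", "protein_b", "n_iface_a", "n_iface_b"))
  expect_equal(nrow(edges), 3L)
  expect_true(all(edges$n_iface_a >= 5 & edges$n_iface_b >= 5))
  res <- read.delim(r)
  expect_true(all(c("protein", "position", "location") %in% names(res)))
})
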