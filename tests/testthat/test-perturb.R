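test_that("mutations map to the edges their location dictates", {
  net <- toy_network_hub()
  # surface: no edges
  expect_equal(affected_edges(net, "P0", 21), character(0))
  # core: every incident edge
  expect_setequal(affected_edges(net, "P0", 20), c("P1", "P2", "P3"))
  # interface shared by two of three edges
  expect_setequal(affected_edges(net, "P0", 4), c("P1", "P2"))
  expect_equal(affected_edges(net, "P0", 12), "P3")
  # unresolved / unannotated / unknown protein: unscoreable
  expect_null(affected_edges(net, "P0", 22))
  expect_null(affected_edges(net, "P0", 999))
  expect_null(affected_edges(net, "ZZ", 1))
})

test_that("perturbation features on the A-B-C path match hand computation", {
  net <- toy_network_path()
  # core mutation on B removes both edges
  core <- perturb_and_diff(net, "B", 20)
  expect_equal(core$location_3d, 0)
  expect_equal(core$degree_change, 2)
  expect_equal(core$percent_degree_change, 100)
  expect_equal(core$betweenness_change, 1)
  expect_equal(core$closeness_change, 1)

  # interface mutation at the B-C interface removes only that edge
  ifc <- perturb_and_diff(net, "B", 6)
  expect_equal(ifc$location_3d, 2)
  expect_equal(ifc$degree_change, 1)
  expect_equal(ifc$percent_degree_change, 50)
  expect_equal(ifc$betweenness_change, 1)
  expect_equal(ifc$closeness_change, 0.5)   # perturbed closeness (1/2)*(1/1)

  # surface mutation changes nothing
  srf <- perturb_and_diff(net, "B", 21)
  expect_equal(srf$location_3d, 1)
  chg <- unlist(srf[setdiff(names(srf), "location_3d")])
  expect_true(all(chg == 0))

  expect_null(perturb_and_diff(net, "B", 999))
})

test_that("perturbed centralities match oracle recomputation on the pruned graph", {
  for (s in 1:6) {
    syn <- generate_interactome(n_proteins = 18, attachment = 2,
                                protein_length = 160, iface_per_edge = 5,
                                seed = 300 + s)
    net <- syn$network
    base <- network_centralities(net$graph)
    prots <- igraph::V(net$graph)$name
    muts <- data.frame(
      protein = prots[c(1, 3, 5)],
      position = vapply(prots[c(1, 3, 5)], function(p) {
        locs <- residue_location(net, p)
        as.integer(names(locs[locs != "unresolved"])[1])
      }, integer(1)))
    for (i in seq_len(nrow(muts))) {
      p <- muts$protein[i]; q <- muts$position[i]
      partners <- affected_edges(net, p, q)
      rf <- perturb_and_diff(net, p, q, base = base)
      g2 <- net$graph
      if (length(partners)) {
        g2 <- igraph::delete_edges(
          g2, igraph::get_edge_ids(g2, rbind(rep(p, length(partners)), partners)))
      }
      idx <- match(p, igraph::V(g2)$name)
      expect_equal(rf$degree_change, length(partners))  # exact identity
      expect_equal(base[p, "betweenness"] - rf$betweenness_change,
                   oracle_betweenness(g2)[idx], tolerance = 1e-9)
      expect_equal(base[p, "load"] - rf$load_change,
                   oracle_load(g2)[idx], tolerance = 1e-9)
      expect_equal(base[p, "closeness"] - rf$closeness_change,
                   oracle_closeness(g2)[idx], tolerance = 1e-9)
      expect_equal(base[p, "clustering"] - rf$clustering_change,
                   oracle_clustering(g2)[idx], tolerance = 1e-9)
      expect_equal(base[p, "eigenvector"] - rf$eigenvector_change,
                   oracle_eigenvector(g2)[idx], tolerance = 1e-5)
      expect_equal(base[p, "pagerank"] - rf$pagerank_change,
                   oracle_pagerank(g2)[idx], tolerance = 1e-9)
    }
  }
})

test_that("featurize assembles documented columns, coverage and AA block", {
  net <- toy_network_hub()
  muts <- data.frame(
    protein = c("P0", "P0", "P0", "ZZ"),
    position = c(20L, 4L, 22L, 1L),      # core, interface, unresolved, unknown
    ref_aa = "A", alt_aa = "V",
    label = c("positive", "negative", "positive", "negative"))
  fe <- featurize(net, muts)
  expect_equal(nrow(fe), 2L)
  expect_equal(attr(fe, "coverage"), 0.5)
  expect_equal(names(fe),
               c("protein", "position", "ref_aa", "alt_aa", "gene", "label",
                 srn_feature_columns("net")))
  expect_equal(fe$gene, c("P0", "P0"))   # gene defaults to protein

  aa <- generate_aa_features(fe, n_features = 83, seed = 3)
  fe99 <- featurize(net, muts, aa_features = aa)
  expect_equal(ncol(fe99), 6 + 16 + 83)
  expect_equal(nrow(fe99), 2L)
  expect_equal(attr(fe99, "aa_columns"), sprintf("aa_%02d", 1:83))

  # empty input
  fe0 <- featurize(net, muts[0, ])
  expect_equal(nrow(fe0), 0L)
  expect_true(is.nan(attr(fe0, "coverage")))
})

test_that("feature tables are bit-identical across repeated runs", {
  syn <- generate_interactome(n_proteins = 25, attachment = 2,
                              protein_length = 150, seed = 9)
  muts <- generate_mutations(syn$network, 60, planted_model(seed = 9))
  f1 <- featurize(syn$network, muts)
  f2 <- featurize(syn$network, muts)
  expect_identical(f1, f2)
})
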