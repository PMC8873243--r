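test_that("balancing caps negatives per gene at the median positive count", {
  # genes with 2, 16 and 30 positives -> cap = 16
  ds <- data.frame(
    gene = c(rep("g1", 2), rep("g2", 16), rep("g3", 30), rep("g4", 40)),
    label = c(rep("positive", 48), rep("negative", 40)))
  ds$protein <- ds$gene; ds$x <- rnorm(nrow(ds))
  bal <- balance_training_set(ds, ratio = 4, seed = 1)
  expect_equal(attr(bal, "cap"), 16)
  expect_equal(sum(bal$label == "positive"), 48)       # positives never dropped
  expect_equal(sum(bal$gene == "g4" & bal$label == "negative"), 16)

  # ratio target honoured when the pool permits
  ds2 <- data.frame(gene = c(rep("g1", 10), rep(sprintf("n%02d", 1:60), each = 2)),
                    label = c(rep("positive", 10), rep("negative", 120)))
  ds2$x <- rnorm(nrow(ds2))
  bal2 <- balance_training_set(ds2, ratio = 4, seed = 2)
  expect_equal(sum(bal2$label == "negative"), 40)      # 4 x 10, pool of 120
  expect_true(max(table(bal2$gene[bal2$label == "negative"])) <=
                attr(bal2, "cap"))

  expect_error(balance_training_set(ds2[ds2$label == "positive", ]),
               "no negatives")
  # same seed, same draw
  expect_identical(balance_training_set(ds2, ratio = 4, seed = 9),
                   balance_training_set(ds2, ratio = 4, seed = 9))
})

test_that("gene-holdout folds partition genes and balance positives", {
  ds <- toy_dataset(n_genes = 10, per_gene = 8, seed = 3)
  f <- gene_holdout_folds(ds, k = 5, seed = 3)
  expect_setequal(names(f), unique(ds$gene))
  expect_equal(sort(unique(unname(f))), 1:5)
  expect_identical(f, gene_holdout_folds(ds, k = 5, seed = 3))

  # 5 genes with 10 positives each, k = 5: exactly one gene per fold
  ds2 <- data.frame(gene = rep(letters[1:5], each = 10), label = "positive")
  f2 <- gene_holdout_folds(ds2, k = 5, seed = 1)
  expect_equal(sort(unname(f2)), 1:5)

  expect_error(gene_holdout_folds(ds2, k = 6), "at least")
})

test_that("evaluation metrics match hand-worked and oracle values", {
  rep1 <- evaluate_scores(c(0.9, 0.8, 0.3, 0.2), c(1, 0, 1, 0))
  expect_equal(rep1$auroc, 0.75)   # 3 of 4 positive-negative pairs ordered

  perf <- evaluate_scores(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))
  expect_equal(perf$auroc, 1)
  expect_equal(perf$accuracy, 1)
  expect_equal(perf$f1, 1)
  expect_equal(perf$mcc, 1)

  # TP = TN = FP = FN = 1 -> MCC exactly 0
  conf <- evaluate_scores(c(0.9, 0.9, 0.1, 0.1), c(1, 0, 1, 0))
  expect_equal(conf$mcc, 0)
  expect_equal(conf$accuracy, 0.5)

  expect_error(evaluate_scores(c(0.1, 0.2), c(1, 1)), "both classes")

  # pair-counting oracle + independent ROC library on random instances
  set.seed(42)
  for (i in 1:5) {
    n <- 60
    lab <- runif(n) < 0.4
    sc <- round(runif(n), 2)       # rounding forces ties
    r <- evaluate_scores(sc, lab)
    expect_equal(r$auroc, oracle_auroc(sc, lab), tolerance = 1e-12)
    proc_auc <- as.numeric(pROC::auc(pROC::roc(lab, sc, quiet = TRUE,
                                               direction = "<")))
    expect_equal(r$auroc, proc_auc, tolerance = 1e-12)
  }
})

test_that("MCC is invariant under label swap with score reflection", {
  set.seed(7)
  for (i in 1:5) {
    lab <- runif(50) < 0.5
    sc <- runif(50)
    if (length(unique(lab)) < 2) next
    a <- evaluate_scores(sc, lab, threshold = 0.5)
    b <- evaluate_scores(1 - sc + 1e-12, !lab, threshold = 0.5)
    expect_equal(a$mcc, b$mcc, tolerance = 1e-9)
    expect_equal(a$auroc, b$auroc, tolerance = 1e-9)
  }
})

test_that("DeLong test has the documented edge cases and symmetry", {
  set.seed(1)
  lab <- rep(c(TRUE, FALSE), 10)
  sc <- runif(20)
  self <- delong_test(sc, sc, lab)
  expect_equal(self$z, 0)
  expect_equal(self$p, 1)

  good <- as.numeric(lab); bad <- 1 - as.numeric(lab)
  dt <- delong_test(good, bad, lab)
  expect_equal(dt$auroc_1, 1)
  expect_equal(dt$auroc_2, 0)
  expect_lt(dt$p, 0.05)

  s2 <- runif(20)
  a <- delong_test(sc, s2, lab)
  b <- delong_test(s2, sc, lab)
  expect_equal(a$z, -b$z, tolerance = 1e-12)
  expect_equal(a$p, b$p, tolerance = 1e-12)

  # cross-check z and p against the independent pROC implementation
  r1 <- pROC::roc(lab, sc, quiet = TRUE, direction = "<")
  r2 <- pROC::roc(lab, s2, quiet = TRUE, direction = "<")
  ref <- pROC::roc.test(r1, r2, method = "delong", paired = TRUE)
  expect_equal(a$p, ref$p.value, tolerance = 1e-9)
})

test_that("cross-validation is seeded, gene-clean and recovers planted signal", {
  ds <- toy_dataset(n_genes = 12, per_gene = 10, seed = 5)
  cv1 <- cross_validate(ds, feature_set = c("x1", "x2"), k = 4, seed = 11,
                        ntree = 300)
  cv2 <- cross_validate(ds, feature_set = c("x1", "x2"), k = 4, seed = 11,
                        ntree = 300)
  expect_identical(cv1$scores$score, cv2$scores$score)
  expect_equal(nrow(cv1$scores), nrow(ds))
  # no gene straddles folds
  byg <- tapply(cv1$scores$fold, cv1$scores$gene, function(v) length(unique(v)))
  expect_true(all(byg == 1))
  # x1 carries a 2-sigma shift: easily separable
  expect_gt(cv1$report$auroc, 0.8)

  # label-shuffled control sits near chance
  sh <- ds; set.seed(77); sh$label <- sample(sh$label)
  cvn <- cross_validate(sh, feature_set = c("x1", "x2"), k = 4, seed = 11,
                        ntree = 300)
  expect_gt(cvn$report$auroc, 0.35)
  expect_lt(cvn$report$auroc, 0.65)

  expect_error(cross_validate(ds, feature_set = "nope", k = 4, seed = 1),
               "unknown feature")
})

test_that("feature importances are normalised and rank planted signal first", {
  ds <- toy_dataset(n_genes = 12, per_gene = 12, seed = 8)
  ds$x3 <- rnorm(nrow(ds)); ds$x4 <- rnorm(nrow(ds))
  m <- train_classifier(ds, feature_set = c("x1", "x2", "x3", "x4"),
                        ntree = 500, seed = 2)
  imp <- feature_importances(m)
  expect_equal(sum(imp$importance), 1, tolerance = 1e-9)
  expect_equal(imp$feature[1], "x1")       # only x1 carries signal
  expect_true(all(diff(imp$importance) <= 0))
  expect_error(feature_importances(list()), "srn_model")
})
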