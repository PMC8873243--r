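#' Balance a labelled training set
#'
#' Caps the number of negatives contributed by any single gene at the median
#' per-gene positive count (over genes that carry positives, rounded half
#' up), then draws negatives uniformly from the capped pool until the target
#' negative:positive ratio is reached (or the pool is exhausted). Positives
#' are always all kept. This keeps recurrently mutated genes from dominating
#' the negative class while approximating the desired class ratio.
#'
#' @param ds data.frame with `label` (`"positive"`/`"negative"`) and `gene`
#'   columns (e.g. output of [featurize()]).
#' @param ratio target negatives per positive (default 4).
#' @param seed integer seed for the subsampling draws.
#' @return the balanced subset of `ds`; attributes `cap` (per-gene cap) and
#'   `n_drawn` (negatives drawn) describe the sampling.
#' @export
balance_training_set <- function(ds, ratio = 4, seed = 1L) {
  ds <- as.data.frame(ds)
  pos <- ds[ds$label == "positive", , drop = FALSE]
  neg <- ds[ds$label == "negative", , drop = FALSE]
  if (nrow(pos) == 0L) stop("training set has no positives")
  if (nrow(neg) == 0L) stop("training set has no negatives")

  pos_per_gene <- table(pos$gene)
  cap <- floor(median(as.numeric(pos_per_gene)) + 0.5)  # round half up

  set.seed(seed)
  neg_idx <- seq_len(nrow(neg))
  capped <- unlist(lapply(split(neg_idx, neg$gene), function(ix) {
    if (length(ix) > cap) sort(sample(ix, cap)) else ix
  }), use.names = FALSE)
  target <- min(round(ratio * nrow(pos)), length(capped))
  drawn <- sort(sample(capped, target))

  out <- rbind(pos, neg[drawn, , drop = FALSE])
  rownames(out) <- NULL
  attr(out, "cap") <- cap
  attr(out, "n_drawn") <- target
  out
}

#' Gene-holdout fold assignment
#'
#' Partitions genes (not mutations) into k folds so that no gene's mutations
#' are split across folds, while keeping the number of positives (and then
#' total rows) as even as possible: genes are shuffled, sorted by positive
#' count descending, and greedily assigned to the fold with the fewest
#' positives so far (ties broken by fewest rows, then lowest fold index).
#'
#' @param ds data.frame with `gene` and `label` columns.
#' @param k number of folds (default 5).
#' @param seed integer seed for the shuffle.
#' @return named integer vector: gene -> fold in `1..k`.
#' @export
gene_holdout_folds <- function(ds, k = 5L, seed = 1L) {
  genes <- unique(as.character(ds$gene))
  if (length(genes) < k) stop("need at least k = ", k, " distinct genes")
  n_pos <- vapply(genes, function(g)
    sum(ds$gene == g & ds$label == "positive"), numeric(1L))
  n_all <- vapply(genes, function(g) sum(ds$gene == g), numeric(1L))

  set.seed(seed)
  ord <- sample(length(genes))                       # random tie order
  ord <- ord[order(n_pos[ord], decreasing = TRUE)]   # stable: shuffle survives ties

  fold_pos <- numeric(k)
  fold_rows <- numeric(k)
  assign_to <- integer(length(genes))
  for (gi in ord) {
    best <- order(fold_pos, fold_rows, seq_len(k))[1L]
    assign_to[gi] <- best
    fold_pos[best] <- fold_pos[best] + n_pos[gi]
    fold_rows[best] <- fold_rows[best] + n_all[gi]
  }
  stats::setNames(assign_to, genes)
}

# resolve a named feature subset to concrete columns of ds
.resolve_feature_set <- function(ds, feature_set) {
  aa_cols <- attr(ds, "aa_columns")
  if (is.null(aa_cols)) {
    aa_cols <- setdiff(names(ds), c("protein", "position", "ref_aa", "alt_aa",
                                    "gene", "label", srn_feature_columns("net")))
  }
  if (length(feature_set) > 1L || !feature_set %in%
        c("net", "prot", "res", "aa", "res_aa", "net_aa")) {
    cols <- feature_set                 # explicit column vector
    miss <- setdiff(cols, names(ds))
    if (length(miss)) stop("unknown feature column(s): ",
                           paste(miss, collapse = ", "))
    return(cols)
  }
  cols <- switch(feature_set,
    net = srn_feature_columns("net"),
    prot = srn_feature_columns("prot"),
    res = srn_feature_columns("res"),
    aa = aa_cols,
    res_aa = c(srn_feature_columns("res"), aa_cols),
    net_aa = c(srn_feature_columns("net"), aa_cols))
  if (length(cols) == 0L) stop("feature set '", feature_set,
                               "' resolves to no columns in this dataset")
  cols
}

#' Train a random-forest mutation classifier
#'
#' Fits an ensemble of 1000 classification trees with sqrt(p) candidate
#' features per split; the prediction score of a mutation is the fraction of
#' trees voting for the positive class.
#'
#' @param ds labelled feature data.frame (see [featurize()]); rows with label
#'   `"unknown"` are dropped.
#' @param feature_set one of `"net"`, `"prot"`, `"res"`, `"aa"`, `"res_aa"`,
#'   `"net_aa"`, or an explicit character vector of feature columns.
#' @param ntree number of trees (default 1000).
#' @param seed integer seed for tree randomness.
#' @return an object of class `srn_model`.
#' @export
train_classifier <- function(ds, feature_set = "net", ntree = 1000L,
                             seed = 1L) {
  cols <- .resolve_feature_set(ds, feature_set)
  ds <- ds[ds$label %in% c("positive", "negative"), , drop = FALSE]
  if (length(unique(ds$label)) < 2L) stop("need both classes to train")
  x <- ds[, cols, drop = FALSE]
  y <- factor(ds$label, levels = c("negative", "positive"))
  set.seed(seed)
  rf <- randomForest::randomForest(
    x = x, y = y, ntree = ntree, mtry = max(1L, floor(sqrt(ncol(x)))))
  structure(list(forest = rf, columns = cols, seed = seed, ntree = ntree),
            class = "srn_model")
}

#' @export
print.srn_model <- function(x, ...) {
  cat("srnet random-forest classifier:", x$ntree, "trees,",
      length(x$columns), "features\n")
  invisible(x)
}

#' Score mutations with a trained classifier
#'
#' @param object an `srn_model`.
#' @param newdata feature data.frame containing the model's columns.
#' @param ... unused.
#' @return numeric vector of scores in `[0, 1]` (fraction of trees voting
#'   positive).
#' @export
predict.srn_model <- function(object, newdata, ...) {
  x <- newdata[, object$columns, drop = FALSE]
  as.numeric(predict(object$forest, x, type = "prob")[, "positive"])
}

#' Gene-holdout cross-validated evaluation
#'
#' Trains on k-1 folds and scores the held-out fold, for each fold; the
#' pooled out-of-fold scores give a single evaluation. Per-fold training
#' seeds are derived deterministically from the master seed so that fold
#' membership and tree randomness are decoupled.
#'
#' @param ds labelled feature data.frame with `gene` column.
#' @param feature_set see [train_classifier()].
#' @param k number of folds (default 5).
#' @param seed master seed (folds and per-fold forests).
#' @param ntree trees per forest.
#' @param threshold score threshold for the confusion-matrix metrics.
#' @return list with `scores` (data.frame: keys, gene, label, fold, score),
#'   `report` (see [evaluate_scores()]) and `folds` (gene -> fold).
#' @export
cross_validate <- function(ds, feature_set = "net", k = 5L, seed = 1L,
                           ntree = 1000L, threshold = 0.5) {
  ds <- as.data.frame(ds)[, , drop = FALSE]
  cols <- .resolve_feature_set(ds, feature_set)
  ds <- ds[ds$label %in% c("positive", "negative"), , drop = FALSE]
  folds <- gene_holdout_folds(ds, k = k, seed = seed)
  fold_of <- unname(folds[as.character(ds$gene)])

  out <- vector("list", k)
  for (f in seq_len(k)) {
    train <- ds[fold_of != f, , drop = FALSE]
    test <- ds[fold_of == f, , drop = FALSE]
    if (nrow(test) == 0L) next
    model <- train_classifier(train, feature_set = cols, ntree = ntree,
                              seed = (seed * 131L + f) %% .Machine$integer.max)
    sc <- predict(model, test)
    keycols <- intersect(c("protein", "position", "ref_aa", "alt_aa", "gene",
                           "label"), names(test))
    out[[f]] <- cbind(test[, keycols, drop = FALSE],
                      data.frame(fold = f, score = sc))
  }
  scores <- do.call(rbind, out)
  rownames(scores) <- NULL
  report <- evaluate_scores(scores$score,
                            scores$label == "positive", threshold = threshold)
  list(scores = scores, report = report, folds = folds)
}

#' Classifier evaluation metrics
#'
#' Computes auROC (pairwise concordance, ties counted 1/2), auPRC (stepwise
#' precision-recall integration without interpolation), and accuracy, F1 and
#' Matthews correlation at a score threshold (score >= threshold predicts
#' positive). MCC is defined as 0 when any confusion-matrix marginal is
#' empty; F1 is 0 when precision and recall are both undefined or zero.
#'
#' @param scores numeric prediction scores.
#' @param labels logical (or 0/1, or `"positive"`/`"negative"`) true labels.
#' @param threshold decision threshold (default 0.5).
#' @return list of class `srn_eval`: `auroc`, `auprc`, `accuracy`, `f1`,
#'   `mcc`, `threshold`, `n_pos`, `n_neg`.
#' @export
evaluate_scores <- function(scores, labels, threshold = 0.5) {
  labels <- .as_binary(labels)
  if (length(scores) != length(labels)) stop("scores/labels length mismatch")
  n_pos <- sum(labels)
  n_neg <- sum(!labels)
  if (n_pos == 0L || n_neg == 0L) stop("need both classes to evaluate")

  # auROC via the rank (Mann-Whitney) identity; midranks give ties 1/2
  r <- rank(scores, ties.method = "average")
  auroc <- (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)

  # auPRC: walk thresholds from high to low, grouping tied scores
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  l <- labels[ord]
  grp <- cumsum(!duplicated(s))
  tp <- cumsum(l)
  fp <- cumsum(!l)
  last <- which(!duplicated(grp, fromLast = TRUE))   # last index of each tie group
  tp_g <- tp[last]
  fp_g <- fp[last]
  prec <- tp_g / (tp_g + fp_g)
  dtp <- diff(c(0, tp_g))
  auprc <- sum(prec * dtp) / n_pos

  pred <- scores >= threshold
  tp_c <- as.numeric(sum(pred & labels)); fp_c <- as.numeric(sum(pred & !labels))
  fn_c <- as.numeric(sum(!pred & labels)); tn_c <- as.numeric(sum(!pred & !labels))
  accuracy <- (tp_c + tn_c) / length(labels)
  f1 <- if (2 * tp_c + fp_c + fn_c == 0) 0 else 2 * tp_c / (2 * tp_c + fp_c + fn_c)
  denom <- (tp_c + fp_c) * (tp_c + fn_c) * (tn_c + fp_c) * (tn_c + fn_c)
  mcc <- if (denom == 0) 0 else
    (tp_c * tn_c - fp_c * fn_c) / sqrt(denom)

  structure(list(auroc = auroc, auprc = auprc, accuracy = accuracy, f1 = f1,
                 mcc = mcc, threshold = threshold, n_pos = n_pos,
                 n_neg = n_neg), class = "srn_eval")
}

#' @export
print.srn_eval <- function(x, ...) {
  cat(sprintf("auROC %.3f | auPRC %.3f | acc %.3f | F1 %.3f | MCC %.3f (threshold %.2f, %d+/%d-)\n",
              x$auroc, x$auprc, x$accuracy, x$f1, x$mcc, x$threshold,
              x$n_pos, x$n_neg))
  invisible(x)
}

.as_binary <- function(labels) {
  if (is.logical(labels)) return(labels)
  if (is.numeric(labels)) return(labels != 0)
  tolower(as.character(labels)) %in% c("positive", "1", "true")
}

#' DeLong test for two correlated ROC curves
#'
#' Compares the auROCs of two score vectors computed on the same instances,
#' using the midrank-placement estimate of the covariance of the two auROC
#' estimators. A negative z means the first scorer has the lower auROC.
#'
#' @param scores_1,scores_2 numeric score vectors aligned to `labels`.
#' @param labels true labels (see [evaluate_scores()]).
#' @return list: `z`, `p` (two-sided), `auroc_1`, `auroc_2`.
#' @export
delong_test <- function(scores_1, scores_2, labels) {
  labels <- .as_binary(labels)
  m <- sum(labels)
  n <- sum(!labels)
  if (m == 0L || n == 0L) stop("need both classes")

  placements <- function(sc) {
    x <- sc[labels]                     # positives
    y <- sc[!labels]                    # negatives
    r_all <- rank(c(x, y), ties.method = "average")
    r_x <- rank(x, ties.method = "average")
    r_y <- rank(y, ties.method = "average")
    v10 <- (r_all[seq_len(m)] - r_x) / n          # per-positive placements
    v01 <- 1 - (r_all[m + seq_len(n)] - r_y) / m  # per-negative placements
    auc <- sum(r_all[seq_len(m)] - r_x) / (m * n)
    list(v10 = v10, v01 = v01, auc = auc)
  }
  p1 <- placements(scores_1)
  p2 <- placements(scores_2)
  s10 <- stats::var(p1$v10 - p2$v10)
  s01 <- stats::var(p1$v01 - p2$v01)
  v <- s10 / m + s01 / n
  d <- p1$auc - p2$auc
  if (!is.finite(v) || v <= 0) {
    # degenerate variance: identical placements give z = 0; a real auROC
    # difference with no placement variability is infinitely significant
    if (abs(d) < .Machine$double.eps^0.5) {
      z <- 0; p <- 1
    } else {
      z <- sign(d) * Inf; p <- 0
    }
  } else {
    z <- d / sqrt(v)
    p <- 2 * pnorm(-abs(z))
  }
  list(z = z, p = p, auroc_1 = p1$auc, auroc_2 = p2$auc)
}

#' Gini feature importances of a trained classifier
#'
#' Mean decrease in node impurity attributable to splits on each feature,
#' normalised to sum to one and sorted descending.
#'
#' @param model an `srn_model`.
#' @return data.frame with columns `feature`, `importance`.
#' @export
feature_importances <- function(model) {
  if (!inherits(model, "srn_model")) stop("not a trained srn_model")
  imp <- randomForest::importance(model$forest, type = 2)[, 1L]
  imp <- imp / sum(imp)
  ord <- order(imp, decreasing = TRUE)
  data.frame(feature = names(imp)[ord], importance = unname(imp[ord]),
             row.names = NULL)
}
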