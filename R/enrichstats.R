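#' Fisher odds ratio with confidence interval
#'
#' Sample odds ratio `ad/bc` for a 2x2 contingency table, the exact
#' (hypergeometric) two-sided p-value, and a 95% Wald confidence interval on
#' the log odds ratio; when any cell is zero the CI uses the
#' Haldane-Anscombe 0.5 correction. The sample OR (not the conditional MLE)
#' is reported so that the point estimate matches the textbook `ad/bc`.
#'
#' @param table 2x2 integer matrix (rows = group, columns = outcome class),
#'   or the four counts `a, b, c, d` in row-major order.
#' @param conf_level confidence level (default 0.95).
#' @return list of class `srn_enrichment`: `odds_ratio` (may be `Inf`),
#'   `ci_low`, `ci_high`, `p`.
#' @export
fisher_or <- function(table, conf_level = 0.95) {
  if (!is.matrix(table)) table <- matrix(as.numeric(table), 2, 2, byrow = TRUE)
  if (any(table < 0) || any(table != floor(table))) {
    stop("table must hold non-negative integer counts")
  }
  if (sum(table) == 0) stop("all-zero contingency table")
  a <- table[1, 1]; b <- table[1, 2]; c <- table[2, 1]; d <- table[2, 2]
  or <- if (b * c == 0) {
    if (a * d > 0) Inf else NaN
  } else (a * d) / (b * c)
  p <- fisher.test(table)$p.value
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  cc <- if (any(c(a, b, c, d) == 0)) 0.5 else 0
  la <- log(((a + cc) * (d + cc)) / ((b + cc) * (c + cc)))
  se <- sqrt(1 / (a + cc) + 1 / (b + cc) + 1 / (c + cc) + 1 / (d + cc))
  structure(list(odds_ratio = or, ci_low = exp(la - z * se),
                 ci_high = exp(la + z * se), p = p),
            class = "srn_enrichment")
}

#' @export
print.srn_enrichment <- function(x, ...) {
  cat(sprintf("OR %.3g [%.3g, %.3g], p = %.3g\n",
              x$odds_ratio, x$ci_low, x$ci_high, x$p))
  invisible(x)
}

#' Structural-location enrichment between two mutation groups
#'
#' Runs the two standard location contrasts between two groups of mutations
#' (e.g. pathogenic vs neutral) annotated on a structurally resolved network:
#'
#' * `surface_vs_core`: surface-exposed (surface or interface) versus core.
#'   OR > 1 means group 1 is more often surface-exposed.
#' * `interface_vs_surface`: among surface-exposed residues only, interface
#'   versus non-interface surface. OR > 1 means group 1 is more often at an
#'   interface.
#'
#' Residues with ambiguous (`unresolved`) or missing location are excluded.
#'
#' @param net an `srn_network`.
#' @param mutations data.frame with `protein`, `position` and a group column.
#' @param group name of the column splitting mutations into exactly two
#'   groups (default `"label"`); group 1 is the first level encountered
#'   sorted decreasingly (`"positive"` before `"negative"`).
#' @return data.frame with one row per contrast: `analysis`, `group1`,
#'   `group2`, the four counts, `odds_ratio`, `ci_low`, `ci_high`, `p`.
#' @export
location_enrichment <- function(net, mutations, group = "label") {
  mutations <- as.data.frame(mutations)
  loc <- mapply(function(p, q) residue_location(net, as.character(p),
                                                as.integer(q)),
                mutations$protein, mutations$position)
  g <- as.character(mutations[[group]])
  keep <- !is.na(loc) & loc != "unresolved"
  loc <- loc[keep]; g <- g[keep]
  lv <- sort(unique(g), decreasing = TRUE)
  if (length(lv) != 2L) stop("group column must have exactly two levels")

  count <- function(gv, locs) sum(g == gv & loc %in% locs)
  # contrast 1: surface-exposed (surface + interface) vs core
  t1 <- matrix(c(count(lv[1], c("surface", "interface")), count(lv[1], "core"),
                 count(lv[2], c("surface", "interface")), count(lv[2], "core")),
               2, 2, byrow = TRUE)
  # contrast 2: interface vs plain surface, among surface-exposed residues
  t2 <- matrix(c(count(lv[1], "interface"), count(lv[1], "surface"),
                 count(lv[2], "interface"), count(lv[2], "surface")),
               2, 2, byrow = TRUE)
  res <- lapply(list(surface_vs_core = t1, interface_vs_surface = t2),
                fisher_or)
  data.frame(
    analysis = names(res),
    group1 = lv[1], group2 = lv[2],
    a = c(t1[1, 1], t2[1, 1]), b = c(t1[1, 2], t2[1, 2]),
    c = c(t1[2, 1], t2[2, 1]), d = c(t1[2, 2], t2[2, 2]),
    odds_ratio = vapply(res, `[[`, numeric(1), "odds_ratio"),
    ci_low = vapply(res, `[[`, numeric(1), "ci_low"),
    ci_high = vapply(res, `[[`, numeric(1), "ci_high"),
    p = vapply(res, `[[`, numeric(1), "p"),
    row.names = NULL)
}

#' Pairwise Mann-Whitney comparison of groups
#'
#' Two-sided Mann-Whitney U test for every pair of groups: exact enumeration
#' when both samples have at most 20 observations and no ties, otherwise the
#' normal approximation with tie and continuity correction. Optional
#' Bonferroni correction multiplies each p by the number of pairs (capped at
#' 1).
#'
#' @param values_by_group named list of numeric vectors (>= 2 groups).
#' @param correction `"none"` or `"bonferroni"`.
#' @return data.frame with `group1`, `group2`, `u` (statistic for group1),
#'   `p`.
#' @export
group_compare <- function(values_by_group, correction = c("none", "bonferroni")) {
  correction <- match.arg(correction)
  if (length(values_by_group) < 2L) stop("need at least two groups")
  if (any(lengths(values_by_group) == 0L)) stop("empty group sample")
  nms <- names(values_by_group)
  if (is.null(nms)) nms <- paste0("group", seq_along(values_by_group))
  pairs <- utils::combn(seq_along(values_by_group), 2)
  n_pairs <- ncol(pairs)
  rows <- lapply(seq_len(n_pairs), function(j) {
    i1 <- pairs[1, j]; i2 <- pairs[2, j]
    x <- values_by_group[[i1]]; y <- values_by_group[[i2]]
    exact <- length(x) <= 20 && length(y) <= 20 &&
      !any(duplicated(c(x, y)))
    wt <- suppressWarnings(
      wilcox.test(x, y, alternative = "two.sided", exact = exact,
                  correct = TRUE))
    data.frame(group1 = nms[i1], group2 = nms[i2],
               u = unname(wt$statistic), p = wt$p.value)
  })
  out <- do.call(rbind, rows)
  if (correction == "bonferroni") out$p <- pmin(1, out$p * n_pairs)
  out
}

#' Pairwise Pearson correlations of feature columns
#'
#' @param matrix numeric data.frame or matrix of feature columns (>= 2 rows).
#' @return symmetric correlation matrix with unit diagonal; columns with zero
#'   variance give `NA` (flagged with a warning), never a silent 0.
#' @export
feature_correlations <- function(matrix) {
  m <- as.matrix(matrix)
  if (nrow(m) < 2L) stop("need at least two rows")
  sds <- apply(m, 2, sd)
  if (any(sds == 0)) {
    warning("constant column(s): ",
            paste(colnames(m)[sds == 0], collapse = ", "))
  }
  r <- suppressWarnings(cor(m, method = "pearson"))
  diag(r) <- 1
  r
}

#' Filter a correlation matrix for reporting
#'
#' Keeps features having at least one off-diagonal correlation with absolute
#' value above `gate`, and masks retained entries with absolute value at or
#' below `floor` as `NA`. Mirrors the common display convention for feature
#' correlation heatmaps.
#'
#' @param r correlation matrix.
#' @param gate minimum |r| a feature must reach somewhere to be kept
#'   (default 0.3).
#' @param floor entries with |r| <= `floor` are masked (default 0.1).
#' @return the filtered (possibly smaller) matrix.
#' @export
filter_correlations <- function(r, gate = 0.3, floor = 0.1) {
  off <- abs(r)
  diag(off) <- 0
  keep <- apply(off, 1, function(v) any(v > gate, na.rm = TRUE))
  out <- r[keep, keep, drop = FALSE]
  mask <- abs(out) <= floor
  diag(mask) <- FALSE
  out[mask] <- NA
  out
}

#' Long-format export of a correlation matrix
#'
#' @param r correlation matrix.
#' @param path output TSV path (`feature_i  feature_j  r`), upper triangle.
#' @export
write_correlations <- function(r, path) {
  idx <- which(upper.tri(r), arr.ind = TRUE)
  out <- data.frame(feature_i = rownames(r)[idx[, 1]],
                    feature_j = colnames(r)[idx[, 2]],
                    r = r[idx])
  fwrite(out, path, sep = "\t")
  invisible(path)
}
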