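# Quality screening: a case passes when its test and control samples are
# perfectly separated both by PCA (component-1 threshold score of 1) and by
# DEG-based two-way hierarchical clustering (G2HC). Samples are pruned
# greedily until both tests pass or a budget is reached.

#' PCA projection of samples
#'
#' Principal component analysis of the samples of an expression matrix
#' after gene-wise centering (no scaling), the standard treatment for
#' expression arrays. Components are orthogonal directions in gene space;
#' variance fractions are non-increasing.
#'
#' @param mat genes x samples numeric matrix.
#' @param n_components number of components to return (capped at the rank).
#' @return list with `scores` (samples x components matrix) and
#'   `variance_fractions` (non-increasing, summing to at most 1).
#' @export
pca_projection <- function(mat, n_components = 2) {
  stopifnot(is.matrix(mat), ncol(mat) >= 2)
  if (anyNA(mat)) stop("expression matrix contains missing values")
  pc <- prcomp(t(mat), center = TRUE, scale. = FALSE)
  tot <- sum(pc$sdev^2)
  if (tot <= 0) stop("degenerate matrix: zero total variance")
  k <- min(n_components, sum(pc$sdev^2 / tot > 1e-12))
  list(scores = pc$x[, seq_len(k), drop = FALSE],
       variance_fractions = (pc$sdev^2 / tot)[seq_len(k)])
}

#' Separation score on a one-dimensional projection
#'
#' Operational definition of the 0-to-1 "separation score": twice the best
#' achievable one-dimensional threshold classification accuracy minus one,
#' clipped to `[0, 1]`. The score is 1 exactly when the two groups project
#' onto disjoint intervals, 0 when no threshold beats chance. Symmetric in
#' the group labels.
#'
#' @param pc1_scores numeric vector (typically PC1 coordinates).
#' @param labels vector with exactly two distinct values, same length.
#' @return score in `[0, 1]`.
#' @export
separation_score <- function(pc1_scores, labels) {
  stopifnot(length(pc1_scores) == length(labels))
  labels <- as.character(labels)
  lv <- unique(labels)
  if (length(lv) != 2) stop("exactly two non-empty label groups required")
  y <- labels == lv[1]
  xs <- sort(unique(pc1_scores))
  thr <- c(-Inf, (xs[-1] + xs[-length(xs)]) / 2, Inf)
  best <- 0
  for (t in thr) {
    acc <- mean((pc1_scores > t) == y)
    best <- max(best, acc, 1 - acc)
  }
  min(1, max(0, 2 * (best - 0.5)))
}

#' Two-way hierarchical-clustering separation test (G2HC)
#'
#' Clusters the samples on the DEG-restricted matrix (distance
#' `1 - Pearson correlation`, average linkage by default) and reports
#' whether cutting the dendrogram into two clusters reproduces the
#' test/control partition exactly.
#'
#' @param mat genes x samples matrix.
#' @param deg_genes non-empty character vector of genes to restrict to.
#' @param labels test/control labels per sample.
#' @param linkage linkage method passed to [stats::hclust()].
#' @return logical: `TRUE` iff the 2-cut partition equals the labels.
#' @export
g2hc_separation <- function(mat, deg_genes, labels, linkage = "average") {
  stopifnot(length(labels) == ncol(mat))
  labels <- as.character(labels)
  if (min(table(labels)) < 2 || length(unique(labels)) != 2)
    stop("need at least 2 samples in each of two groups")
  deg_genes <- intersect(deg_genes, rownames(mat))
  if (length(deg_genes) == 0) stop("deg_genes is empty or disjoint from matrix")
  sub <- mat[deg_genes, , drop = FALSE]
  d <- as.dist(1 - cor(sub))
  hc <- hclust(d, method = linkage)
  cl <- cutree(hc, k = 2)
  identical_partition(cl, labels)
}

# TRUE iff two labellings induce the same 2-block partition.
identical_partition <- function(a, b) {
  a <- as.integer(factor(a)); b <- as.integer(factor(b))
  all(a == b) || all(a == 3L - b)
}

#' Greedy sample pruning toward perfect test/control separation
#'
#' Iterates: compute provisional DEGs under a fixed relaxed criterion (raw
#' p < `p_cut` and |log2FC| > `lfc_cut`, ordinary t), evaluate the PCA
#' component-1 [separation_score()] and [g2hc_separation()]; while either
#' test is imperfect, remove the single sample whose removal maximally
#' increases the PCA score (ties broken by sample-id lexicographic order),
#' subject to `min_group_size` and `max_removals`. The relaxed provisional
#' criterion avoids circularity with the final case-specific FDR
#' thresholds. If no provisional DEG passes, the `fallback_n` genes with
#' smallest p are used so the G2HC test remains defined.
#'
#' Failure to reach separation within the budget is not an error: the
#' report is returned flagged `separated = FALSE`.
#'
#' @param mat genes x samples matrix.
#' @param labels test/control labels per sample.
#' @param min_group_size smallest admissible group size (at least 4).
#' @param max_removals pruning budget.
#' @param p_cut,lfc_cut provisional DEG criterion.
#' @param fallback_n genes used when no provisional DEG passes.
#' @return list of class `separation_report`: `pc_variance_fractions`,
#'   `pc1_score`, `g2hc_separated`, `separated`, `pruned_samples`,
#'   `final_sizes`, plus `exprs` and `labels` for the reduced data.
#' @export
prune_samples <- function(mat, labels, min_group_size = 4,
                          max_removals = Inf, p_cut = 0.01, lfc_cut = 1,
                          fallback_n = 100) {
  stopifnot(min_group_size >= 4, length(labels) == ncol(mat))
  labels <- as.character(labels)
  pruned <- character(0)

  provisional_degs <- function(m, l) {
    tab <- fit_differential(m, l, method = "ordinary_t")
    sel <- tab$gene[tab$p < p_cut & abs(tab$log2fc) > lfc_cut]
    if (length(sel) == 0)
      sel <- tab$gene[order(tab$p)][seq_len(min(fallback_n, nrow(tab)))]
    sel
  }
  evaluate <- function(m, l) {
    pc <- pca_projection(m, n_components = min(5, ncol(m) - 1))
    sc <- separation_score(pc$scores[, 1], l)
    degs <- provisional_degs(m, l)
    g2 <- g2hc_separation(m, degs, l)
    list(pc = pc, score = sc, g2hc = g2)
  }

  repeat {
    ev <- evaluate(mat, labels)
    if (ev$score >= 1 && ev$g2hc) break
    sizes <- table(labels)
    removable <- colnames(mat)[sizes[labels] > min_group_size]
    if (length(removable) == 0 || length(pruned) >= max_removals) break
    cand <- sort(removable)
    gain <- vapply(cand, function(s) {
      keep <- colnames(mat) != s
      pc <- pca_projection(mat[, keep, drop = FALSE],
                           n_components = 1)
      separation_score(pc$scores[, 1], labels[keep])
    }, numeric(1))
    drop_s <- cand[which.max(gain)]   # which.max takes first tie, cand sorted
    keep <- colnames(mat) != drop_s
    mat <- mat[, keep, drop = FALSE]
    labels <- labels[keep]
    pruned <- c(pruned, drop_s)
  }

  ev <- evaluate(mat, labels)
  structure(list(
    pc_variance_fractions = ev$pc$variance_fractions,
    pc1_score = ev$score,
    g2hc_separated = ev$g2hc,
    separated = ev$score >= 1 && ev$g2hc,
    pruned_samples = pruned,
    final_sizes = c(n_test = sum(labels == "test"),
                    n_control = sum(labels == "control")),
    exprs = mat, labels = labels), class = "separation_report")
}

#' @export
print.separation_report <- function(x, ...) {
  cat("Separation report\n")
  cat("  PC variance fractions:",
      paste(sprintf("%.2f%%", 100 * x$pc_variance_fractions), collapse = ", "),
      "\n")
  cat("  PC1 score:", format(x$pc1_score), " G2HC separated:",
      x$g2hc_separated, "\n")
  cat("  pruned:", if (length(x$pruned_samples))
    paste(x$pruned_samples, collapse = ", ") else "(none)", "\n")
  cat("  final sizes: test =", x$final_sizes[["n_test"]],
      ", control =", x$final_sizes[["n_control"]], "\n")
  invisible(x)
}
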