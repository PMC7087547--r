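# Differential expression: per-gene test-minus-control log2 fold change
# with either an ordinary pooled-variance t or a moderated (empirical
# Bayes, via limma) t, Benjamini-Hochberg FDR, and the strict
# FDR-and-fold-change selection criterion.

#' Per-gene two-sample differential expression
#'
#' `log2fc` is always `mean(test) - mean(control)` on the log2-scale input.
#' `"moderated_t"` (the default, matching the original LIMMA-based
#' screening) shrinks per-gene variances toward a moment-matched prior via
#' [limma::eBayes()] before the t computation; `"ordinary_t"` is a plain
#' pooled-variance two-sample t retained as an oracle route. For a
#' zero-variance gene under `"ordinary_t"` the p-value is set to its limit
#' (0 if the means differ, 1 otherwise) with a warning.
#'
#' @param mat genes x samples matrix of log2 expression.
#' @param labels per-sample labels, `"test"` / `"control"`, at least 2 each.
#' @param method `"moderated_t"` or `"ordinary_t"`.
#' @return data.frame with columns `gene`, `log2fc`, `stat`, `p`, `fdr`,
#'   `direction` (`"up"` iff `log2fc > 0`), sorted by `fdr` ascending, ties
#'   by `|log2fc|` descending then gene id.
#' @export
fit_differential <- function(mat, labels,
                             method = c("moderated_t", "ordinary_t")) {
  method <- match.arg(method)
  stopifnot(is.matrix(mat), length(labels) == ncol(mat))
  labels <- as.character(labels)
  if (!all(labels %in% c("test", "control")))
    stop("labels must be 'test' or 'control'")
  n_t <- sum(labels == "test"); n_c <- sum(labels == "control")
  if (n_t < 2 || n_c < 2) stop("need at least 2 samples per group")

  tmat <- mat[, labels == "test", drop = FALSE]
  cmat <- mat[, labels == "control", drop = FALSE]
  lfc <- rowMeans(tmat) - rowMeans(cmat)

  if (method == "ordinary_t") {
    v_t <- apply(tmat, 1, var)
    v_c <- apply(cmat, 1, var)
    df <- n_t + n_c - 2
    sp2 <- ((n_t - 1) * v_t + (n_c - 1) * v_c) / df
    se <- sqrt(sp2 * (1 / n_t + 1 / n_c))
    stat <- lfc / se
    p <- 2 * pt(-abs(stat), df)
    zv <- se == 0
    if (any(zv)) {
      warning(sum(zv), " zero-variance gene(s) under ordinary_t; ",
              "p set to limiting value")
      p[zv] <- ifelse(lfc[zv] != 0, 0, 1)
      stat[zv] <- ifelse(lfc[zv] != 0, sign(lfc[zv]) * Inf, 0)
    }
  } else {
    design <- cbind(intercept = 1, test = as.integer(labels == "test"))
    fit <- limma::lmFit(mat, design)
    fit <- limma::eBayes(fit)
    stat <- fit$t[, "test"]
    p <- fit$p.value[, "test"]
    lfc <- fit$coefficients[, "test"]
  }

  out <- data.frame(gene = rownames(mat), log2fc = unname(lfc),
                    stat = unname(stat), p = unname(p),
                    fdr = bh_fdr(unname(p)),
                    direction = ifelse(lfc > 0, "up", "down"),
                    stringsAsFactors = FALSE)
  out <- out[order(out$fdr, -abs(out$log2fc), out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Benjamini-Hochberg step-up FDR adjustment
#'
#' `adj[i] = min_{j: p(j) >= p(i)} min(1, m * p(j) / rank(j))` -- the
#' classical step-up construction with enforced monotonicity, returned in
#' the input order.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return adjusted values in `[0, 1]`, same length and order.
#' @export
bh_fdr <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (any(is.na(p)) || any(p < 0) || any(p > 1))
    stop("p-values must be in [0, 1] and non-missing")
  m <- length(p)
  o <- order(p)
  adj <- pmin(1, rev(cummin(rev(p[o] * m / seq_len(m)))))
  out <- numeric(m)
  out[o] <- adj
  out
}

#' Select differentially expressed genes
#'
#' Strict inequalities, mirroring the screening criterion
#' `FDR < fdr_threshold` and `|log2FC| > lfc_threshold`.
#'
#' @param table a data.frame from [fit_differential()].
#' @param fdr_threshold FDR cutoff (strict `<`).
#' @param lfc_threshold absolute log2 fold-change cutoff (strict `>`).
#' @return the selected rows of `table` (possibly zero rows).
#' @export
select_degs <- function(table, fdr_threshold, lfc_threshold = 1) {
  stopifnot(fdr_threshold > 0, lfc_threshold >= 0)
  sel <- table[table$fdr < fdr_threshold &
                 abs(table$log2fc) > lfc_threshold, , drop = FALSE]
  rownames(sel) <- NULL
  sel
}
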