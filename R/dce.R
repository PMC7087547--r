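# Differential co-expression. Within each cohort, gene expression is
# standardized gene-wise ("t-scores": mean 0, unit sample sd). The
# regression slope between two standardized genes equals their Pearson
# correlation r; each r is Fisher-z transformed and the pairwise
# difference between cohorts is scored by the heterogeneity statistic
#
#   Q = (n_t - 3) (z_t - [z])^2 + (n_c - 3) (z_c - [z])^2,
#
# where [z] is an average over pairs. Pairs in the top quantile of Q
# (default 0.1%) are the differentially co-expressed (DCE) pairs, labelled
# GOC (gain of co-expression) when r_t > r_c and LOC (loss) when r_t < r_c.

#' Standardize a cohort submatrix gene-wise
#'
#' Centers and scales every gene (row) to mean 0 and unit sample standard
#' deviation (n - 1 denominator) within the cohort. Zero-variance genes
#' cannot be standardized: they are excluded with a warning and recorded in
#' the `excluded` attribute.
#'
#' @param mat genes x samples matrix for one cohort.
#' @return the standardized matrix (possibly fewer rows), with attribute
#'   `excluded` listing dropped gene ids.
#' @export
standardize_cohort <- function(mat) {
  stopifnot(is.matrix(mat), ncol(mat) >= 2)
  mu <- rowMeans(mat)
  s <- apply(mat, 1, sd)
  zv <- s == 0 | is.na(s)
  if (any(zv))
    warning(sum(zv), " zero-variance gene(s) excluded from pairing")
  out <- (mat[!zv, , drop = FALSE] - mu[!zv]) / s[!zv]
  attr(out, "excluded") <- rownames(mat)[zv]
  out
}

#' Pairwise correlations of standardized genes
#'
#' For gene-wise standardized rows the Pearson correlation is
#' `sum(x_i * x_j) / (n - 1)`, which also equals the regression slope of
#' one standardized gene on the other. Values are clipped to
#' `1 - 1e-12` in absolute value so the Fisher z transform stays finite
#' for degenerate duplicate genes.
#'
#' @param std_mat standardized matrix from [standardize_cohort()].
#' @param pairs optional two-column matrix/data.frame of gene ids; if
#'   omitted, all unordered pairs are returned.
#' @return data.frame with columns `gene_i`, `gene_j`, `r`.
#' @export
pair_correlation <- function(std_mat, pairs = NULL) {
  stopifnot(is.matrix(std_mat), ncol(std_mat) >= 4)
  n <- ncol(std_mat)
  if (is.null(pairs)) {
    idx <- which(upper.tri(diag(nrow(std_mat))), arr.ind = TRUE)
    r <- tcrossprod(std_mat)[idx] / (n - 1)
    out <- data.frame(gene_i = rownames(std_mat)[idx[, 1]],
                      gene_j = rownames(std_mat)[idx[, 2]],
                      r = clip_r(r), stringsAsFactors = FALSE)
  } else {
    gi <- as.character(pairs[[1]]); gj <- as.character(pairs[[2]])
    a <- std_mat[gi, , drop = FALSE]; b <- std_mat[gj, , drop = FALSE]
    out <- data.frame(gene_i = gi, gene_j = gj,
                      r = clip_r(rowSums(a * b) / (n - 1)),
                      stringsAsFactors = FALSE)
  }
  out
}

clip_r <- function(r, eps = 1e-12) pmin(pmax(r, -(1 - eps)), 1 - eps)

#' Fisher z transform
#'
#' `z = (1/2) log((1 + r) / (1 - r)) = arctanh(r)`; odd and strictly
#' increasing on (-1, 1).
#'
#' @param r correlation(s), strictly inside (-1, 1).
#' @return z value(s).
#' @export
fisher_z <- function(r) {
  if (any(abs(r) >= 1)) stop("|r| must be < 1 for the Fisher z transform")
  atanh(r)
}

#' Heterogeneity Q statistic for one gene pair
#'
#' `Q = (n_t - 3) (z_t - z_bar)^2 + (n_c - 3) (z_c - z_bar)^2`.
#'
#' @param z_t,z_c Fisher z of the within-cohort correlations (vectorized).
#' @param n_t,n_c cohort sizes (at least 4).
#' @param z_bar the pooled mean z (see [mean_z()]); scalar or vector.
#' @return Q value(s), non-negative.
#' @export
q_statistic <- function(z_t, z_c, n_t, n_c, z_bar) {
  stopifnot(n_t >= 4, n_c >= 4)
  (n_t - 3) * (z_t - z_bar)^2 + (n_c - 3) * (z_c - z_bar)^2
}

#' Mean z over pairs
#'
#' Two pooling modes for the `[z]` entering the Q statistic:
#' `"global"` -- a single arithmetic mean over all `z_t` and `z_c` values of
#' all pairs (the literal reading of "averaged over all pairs");
#' `"per_pair_weighted"` -- the classical heterogeneity form
#' `((n_t - 3) z_t + (n_c - 3) z_c) / (n_t + n_c - 6)`, one value per pair.
#'
#' @param z_t,z_c Fisher z vectors over pairs.
#' @param n_t,n_c cohort sizes.
#' @param pooling `"global"` or `"per_pair_weighted"`.
#' @return a scalar (global) or per-pair vector (weighted).
#' @export
mean_z <- function(z_t, z_c, n_t, n_c,
                   pooling = c("global", "per_pair_weighted")) {
  pooling <- match.arg(pooling)
  if (length(z_t) == 0) stop("no z values")
  if (pooling == "global") mean(c(z_t, z_c))
  else ((n_t - 3) * z_t + (n_c - 3) * z_c) / ((n_t - 3) + (n_c - 3))
}

#' Gain/loss-of-co-expression label
#'
#' `"GOC"` iff `r_t > r_c`, `"LOC"` iff `r_t < r_c`. Exact ties cannot be
#' labelled and yield `NA` with a warning (such pairs are dropped upstream).
#'
#' @param r_t,r_c within-cohort correlations (vectorized).
#' @return character vector of `"GOC"` / `"LOC"` (NA on ties).
#' @export
classify_goc_loc <- function(r_t, r_c) {
  out <- ifelse(r_t > r_c, "GOC", ifelse(r_t < r_c, "LOC", NA_character_))
  if (anyNA(out)) warning(sum(is.na(out)), " tied pair(s) (r_t == r_c) dropped")
  out
}

#' Number of pairs retained by a top-quantile selection
#'
#' `floor(fraction * choose(n_genes, 2))` -- e.g. all unordered pairs of
#' 21,765 genes at the default 0.1% retain 236,846 pairs.
#'
#' @param n_genes gene count.
#' @param fraction selection quantile.
#' @return integer-valued count.
#' @export
top_fraction_count <- function(n_genes, fraction = 0.001) {
  floor(fraction * choose(n_genes, 2))
}

#' Select the top-quantile pairs by Q
#'
#' Keeps the `k = floor(fraction * P)` pairs of largest `q` out of the
#' `P` supplied pairs. The ordering is total -- `q` descending, ties broken
#' by (`gene_i`, `gene_j`) lexicographic order -- so the result is invariant
#' to the input order. The smallest selected `q` is recorded as
#' `q_threshold`.
#'
#' @param pairs data.frame with columns `gene_i`, `gene_j`, `q` (and
#'   typically `r_t`, `r_c`, `z_t`, `z_c`, `class`).
#' @param fraction selection quantile (default 0.001, i.e. top 0.1%).
#' @param total_pairs the population size P; defaults to `nrow(pairs)`
#'   (override when `pairs` is already a pre-screened subset).
#' @return the selected rows sorted by decreasing `q`, with attributes
#'   `q_threshold`, `fraction`, `n_pairs_total`.
#' @export
select_dce <- function(pairs, fraction = 0.001, total_pairs = nrow(pairs)) {
  stopifnot(fraction > 0, fraction < 1)
  k <- floor(fraction * total_pairs)
  if (k == 0) {
    warning("selection fraction retains zero pairs")
    out <- pairs[0, , drop = FALSE]
    attr(out, "q_threshold") <- NA_real_
  } else {
    o <- order(-pairs$q, pairs$gene_i, pairs$gene_j)
    out <- pairs[o[seq_len(min(k, nrow(pairs)))], , drop = FALSE]
    rownames(out) <- NULL
    attr(out, "q_threshold") <- min(out$q)
  }
  attr(out, "fraction") <- fraction
  attr(out, "n_pairs_total") <- total_pairs
  out
}

#' All-pairs differential co-expression analysis
#'
#' The end-to-end operation: standardize each cohort, compute all
#' unordered-pair correlations in both cohorts, Fisher-z transform, pool
#' the mean `[z]`, score every pair with the heterogeneity Q statistic and
#' keep the top `fraction` with GOC/LOC labels. Exactly tied pairs
#' (`r_t == r_c`) are excluded from candidacy.
#'
#' Computation is blocked (tiles of `block_size` genes) so memory stays
#' bounded; results are identical to the naive double loop because the
#' selection comparator is a total order maintained across blocks.
#'
#' @param mat genes x samples matrix (log2 expression).
#' @param labels per-sample `"test"` / `"control"` labels.
#' @param fraction selection quantile (default 0.001).
#' @param pooling `[z]` pooling mode, see [mean_z()].
#' @param block_size tile size in genes.
#' @return object of class `dce_result`: data.frame with columns `gene_i`,
#'   `gene_j`, `r_t`, `r_c`, `z_t`, `z_c`, `q`, `class`, plus a `context`
#'   attribute (list: `n_t`, `n_c`, `z_bar` (NA for per-pair pooling),
#'   `q_threshold`, `fraction`, `pooling`, `n_pairs_total`,
#'   `excluded_genes`).
#' @export
dce_pairs <- function(mat, labels, fraction = 0.001,
                      pooling = c("global", "per_pair_weighted"),
                      block_size = 512) {
  pooling <- match.arg(pooling)
  stopifnot(is.matrix(mat), length(labels) == ncol(mat),
            fraction > 0, fraction < 1, block_size >= 2)
  labels <- as.character(labels)
  n_t <- sum(labels == "test"); n_c <- sum(labels == "control")
  if (n_t < 4 || n_c < 4) stop("need at least 4 samples per cohort")

  st <- standardize_cohort(mat[, labels == "test", drop = FALSE])
  sc <- standardize_cohort(mat[, labels == "control", drop = FALSE])
  excluded <- union(attr(st, "excluded"), attr(sc, "excluded"))
  genes <- intersect(rownames(st), rownames(sc))
  st <- st[genes, , drop = FALSE]
  sc <- sc[genes, , drop = FALSE]
  G <- length(genes)
  if (G < 2) stop("fewer than 2 usable genes")

  starts <- seq(1, G, by = block_size)
  blocks <- lapply(starts, function(s) s:min(s + block_size - 1, G))

  block_r <- function(bi, bj) {
    I <- blocks[[bi]]; J <- blocks[[bj]]
    rt <- clip_r(tcrossprod(st[I, , drop = FALSE],
                            st[J, , drop = FALSE]) / (n_t - 1))
    rc <- clip_r(tcrossprod(sc[I, , drop = FALSE],
                            sc[J, , drop = FALSE]) / (n_c - 1))
    if (bi == bj) {
      idx <- which(upper.tri(rt), arr.ind = TRUE)
    } else {
      idx <- as.matrix(expand.grid(seq_along(I), seq_along(J)))
    }
    list(i = I[idx[, 1]], j = J[idx[, 2]],
         r_t = rt[idx], r_c = rc[idx])
  }

  P <- choose(G, 2)
  z_bar <- NA_real_
  if (pooling == "global") {
    zsum <- 0
    for (bi in seq_along(blocks)) for (bj in bi:length(blocks)) {
      b <- block_r(bi, bj)
      zsum <- zsum + sum(atanh(b$r_t)) + sum(atanh(b$r_c))
    }
    z_bar <- zsum / (2 * P)
  }

  k <- floor(fraction * P)
  pool <- NULL
  for (bi in seq_along(blocks)) for (bj in bi:length(blocks)) {
    b <- block_r(bi, bj)
    zt <- atanh(b$r_t); zc <- atanh(b$r_c)
    zb <- if (pooling == "global") z_bar
          else mean_z(zt, zc, n_t, n_c, "per_pair_weighted")
    q <- q_statistic(zt, zc, n_t, n_c, zb)
    df <- data.frame(gene_i = genes[b$i], gene_j = genes[b$j],
                     r_t = b$r_t, r_c = b$r_c, z_t = zt, z_c = zc, q = q,
                     stringsAsFactors = FALSE)
    swap <- df$gene_i > df$gene_j
    if (any(swap)) {  # keep gene_i < gene_j lexicographically
      tmp <- df$gene_i[swap]
      df$gene_i[swap] <- df$gene_j[swap]; df$gene_j[swap] <- tmp
    }
    df <- df[df$r_t != df$r_c, , drop = FALSE]  # exact ties never labelled
    pool <- rbind(pool, df)
    if (nrow(pool) > k) {
      o <- order(-pool$q, pool$gene_i, pool$gene_j)
      pool <- pool[o[seq_len(k)], , drop = FALSE]
    }
  }
  if (k == 0) warning("selection fraction retains zero pairs")
  pool <- pool[order(-pool$q, pool$gene_i, pool$gene_j), , drop = FALSE]
  rownames(pool) <- NULL
  pool$class <- classify_goc_loc(pool$r_t, pool$r_c)

  structure(pool, class = c("dce_result", "data.frame"),
            context = list(n_t = n_t, n_c = n_c, z_bar = z_bar,
                           q_threshold = if (nrow(pool)) min(pool$q)
                                         else NA_real_,
                           fraction = fraction, pooling = pooling,
                           n_pairs_total = P,
                           excluded_genes = excluded))
}

#' Context of a differential co-expression analysis
#'
#' @param x a `dce_result` from [dce_pairs()].
#' @return the context list (cohort sizes, `z_bar`, `q_threshold`,
#'   `fraction`, pooling mode, total pair count, excluded genes).
#' @export
dce_context <- function(x) attr(x, "context")

#' Write a DCE pair table and its context
#'
#' @param x a `dce_result`.
#' @param path TSV path for the pair table.
#' @param context_path optional JSON path for the context.
#' @export
write_dce <- function(x, path, context_path = NULL) {
  write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  if (!is.null(context_path)) {
    ctx <- dce_context(x)
    ctx$excluded_genes <- as.list(ctx$excluded_genes)
    jsonlite::write_json(ctx, context_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}
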