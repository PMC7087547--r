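# Gene-set over-representation by one-sided Fisher's exact test
# (hypergeometric upper tail). The original workflow called significance
# at raw p < 0.05 without multiplicity correction; a BH-adjusted column is
# emitted alongside for users but plays no role in the calls.

#' One-sided Fisher's exact over-representation test
#'
#' Both the query and the set are intersected with the universe before
#' counting. With `N` universe genes, `K` set members, `n` query genes and
#' `k` in the overlap, the p-value is the hypergeometric upper tail
#' `P(X >= k)`.
#'
#' @param query_genes character vector of query gene ids.
#' @param set_members character vector of set member ids.
#' @param universe character vector defining the background.
#' @return list: `overlap_genes`, `k`, `K`, `n`, `N`, `p`.
#' @export
fisher_enrich <- function(query_genes, set_members, universe) {
  universe <- unique(as.character(universe))
  if (length(universe) == 0) stop("empty universe")
  q <- intersect(unique(as.character(query_genes)), universe)
  if (length(q) == 0) stop("empty query after intersection with universe")
  s <- intersect(unique(as.character(set_members)), universe)
  ov <- intersect(q, s)
  k <- length(ov); K <- length(s); n <- length(q); N <- length(universe)
  p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  list(overlap_genes = sort(ov), k = k, K = K, n = n, N = N, p = p)
}

#' Enrichment of a query set across a gene-set collection
#'
#' One [fisher_enrich()] per set, ranked by ascending p (ties by set
#' name). Significance is called at the raw `alpha` -- no multiple-testing
#' correction, mirroring the original procedure -- while a BH-adjusted
#' `p_bh` column is reported for reference. `disruption_type` tags the
#' query's provenance: 1 for a DEG query, 2 for an IGN/xIGN query.
#'
#' @param query_genes character vector of query gene ids.
#' @param collection named list of gene sets (see [read_gmt()]).
#' @param universe background gene ids.
#' @param alpha raw significance level (default 0.05).
#' @param disruption_type 1 (DEG query) or 2 (network query), or NA.
#' @return data.frame: `set_name`, `k`, `K`, `n`, `N`, `p`, `p_bh`,
#'   `significant`, `disruption_type`, `overlap_genes` (comma-joined),
#'   sorted by p then set name.
#' @export
enrich_collection <- function(query_genes, collection, universe,
                              alpha = 0.05, disruption_type = NA) {
  stopifnot(is.list(collection), !is.null(names(collection)))
  res <- lapply(names(collection), function(nm) {
    e <- fisher_enrich(query_genes, collection[[nm]], universe)
    data.frame(set_name = nm, k = e$k, K = e$K, n = e$n, N = e$N, p = e$p,
               overlap_genes = paste(e$overlap_genes, collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$p_bh <- bh_fdr(out$p)
  out$significant <- out$p < alpha
  out$disruption_type <- disruption_type
  out <- out[order(out$p, out$set_name),
             c("set_name", "k", "K", "n", "N", "p", "p_bh", "significant",
               "disruption_type", "overlap_genes")]
  rownames(out) <- NULL
  out
}

#' Enrichment of curated gene sets in a known-target list
#'
#' For each curated set (e.g. the DEG / IGN / xIGN set of each case) the
#' over-representation of the known-target list is measured with
#' [fisher_enrich()] and reported as `-log10(p)` -- the histogram-matrix
#' view of how strongly each curated set overlaps the targets.
#'
#' @param curated_sets either a flat named list of gene vectors, or a
#'   two-level list `curated_sets[[case]][[kind]]` which is returned as a
#'   kind x case matrix.
#' @param target_list non-empty character vector of known target genes.
#' @param universe background gene ids.
#' @return a named numeric vector (flat input) or matrix (nested input) of
#'   `-log10(p)`.
#' @export
known_target_enrichment <- function(curated_sets, target_list, universe) {
  if (length(target_list) == 0) stop("target_list is empty")
  one <- function(genes) {
    -log10(fisher_enrich(genes, target_list, universe)$p)
  }
  nested <- is.list(curated_sets[[1]])
  if (!nested)
    return(vapply(curated_sets, one, numeric(1)))
  kinds <- names(curated_sets[[1]])
  out <- sapply(curated_sets, function(case) {
    vapply(kinds, function(kk) one(case[[kk]]), numeric(1))
  })
  out <- matrix(out, nrow = length(kinds),
                dimnames = list(kinds, names(curated_sets)))
  out
}
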