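# Synthetic-data generator. The stated world it emulates: two cohorts of
# ~8-23 microarray samples, thousands of genes on the log2 scale, a minority
# of genes with a planted expression shift (|log2FC| > 1, predominantly
# down-regulated, 7:3 down:up as observed in the aging cohort), a planted
# set of gene pairs whose within-cohort correlation differs between cohorts
# (both gain and loss of co-expression), a PPI graph covering a chosen
# fraction of those pairs, and pathway gene sets enriched for planted
# signal.

#' Simulation configuration
#'
#' Describes one synthetic test/control case. Defaults are the package's
#' stated world (see the methods vignette): baseline expression uniform on
#' 4--12 log2 units, residual noise sd 0.5, planted shift magnitude 2 log2
#' units with a 7:3 down:up mix, planted pair correlations 0.8 versus 0.0
#' with alternating orientation so both gain (GOC) and loss (LOC) of
#' co-expression are planted.
#'
#' @param n_genes number of genes.
#' @param n_test,n_control cohort sizes (each at least 4).
#' @param de_fraction proportion of genes with a planted expression shift.
#' @param de_lfc planted log2 fold change. Its magnitude is the shift size;
#'   down-regulated genes receive `-abs(de_lfc)`, up-regulated `+abs(de_lfc)`.
#' @param n_dce_pairs number of planted differentially co-expressed pairs;
#'   pairs use disjoint genes, so at most `floor(n_genes / 2)`.
#' @param r_test,r_control target within-cohort population correlations for
#'   planted pairs; recycled across pairs, so vectors may be supplied (the
#'   defaults alternate 0.8/0.0 with 0.0/0.8, planting both GOC and LOC).
#' @param noise_sd residual standard deviation, log2 units.
#' @param down_up_ratio proportion of planted shifted genes that are
#'   down-regulated.
#' @param seed RNG seed.
#' @param de_genes optional explicit gene ids to receive the planted shift
#'   (overrides random selection; length must equal
#'   `round(de_fraction * n_genes)` unless `de_fraction` is left at its
#'   default, in which case the explicit list wins).
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_genes = 2000, n_test = 10, n_control = 10,
                       de_fraction = 0.05, de_lfc = 2,
                       n_dce_pairs = 20,
                       r_test = c(0.8, 0.0), r_control = c(0.0, 0.8),
                       noise_sd = 0.5, down_up_ratio = 0.7,
                       seed = 1L, de_genes = NULL) {
  stopifnot(n_genes >= 2, de_fraction >= 0, de_fraction <= 1,
            noise_sd > 0, down_up_ratio >= 0, down_up_ratio <= 1,
            all(abs(r_test) < 1), all(abs(r_control) < 1))
  if (n_test < 4 || n_control < 4)
    stop("cohort sizes must be at least 4")
  if (n_dce_pairs > floor(n_genes / 2))
    stop("n_dce_pairs exceeds floor(n_genes/2) = ", floor(n_genes / 2))
  structure(list(n_genes = as.integer(n_genes),
                 n_test = as.integer(n_test),
                 n_control = as.integer(n_control),
                 de_fraction = de_fraction, de_lfc = de_lfc,
                 n_dce_pairs = as.integer(n_dce_pairs),
                 r_test = r_test, r_control = r_control,
                 noise_sd = noise_sd, down_up_ratio = down_up_ratio,
                 seed = as.integer(seed), de_genes = de_genes),
            class = "sim_config")
}

#' Generate one synthetic test/control case
#'
#' Expression is `baseline + planted shift + noise` on the log2 scale, with
#' homoscedastic Gaussian noise. Planted co-expressed pairs share a latent
#' factor with cohort-specific loadings chosen so the induced population
#' correlation equals the configured `r_test` / `r_control` exactly: for a
#' target correlation rho, each member is
#' `sqrt(|rho|) * f + sqrt(1 - |rho|) * e` (the second member's loading
#' carries `sign(rho)`), scaled by `noise_sd`. Output is byte-identical for
#' identical configurations (the seed is part of the configuration).
#'
#' @param config a [sim_config()].
#' @param case case label written into the metadata.
#' @return list with elements `exprs` (genes x samples matrix),
#'   `metadata` (sample_id/group/case data.frame) and `truth`
#'   (class `truth_record`: `de_genes` data.frame of gene and planted lfc,
#'   `dce_pairs` data.frame of gene_i, gene_j, r_test, r_control, class,
#'   `null_genes`, `genes`).
#' @export
generate_case <- function(config, case = "CASE") {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  G <- config$n_genes
  genes <- sprintf("G%05d", seq_len(G))
  n_t <- config$n_test; n_c <- config$n_control
  n <- n_t + n_c
  samples <- c(sprintf("T%02d", seq_len(n_t)), sprintf("C%02d", seq_len(n_c)))
  group <- rep(c("test", "control"), c(n_t, n_c))

  baseline <- runif(G, 4, 12)
  mat <- matrix(rnorm(G * n, 0, config$noise_sd), G, n,
                dimnames = list(genes, samples))

  # ---- planted differential co-expression -------------------------------
  k <- config$n_dce_pairs
  dce_pairs <- data.frame(gene_i = character(0), gene_j = character(0),
                          r_test = numeric(0), r_control = numeric(0),
                          class = character(0), stringsAsFactors = FALSE)
  if (k > 0) {
    pg <- sample(genes, 2L * k)
    gi <- pg[seq(1, 2 * k, by = 2)]
    gj <- pg[seq(2, 2 * k, by = 2)]
    rt <- rep_len(config$r_test, k)
    rc <- rep_len(config$r_control, k)
    tie <- rt == rc
    if (any(tie)) stop("planted pairs must have r_test != r_control")
    for (p in seq_len(k)) {
      rows <- c(match(gi[p], genes), match(gj[p], genes))
      for (coh in c("test", "control")) {
        cols <- which(group == coh)
        rho <- if (coh == "test") rt[p] else rc[p]
        f <- rnorm(length(cols))
        e1 <- rnorm(length(cols)); e2 <- rnorm(length(cols))
        a <- sqrt(abs(rho)); b <- sqrt(1 - abs(rho))
        mat[rows[1], cols] <- config$noise_sd * (a * f + b * e1)
        mat[rows[2], cols] <- config$noise_sd * (sign(rho) * a * f + b * e2)
        if (rho == 0)  # sign(0) = 0 would zero the factor loading
          mat[rows[2], cols] <- config$noise_sd * (a * f * 0 + b * e2)
      }
    }
    ord <- gi > gj
    tmp <- gi[ord]; gi[ord] <- gj[ord]; gj[ord] <- tmp
    dce_pairs <- data.frame(gene_i = gi, gene_j = gj, r_test = rt,
                            r_control = rc,
                            class = ifelse(rt > rc, "GOC", "LOC"),
                            stringsAsFactors = FALSE)
    dce_pairs <- dce_pairs[order(dce_pairs$gene_i, dce_pairs$gene_j), ,
                           drop = FALSE]
    rownames(dce_pairs) <- NULL
  }

  # ---- planted differential expression ----------------------------------
  n_de <- round(config$de_fraction * G)
  de_genes <- data.frame(gene = character(0), lfc = numeric(0),
                         stringsAsFactors = FALSE)
  if (!is.null(config$de_genes)) {
    dg <- as.character(config$de_genes)
    if (!all(dg %in% genes)) stop("explicit de_genes not all in gene universe")
    n_de <- length(dg)
  } else if (n_de > 0) {
    dg <- sample(genes, n_de)
  } else dg <- character(0)
  if (n_de > 0) {
    n_down <- round(config$down_up_ratio * n_de)
    sgn <- rep(c(-1, 1), c(n_down, n_de - n_down))
    lfc <- sgn * abs(config$de_lfc)
    shift_rows <- match(dg, genes)
    mat[shift_rows, group == "test"] <-
      mat[shift_rows, group == "test"] + lfc
    de_genes <- data.frame(gene = dg, lfc = lfc, stringsAsFactors = FALSE)
    de_genes <- de_genes[order(de_genes$gene), , drop = FALSE]
    rownames(de_genes) <- NULL
  }

  mat <- mat + baseline
  planted <- union(de_genes$gene, c(dce_pairs$gene_i, dce_pairs$gene_j))
  truth <- structure(list(de_genes = de_genes, dce_pairs = dce_pairs,
                          null_genes = setdiff(genes, planted),
                          genes = genes),
                     class = "truth_record")
  metadata <- data.frame(sample_id = samples, group = group, case = case,
                         stringsAsFactors = FALSE)
  list(exprs = mat, metadata = metadata, truth = truth)
}

#' Generate a synthetic protein-protein interaction graph
#'
#' Builds a simple undirected graph over the case's gene universe in which
#' exactly `round(dce_coverage * nrow(truth$dce_pairs))` planted
#' differentially co-expressed pairs appear as edges, plus
#' `background_edges` edges drawn uniformly from non-planted pairs.
#'
#' @param truth a `truth_record` from [generate_case()].
#' @param dce_coverage proportion of planted pairs to cover, in `[0, 1]`.
#' @param background_edges number of additional random (non-planted) edges.
#' @param seed RNG seed.
#' @return data.frame with columns `gene_i`, `gene_j` (lexicographically
#'   ordered, no self-loops, no duplicates).
#' @export
generate_ppi <- function(truth, dce_coverage = 0.5, background_edges = 100,
                         seed = 1L) {
  stopifnot(inherits(truth, "truth_record"),
            dce_coverage >= 0, dce_coverage <= 1, background_edges >= 0)
  set.seed(seed)
  genes <- truth$genes
  G <- length(genes)
  planted <- truth$dce_pairs
  n_planted <- nrow(planted)
  avail <- choose(G, 2) - n_planted
  if (background_edges > avail)
    stop("background_edges exceeds available non-planted pairs (", avail, ")")
  n_cov <- round(dce_coverage * n_planted)
  covered <- if (n_cov > 0) planted[sort(sample(n_planted, n_cov)), 1:2]
             else planted[0, 1:2]
  planted_keys <- pair_key(planted$gene_i, planted$gene_j)
  bg_i <- character(0); bg_j <- character(0)
  if (background_edges > 0) {
    seen <- character(0)
    while (length(bg_i) < background_edges) {
      need <- background_edges - length(bg_i)
      a <- genes[sample.int(G, 2 * need, replace = TRUE)]
      b <- genes[sample.int(G, 2 * need, replace = TRUE)]
      ok <- a != b
      a <- a[ok]; b <- b[ok]
      gi <- pmin(a, b); gj <- pmax(a, b)
      key <- paste(gi, gj, sep = "\r")
      keep <- !(key %in% planted_keys) & !(key %in% seen) & !duplicated(key)
      gi <- gi[keep]; gj <- gj[keep]; key <- key[keep]
      take <- seq_len(min(need, length(gi)))
      bg_i <- c(bg_i, gi[take]); bg_j <- c(bg_j, gj[take])
      seen <- c(seen, key[take])
    }
  }
  ppi <- data.frame(gene_i = c(covered$gene_i, bg_i),
                    gene_j = c(covered$gene_j, bg_j),
                    stringsAsFactors = FALSE)
  ppi <- ppi[order(ppi$gene_i, ppi$gene_j), , drop = FALSE]
  rownames(ppi) <- NULL
  ppi
}

#' Generate synthetic pathway gene sets
#'
#' Produces `n_sets` named gene sets. The first `n_signal_sets` sets are
#' "signal" sets drawing `round(signal_fraction * set_size)` members from
#' the planted differentially expressed genes and the remainder from null
#' genes; non-signal sets are drawn entirely from null genes (hence exactly
#' disjoint from the planted set).
#'
#' @param truth a `truth_record` from [generate_case()].
#' @param n_sets number of sets.
#' @param set_size members per set.
#' @param signal_fraction proportion of a signal set drawn from planted
#'   differentially expressed genes.
#' @param n_signal_sets how many of the sets carry signal (default 1).
#' @param seed RNG seed.
#' @return a named list of gene vectors (GMT-compatible, see [write_gmt()])
#'   with a `description` attribute.
#' @export
generate_gene_sets <- function(truth, n_sets = 10, set_size = 20,
                               signal_fraction = 0.5, n_signal_sets = 1,
                               seed = 1L) {
  stopifnot(inherits(truth, "truth_record"),
            signal_fraction >= 0, signal_fraction <= 1,
            n_signal_sets <= n_sets, set_size <= length(truth$genes))
  set.seed(seed)
  de <- truth$de_genes$gene
  nulls <- truth$null_genes
  n_sig_members <- round(signal_fraction * set_size)
  if (n_signal_sets > 0 && n_sig_members > length(de))
    stop("signal_fraction demands ", n_sig_members,
         " planted genes but only ", length(de), " exist")
  sets <- vector("list", n_sets)
  nm <- character(n_sets)
  for (s in seq_len(n_sets)) {
    if (s <= n_signal_sets) {
      sig <- sample(de, n_sig_members)
      fill <- sample(nulls, set_size - n_sig_members)
      sets[[s]] <- sort(c(sig, fill))
      nm[s] <- sprintf("SIG_%02d", s)
    } else {
      sets[[s]] <- sort(sample(nulls, set_size))
      nm[s] <- sprintf("NULL_%02d", s - n_signal_sets)
    }
  }
  names(sets) <- nm
  attr(sets, "description") <- setNames(
    ifelse(seq_len(n_sets) <= n_signal_sets, "signal set", "null set"), nm)
  sets
}
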