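# Config-driven orchestration: simulate_study() writes a complete
# on-disk synthetic study (expression + metadata TSVs per case, PPI TSV,
# GMT gene sets, known-target list, truth JSONs); run_pipeline() consumes
# such a study -- or real data laid out the same way -- and runs, per case,
# QC -> DEG -> DCE -> IGN -> xIGN -> enrichment, then the cross-case layer
# (known-target enrichment, overlap summaries, case clustering,
# disease-only hits, pathway augmentation re-enrichment), writing every
# artifact plus a manifest of content hashes. Identical config + seed
# gives identical hashes.

#' Default pipeline configuration for a synthetic study
#'
#' Four cases -- one aging-like control case (`AG`) and three disease-like
#' region cases (`HC`, `PC`, `SFG`) -- sharing one gene universe. The three
#' disease-like cases share a planted block of down-regulated genes absent
#' from `AG`, so the cross-case signature layer has a recoverable
#' disease-only ground truth. Case-level FDR thresholds default to the
#' published per-case values scaled to the synthetic world
#' (`fdr_threshold` 1e-3, `lfc_threshold` 1); degree thresholds default to
#' the published `>2` (aging-like) and `>3` (disease-like).
#'
#' @param seed integer seed controlling every random draw.
#' @param n_genes,n_test,n_control shared case dimensions.
#' @param dir study directory (created by [simulate_study()]).
#' @return a nested list understood by [simulate_study()] and
#'   [run_pipeline()].
#' @export
default_pipeline_config <- function(seed = 1L, n_genes = 600,
                                    n_test = 12, n_control = 12,
                                    dir = tempfile("idcenet_study_")) {
  cases <- list(
    AG  = list(kind = "aging",   fdr_threshold = 1e-3),
    HC  = list(kind = "disease", fdr_threshold = 1e-3),
    PC  = list(kind = "disease", fdr_threshold = 1e-3),
    SFG = list(kind = "disease", fdr_threshold = 1e-3))
  list(
    dir = dir, seed = as.integer(seed),
    n_genes = n_genes, n_test = n_test, n_control = n_control,
    cases = cases,
    lfc_threshold = 1,
    dce = list(fraction = 0.001, pooling = "global", block_size = 512),
    degree_threshold = c(aging = 2, disease = 3),
    qc = list(enabled = TRUE, max_removals = 2, min_group_size = 4),
    signature = list(required_group = c("HC", "PC", "SFG"), min_hits = 2,
                     excluded_cases = "AG", augment_set = "SIG_01"),
    sim = list(de_fraction = 0.05, de_lfc = 2, n_dce_pairs = 15,
               noise_sd = 0.5, down_up_ratio = 0.7,
               shared_disease_degs = 12, ppi_dce_coverage = 0.6,
               ppi_background_edges = 300, n_sets = 8, set_size = 20,
               signal_fraction = 0.6, n_known_targets = 25))
}

#' Read a pipeline configuration from YAML or JSON
#'
#' @param path a `.yaml`/`.yml` or `.json` file whose structure mirrors
#'   [default_pipeline_config()].
#' @return the configuration list.
#' @export
read_pipeline_config <- function(path) {
  if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Write a full synthetic study to disk
#'
#' Generates every input [run_pipeline()] needs: per-case expression and
#' metadata TSVs, a PPI edge list, a GMT pathway collection, a
#' known-target gene list and per-case truth JSONs. The disease-like cases
#' share a planted block of down-regulated genes that the aging-like case
#' never receives.
#'
#' @param config list from [default_pipeline_config()] (or compatible).
#' @return the study directory, invisibly; side effect: files on disk.
#' @export
simulate_study <- function(config = default_pipeline_config()) {
  dir <- config$dir
  if (dir.exists(dir) && length(list.files(dir)))
    stop("study directory already populated: ", dir)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sim <- config$sim
  set.seed(config$seed)
  genes <- sprintf("G%05d", seq_len(config$n_genes))
  n_de <- round(sim$de_fraction * config$n_genes)
  shared <- sample(genes, sim$shared_disease_degs)
  case_names <- names(config$cases)
  case_seeds <- sample.int(1e6, length(case_names) + 2)

  truths <- list()
  for (i in seq_along(case_names)) {
    cs <- case_names[i]
    kind <- config$cases[[cs]]$kind
    own_pool <- setdiff(genes, shared)
    n_own <- max(0, n_de - if (kind == "disease") length(shared) else 0)
    de <- if (kind == "disease") c(shared, sample(own_pool, n_own))
          else sample(own_pool, n_de)
    cfg <- sim_config(n_genes = config$n_genes, n_test = config$n_test,
                      n_control = config$n_control,
                      de_fraction = sim$de_fraction, de_lfc = sim$de_lfc,
                      n_dce_pairs = sim$n_dce_pairs,
                      noise_sd = sim$noise_sd,
                      down_up_ratio = if (kind == "disease") 1
                                      else sim$down_up_ratio,
                      seed = case_seeds[i], de_genes = de)
    case <- generate_case(cfg, case = cs)
    write_expression_matrix(case$exprs, file.path(dir, paste0(cs, "_exprs.tsv")))
    write_sample_metadata(case$metadata, file.path(dir, paste0(cs, "_meta.tsv")))
    write_truth(case$truth, file.path(dir, paste0(cs, "_truth.json")))
    truths[[cs]] <- case$truth
  }

  # one PPI graph over the shared universe, seeded from the first case
  ppi <- generate_ppi(truths[[1]], dce_coverage = sim$ppi_dce_coverage,
                      background_edges = sim$ppi_background_edges,
                      seed = case_seeds[length(case_names) + 1])
  # cover planted pairs of the remaining cases too
  for (cs in case_names[-1]) {
    pl <- truths[[cs]]$dce_pairs
    n_cov <- round(sim$ppi_dce_coverage * nrow(pl))
    if (n_cov > 0)
      ppi <- rbind(ppi, pl[seq_len(n_cov), c("gene_i", "gene_j")])
  }
  ppi <- canonical_pairs(ppi$gene_i, ppi$gene_j)
  write_ppi(ppi, file.path(dir, "ppi.tsv"))

  sets <- generate_gene_sets(truths[["HC"]], n_sets = sim$n_sets,
                             set_size = sim$set_size,
                             signal_fraction = sim$signal_fraction,
                             seed = case_seeds[length(case_names) + 2])
  write_gmt(sets, file.path(dir, "gene_sets.gmt"))

  target_pool <- unique(unlist(lapply(truths, function(t) t$de_genes$gene)))
  targets <- sort(sample(target_pool,
                         min(sim$n_known_targets, length(target_pool))))
  writeLines(targets, file.path(dir, "known_targets.txt"))

  cfg_path <- file.path(dir, "config.json")
  jsonlite::write_json(config, cfg_path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(dir)
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE))
}

#' Run the full multi-case workflow
#'
#' Per case: quality screening with greedy pruning (optional), moderated-t
#' differential expression with the case FDR threshold, all-pairs
#' differential co-expression with top-quantile Q selection, IGN
#' construction against the PPI reference, xIGN extension with iterative
#' degree filtering, and type-1 (DEG) / type-2 (IGN) pathway enrichment.
#' Cross-case: known-target enrichment of every curated set, per-case
#' DEG/IGN/xIGN overlap summaries, case clustering on DEG membership, the
#' disease-only signature rule, and re-enrichment after augmenting the
#' configured pathway with the novel hits. Every artifact is written under
#' `outdir` and listed, with its MD5 content hash, in
#' `manifest.json`.
#'
#' @param config configuration list (see [default_pipeline_config()]) or a
#'   path readable by [read_pipeline_config()]. `config$dir` must contain
#'   a study as laid out by [simulate_study()].
#' @param outdir output directory (default `<dir>/results`).
#' @return the manifest data.frame (artifact, path, md5), invisibly
#'   written to `manifest.json`.
#' @export
run_pipeline <- function(config, outdir = file.path(config$dir, "results")) {
  if (is.character(config)) config <- read_pipeline_config(config)
  dir <- config$dir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  set.seed(config$seed)
  artifacts <- character(0)
  emit <- function(obj, name, writer) {
    path <- file.path(outdir, name)
    writer(obj, path)
    artifacts[[name]] <<- path
    obj
  }
  write_tsv <- function(x, p) write.table(x, p, sep = "\t", quote = FALSE,
                                          row.names = FALSE)
  write_json_art <- function(x, p)
    jsonlite::write_json(x, p, auto_unbox = TRUE, digits = 12, null = "null")

  ppi <- stage("ppi", read_ppi(file.path(dir, "ppi.tsv")))
  sets <- stage("gene_sets", read_gmt(file.path(dir, "gene_sets.gmt")))
  targets <- readLines(file.path(dir, "known_targets.txt"))

  case_names <- names(config$cases)
  deg_sets <- list(); ign_sets <- list(); xign_sets <- list()
  curated <- list()
  for (cs in case_names) {
    exprs <- stage(paste0(cs, ":read"),
                   read_expression_matrix(file.path(dir, paste0(cs, "_exprs.tsv"))))
    meta <- read_sample_metadata(file.path(dir, paste0(cs, "_meta.tsv")))
    labels <- meta$group[match(colnames(exprs), meta$sample_id)]
    universe <- rownames(exprs)

    if (isTRUE(config$qc$enabled)) {
      rep <- stage(paste0(cs, ":qc"),
                   prune_samples(exprs, labels,
                                 min_group_size = config$qc$min_group_size,
                                 max_removals = config$qc$max_removals))
      emit(list(pc_variance_fractions = rep$pc_variance_fractions,
                pc1_score = rep$pc1_score,
                g2hc_separated = rep$g2hc_separated,
                separated = rep$separated,
                pruned_samples = as.list(rep$pruned_samples),
                final_sizes = as.list(rep$final_sizes)),
           paste0(cs, "_qc.json"), write_json_art)
      exprs <- rep$exprs; labels <- rep$labels
    }

    deg_tab <- stage(paste0(cs, ":deg"),
                     fit_differential(exprs, labels, method = "moderated_t"))
    emit(deg_tab, paste0(cs, "_deg_table.tsv"), write_tsv)
    degs <- select_degs(deg_tab, config$cases[[cs]]$fdr_threshold,
                        config$lfc_threshold)
    emit(degs, paste0(cs, "_degs.tsv"), write_tsv)

    dce <- stage(paste0(cs, ":dce"),
                 dce_pairs(exprs, labels, fraction = config$dce$fraction,
                           pooling = config$dce$pooling,
                           block_size = config$dce$block_size))
    emit(as.data.frame(dce), paste0(cs, "_dce_pairs.tsv"), write_tsv)
    ctx <- dce_context(dce)
    ctx$excluded_genes <- as.list(ctx$excluded_genes)
    emit(ctx, paste0(cs, "_dce_context.json"), write_json_art)

    ign <- stage(paste0(cs, ":ign"), build_ign(dce, ppi))
    kind <- config$cases[[cs]]$kind
    thr <- config$degree_threshold[[kind]]
    xign <- stage(paste0(cs, ":xign"),
                  filter_by_degree(extend_ign(ign, dce, ppi), thr))
    emit(ign$edges, paste0(cs, "_ign_edges.tsv"), write_tsv)
    emit(xign$edges, paste0(cs, "_xign_edges.tsv"), write_tsv)

    if (nrow(degs) > 0) {
      e1 <- stage(paste0(cs, ":enrich"),
                  enrich_collection(degs$gene, sets, universe,
                                    disruption_type = 1))
      emit(e1, paste0(cs, "_enrich_deg.tsv"), write_tsv)
    }
    if (length(ign$nodes) > 0) {
      e2 <- stage(paste0(cs, ":enrich"),
                  enrich_collection(ign$nodes, sets, universe,
                                    disruption_type = 2))
      emit(e2, paste0(cs, "_enrich_ign.tsv"), write_tsv)
    }

    deg_sets[[cs]] <- degs
    ign_sets[[cs]] <- ign$nodes
    xign_sets[[cs]] <- xign$nodes
    curated[[cs]] <- list(DEG = degs$gene, IGN = ign$nodes,
                          XIGN = xign$nodes)
    emit(as.data.frame(overlap_summary(degs$gene, ign$nodes, xign$nodes)),
         paste0(cs, "_overlap.tsv"),
         function(x, p) write.table(data.frame(region = rownames(x),
                                               count = x[[1]]),
                                    p, sep = "\t", quote = FALSE,
                                    row.names = FALSE))
  }

  universe <- rownames(read_expression_matrix(
    file.path(dir, paste0(case_names[1], "_exprs.tsv"))))
  kt <- stage("known_targets",
              known_target_enrichment(
                lapply(curated, function(x)
                  lapply(x, function(g) if (length(g)) g else universe)),
                targets, universe))
  emit(as.data.frame(kt), "known_target_enrichment.tsv",
       function(x, p) write.table(data.frame(kind = rownames(x), x),
                                  p, sep = "\t", quote = FALSE,
                                  row.names = FALSE))

  cl <- stage("clustering", case_clustering(deg_sets))
  emit(cl$newick, "case_clustering.newick",
       function(x, p) writeLines(x, p))

  sig <- config$signature
  rule <- signature_rule(required_group = sig$required_group,
                         min_hits = sig$min_hits,
                         excluded_cases = sig$excluded_cases)
  hits <- stage("signature",
                alz_only_hits(membership_table(deg_sets), rule, sets))
  emit(hits, "disease_only_hits.tsv", write_tsv)
  emit(list(rule = unclass(rule), n_hits = nrow(hits)),
       "disease_only_provenance.json", write_json_art)

  if (nrow(hits) && !is.null(sig$augment_set)) {
    aug <- augment_gene_set(sets, sig$augment_set, hits$gene)
    re_cases <- case_names[vapply(case_names, function(cs)
      length(curated[[cs]]$DEG) > 0, logical(1))]
    re_tab <- do.call(rbind, lapply(re_cases, function(cs) {
      e <- enrich_collection(curated[[cs]]$DEG, aug, universe,
                             disruption_type = 1)
      cbind(case = cs, e[e$set_name == sig$augment_set, ])
    }))
    emit(re_tab, "augmented_enrichment.tsv", write_tsv)
  }

  manifest <- data.frame(artifact = names(artifacts),
                         path = unname(unlist(artifacts)),
                         md5 = unname(tools::md5sum(unlist(artifacts))),
                         stringsAsFactors = FALSE)
  manifest <- manifest[order(manifest$artifact), ]
  rownames(manifest) <- NULL
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
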