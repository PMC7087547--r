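# Cross-case comparative layer: the disease-only ("ALZ-only") signature
# rule over per-case DEG membership, pathway augmentation, three-way
# DEG/IGN/xIGN overlap summaries, and hierarchical clustering of cases on
# DEG membership.

#' Signature selection rule
#'
#' A gene is selected when it belongs to the union of the scope pathways,
#' is a DEG in at least `min_hits` of the `required_group` cases, and is a
#' DEG in none of the `excluded_cases`. The defaults encode the published
#' rule: DEG in at least two of HC/PC/SFG and not in AG, scoped to the six
#' recurrently enriched pathways. The all-down-regulated observation is an
#' emergent check, not a filter; set `direction` to impose it.
#'
#' @param required_group case labels counted toward `min_hits`.
#' @param min_hits minimum number of required-group DEG hits.
#' @param excluded_cases case labels in which the gene must not be a DEG.
#' @param pathway_scope names of scope sets (NULL = every set in the
#'   collection passed to [alz_only_hits()]).
#' @param direction optional `"down"` / `"up"` constraint on every hit.
#' @return object of class `signature_rule`.
#' @export
signature_rule <- function(required_group = c("HC", "PC", "SFG"),
                           min_hits = 2, excluded_cases = "AG",
                           pathway_scope = NULL, direction = NULL) {
  stopifnot(min_hits >= 1, min_hits <= length(required_group))
  structure(list(required_group = required_group, min_hits = min_hits,
                 excluded_cases = excluded_cases,
                 pathway_scope = pathway_scope, direction = direction),
            class = "signature_rule")
}

#' Assemble a per-gene case-membership table
#'
#' @param deg_sets named list (per case) of DEG tables from
#'   [fit_differential()] / [select_degs()], or plain gene vectors.
#' @return long data.frame: `gene`, `case`, `deg` (logical), `direction`
#'   (NA when unknown).
#' @export
membership_table <- function(deg_sets) {
  stopifnot(is.list(deg_sets), !is.null(names(deg_sets)))
  rows <- lapply(names(deg_sets), function(cs) {
    x <- deg_sets[[cs]]
    if (is.data.frame(x))
      data.frame(gene = x$gene, case = cs, deg = TRUE,
                 direction = if ("direction" %in% names(x)) x$direction
                             else NA_character_,
                 stringsAsFactors = FALSE)
    else
      data.frame(gene = as.character(x), case = cs, deg = TRUE,
                 direction = NA_character_, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Select disease-only signature hits
#'
#' Applies a [signature_rule()] to per-gene, per-case DEG membership within
#' the scope pathways. Returns one row per selected gene with full
#' provenance: which required-group cases triggered the selection and
#' which scope sets contain the gene.
#'
#' @param memberships data.frame with columns `gene`, `case`, `deg`
#'   (logical; rows with `deg = FALSE` may be omitted) and optionally
#'   `direction` (see [membership_table()]).
#' @param rule a [signature_rule()].
#' @param scope_collection named list of gene sets; the union of the rule's
#'   `pathway_scope` sets (default: all sets) defines eligible genes.
#' @return data.frame: `gene`, `n_required_hits`, `required_cases`,
#'   `all_deg_cases`, `scope_sets`, `direction` (comma-joined provenance),
#'   sorted by gene id.
#' @export
alz_only_hits <- function(memberships, rule = signature_rule(),
                          scope_collection) {
  stopifnot(inherits(rule, "signature_rule"),
            all(c("gene", "case", "deg") %in% names(memberships)))
  scope_names <- rule$pathway_scope
  if (is.null(scope_names)) scope_names <- names(scope_collection)
  missing_sets <- setdiff(scope_names, names(scope_collection))
  if (length(missing_sets))
    stop("scope sets absent from collection: ",
         paste(missing_sets, collapse = ", "))
  scope <- unique(unlist(scope_collection[scope_names]))
  if (length(scope) == 0) stop("empty pathway scope union")

  mm <- memberships[memberships$deg & memberships$gene %in% scope, ,
                    drop = FALSE]
  if (!"direction" %in% names(mm)) mm$direction <- NA_character_

  out <- lapply(sort(unique(mm$gene)), function(g) {
    rows <- mm[mm$gene == g, , drop = FALSE]
    deg_cases <- unique(rows$case)
    req <- intersect(deg_cases, rule$required_group)
    if (length(req) < rule$min_hits) return(NULL)
    if (any(deg_cases %in% rule$excluded_cases)) return(NULL)
    dirs <- unique(rows$direction[!is.na(rows$direction)])
    if (!is.null(rule$direction) &&
        !(length(dirs) > 0 && all(dirs == rule$direction))) return(NULL)
    in_sets <- scope_names[vapply(scope_names, function(s)
      g %in% scope_collection[[s]], logical(1))]
    data.frame(gene = g, n_required_hits = length(req),
               required_cases = paste(sort(req), collapse = ","),
               all_deg_cases = paste(sort(deg_cases), collapse = ","),
               scope_sets = paste(in_sets, collapse = ","),
               direction = paste(sort(dirs), collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(gene = character(0), n_required_hits = integer(0),
                      required_cases = character(0),
                      all_deg_cases = character(0),
                      scope_sets = character(0), direction = character(0),
                      stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Augment a gene set within a collection
#'
#' Members become `old union new_genes`; other sets are untouched. The
#' count of genuinely new genes is attached as attribute `n_new`.
#'
#' @param collection named list of gene sets.
#' @param set_name the set to augment (must exist).
#' @param new_genes genes to add.
#' @return the modified collection with attribute `n_new`.
#' @export
augment_gene_set <- function(collection, set_name, new_genes) {
  if (!set_name %in% names(collection))
    stop("no such set: ", set_name)
  old <- collection[[set_name]]
  collection[[set_name]] <- union(old, as.character(new_genes))
  attr(collection, "n_new") <- length(setdiff(new_genes, old))
  collection
}

#' Three-way overlap (Venn) summary
#'
#' @param deg_set,ign_set,xign_set character gene vectors over a common
#'   namespace.
#' @return named integer vector of the 7 disjoint region counts:
#'   `deg_only`, `ign_only`, `xign_only`, `deg_ign`, `deg_xign`,
#'   `ign_xign`, `all`.
#' @export
overlap_summary <- function(deg_set, ign_set, xign_set) {
  a <- unique(as.character(deg_set))
  b <- unique(as.character(ign_set))
  g <- unique(unlist(list(a, b, unique(as.character(xign_set)))))
  x <- unique(as.character(xign_set))
  inA <- g %in% a; inB <- g %in% b; inX <- g %in% x
  c(deg_only  = sum(inA & !inB & !inX),
    ign_only  = sum(!inA & inB & !inX),
    xign_only = sum(!inA & !inB & inX),
    deg_ign   = sum(inA & inB & !inX),
    deg_xign  = sum(inA & !inB & inX),
    ign_xign  = sum(!inA & inB & inX),
    all       = sum(inA & inB & inX))
}

#' Hierarchical clustering of cases on DEG membership
#'
#' Builds the binary gene x case membership matrix over the union of DEGs
#' and clusters the cases with Jaccard distance
#' (`1 - |A ∩ B| / |A ∪ B|`; two empty sets have distance 0,
#' an empty versus non-empty set distance 1) and average linkage.
#'
#' @param deg_sets named list (per case) of DEG gene vectors (or tables
#'   with a `gene` column).
#' @return list: `hclust` (the dendrogram), `newick` (Newick string),
#'   `distance` (the case-distance `dist`), `membership` (binary matrix).
#' @export
case_clustering <- function(deg_sets) {
  stopifnot(length(deg_sets) >= 2, !is.null(names(deg_sets)))
  sets <- lapply(deg_sets, function(x)
    unique(if (is.data.frame(x)) as.character(x$gene) else as.character(x)))
  genes <- sort(unique(unlist(sets)))
  memb <- sapply(sets, function(s) as.integer(genes %in% s))
  memb <- matrix(memb, nrow = length(genes),
                 dimnames = list(genes, names(sets)))
  cases <- names(sets)
  m <- length(cases)
  d <- matrix(0, m, m, dimnames = list(cases, cases))
  for (i in seq_len(m - 1)) for (j in (i + 1):m) {
    un <- length(union(sets[[i]], sets[[j]]))
    d[i, j] <- d[j, i] <-
      if (un == 0) 0 else 1 - length(intersect(sets[[i]], sets[[j]])) / un
  }
  hc <- hclust(as.dist(d), method = "average")
  list(hclust = hc, newick = ape::write.tree(ape::as.phylo(hc)),
       distance = as.dist(d), membership = memb)
}

#' Load the packaged 54-gene disease-only hit table
#'
#' A versioned transcription of the published table of 54 disease-only
#' hits across six pathway scopes, with per-case DEG membership, expression
#' direction, network (IGN) membership and KEGG AD-pathway membership.
#'
#' @return data.frame with columns `gene`, `kegg_sets`, `deg_cases`,
#'   `direction`, `ign_cases`, `in_ad_pathway`.
#' @export
alz_hits_fixture <- function() {
  path <- system.file("extdata", "table2_alz_only_hits.tsv",
                      package = "idcenet", mustWork = TRUE)
  read.delim(path, stringsAsFactors = FALSE)
}

#' Expand the fixture into rule inputs
#'
#' Converts the fixture's comma-joined columns into the long membership
#' table and scope collection consumed by [alz_only_hits()], so the
#' published selection rule can be re-validated row by row.
#'
#' @param tab a data.frame as returned by [alz_hits_fixture()].
#' @return list: `memberships` (gene/case/deg/direction), `collection`
#'   (scope sets reconstructed from the `kegg_sets` column).
#' @export
fixture_memberships <- function(tab = alz_hits_fixture()) {
  split_cases <- strsplit(tab$deg_cases, ",", fixed = TRUE)
  memberships <- data.frame(
    gene = rep(tab$gene, lengths(split_cases)),
    case = trimws(unlist(split_cases)),
    deg = TRUE,
    direction = tolower(rep(tab$direction, lengths(split_cases))),
    stringsAsFactors = FALSE)
  split_sets <- strsplit(tab$kegg_sets, ",", fixed = TRUE)
  long <- data.frame(set = trimws(unlist(split_sets)),
                     gene = rep(tab$gene, lengths(split_sets)),
                     stringsAsFactors = FALSE)
  collection <- split(long$gene, long$set)
  list(memberships = memberships, collection = collection)
}
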