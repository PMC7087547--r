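# Readers/writers for the plain-text dialects the pipeline consumes and
# emits: expression TSV (first column gene id, header = sample ids),
# metadata TSV (sample_id, group, case), two-column PPI TSV, GMT gene sets,
# JSON truth records.

#' Write / read an expression matrix as TSV
#'
#' The on-disk dialect is a tab-separated table whose first column (`gene`)
#' holds gene identifiers and whose remaining column names are sample ids.
#' Values are log2-scale expression.
#'
#' @param mat numeric matrix, genes in rows (rownames required), samples in
#'   columns (colnames required).
#' @param path file path.
#' @return `write_expression_matrix` returns `path` invisibly;
#'   `read_expression_matrix` returns the numeric matrix.
#' @export
write_expression_matrix <- function(mat, path) {
  stopifnot(is.matrix(mat), !is.null(rownames(mat)), !is.null(colnames(mat)))
  df <- data.frame(gene = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_expression_matrix
#' @export
read_expression_matrix <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  mat <- as.matrix(df[, -1, drop = FALSE])
  rownames(mat) <- df[[1]]
  storage.mode(mat) <- "double"
  mat
}

#' Write / read per-sample metadata
#'
#' Columns: `sample_id`, `group` (one of `"test"`, `"control"`), `case`.
#'
#' @param meta data.frame with the three columns above.
#' @param path file path.
#' @export
write_sample_metadata <- function(meta, path) {
  stopifnot(all(c("sample_id", "group", "case") %in% names(meta)))
  write.table(meta[, c("sample_id", "group", "case")], path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_sample_metadata
#' @export
read_sample_metadata <- function(path) {
  meta <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("sample_id", "group", "case") %in% names(meta)))
  bad <- setdiff(unique(meta$group), c("test", "control"))
  if (length(bad))
    stop("metadata group labels must be 'test'/'control'; found: ",
         paste(bad, collapse = ", "))
  meta
}

#' Write / read a protein-protein interaction edge list
#'
#' Two-column TSV of gene symbols. On read, edges are undirected:
#' self-loops are dropped and duplicates (in either orientation) removed;
#' each edge is stored with `gene_i < gene_j` lexicographically.
#'
#' @param ppi data.frame with columns `gene_i`, `gene_j`.
#' @param path file path.
#' @export
write_ppi <- function(ppi, path) {
  stopifnot(all(c("gene_i", "gene_j") %in% names(ppi)))
  write.table(ppi[, c("gene_i", "gene_j")], path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ppi
#' @export
read_ppi <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  names(df)[1:2] <- c("gene_i", "gene_j")
  canonical_pairs(df$gene_i, df$gene_j)
}

# Canonicalise an undirected pair list: order endpoints lexicographically,
# drop self-loops and duplicates. Returns data.frame(gene_i, gene_j).
canonical_pairs <- function(a, b) {
  a <- as.character(a); b <- as.character(b)
  keep <- a != b
  a <- a[keep]; b <- b[keep]
  gi <- pmin(a, b); gj <- pmax(a, b)
  dup <- duplicated(paste(gi, gj, sep = "\r"))
  data.frame(gene_i = gi[!dup], gene_j = gj[!dup],
             stringsAsFactors = FALSE)
}

pair_key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")

#' Write / read gene-set collections in GMT format
#'
#' GMT: one set per line, tab-separated `name`, `description`, members.
#' A collection is a named list of character vectors with a `description`
#' attribute (named character vector).
#'
#' @param collection named list of character gene vectors; an optional
#'   `description` attribute supplies per-set descriptions.
#' @param path file path.
#' @export
write_gmt <- function(collection, path) {
  stopifnot(is.list(collection), !is.null(names(collection)))
  desc <- attr(collection, "description")
  lines <- vapply(names(collection), function(nm) {
    d <- if (!is.null(desc) && nm %in% names(desc)) desc[[nm]] else "na"
    paste(c(nm, d, collection[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_gmt
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nm <- vapply(parts, `[[`, character(1), 1L)
  if (anyDuplicated(nm)) stop("duplicate set names in GMT: ", path)
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- nm
  attr(sets, "description") <- setNames(
    vapply(parts, `[[`, character(1), 2L), nm)
  sets
}

#' Write / read a planted-truth record as JSON
#'
#' @param truth a `truth_record` as produced by [generate_case()].
#' @param path file path.
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(unclass(truth), path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$de_genes <- as.data.frame(x$de_genes, stringsAsFactors = FALSE)
  x$dce_pairs <- as.data.frame(x$dce_pairs, stringsAsFactors = FALSE)
  structure(x, class = "truth_record")
}
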