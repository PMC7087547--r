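# Construction of interacting differentially co-expressed (IDCE) networks.
# IGN: DCE pairs that also have a direct PPI edge. xIGN: one extension pass
# adding any outside gene G with a PPI to an IGN gene A and a DCE
# partnership with a different IGN gene B, provided A-B is an IGN edge
# (the new IDCE edge is G-B, a DCE pair with once-removed PPI). Degree
# filtering peels low-degree nodes, iteratively by default.

new_gene_network <- function(kind, edges) {
  edges <- edges[order(edges$gene_i, edges$gene_j), , drop = FALSE]
  rownames(edges) <- NULL
  nodes <- sort(unique(c(edges$gene_i, edges$gene_j)))
  deg <- table(factor(c(edges$gene_i, edges$gene_j), levels = nodes))
  structure(list(kind = kind, edges = edges, nodes = nodes,
                 degree = setNames(as.integer(deg), nodes)),
            class = "gene_network")
}

#' Build the interacting gene network (IGN)
#'
#' Edge set = DCE pairs that are also PPI edges; nodes are the endpoints of
#' retained edges; GOC/LOC labels are carried over from the DCE pairs. An
#' empty intersection yields an empty network, not an error.
#'
#' @param dce data.frame of selected DCE pairs (columns `gene_i`, `gene_j`,
#'   `class`), e.g. a `dce_result`.
#' @param ppi data.frame of PPI edges (columns `gene_i`, `gene_j`).
#' @return object of class `gene_network` (`kind = "IGN"`): list with
#'   `edges` (gene_i, gene_j, class), `nodes`, `degree`.
#' @export
build_ign <- function(dce, ppi) {
  dce <- as.data.frame(dce)
  keep <- pair_key(dce$gene_i, dce$gene_j) %in%
    pair_key(ppi$gene_i, ppi$gene_j)
  edges <- data.frame(gene_i = pmin(dce$gene_i, dce$gene_j)[keep],
                      gene_j = pmax(dce$gene_i, dce$gene_j)[keep],
                      class = dce$class[keep], stringsAsFactors = FALSE)
  new_gene_network("IGN", edges)
}

#' Extend an IGN by once-removed PPI (xIGN)
#'
#' Single, non-cascading pass: every candidate gene `G` outside the
#' original IGN node set is added -- with edge `G--B` labelled by the DCE
#' class -- whenever there exist distinct IGN genes `A != B` such that
#' `(G, A)` is a PPI edge, `(G, B)` is a DCE pair, and `A--B` is an IGN
#' edge. Newly added genes never seed further additions, so the operation
#' is idempotent given the fixed original node set.
#'
#' @param ign the `gene_network` to extend.
#' @param dce data.frame of selected DCE pairs (with `class`).
#' @param ppi data.frame of PPI edges.
#' @return a `gene_network` of kind `"xIGN"` (pre degree filtering) whose
#'   edge set contains the generating IGN's edges.
#' @export
extend_ign <- function(ign, dce, ppi) {
  stopifnot(inherits(ign, "gene_network"))
  dce <- as.data.frame(dce)
  ign_nodes <- ign$nodes
  ign_keys <- pair_key(ign$edges$gene_i, ign$edges$gene_j)

  ppi_long <- data.frame(g = c(ppi$gene_i, ppi$gene_j),
                         nb = c(ppi$gene_j, ppi$gene_i),
                         stringsAsFactors = FALSE)
  ppi_long <- ppi_long[ppi_long$nb %in% ign_nodes &
                         !(ppi_long$g %in% ign_nodes), , drop = FALSE]
  dce_long <- data.frame(g = c(dce$gene_i, dce$gene_j),
                         nb = c(dce$gene_j, dce$gene_i),
                         class = c(dce$class, dce$class),
                         stringsAsFactors = FALSE)
  dce_long <- dce_long[dce_long$nb %in% ign_nodes &
                         !(dce_long$g %in% ign_nodes), , drop = FALSE]

  cands <- sort(intersect(unique(ppi_long$g), unique(dce_long$g)))
  new_edges <- ign$edges[0, , drop = FALSE]
  for (g in cands) {
    A <- ppi_long$nb[ppi_long$g == g]
    drows <- which(dce_long$g == g)
    for (d in drows) {
      B <- dce_long$nb[d]
      ok <- any(A != B & pair_key(A, rep(B, length(A))) %in% ign_keys)
      if (ok)
        new_edges <- rbind(new_edges,
                           data.frame(gene_i = pmin(g, B),
                                      gene_j = pmax(g, B),
                                      class = dce_long$class[d],
                                      stringsAsFactors = FALSE))
    }
  }
  edges <- rbind(ign$edges, new_edges)
  edges <- edges[!duplicated(pair_key(edges$gene_i, edges$gene_j)), ,
                 drop = FALSE]
  new_gene_network("xIGN", edges)
}

#' Filter a network by minimum degree
#'
#' Removes nodes with degree `<= min_degree_exclusive` (strict "degree
#' greater than" survival, as in the thresholds ">2" / ">3"). By default
#' the peel iterates to a fixpoint, recomputing degrees each round
#' (k-core style) -- the result is independent of removal order. A
#' single-pass mode is available for sensitivity checks.
#'
#' @param network a `gene_network`.
#' @param min_degree_exclusive nodes must exceed this degree to survive.
#' @param iterative peel to a fixpoint (default) or apply once.
#' @return the filtered `gene_network` (same kind).
#' @export
filter_by_degree <- function(network, min_degree_exclusive,
                             iterative = TRUE) {
  stopifnot(inherits(network, "gene_network"), min_degree_exclusive >= 0)
  edges <- network$edges
  repeat {
    nodes <- unique(c(edges$gene_i, edges$gene_j))
    deg <- table(factor(c(edges$gene_i, edges$gene_j), levels = nodes))
    bad <- nodes[deg <= min_degree_exclusive]
    if (length(bad) == 0) break
    edges <- edges[!(edges$gene_i %in% bad | edges$gene_j %in% bad), ,
                   drop = FALSE]
    if (!iterative) break
  }
  new_gene_network(network$kind, edges)
}

#' Degree summary of a network
#'
#' @param network a `gene_network`.
#' @return list: `n_nodes`, `n_edges`, `max_degree`, `mean_degree`
#'   (zeros for an empty network).
#' @export
degree_stats <- function(network) {
  stopifnot(inherits(network, "gene_network"))
  if (length(network$nodes) == 0)
    return(list(n_nodes = 0L, n_edges = 0L, max_degree = 0,
                mean_degree = 0))
  list(n_nodes = length(network$nodes),
       n_edges = nrow(network$edges),
       max_degree = max(network$degree),
       mean_degree = mean(network$degree))
}

#' Export a network as edge-list TSV (and optionally GraphML / node table)
#'
#' @param network a `gene_network`.
#' @param path edge-list TSV path (`gene_i`, `gene_j`, `class`).
#' @param graphml_path optional GraphML path (class as an edge attribute).
#' @param nodes_path optional node-table TSV path (gene, degree).
#' @export
write_network <- function(network, path, graphml_path = NULL,
                          nodes_path = NULL) {
  stopifnot(inherits(network, "gene_network"))
  write.table(network$edges, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  if (!is.null(graphml_path)) {
    g <- igraph::graph_from_data_frame(network$edges, directed = FALSE,
                                       vertices = network$nodes)
    igraph::write_graph(g, graphml_path, format = "graphml")
  }
  if (!is.null(nodes_path))
    write.table(data.frame(gene = network$nodes,
                           degree = unname(network$degree)),
                nodes_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
print.gene_network <- function(x, ...) {
  s <- degree_stats(x)
  cat(sprintf("%s: %d nodes, %d edges (max degree %d, mean %.2f)\n",
              x$kind, s$n_nodes, s$n_edges, s$max_degree, s$mean_degree))
  invisible(x)
}
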