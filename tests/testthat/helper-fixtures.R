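# Shared in-code fixtures for the suite. Everything is generated; no
# binary data.

# Two well-separated sample clusters aligned with test/control labels:
# per-gene baselines vary (as on real arrays) and the signal genes shift
# in both directions. `swap` optionally gives one test sample the control
# profile.
make_two_cluster_matrix <- function(n_genes = 60, n_per_group = 6,
                                    shift = 5, noise = 0.3, seed = 42,
                                    swap = NULL) {
  set.seed(seed)
  n <- 2 * n_per_group
  samples <- c(sprintf("T%02d", seq_len(n_per_group)),
               sprintf("C%02d", seq_len(n_per_group)))
  labels <- rep(c("test", "control"), each = n_per_group)
  baseline <- rnorm(n_genes, 8, 1.5)
  mat <- baseline + matrix(rnorm(n_genes * n, 0, noise), n_genes, n)
  dimnames(mat) <- list(sprintf("G%05d", seq_len(n_genes)), samples)
  sig <- seq_len(floor(n_genes / 2))
  sgn <- rep(c(1, -1), length.out = length(sig))
  mat[sig, labels == "test"] <- mat[sig, labels == "test"] + sgn * shift
  if (!is.null(swap)) {
    # give one test sample the control profile
    mat[sig, swap] <- baseline[sig] + rnorm(length(sig), 0, noise)
  }
  list(exprs = mat, labels = labels)
}

# Exhaustive hypergeometric upper-tail oracle (independent of phyper).
hyper_tail_oracle <- function(k, K, n, N) {
  xs <- k:min(K, n)
  sum(choose(K, xs) * choose(N - K, n - xs)) / choose(N, n)
}

# Independent BH step-up oracle: adj(i) = min_{j >= i} min(1, m p(j) / j)
# on the sorted scale, mapped back to input order.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- vapply(seq_len(m), function(i)
    min(1, min(m * ps[i:m] / (i:m))), numeric(1))
  out <- numeric(m)
  out[o] <- adj
  out
}

# Naive all-pairs DCE table by double loop (oracle for the blocked driver).
naive_dce_table <- function(mat, labels, pooling = "global") {
  tmat <- mat[, labels == "test", drop = FALSE]
  cmat <- mat[, labels == "control", drop = FALSE]
  n_t <- ncol(tmat); n_c <- ncol(cmat)
  genes <- rownames(mat)
  G <- length(genes)
  rows <- list()
  for (i in seq_len(G - 1)) for (j in (i + 1):G) {
    r_t <- cor(tmat[i, ], tmat[j, ])
    r_c <- cor(cmat[i, ], cmat[j, ])
    gi <- min(genes[i], genes[j]); gj <- max(genes[i], genes[j])
    rows[[length(rows) + 1]] <-
      data.frame(gene_i = gi, gene_j = gj, r_t = r_t, r_c = r_c,
                 stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out$z_t <- atanh(out$r_t); out$z_c <- atanh(out$r_c)
  zb <- if (pooling == "global") mean(c(out$z_t, out$z_c))
        else ((n_t - 3) * out$z_t + (n_c - 3) * out$z_c) /
             ((n_t - 3) + (n_c - 3))
  out$q <- (n_t - 3) * (out$z_t - zb)^2 + (n_c - 3) * (out$z_c - zb)^2
  out
}

# A small study config that keeps the end-to-end tests fast.
small_study_config <- function(seed, dir) {
  default_pipeline_config(seed = seed, n_genes = 250, n_test = 8,
                          n_control = 8, dir = dir)
}

# Construct a gene_network directly from an edge table (tests only).
new_gene_network_for_test <- function(edges, kind = "IGN") {
  idcenet:::new_gene_network(kind, edges)
}
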