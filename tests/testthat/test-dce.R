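# Differential co-expression: standardization, pairwise correlation, the
# Fisher z transform, the heterogeneity Q statistic, top-quantile
# selection, and the blocked all-pairs driver against a naive double loop.

test_that("cohort standardization is exact, idempotent, and flags constants", {
  m <- matrix(c(1, 2, 3), 1, 3, dimnames = list("g1", c("a", "b", "c")))
  expect_equal(unname(standardize_cohort(m)[1, ]), c(-1, 0, 1))
  set.seed(1)
  m2 <- matrix(rnorm(20), 4, 5, dimnames = list(paste0("g", 1:4), NULL))
  s1 <- standardize_cohort(m2)
  expect_equal(unname(rowMeans(s1)), rep(0, 4), tolerance = 1e-12)
  expect_equal(unname(apply(s1, 1, sd)), rep(1, 4), tolerance = 1e-12)
  s2 <- standardize_cohort(s1)
  expect_equal(unclass(s2)[, ], unclass(s1)[, ], tolerance = 1e-12)
  m3 <- rbind(m2, g5 = rep(7, 5))
  expect_warning(s3 <- standardize_cohort(m3), "zero-variance")
  expect_identical(attr(s3, "excluded"), "g5")
  expect_equal(nrow(s3), 4)
})

test_that("pair correlations equal Pearson r, with clipping at the boundary", {
  set.seed(6)
  m <- matrix(rnorm(5 * 30), 5, 30, dimnames = list(paste0("g", 1:5), NULL))
  m <- rbind(m, g6 = m["g1", ], g7 = -m["g1", ])
  s <- standardize_cohort(m)
  pc <- pair_correlation(s, pairs = data.frame(a = c("g1", "g1", "g2"),
                                               b = c("g6", "g7", "g3")))
  expect_equal(pc$r[1], 1 - 1e-12)   # self-duplicate, clipped
  expect_equal(pc$r[2], -(1 - 1e-12))
  expect_equal(pc$r[3], cor(m["g2", ], m["g3", ]), tolerance = 1e-12)
  # all-pairs route agrees with cor()
  allp <- pair_correlation(s)
  ref <- cor(t(m))
  for (k in seq_len(nrow(allp)))
    expect_equal(allp$r[k], ref[allp$gene_i[k], allp$gene_j[k]],
                 tolerance = 1e-9)
  # independent long genes decorrelate
  set.seed(8)
  big <- standardize_cohort(matrix(rnorm(2 * 1000), 2, 1000,
                                   dimnames = list(c("a", "b"), NULL)))
  expect_lt(abs(pair_correlation(big)$r), 0.1)
})

test_that("fisher_z matches the closed form and is odd", {
  expect_equal(fisher_z(0), 0)
  expect_equal(fisher_z(0.9), 0.5 * log(1.9 / 0.1), tolerance = 1e-12)
  expect_equal(fisher_z(0.9), 1.47222, tolerance = 1e-5)
  r <- seq(0.1, 0.9, by = 0.1)
  expect_equal(fisher_z(-r), -fisher_z(r), tolerance = 1e-14)
  expect_true(all(diff(fisher_z(seq(-0.99, 0.99, 0.01))) > 0))
  expect_error(fisher_z(1), "< 1")
})

test_that("the Q statistic evaluates its defining formula", {
  expect_equal(q_statistic(0.5, 0.5, 10, 10, 0.5), 0)
  expect_equal(q_statistic(1, 0, 13, 13, 0.5), 5.0)
  # cohort sizes of 3 are rejected by the driver but the formula's
  # (n - 3) factors vanishing is still the right limit at n = 4 spacing
  set.seed(12)
  for (i in 1:20) {
    zt <- rnorm(1); zc <- rnorm(1); zb <- rnorm(1)
    nt <- sample(4:30, 1); nc <- sample(4:30, 1)
    expect_equal(q_statistic(zt, zc, nt, nc, zb),
                 (nt - 3) * (zt - zb)^2 + (nc - 3) * (zc - zb)^2,
                 tolerance = 1e-14)
  }
})

test_that("mean_z pooling modes behave as documented", {
  expect_equal(mean_z(c(2, 2), c(2, 2), 10, 10, "global"), 2)
  expect_equal(mean_z(-1, 1, 10, 10, "global"), 0)
  expect_equal(mean_z(c(0, 1), c(1, 0), 12, 12, "per_pair_weighted"),
               c(0.5, 0.5))
  # unequal sizes: weights (n - 3)
  expect_equal(mean_z(1, 0, 13, 7, "per_pair_weighted"), 10 / 14)
})

test_that("top-quantile selection counts, tie-breaks, and order invariance", {
  expect_equal(top_fraction_count(46, 0.001), 1)  # C(46,2) = 1035 pairs
  pairs <- data.frame(gene_i = sprintf("a%02d", 1:10),
                      gene_j = sprintf("b%02d", 1:10),
                      q = c(5, 5, 5, 4, 3, 2, 1, 1, 0, 0))
  sel <- select_dce(pairs, fraction = 0.25, total_pairs = 10)
  expect_equal(nrow(sel), 2)
  expect_equal(sel$gene_i, c("a01", "a02"))  # lexicographic among q = 5 ties
  expect_equal(attr(sel, "q_threshold"), 5)
  shuffled <- pairs[sample(nrow(pairs)), ]
  expect_equal(select_dce(shuffled, 0.25, 10)$gene_i, sel$gene_i)
  expect_warning(empty <- select_dce(pairs, 0.001, 10), "zero pairs")
  expect_equal(nrow(empty), 0)
  # all-tied input keeps the k lexicographically first pairs
  tied <- data.frame(gene_i = sprintf("g%02d", 10:1),
                     gene_j = sprintf("h%02d", 10:1), q = 1)
  expect_equal(select_dce(tied, 0.3, 10)$gene_i, c("g01", "g02", "g03"))
})

test_that("GOC/LOC labels follow the correlation ordering", {
  expect_identical(classify_goc_loc(0.8, 0.1), "GOC")
  expect_identical(classify_goc_loc(-0.8, 0.1), "LOC")
  expect_warning(na <- classify_goc_loc(0.5, 0.5), "tied")
  expect_true(is.na(na))
})

test_that("blocked all-pairs driver equals the naive double loop", {
  set.seed(44)
  mat <- matrix(rnorm(18 * 16), 18, 16,
                dimnames = list(sprintf("g%02d", sample(18)),
                                sprintf("s%02d", 1:16)))
  labels <- rep(c("test", "control"), each = 8)
  for (pooling in c("global", "per_pair_weighted")) {
    naive <- naive_dce_table(mat, labels, pooling)
    naive$class <- ifelse(naive$r_t > naive$r_c, "GOC", "LOC")
    want <- select_dce(naive, fraction = 0.2)
    for (bs in c(4, 7, 100)) {
      got <- dce_pairs(mat, labels, fraction = 0.2, pooling = pooling,
                       block_size = bs)
      expect_equal(got$gene_i, want$gene_i)
      expect_equal(got$gene_j, want$gene_j)
      expect_equal(got$q, want$q, tolerance = 1e-12)
      expect_equal(got$r_t, want$r_t, tolerance = 1e-12)
      expect_equal(got$class, want$class)
    }
    ctx <- dce_context(dce_pairs(mat, labels, fraction = 0.2,
                                 pooling = pooling))
    expect_equal(ctx$n_pairs_total, choose(18, 2))
    if (pooling == "global")
      expect_equal(ctx$z_bar, mean(c(naive$z_t, naive$z_c)),
                   tolerance = 1e-12)
  }
})

test_that("swapping cohorts mirrors r/z, flips classes, preserves Q", {
  set.seed(51)
  mat <- matrix(rnorm(12 * 20), 12, 20,
                dimnames = list(sprintf("g%02d", 1:12), sprintf("s%02d", 1:20)))
  labels <- rep(c("test", "control"), each = 10)
  flipped <- ifelse(labels == "test", "control", "test")
  a <- dce_pairs(mat, labels, fraction = 0.5)
  b <- dce_pairs(mat, flipped, fraction = 0.5)
  key <- function(x) paste(x$gene_i, x$gene_j)
  b <- b[match(key(a), key(b)), ]
  expect_equal(a$r_t, b$r_c, tolerance = 1e-12)
  expect_equal(a$z_c, b$z_t, tolerance = 1e-12)
  expect_equal(a$q, b$q, tolerance = 1e-12)
  expect_identical(a$class, ifelse(b$class == "GOC", "LOC", "GOC"))
})

test_that("planted differential co-expression dominates the ranking at n = 50", {
  # at n = 50 per cohort the planted |r_t - r_c| = 0.8 signal is far above
  # the null Q scale; Monte-Carlo at this n puts recovery near 1
  cfg <- sim_config(n_genes = 150, n_test = 50, n_control = 50,
                    de_fraction = 0, n_dce_pairs = 10,
                    r_test = 0.8, r_control = 0, seed = 77)
  case <- generate_case(cfg)
  res <- dce_pairs(case$exprs, case$metadata$group, fraction = 0.001)
  # top 0.1% of C(150,2) = 11,175 pairs -> 11 pairs
  expect_equal(nrow(res), 11)
  truth_keys <- paste(case$truth$dce_pairs$gene_i, case$truth$dce_pairs$gene_j)
  got_keys <- paste(res$gene_i, res$gene_j)
  expect_gte(mean(truth_keys %in% got_keys), 0.8)
})
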