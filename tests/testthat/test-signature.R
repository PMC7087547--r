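# Cross-case signature layer: the disease-only rule with provenance, the
# packaged published-table fixture, pathway augmentation, overlap
# summaries, and case clustering.

toy_scope <- list(P1 = c("g1", "g2", "g3"), P2 = c("g3", "g4"))
toy_members <- function(...) {
  rows <- list(...)
  data.frame(gene = vapply(rows, `[[`, "", 1),
             case = vapply(rows, `[[`, "", 2),
             deg = TRUE,
             direction = vapply(rows, function(r)
               if (length(r) > 2) r[[3]] else NA_character_, ""),
             stringsAsFactors = FALSE)
}

test_that("the selection rule enforces scope, min hits, and exclusion", {
  rule <- signature_rule(required_group = c("HC", "PC", "SFG"),
                         min_hits = 2, excluded_cases = "AG")
  mm <- toy_members(
    list("g1", "HC", "down"), list("g1", "PC", "down"),   # selected
    list("g2", "HC", "down"),                              # only 1 hit
    list("g3", "HC", "down"), list("g3", "PC", "down"),
    list("g3", "AG", "down"),                              # excluded by AG
    list("g9", "HC", "down"), list("g9", "PC", "down"))    # not in scope
  hits <- alz_only_hits(mm, rule, toy_scope)
  expect_equal(hits$gene, "g1")
  expect_equal(hits$n_required_hits, 2)
  expect_equal(hits$required_cases, "HC,PC")
  expect_equal(hits$scope_sets, "P1")
  # multi-set provenance counts the gene once
  mm2 <- toy_members(list("g3", "HC", "down"), list("g3", "SFG", "down"))
  hits2 <- alz_only_hits(mm2, rule, toy_scope)
  expect_equal(hits2$gene, "g3")
  expect_equal(hits2$scope_sets, "P1,P2")
  expect_error(alz_only_hits(mm, rule, list(P9 = character(0))), "empty")
  expect_error(alz_only_hits(mm, signature_rule(pathway_scope = "P9"),
                             toy_scope), "absent")
})

test_that("the rule is monotone in exclusions and min_hits", {
  set.seed(5)
  cases <- c("AG", "EC", "HC", "PC", "SFG")
  genes <- sprintf("g%02d", 1:40)
  mm <- do.call(rbind, lapply(genes, function(g) {
    cs <- sample(cases, sample(0:4, 1))
    if (length(cs) == 0) return(NULL)
    data.frame(gene = g, case = cs, deg = TRUE,
               direction = "down", stringsAsFactors = FALSE)
  }))
  scope <- list(ALL = genes)
  base <- alz_only_hits(mm, signature_rule(c("HC", "PC", "SFG"), 2, "AG"),
                        scope)
  more_excl <- alz_only_hits(
    mm, signature_rule(c("HC", "PC", "SFG"), 2, c("AG", "EC")), scope)
  expect_true(all(more_excl$gene %in% base$gene))
  fewer_hits <- alz_only_hits(
    mm, signature_rule(c("HC", "PC", "SFG"), 1, "AG"), scope)
  expect_true(all(base$gene %in% fewer_hits$gene))
  # provenance re-check: every returned row satisfies the rule
  for (r in seq_len(nrow(base))) {
    cs <- strsplit(base$all_deg_cases[r], ",")[[1]]
    expect_gte(length(intersect(cs, c("HC", "PC", "SFG"))), 2)
    expect_false("AG" %in% cs)
  }
})

test_that("the packaged published table validates row by row", {
  tab <- alz_hits_fixture()
  expect_equal(nrow(tab), 54)
  fx <- fixture_memberships(tab)
  hits <- alz_only_hits(fx$memberships, signature_rule(), fx$collection)
  expect_equal(nrow(hits), 54)
  expect_setequal(hits$gene, tab$gene)
  # every hit is down-regulated (emergent observation, not a filter)
  expect_true(all(tolower(tab$direction) == "down"))
  # the direction-constrained rule selects the same genes
  hits_dir <- alz_only_hits(fx$memberships,
                            signature_rule(direction = "down"),
                            fx$collection)
  expect_setequal(hits_dir$gene, tab$gene)
})

test_that("fixture tallies match the published composition", {
  tab <- alz_hits_fixture()
  in_set <- function(code) grepl(paste0("(^|,)", code, "($|,)"),
                                 tab$kegg_sets)
  expect_equal(sum(in_set("Oxp")), 26)   # OXPHOS members
  expect_equal(sum(in_set("PSM")), 14)   # Proteasome members
  expect_equal(sum(in_set("Ecol")), 5)
  # 10 from Pyruvate/TCA combined, one of them shared with OXPHOS and
  # four common to both
  expect_equal(sum(in_set("Pym") | in_set("TCA")), 10)
  expect_equal(sum(in_set("Oxp") & (in_set("Pym") | in_set("TCA"))), 1)
  expect_equal(sum(in_set("Pym") & in_set("TCA")), 4)
  # 32 hits outside the KEGG AD list; the 22 inside are OXPHOS (incl. SDHA)
  expect_equal(sum(tab$in_ad_pathway == "no"), 32)
  expect_true(all(in_set("Oxp")[tab$in_ad_pathway == "yes"]))
  # per-case DEG tallies as printed in the table rows
  case_tally <- function(cs) sum(grepl(paste0("(^|,)", cs, "($|,)"),
                                       tab$deg_cases))
  expect_equal(case_tally("PC"), 47)
  expect_equal(case_tally("HC") + case_tally("PC") + case_tally("SFG"), 126)
})

test_that("augmentation grows sets correctly and can only help enrichment", {
  coll <- list(AD = sprintf("g%02d", 1:10), OTHER = sprintf("g%02d", 40:45))
  same <- augment_gene_set(coll, "AD", sprintf("g%02d", 3:5))
  expect_identical(same$AD, coll$AD)
  expect_equal(attr(same, "n_new"), 0)
  grown <- augment_gene_set(coll, "AD", sprintf("h%02d", 1:32))
  expect_length(grown$AD, 42)
  expect_equal(attr(grown, "n_new"), 32)
  expect_identical(grown$OTHER, coll$OTHER)
  expect_error(augment_gene_set(coll, "NOPE", "x"), "no such set")
  # adding query hits to a set can only decrease the overlap p
  U <- sprintf("g%02d", 1:60)
  query <- U[1:20]
  p_old <- fisher_enrich(query, U[1:5], U)$p
  aug <- union(U[1:5], U[6:12])           # new members are all query hits
  p_new <- fisher_enrich(query, aug, U)$p
  expect_lte(p_new, p_old)
})

test_that("three-way overlap counts match brute-force region tallies", {
  same <- overlap_summary(letters[1:5], letters[1:5], letters[1:5])
  expect_equal(unname(same["all"]), 5)
  expect_equal(sum(same), 5)
  disj <- overlap_summary(letters[1:3], letters[4:6], letters[7:9])
  expect_equal(unname(disj[c("deg_only", "ign_only", "xign_only")]),
               c(3, 3, 3))
  expect_equal(sum(disj), 9)
  set.seed(10)
  for (i in 1:10) {
    a <- sample(letters, sample(0:15, 1))
    b <- sample(letters, sample(0:15, 1))
    x <- sample(letters, sample(0:15, 1))
    got <- overlap_summary(a, b, x)
    univ <- unique(c(a, b, x))
    brute <- table(factor(paste0(
      ifelse(univ %in% a, "D", ""), ifelse(univ %in% b, "I", ""),
      ifelse(univ %in% x, "X", "")),
      levels = c("D", "I", "X", "DI", "DX", "IX", "DIX")))
    expect_equal(unname(got), unname(as.integer(brute)))
  }
})

test_that("case clustering groups cases by DEG sharing", {
  g <- sprintf("g%03d", 1:100)
  sets <- list(A = g[1:40], B = g[1:40], C = c(g[1:32], g[61:68]),
               D = g[81:100], E = character(0))
  cl <- case_clustering(sets)
  dm <- as.matrix(cl$distance)
  expect_equal(dm["A", "B"], 0)
  expect_equal(dm["E", "A"], 1)          # empty set is maximally distant
  expect_equal(dm["A", "C"], 1 - 32 / 48)
  # the three sharing cases merge before any join with D or E
  merge_h <- cl$hclust$height[1:2]
  expect_true(all(merge_h < dm["A", "D"]))
  expect_match(cl$newick, "^\\(.*\\);$")
  expect_true(all(sort(cl$hclust$labels) == sort(names(sets))))
  # membership matrix is the binary indicator over the union
  expect_equal(sum(cl$membership[, "A"]), 40)
  expect_equal(dim(cl$membership), c(length(unique(unlist(sets))), 5))
})
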