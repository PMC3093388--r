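test_that("common_quantified intersects quantified sets", {
  a <- make_profile("a", c("g1", "g2", "g3"), c(0, 0, 0), rep("unchanged", 3))
  b <- make_profile("b", c("g2", "g3", "g4"), c(0, 0, 0), rep("unchanged", 3))
  expect_equal(common_quantified(list(a, b)), c("g2", "g3"))
  expect_equal(common_quantified(list(a, a)), sort(quantified_genes(a)))
  d <- make_profile("d", c("g9", "g8", "g7"), c(0, 0, 0), rep("unchanged", 3))
  expect_warning(out <- common_quantified(list(a, d)), "no genes")
  expect_equal(length(out), 0)
})

test_that("venn_regions partitions three increased sets into 7 regions", {
  a <- make_profile("a", c("g1", "g2"), c(0.5, 0.6), rep("increased", 2))
  b <- make_profile("b", c("g2", "g3"), c(0.5, 0.6), rep("increased", 2))
  c3 <- make_profile("c", "g2", 0.5, "increased")
  vr <- venn_regions(list(a, b, c3), "increased")
  expect_equal(vr[["a&b&c"]], "g2")
  expect_equal(vr[["a"]], "g1")
  expect_equal(vr[["c"]], character(0))
  expect_equal(vr[["b"]], "g3")
  expect_equal(length(vr), 7)
  expect_error(venn_regions(list(a, b), "increased"), "exactly 3")
})

test_that("venn regions are disjoint and conserve the union (property)", {
  set.seed(31)
  pool <- sprintf("g%03d", 1:120)
  for (i in 1:15) {
    profs <- lapply(c("a", "b", "c"), random_profile, pool = pool,
                    n_quant = 60)
    for (dir in c("increased", "decreased")) {
      vr <- venn_regions(profs, dir)
      all_genes <- unlist(vr)
      getter <- if (dir == "increased") increased_genes else decreased_genes
      expect_equal(anyDuplicated(all_genes), 0)
      expect_setequal(all_genes, unique(unlist(lapply(profs, getter))))
    }
  }
})

test_that("overlap_percent implements Jaccard on the shared universe", {
  uni <- sprintf("g%d", 1:10)
  a <- make_profile("a", uni, c(rep(0.5, 3), rep(0, 7)),
                    c(rep("increased", 3), rep("unchanged", 7)))
  b <- make_profile("b", uni, c(0, 0.5, 0.5, 0.5, rep(0, 6)),
                    c("unchanged", rep("increased", 3), rep("unchanged", 6)))
  # A = {g1,g2,g3}, B = {g2,g3,g4}: 2 shared of 4 -> 50%
  expect_equal(overlap_percent(a, b, uni), 50)
  expect_equal(overlap_percent(a, b, uni, method = "smaller"), 100 * 2 / 3)
  expect_equal(overlap_percent(a, a, uni), 100)
  expect_equal(overlap_percent(b, a, uni), overlap_percent(a, b, uni))
  none <- make_profile("n", uni, rep(0, 10), rep("unchanged", 10))
  expect_equal(overlap_percent(a, none, uni), 0)
})

test_that("pearson_profiles correlates shared genes only", {
  genes <- sprintf("g%d", 1:20)
  set.seed(8)
  r <- rnorm(20, 0, 0.6)
  a <- make_profile("a", genes, r, rep("unchanged", 20))
  b <- make_profile("b", genes, -r, rep("unchanged", 20))
  expect_equal(pearson_profiles(a, a), 1)
  expect_equal(pearson_profiles(a, b), -1)

  # invariant under genes quantified in only one profile
  extra <- make_profile("a2", c(genes, "only1", "only2"),
                        c(r, 5, -5), rep("unchanged", 22))
  expect_equal(pearson_profiles(extra, b), pearson_profiles(a, b))

  small <- make_profile("s", c("g1", "g2"), c(0, 0), rep("unchanged", 2))
  expect_error(pearson_profiles(small, a), ">= 3 genes")
})

test_that("pattern classes follow confounder/cancer directions", {
  conf <- list(
    make_profile("c1", c("Loxl1", "Fasn", "Lcn2"), c(-0.8, 0.5, 0.6),
                 c("decreased", "increased", "increased")),
    make_profile("c2", c("Loxl1", "Fasn"), c(-0.7, 0.4),
                 c("decreased", "increased"))
  )
  canc <- list(
    make_profile("k1", c("Loxl1", "Fasn", "Quiet"), c(0.9, 0.6, 0),
                 c("increased", "increased", "unchanged"))
  )
  pat <- pattern_classify(conf, canc)
  get <- function(g) pat$pattern[pat$gene_symbol == g]
  expect_equal(get("Loxl1"), "C")  # down in confounders, up in cancer
  expect_equal(get("Fasn"), "A")   # up everywhere
  expect_equal(get("Lcn2"), "other")  # no cancer evidence
  expect_false(any(pat$conflict))

  # opposite confounder calls -> both A and B apply -> flagged conflict
  conf2 <- list(
    make_profile("c1", "X", 0.5, "increased"),
    make_profile("c2", "X", -0.5, "decreased")
  )
  canc2 <- list(make_profile("k", "X", 0.7, "increased"))
  pat2 <- pattern_classify(conf2, canc2)
  expect_true(pat2$conflict)
  expect_equal(pat2$pattern, "conflict")
  expect_match(pat2$labels, "A")
  expect_match(pat2$labels, "C")
})

test_that("prioritization separates cancer-restricted from confounded genes", {
  canc <- list(
    make_profile("k1", c("Big", "Tiny", "Shared"), c(1.5, 0.4, 0.8),
                 c("increased", "increased", "increased"))
  )
  conf <- list(
    make_profile("c1", c("Shared", "Other"), c(0.6, -0.5),
                 c("increased", "decreased"))
  )
  pri <- prioritize_cancer_restricted(canc, conf)
  expect_equal(pri$prioritized$gene_symbol, c("Big", "Tiny"))  # by |ratio|
  expect_equal(pri$confounded$gene_symbol, "Shared")
  expect_equal(pri$prioritized$max_abs_log2_ratio, c(1.5, 0.4))

  # ties break lexicographically
  canc2 <- list(make_profile("k", c("Zed", "Abc"), c(0.9, 0.9),
                             rep("increased", 2)))
  pri2 <- prioritize_cancer_restricted(canc2, conf)
  expect_equal(pri2$prioritized$gene_symbol, c("Abc", "Zed"))

  empty <- list(make_profile("k0", "G", 0, "unchanged"))
  pri3 <- prioritize_cancer_restricted(empty, conf)
  expect_equal(nrow(pri3$prioritized), 0)
})
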