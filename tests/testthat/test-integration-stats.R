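test_that("gene-class definitions use strict FPKM boundaries", {
  expr <- data.frame(gene_id = c("a", "b", "c", "d"),
                     fpkm_RT = c(1.0, 2.0, 0, 5),
                     fpkm_cold = c(5.0, 1.1, 0, 0.5),
                     fpkm_leaf = c(2, 3, 0, 1))
  act <- active_genes(expr, "RT", "cold")
  expect_false("a" %in% act)   # FPKM exactly 1 is excluded
  expect_true("b" %in% act)
  sil <- silenced_genes(expr, c("RT", "cold", "leaf"))
  expect_equal(sil, "c")
  expect_length(intersect(act, sil), 0)
  expect_error(active_genes(expr, "RT", "root"), "missing sample")
})

test_that("DE intersection drops conflicts and caller-specific calls", {
  a <- data.frame(gene_id = c("g1", "g2", "g3"),
                  direction = c("up", "down", "up"),
                  fdr = c(0.001, 0.002, 0.5))
  b <- data.frame(gene_id = c("g1", "g2", "g4"),
                  direction = c("up", "up", "down"),
                  fdr = c(0.003, 0.001, 0.002))
  de <- intersect_de(a, b)
  expect_equal(de$gene_id, "g1")           # g2 conflicts, g3 fails FDR in A
  expect_equal(attr(de, "conflicts"), "g2")
  disjoint <- intersect_de(a[1, ], b[3, ])
  expect_equal(nrow(disjoint), 0)
})

test_that("two-proportion z test matches the pooled-variance formula", {
  eq <- proportion_ztest(30, 100, 60, 200)
  expect_equal(eq$z, 0)
  expect_equal(eq$p_two_tailed, 1)

  zt <- proportion_ztest(50, 100, 25, 100)
  expect_equal(zt$z, 3.6514, tolerance = 1e-4)
  expect_equal(zt$p_two_tailed, 2.60e-4, tolerance = 1e-2)
  # agrees with the chi-square test without continuity correction
  chi <- suppressWarnings(prop.test(c(50, 25), c(100, 100), correct = FALSE))
  expect_equal(zt$z^2, unname(chi$statistic), tolerance = 1e-10)
  expect_equal(zt$p_two_tailed, chi$p.value, tolerance = 1e-10)
  # antisymmetry
  sw <- proportion_ztest(25, 100, 50, 100)
  expect_equal(sw$z, -zt$z)
  expect_equal(sw$p_two_tailed, zt$p_two_tailed)
  # degenerate pooled proportion
  deg <- proportion_ztest(0, 10, 0, 10)
  expect_equal(c(deg$z, deg$p_two_tailed), c(0, 1))
})

test_that("rank-sum test: exact enumeration, ties, and the normal branch", {
  expect_equal(wilcoxon_rank_sum(c(1, 2, 3), c(1, 2, 3))$p_two_tailed, 1)
  ex <- wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))
  expect_equal(ex$p_two_tailed, 0.1)       # U = 0; 2 * (1/20)
  expect_equal(ex$method, "exact")

  # exact branch agrees with wilcox.test on untied small samples
  set.seed(2)
  for (i in 1:20) {
    a <- rnorm(sample(3:6, 1)); b <- rnorm(sample(3:6, 1))
    expect_equal(wilcoxon_rank_sum(a, b)$p_two_tailed,
                 wilcox.test(a, b, exact = TRUE)$p.value, tolerance = 1e-12)
  }
  # normal branch agrees with wilcox.test's corrected approximation
  set.seed(3)
  a <- rnorm(30); b <- rnorm(25, 0.5)
  expect_equal(wilcoxon_rank_sum(a, b)$p_two_tailed,
               wilcox.test(a, b, exact = FALSE, correct = TRUE)$p.value,
               tolerance = 1e-12)
  # self-consistency: approximation close to exact at n = 6 + 6
  set.seed(4)
  diffs <- replicate(100, {
    a <- rnorm(6); b <- rnorm(6)
    ex <- wilcoxon_rank_sum(a, b)$p_two_tailed
    ap <- wilcox.test(a, b, exact = FALSE, correct = TRUE)$p.value
    abs(ex - ap)
  })
  expect_gte(mean(diffs <= 0.02), 0.9)
  expect_lt(max(diffs), 0.07)
})

test_that("windowed density correlation matches the textbook formula", {
  set.seed(5)
  tr <- null_track(5000, L = 1e5, seed = 5)
  same <- window_density_correlation(tr, tr, 100)
  expect_equal(same$r, 1)

  tr2 <- null_track(5000, L = 1e5, seed = 6)
  indep <- window_density_correlation(tr, tr2, 100)
  expect_lt(abs(indep$r), 0.1)

  # 5-window toy, hand-computed Pearson r
  a <- cut_site_track(list(chr1 = c(0, 1, 10, 11, 12, 20, 30, 30, 31, 44)),
                      c(chr1 = 50))
  b <- cut_site_track(list(chr1 = c(2, 12, 13, 21, 22, 23, 33, 41, 42, 43)),
                      c(chr1 = 50))
  wc <- window_density_correlation(a, b, 10)
  ca <- c(2, 3, 1, 3, 1); cb <- c(1, 2, 3, 1, 3)
  r_hand <- sum((ca - mean(ca)) * (cb - mean(cb))) /
    sqrt(sum((ca - mean(ca))^2) * sum((cb - mean(cb))^2))
  expect_equal(wc$r, r_hand, tolerance = 1e-12)
  expect_error(window_density_correlation(a, b, 1e6), "fewer than 3")
})

test_that("z-test p-values are uniform under the null", {
  set.seed(7)
  n <- 2000
  pv <- replicate(2000, {
    x1 <- rbinom(1, n, 0.5); x2 <- rbinom(1, n, 0.5)
    proportion_ztest(x1, n, x2, n)$p_two_tailed
  })
  expect_gt(suppressWarnings(ks.test(pv, "punif")$p.value), 0.01)
})

test_that("DHS/gene association tables count harboring genes per category", {
  anno <- toy_annotation()
  empty <- random_dhs(5, seed = 1)[0, ]
  res0 <- dhs_gene_association(empty, anno, list(up = "geneA", down = "geneB"))
  expect_true(all(res0$table$count == 0))

  # printed-ratio arithmetic used in reporting
  expect_equal(percent_of(21430, 50531), 42.4)
  expect_equal(percent_of(11983, 31089), 38.5)

  dhs <- data.frame(chrom = "chr1",
                    start = c(2300, 2700, 9400, 1200),
                    end = c(2500, 2900, 9600, 1400),
                    summit = c(2400, 2800, 9500, 1300),
                    summit_count = 5, peak_density = 1, read_density = 1,
                    sample = "cold", stringsAsFactors = FALSE)
  res <- dhs_gene_association(dhs, anno,
                              list(up = c("geneA", "geneC"), down = "geneB"))
  tab <- res$table
  # geneA harbors an exonic and an intronic DHS, geneC an exonic one,
  # the upstream DHS also belongs to geneA
  expect_equal(tab$count[tab$class == "up" & tab$category == "exon"], 2)
  expect_equal(tab$count[tab$class == "up" & tab$category == "intron"], 1)
  expect_equal(tab$count[tab$class == "up" & tab$category == "upstream1k"], 1)
  expect_equal(tab$percent[tab$class == "up" & tab$category == "exon"], 100)
  expect_true(all(tab$count[tab$class == "down"] == 0))
  expect_true(is.data.frame(res$tests))
  # category fractions over a DHS set sum to 1
  set.seed(8)
  rd <- random_dhs(100, L = 20000, seed = 8)
  labs <- assign_dhs_feature(anno, rd)
  expect_equal(sum(table(labs)) / nrow(rd), 1)
})
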