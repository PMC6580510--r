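test_that("annotation generation respects spacing, emptiness and determinism", {
  empty <- generate_annotation(sim_config(n_genes = 0))
  expect_equal(nrow(empty$annotation$genes), 0)

  cfg <- sim_config(n_chroms = 1, chrom_length = 1e6, n_genes = 50, seed = 4)
  a1 <- generate_annotation(cfg)
  a2 <- generate_annotation(cfg)
  expect_identical(a1, a2)

  g <- a1$annotation$genes
  for (ch in unique(g$chrom)) {
    gi <- g[g$chrom == ch, ]
    gi <- gi[order(gi$start), ]
    if (nrow(gi) > 1)
      expect_true(all(gi$start[-1] - gi$end[-nrow(gi)] >= 2000))
  }
  # exons inside body, sorted, non-overlapping
  ex <- a1$annotation$exons
  for (id in unique(ex$gene_id)) {
    e <- ex[ex$gene_id == id, ]
    gi <- g[g$gene_id == id, ]
    expect_true(all(e$start >= gi$start & e$end <= gi$end))
    if (nrow(e) > 1) expect_true(all(e$start[-1] >= e$end[-nrow(e)]))
  }
  # sizing error when the chromosome cannot hold the genes
  expect_error(generate_annotation(sim_config(n_chroms = 1,
                                              chrom_length = 5e4,
                                              n_genes = 50)),
               "too short")
})

test_that("DNase simulation plants cold-only gene-body signal", {
  cfg <- small_config()
  ann <- generate_annotation(cfg)
  expect_error(simulate_dnase(cfg, ann$annotation, ann$labels, "tropical"),
               "unknown condition")

  empty_cfg <- small_config()
  empty_cfg$dnase_depth <- 0
  tr0 <- simulate_dnase(empty_cfg, ann$annotation, ann$labels, "RT", 1)
  expect_equal(tr0$library_size, 0)

  tr <- simulate_dnase(cfg, ann$annotation, ann$labels, "cold", 1)
  expect_equal(tr$library_size, cfg$dnase_depth)  # depth conservation
  expect_identical(tr, simulate_dnase(cfg, ann$annotation, ann$labels,
                                      "cold", 1))

  # cold > RT gene-body cuts for a cold-only genic gene: sign test, 20 seeds
  gid <- ann$labels$gene_id[ann$labels$genic_dhs_cold_only][1]
  gi <- ann$annotation$genes[ann$annotation$genes$gene_id == gid, ]
  lo <- min(gi$tss, gi$tts); hi <- max(gi$tss, gi$tts)
  wins <- vapply(1:20, function(s) {
    c2 <- cfg; c2$seed <- s
    an2 <- generate_annotation(c2)
    gid2 <- an2$labels$gene_id[an2$labels$genic_dhs_cold_only][1]
    gg <- an2$annotation$genes[an2$annotation$genes$gene_id == gid2, ]
    lo2 <- min(gg$tss, gg$tts); hi2 <- max(gg$tss, gg$tts)
    cold <- simulate_dnase(c2, an2$annotation, an2$labels, "cold", 1)
    rt <- simulate_dnase(c2, an2$annotation, an2$labels, "RT", 1)
    count_events(cold, gg$chrom, lo2, hi2) >
      count_events(rt, gg$chrom, lo2, hi2)
  }, logical(1))
  expect_lt(binom.test(sum(wins), 20, 0.5, "greater")$p.value, 0.01)
})

test_that("background cut rate obeys a Poisson tail bound", {
  cfg <- sim_config(n_chroms = 1, chrom_length = 1e6, n_genes = 8,
                    dnase_depth = 2e5, seed = 9)
  ann <- generate_annotation(cfg)
  tr <- simulate_dnase(cfg, ann$annotation, ann$labels, "RT", 1)
  g <- ann$annotation$genes
  # find a 10 kb stretch at least 3 kb from every gene
  cand <- seq(0, 1e6 - 1e4, by = 1e4)
  ok <- vapply(cand, function(s)
    all(g$end + 3000 <= s | g$start - 3000 >= s + 1e4), logical(1))
  s <- cand[which(ok)[1]]
  lambda <- 0.5 * cfg$dnase_depth / 1e6       # background share per bp
  cnt <- count_events(tr, "chr1", s, s + 1e4)
  expect_lt(abs(cnt - lambda * 1e4), 4 * sqrt(lambda * 1e4))
})

test_that("ChIP channels follow the planted mark logic", {
  cfg <- small_config(seed = 6)
  ann <- generate_annotation(cfg)
  expect_error(simulate_chip(cfg, ann$annotation, ann$labels, "H3K9me2",
                             "cold"),
               "unknown channel")

  # input midpoints uniform across the genome (chi-square GOF)
  big <- small_config(seed = 6)
  big$chip_depth <- 1e5
  inp <- simulate_chip(big, ann$annotation, ann$labels, "input", "cold")
  expect_equal(inp$library_size, 1e5)
  cnt <- tabulate(track_events(inp, "chr1") %/% 20000 + 1L, nbins = 20)
  expect_gt(chisq.test(cnt)$p.value, 0.01)

  # bivalent gene: K4-K27 body count exceeds K4-noAb across seeds
  wins <- vapply(1:10, function(s) {
    c2 <- small_config(seed = s)
    an2 <- generate_annotation(c2)
    gid <- an2$labels$gene_id[an2$labels$bivalent_planted][1]
    gg <- an2$annotation$genes[an2$annotation$genes$gene_id == gid, ]
    lo <- min(gg$tss, gg$tts); hi <- max(gg$tss, gg$tts)
    seqt <- simulate_chip(c2, an2$annotation, an2$labels, "K4-K27", "cold")
    noab <- simulate_chip(c2, an2$annotation, an2$labels, "K4-noAb", "cold")
    count_events(seqt, gg$chrom, lo, hi) > count_events(noab, gg$chrom, lo, hi)
  }, logical(1))
  expect_lt(binom.test(sum(wins), 10, 0.5, "greater")$p.value, 0.01)

  # K4-only gene body in K27-K4 is background-like vs flanking intergenic
  lab <- ann$labels
  k4only <- lab$gene_id[lab$expression_class != "silenced" &
                          !lab$bivalent_planted][1]
  gg <- ann$annotation$genes[ann$annotation$genes$gene_id == k4only, ]
  lo <- min(gg$tss, gg$tts); hi <- max(gg$tss, gg$tts)
  tr <- simulate_chip(cfg, ann$annotation, ann$labels, "K27-K4", "cold")
  body <- count_events(tr, gg$chrom, lo, hi)
  flank <- count_events(tr, gg$chrom, hi + 500, hi + 500 + (hi - lo))
  pt <- poisson.test(c(body, flank), c(1, 1))
  expect_gt(pt$p.value, 0.001)
})

test_that("expression tables encode truth and the DE intersection rule", {
  cfg <- small_config(seed = 8)
  ann <- generate_annotation(cfg)
  ex <- simulate_expression(cfg, ann$labels)
  lab <- ann$labels
  sil <- lab$gene_id[lab$expression_class == "silenced"]
  e <- ex$expression
  expect_true(all(e$fpkm_RT[e$gene_id %in% sil] == 0))
  expect_true(all(e$fpkm_cold[e$gene_id %in% sil] == 0))
  up <- lab$gene_id[lab$expression_class == "up"]
  expect_true(all(e$fpkm_cold[e$gene_id %in% up] >
                    e$fpkm_RT[e$gene_id %in% up]))
  down <- lab$gene_id[lab$expression_class == "down"]
  fc <- e$fpkm_RT[e$gene_id %in% down] / e$fpkm_cold[e$gene_id %in% down]
  expect_gte(median(fc), 1.5)
  # intersection recovers exactly the planted DEG set
  de <- intersect_de(ex$de_callerA, ex$de_callerB)
  planted <- sort(lab$gene_id[lab$expression_class %in% c("up", "down")])
  expect_identical(sort(de$gene_id), planted)
  dirs <- setNames(lab$expression_class, lab$gene_id)
  expect_identical(unname(dirs[de$gene_id]), de$direction)
  # each caller carries its own false positives (rule is non-trivial)
  expect_gt(nrow(ex$de_callerA), length(planted))
})
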