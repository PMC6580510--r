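test_that("chip signal matches hand-enumerated midpoint counting", {
  # 10-fragment toy: 6 midpoints inside [1000, 2000), input has 2
  tr <- frag_track(starts = c(950, 1000, 1100, 1200, 1300, 1500, 1700, 2100,
                              300, 5000),
                   ends = c(1150, 1160, 1260, 1380, 1460, 1640, 1860, 2260,
                            460, 5160))
  inp <- frag_track(starts = c(1100, 1500, 3000, 7000),
                    ends = c(1260, 1660, 3160, 7160),
                    channel = "input")
  iv <- data.frame(chrom = "chr1", start = 1000, end = 2000)
  # by hand: track mids {1050,1080,1180,1290,1380,1570,1780,2180,380,5080}
  #   -> 7 in window; input mids {1180,1580,3080,7080} -> 2 in window
  s_tr <- 7 / 1000 / (10 / 1e6)
  s_in <- 2 / 1000 / (4 / 1e6)
  expect_equal(chip_signal(tr, iv, inp), s_tr / s_in)

  # zero fragments in the interval -> 0
  iv0 <- data.frame(chrom = "chr1", start = 9000, end = 9500)
  expect_equal(chip_signal(tr, iv0, inp), 0)
  # a track normalized against itself is 1 wherever it has coverage
  expect_equal(chip_signal(tr, iv, tr), 1)
  bad <- frag_track(integer(0), integer(0))
  expect_error(chip_signal(bad, iv, inp), "zero library")
})

test_that("signal ratios are reciprocal and detect planted cold gains", {
  tr <- frag_track(starts = seq(100, 9000, by = 120),
                   ends = seq(250, 9150, by = 120))
  inp <- frag_track(starts = seq(130, 9100, by = 150),
                    ends = seq(280, 9250, by = 150), channel = "input")
  iv <- data.frame(chrom = "chr1", start = c(1000, 4000), end = c(2000, 5000))
  expect_equal(signal_ratio(tr, tr, inp, inp, iv), c(1, 1))
  r_ab <- signal_ratio(tr, inp, inp, inp, iv)
  r_ba <- signal_ratio(inp, tr, inp, inp, iv)
  expect_equal(r_ab * r_ba, c(1, 1), tolerance = 1e-6)
})

test_that("bivalent scoring validates channel pairing", {
  seqt <- frag_track(starts = c(100, 300), ends = c(250, 450),
                     channel = "K4-K27")
  noab <- frag_track(starts = c(150, 350), ends = c(300, 500),
                     channel = "K4-noAb")
  wrong <- frag_track(starts = c(150, 350), ends = c(300, 500),
                      channel = "K27-noAb")
  g <- data.frame(gene_id = "g", chrom = "chr1", strand = "+",
                  start = 0, end = 1000, tss = 0, tts = 1000)
  expect_error(bivalent_score(seqt, wrong, g), "pairing")
  expect_equal(bivalent_score(seqt, noab, g), 1)  # same counts, same depth
})

test_that("dual-order bivalent calling recovers the planted gene set", {
  scores0 <- data.frame(gene_id = c("a", "b"),
                        k4k27_RT = c(1, 2), k4k27_cold = c(1, 2),
                        k27k4_RT = c(1, 1), k27k4_cold = c(1, 1))
  expect_false(any(call_bivalent(scores0)$is_bivalent))

  cfg <- small_config(seed = 3)
  ann <- generate_annotation(cfg)
  tracks <- list()
  for (cond in c("RT", "cold"))
    for (chan in c("K4-K27", "K4-noAb", "K27-K4", "K27-noAb"))
      tracks[[cond]][[chan]] <-
        simulate_chip(cfg, ann$annotation, ann$labels, chan, cond)
  act <- ann$labels$gene_id[ann$labels$expression_class != "silenced"]
  calls <- call_bivalent(bivalent_scores(ann$annotation, act, tracks))
  truth <- ann$labels$gene_id[ann$labels$bivalent_planted]
  called <- calls$gene_id[calls$is_bivalent]
  tp <- length(intersect(called, truth))
  expect_gte(tp / max(1, length(called)), 0.9)  # precision
  expect_gte(tp / length(truth), 0.9)           # recall

  # invariance under uniform depth rescaling of one channel
  dbl <- tracks
  f2 <- tracks$cold$`K4-K27`$fragments$chr1[, c("start", "end")]
  dbl$cold$`K4-K27` <- fragment_track(
    list(chr1 = rbind(f2, f2)), c(chr1 = cfg$chrom_length),
    channel = "K4-K27", condition = "cold")
  calls2 <- call_bivalent(bivalent_scores(ann$annotation, act, dbl))
  expect_identical(calls2$is_bivalent, calls$is_bivalent)
})

test_that("mark classes recover the planted mark states", {
  expect_equal(mark_class(c(0.5, 3.0, 0.2, 2.0), c(0.4, 0.5, 3.0, 2.5)),
               c("neither", "K4-only", "K27-only", "both"))

  cfg <- small_config(seed = 5)
  ann <- generate_annotation(cfg)
  k4t <- simulate_chip(cfg, ann$annotation, ann$labels, "K4me3", "cold")
  k27t <- simulate_chip(cfg, ann$annotation, ann$labels, "K27me3", "cold")
  inp <- simulate_chip(cfg, ann$annotation, ann$labels, "input", "cold")
  g <- ann$annotation$genes
  iv <- data.frame(chrom = g$chrom, start = pmin(g$tss, g$tts),
                   end = pmax(g$tss, g$tts))
  cls <- mark_class(chip_signal(k4t, iv, inp), chip_signal(k27t, iv, inp))
  lab <- ann$labels[match(g$gene_id, ann$labels$gene_id), ]
  want <- ifelse(lab$bivalent_planted, "both",
                 ifelse(lab$expression_class == "silenced", "K27-only",
                        "K4-only"))
  expect_gte(mean(cls == want), 0.9)
})
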