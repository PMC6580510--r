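test_that("kernel density matches the direct Gaussian-summation oracle", {
  L <- 1000
  tr0 <- cut_site_track(list(chr1 = integer(0)), c(chr1 = L))
  expect_equal(kde_density(tr0, 50, "chr1"), numeric(L))

  tr1 <- cut_site_track(list(chr1 = 400), c(chr1 = L))
  d1 <- kde_density(tr1, 50, "chr1")
  expect_equal(which.max(d1) - 1, 400)
  expect_equal(max(d1), 1 / (sqrt(2 * pi) * 50), tolerance = 1e-9)

  cuts <- c(100, 110, 500)
  tr3 <- cut_site_track(list(chr1 = cuts), c(chr1 = L))
  d3 <- kde_density(tr3, 50, "chr1")
  expect_lt(max(abs(d3 - brute_kde(cuts, 50, L))), 1e-9)
  # profile integrates to the cut count up to boundary truncation
  expect_equal(sum(d3), sum(brute_kde(cuts, 50, L)), tolerance = 1e-6)
  expect_gt(sum(d3), 2.9)
})

test_that("null threshold controls the called fraction and is seed-stable", {
  tr <- null_track(2e4, L = 1e5, seed = 5)
  p <- caller_params(n_null = 10, seed = 2)
  th1 <- null_threshold(tr, p)
  th2 <- null_threshold(tr, p)
  expect_identical(th1$threshold, th2$threshold)

  # on a null input the called-base fraction stays within 1.5x nominal fdr
  called <- call_dhs(tr, p, "null")
  frac <- sum(called$end - called$start) / 1e5
  expect_lte(frac, 0.05 * 1.5)

  # fdr -> 1 limit: threshold drops to the low end of the density range
  p_loose <- caller_params(n_null = 5, fdr = 0.99, seed = 2)
  th_loose <- null_threshold(tr, p_loose)$threshold
  d <- kde_density(tr, 300, "chr1")
  expect_lt(th_loose, quantile(d, 0.5))
  expect_lt(th_loose, th1$threshold)

  # doubling n_null changes the threshold by < 10%
  p20 <- caller_params(n_null = 20, seed = 2)
  th20 <- null_threshold(tr, p20)$threshold
  if (is.finite(th1$threshold) && is.finite(th20))
    expect_lt(abs(th20 - th1$threshold) / th1$threshold, 0.10)
})

test_that("planted hotspots are recovered as distinct DHSs", {
  tr_empty <- cut_site_track(list(chr1 = integer(0)), c(chr1 = 1e5))
  expect_equal(nrow(call_dhs(tr_empty, caller_params(), "x")), 0)

  # one hotspot of 500 excess cuts on a uniform background
  tr1 <- hotspot_track(5e4, 500, 2e4, L = 1e5, hotspot_sd = 75, seed = 3)
  d1 <- call_dhs(tr1, caller_params(n_null = 10, seed = 3), "x")
  expect_equal(nrow(d1), 1)
  expect_true(d1$start <= 5e4 && d1$end > 5e4)

  # two hotspots 10 kb apart -> two disjoint DHSs, summits within 50 bp
  tr2 <- hotspot_track(c(4e4, 5e4), 500, 2e4, L = 1e5, seed = 4)
  d2 <- call_dhs(tr2, caller_params(n_null = 10, seed = 4), "x")
  expect_equal(nrow(d2), 2)
  expect_true(all(d2$start[-1] >= d2$end[-nrow(d2)]))
  expect_lt(abs(d2$summit[1] - 4e4), 50)
  expect_lt(abs(d2$summit[2] - 5e4), 50)
  # summit is inside its interval and density exceeds the threshold
  expect_true(all(d2$summit >= d2$start & d2$summit < d2$end))
  expect_true(all(d2$peak_density >= attr(d2, "threshold")))
})

test_that("consensus keeps 1-bp overlaps and unions partner intervals", {
  a <- random_dhs(1, seed = 1)
  a$start <- 100; a$end <- 200; a$summit <- 150; a$summit_count <- 5
  b <- a
  expect_equal(nrow(consensus_dhs(a, b[0, ])), 0)

  b$start <- 199; b$end <- 300; b$summit <- 250; b$summit_count <- 9
  cons <- consensus_dhs(a, b)
  expect_equal(nrow(cons), 1)
  expect_equal(c(cons$start, cons$end), c(100, 300))
  expect_equal(cons$summit, 250)        # replicate with larger summit count
  expect_equal(cons$sample, a$sample)   # identity follows replicate 1

  # half-open adjacency shares no base
  b2 <- b; b2$start <- 200
  expect_equal(nrow(consensus_dhs(a, b2)), 0)

  # summit-count tie goes to replicate 1
  b3 <- b; b3$summit_count <- 5
  expect_equal(consensus_dhs(a, b3)$summit, 150)
})

test_that("consensus and specific sets agree with the brute-force oracle", {
  for (seed in 1:4) {
    set.seed(seed)
    a <- random_dhs(sample(50:200, 1), seed = seed)
    b <- random_dhs(sample(50:200, 1), seed = seed + 100)
    hits <- brute_overlaps(a, b)
    spec <- specific_dhs(a, b)
    expect_identical(spec$start, a$start[rowSums(hits) == 0])
    cons <- consensus_dhs(a, b)
    expect_equal(nrow(cons), sum(rowSums(hits) > 0))
    # partition: specific + overlapping = all of A
    expect_equal(nrow(spec) + sum(rowSums(hits) > 0), nrow(a))
  }
  # setB empty leaves setA unchanged
  a <- random_dhs(20, seed = 9)
  expect_identical(specific_dhs(a, a[0, ]), a)
  # an exactly-1-bp overlap disqualifies
  b1 <- a[1, ]; b1$start <- a$end[1] - 1; b1$end <- a$end[1] + 50
  expect_false(a$start[1] %in% specific_dhs(a, b1)$start)
})

test_that("top regions rank by read density with a full-sort oracle", {
  d <- random_dhs(200, seed = 12)
  top <- top_dhs_regions(d, k = 50, halfwidth = 50)
  expect_equal(nrow(top), 50)
  expect_true(all(top$end - top$start == 100))
  ord <- order(-d$read_density, -d$summit_count, d$chrom, d$start)
  expect_equal(top$read_density, d$read_density[ord[1:50]])
  # k larger than the set returns everything
  expect_equal(nrow(top_dhs_regions(d, k = 1e4)), 200)
  expect_error(top_dhs_regions(d[0, ]), "empty")
})
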