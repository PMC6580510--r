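# Shared fixtures and independent oracles, all built in code.

# A 3-gene toy annotation on one 20 kb chromosome:
#   geneA (+): [2000, 4000), two exons [2000,2600) and [3200,4000)
#   geneB (-): [4000, 5000) body, TSS at 5000 (minus strand), single exon
#   geneC (+): [9000, 12000), single exon
toy_annotation <- function() {
  genes <- data.frame(
    gene_id = c("geneA", "geneB", "geneC"),
    chrom = "chr1",
    strand = c("+", "-", "+"),
    start = c(2000, 4000, 9000),
    end = c(4000, 5000, 12000))
  exons <- data.frame(
    gene_id = c("geneA", "geneA", "geneB", "geneC"),
    chrom = "chr1",
    start = c(2000, 3200, 4000, 9000),
    end = c(2600, 4000, 5000, 12000))
  gene_annotation(genes, exons, c(chr1 = 20000))
}

# Small synthetic study used for fast recovery tests.
small_config <- function(seed = 3, ...) {
  sim_config(n_chroms = 1, chrom_length = 4e5, n_genes = 60,
             dnase_depth = 6e4, chip_depth = 6e4, seed = seed, ...)
}

# Independent brute-force KDE: sum a Gaussian at every bp.
brute_kde <- function(cuts, bandwidth, L) {
  x <- seq(0, L - 1)
  out <- numeric(L)
  for (cut in cuts) out <- out + stats::dnorm(x, mean = cut, sd = bandwidth)
  out
}

# Brute-force O(n*m) half-open interval overlap oracle.
brute_overlaps <- function(a, b) {
  hits <- matrix(FALSE, nrow(a), nrow(b))
  for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b)))
    hits[i, j] <- a$chrom[i] == b$chrom[j] &&
      a$start[i] < b$end[j] && b$start[j] < a$end[i]
  hits
}

# Random DHS-like table for overlap property tests.
random_dhs <- function(n, L = 1e5, sample = "s", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  start <- sort(sample.int(L - 500, n))
  width <- sample(50:400, n, replace = TRUE)
  d <- data.frame(chrom = "chr1", start = start, end = pmin(start + width, L),
                  summit = start + width %/% 2,
                  summit_count = sample(1:50, n, replace = TRUE),
                  peak_density = runif(n), read_density = runif(n),
                  sample = sample, stringsAsFactors = FALSE)
  class(d) <- c("dhs_set", "data.frame")
  d
}

# Uniform-cut null track.
null_track <- function(n_cuts, L = 1e5, seed = 1, sample = "null") {
  set.seed(seed)
  cut_site_track(list(chr1 = floor(runif(n_cuts, 0, L))), c(chr1 = L),
                 sample = sample)
}

# Planted-hotspot track: uniform background plus Gaussian hotspots.
hotspot_track <- function(centers, cuts_per_hotspot, n_bg, L = 1e6,
                          hotspot_sd = 40, seed = 1) {
  set.seed(seed)
  bg <- floor(runif(n_bg, 0, L))
  hot <- unlist(lapply(centers, function(cc)
    round(stats::rnorm(cuts_per_hotspot, cc, hotspot_sd))))
  cut_site_track(list(chr1 = pmin(pmax(c(bg, hot), 0), L - 1)),
                 c(chr1 = L), sample = "planted")
}

# Fragment track from explicit fragments on chr1.
frag_track <- function(starts, ends, L = 20000, channel = "K4me3",
                       condition = "cold") {
  fragment_track(list(chr1 = data.frame(start = starts, end = ends)),
                 c(chr1 = L), channel = channel, condition = condition)
}
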