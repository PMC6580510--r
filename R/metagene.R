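#' Depth- and length-normalized signal
#'
#' The scaling used for all DNase and ChIP quantification: events per bp of
#' interval per million mapped reads, i.e.
#' `count / length / (library_size / 1e6)`.
#'
#' @param count event count in the interval.
#' @param length interval length in bp (> 0).
#' @param library_size total mapped events in the library (> 0).
#' @return normalized signal (vectorized).
#' @export
normalize_signal <- function(count, length, library_size) {
  if (any(library_size <= 0)) stop_input("library_size must be positive")
  if (any(length <= 0)) stop_input("length must be positive")
  count / length / (library_size / 1e6)
}

#' Metagene matrix of normalized signal
#'
#' For each gene, counts track events (DNase cut bases, or ChIP fragment
#' midpoints) in 100 gene-body bins spanning TSS to TTS plus 100 bins over
#' each 1 kb flank, normalizes each bin with [normalize_signal()], and
#' orients rows 5' to 3'. Genes shorter than `n_bins` bp are excluded with a
#' warning. Events on a bin boundary belong to the left (half-open) bin.
#'
#' @param track `cut_site_track` or `fragment_track`.
#' @param anno `gene_annotation`.
#' @param n_bins bins per segment (default 100).
#' @param flank flank width in bp (default 1000).
#' @return matrix (genes x `3 * n_bins`) of class `metagene_matrix`, rownames
#'   are gene ids; columns 1..100 upstream flank, 101..200 body,
#'   201..300 downstream flank.
#' @export
metagene_profile <- function(track, anno, n_bins = 100, flank = 1000) {
  g <- anno$genes
  short <- abs(g$tss - g$tts) < n_bins
  if (any(short)) {
    warning(sum(short), " gene(s) shorter than ", n_bins,
            " bp excluded from metagene profile")
    g <- g[!short, , drop = FALSE]
  }
  m <- matrix(0, nrow = nrow(g), ncol = 3 * n_bins,
              dimnames = list(g$gene_id, NULL))
  if (track$library_size > 0) {
    events <- lapply(names(track$chrom_lengths),
                     function(ch) track_events(track, ch))
    names(events) <- names(track$chrom_lengths)
    for (i in seq_len(nrow(g))) {
      bins <- gene_body_bins(g[i, ], n_bins = n_bins, flank = flank)
      gb <- bins[order(bins$start), , drop = FALSE]   # ascending genomic
      bounds <- c(gb$start, gb$end[nrow(gb)])
      ev <- events[[g$chrom[i]]]
      ev <- ev[ev >= bounds[1] & ev < bounds[length(bounds)]]
      cnt <- if (length(ev))
        tabulate(findInterval(ev, bounds), nbins = nrow(gb)) else
        integer(nrow(gb))
      m[i, gb$bin] <- normalize_signal(cnt, gb$end - gb$start,
                                       track$library_size)
    }
  }
  structure(m, class = c("metagene_matrix", class(m)),
            sample = if (!is.null(track$sample)) track$sample else
              paste(track$channel, track$condition, sep = "/"),
            n_bins = n_bins, flank = flank)
}

#' Expression quartile groups
#'
#' Splits the expressed genes (FPKM > 1) of one sample into four groups by
#' FPKM rank, from low (0-25%) to high (75-100%). A tie group straddling a
#' boundary is assigned whole to the lower quartile, so group sizes differ
#' by at most one only when values are distinct.
#'
#' @param expr data.frame with `gene_id` and an `fpkm_<sample>` column.
#' @param sample sample name, e.g. "RT".
#' @return named list of four character vectors of gene ids
#'   (`Q1` low ... `Q4` high).
#' @export
expression_quartiles <- function(expr, sample) {
  col <- paste0("fpkm_", sample)
  if (!col %in% names(expr)) stop_input("missing column ", col)
  e <- expr[expr[[col]] > 1, , drop = FALSE]
  if (!nrow(e)) return(stats::setNames(rep(list(character(0)), 4),
                                       paste0("Q", 1:4)))
  r <- rank(e[[col]], ties.method = "min")
  q <- ceiling(4 * r / length(r))
  lapply(stats::setNames(1:4, paste0("Q", 1:4)),
         function(k) e$gene_id[q == k])
}

#' Gene-body DNase I sensitivity
#'
#' Normalized event density over the gene body \[TSS, TTS).
#'
#' @param track a track object.
#' @param gene one row of the `genes` table.
#' @return scalar normalized signal.
#' @export
genic_sensitivity <- function(track, gene) {
  lo <- min(gene$tss, gene$tts); hi <- max(gene$tss, gene$tts)
  normalize_signal(count_events(track, gene$chrom, lo, hi), hi - lo,
                   track$library_size)
}

#' Per-gene sensitivity change between two conditions
#'
#' For each gene, the log2 ratio of gene-body sensitivity between tracks A
#' and B with a pseudo-signal of 0.01 keeping zero-signal genes finite. The
#' paired Wilcoxon signed-rank test across genes is reported alongside the
#' unpaired rank-sum between the two per-gene signal sets.
#'
#' @param trackA,trackB track objects (each normalized to its own library).
#' @param anno `gene_annotation`.
#' @param gene_ids genes to compare (non-empty).
#' @param eps pseudo-signal (default 0.01).
#' @return list: `table` (gene_id, signal_a, signal_b, log2_ratio),
#'   `median_log2`, `p_paired`, `p_unpaired`.
#' @export
sensitivity_change <- function(trackA, trackB, anno, gene_ids, eps = 0.01) {
  if (!length(gene_ids)) stop_input("empty gene set")
  g <- anno$genes[match(gene_ids, anno$genes$gene_id), , drop = FALSE]
  if (anyNA(g$gene_id)) stop_input("unknown gene ids")
  sa <- vapply(seq_len(nrow(g)),
               function(i) genic_sensitivity(trackA, g[i, ]), numeric(1))
  sb <- vapply(seq_len(nrow(g)),
               function(i) genic_sensitivity(trackB, g[i, ]), numeric(1))
  lr <- log2((sa + eps) / (sb + eps))
  p_paired <- if (all(lr == 0)) 1 else
    stats::wilcox.test(sa, sb, paired = TRUE, exact = FALSE)$p.value
  p_unpaired <- if (all(lr == 0)) 1 else
    stats::wilcox.test(sa, sb, exact = FALSE)$p.value
  list(table = data.frame(gene_id = g$gene_id, signal_a = sa, signal_b = sb,
                          log2_ratio = lr, stringsAsFactors = FALSE),
       median_log2 = stats::median(lr),
       p_paired = p_paired, p_unpaired = p_unpaired)
}
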