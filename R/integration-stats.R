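#' Active genes: expressed in both samples
#'
#' Genes with FPKM strictly greater than 1 in both samples.
#'
#' @param expr expression table with `fpkm_<sample>` columns.
#' @param sampleA,sampleB sample names, e.g. "RT", "cold".
#' @return character vector of gene ids.
#' @export
active_genes <- function(expr, sampleA, sampleB) {
  ca <- paste0("fpkm_", sampleA); cb <- paste0("fpkm_", sampleB)
  if (!all(c(ca, cb) %in% names(expr)))
    stop_input("missing sample column(s): ",
               paste(setdiff(c(ca, cb), names(expr)), collapse = ", "))
  expr$gene_id[expr[[ca]] > 1 & expr[[cb]] > 1]
}

#' Constitutively silenced genes
#'
#' Genes with FPKM equal to 0 in every listed sample.
#'
#' @param expr expression table.
#' @param samples sample names to require zero expression in.
#' @return character vector of gene ids.
#' @export
silenced_genes <- function(expr, samples) {
  cols <- paste0("fpkm_", samples)
  if (!all(cols %in% names(expr)))
    stop_input("missing sample column(s)")
  keep <- rowSums(as.matrix(expr[, cols, drop = FALSE]) == 0) == length(cols)
  expr$gene_id[keep]
}

#' Intersect two DE caller tables
#'
#' A gene is retained when both callers report it at FDR < `fdr_max` with
#' the same direction; direction conflicts are dropped (and reported in the
#' `conflicts` attribute).
#'
#' @param callsA,callsB data.frames with `gene_id`, `direction`
#'   ("up"/"down"), `fdr`.
#' @param fdr_max per-caller FDR cutoff (default 0.01).
#' @return data.frame `gene_id`, `direction` of the agreed DEG set, with
#'   attribute `conflicts` listing direction-conflicting gene ids.
#' @export
intersect_de <- function(callsA, callsB, fdr_max = 0.01) {
  a <- callsA[callsA$fdr < fdr_max, , drop = FALSE]
  b <- callsB[callsB$fdr < fdr_max, , drop = FALSE]
  m <- merge(a[, c("gene_id", "direction")], b[, c("gene_id", "direction")],
             by = "gene_id", suffixes = c("_a", "_b"))
  conflicts <- m$gene_id[m$direction_a != m$direction_b]
  keep <- m[m$direction_a == m$direction_b, , drop = FALSE]
  out <- data.frame(gene_id = keep$gene_id, direction = keep$direction_a,
                    stringsAsFactors = FALSE)
  out <- out[order(out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "conflicts") <- conflicts
  out
}

#' Two-proportion z test (pooled, two-tailed)
#'
#' Pooled-variance two-proportion z statistic with a two-tailed normal
#' p-value and no continuity correction. Degenerate tables (pooled
#' proportion 0 or 1) return z = 0, p = 1.
#'
#' @param x1,n1 successes and trials in group 1.
#' @param x2,n2 successes and trials in group 2.
#' @return list `x1`, `n1`, `x2`, `n2`, `z`, `p_two_tailed`.
#' @export
proportion_ztest <- function(x1, n1, x2, n2) {
  stopifnot(n1 > 0, n2 > 0, x1 >= 0, x2 >= 0, x1 <= n1, x2 <= n2)
  p_pool <- (x1 + x2) / (n1 + n2)
  if (p_pool == 0 || p_pool == 1) {
    z <- 0; p <- 1
  } else {
    se <- sqrt(p_pool * (1 - p_pool) * (1 / n1 + 1 / n2))
    z <- (x1 / n1 - x2 / n2) / se
    p <- 2 * stats::pnorm(-abs(z))
  }
  list(x1 = x1, n1 = n1, x2 = x2, n2 = n2, z = z, p_two_tailed = p)
}

#' Wilcoxon rank-sum test (exact at small n, tie-corrected otherwise)
#'
#' Two-sided rank-sum test: when the combined sample size is at most 12 the
#' p-value is computed by exact enumeration over all C(n, n_a) group
#' assignments of the (mid)ranks — valid with ties — otherwise by the normal
#' approximation with tie correction. All-tied input returns p = 1.
#'
#' @param a,b numeric vectors (non-empty).
#' @return list `W` (rank-sum U statistic of `a`), `p_two_tailed`,
#'   `method` ("exact" or "normal").
#' @export
wilcoxon_rank_sum <- function(a, b) {
  if (!length(a) || !length(b)) stop_input("both groups must be non-empty")
  na <- length(a); nb <- length(b); n <- na + nb
  r <- rank(c(a, b))
  ra <- sum(r[seq_len(na)])
  U <- ra - na * (na + 1) / 2
  if (length(unique(c(a, b))) == 1)
    return(list(W = U, p_two_tailed = 1, method = "degenerate"))
  if (n <= 12) {
    combs <- utils::combn(n, na)
    sums <- colSums(matrix(r[combs], nrow = na))
    d_obs <- abs(ra - na * (n + 1) / 2)
    p <- mean(abs(sums - na * (n + 1) / 2) >= d_obs - 1e-9)
    return(list(W = U, p_two_tailed = p, method = "exact"))
  }
  mu <- na * nb / 2
  ties <- table(r)
  sigma2 <- na * nb / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  z <- (abs(U - mu) - 0.5) / sqrt(sigma2)  # continuity-corrected
  list(W = U, p_two_tailed = min(1, 2 * stats::pnorm(-abs(z))),
       method = "normal")
}

#' Pearson correlation of windowed event densities
#'
#' Counts the events of two tracks in non-overlapping windows across the
#' genome and reports the Pearson correlation with its t-distribution
#' p-value (the computation behind replicate-coverage and density-vs-gene
#' correlations).
#'
#' @param trackA,trackB track objects over the same chromosomes.
#' @param window window size in bp (100 for replicate coverage, larger for
#'   density correlations).
#' @return list `r`, `p`, `n_windows`, plus the per-window count table.
#' @export
window_density_correlation <- function(trackA, trackB, window) {
  if (!identical(names(trackA$chrom_lengths), names(trackB$chrom_lengths)))
    stop_input("tracks are on different genomes")
  counts <- lapply(names(trackA$chrom_lengths), function(ch) {
    L <- trackA$chrom_lengths[[ch]]
    nb <- max(1L, as.integer(ceiling(L / window)))
    ca <- tabulate(track_events(trackA, ch) %/% window + 1L, nbins = nb)
    cb <- tabulate(track_events(trackB, ch) %/% window + 1L, nbins = nb)
    data.frame(chrom = ch, window = seq_len(nb) - 1L, a = ca, b = cb)
  })
  tab <- do.call(rbind, counts)
  if (nrow(tab) < 3) stop_input("fewer than 3 windows")
  ct <- stats::cor.test(tab$a, tab$b, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n_windows = nrow(tab),
       table = tab)
}

#' Association of condition-specific DHSs with gene classes
#'
#' Assigns each condition-specific DHS to the gene and feature containing
#' its summit, then for every gene class (e.g. up/down/constitutive DEGs)
#' and feature category counts the genes of the class harboring at least
#' one specific DHS in that category, with percentages of the class size.
#' Two-proportion z tests between the first two classes are attached per
#' category.
#'
#' @param dhs `dhs_set` of condition-specific DHSs.
#' @param anno `gene_annotation`.
#' @param gene_classes named list of character vectors of gene ids.
#' @param refined use the refined feature category set (default FALSE).
#' @return list: `table` (class x category counts and percentages) and
#'   `tests` (per-category z tests between the first two classes), plus
#'   `assignment` (per-DHS feature/gene).
#' @export
dhs_gene_association <- function(dhs, anno, gene_classes, refined = FALSE) {
  cats <- if (refined)
    c("exon", "intron", "TSS200", "upstream1k", "TTS200", "downstream1k",
      "intergenic_1to5k", "intergenic")
  else c("exon", "intron", "upstream1k", "downstream1k", "intergenic")
  asg <- assign_dhs_feature(anno, dhs, refined = refined, detail = TRUE)
  rows <- lapply(names(gene_classes), function(cl) {
    ids <- gene_classes[[cl]]
    n <- length(ids)
    cnt <- vapply(cats, function(ct) {
      length(unique(asg$gene_id[!is.na(asg$gene_id) &
                                  asg$label == ct & asg$gene_id %in% ids]))
    }, integer(1))
    pct <- if (n > 0) vapply(cnt, percent_of, numeric(1), n = n) else
      rep(NA_real_, length(cnt))
    data.frame(class = cl, n_genes = n, category = cats, count = cnt,
               percent = pct, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  tests <- NULL
  if (length(gene_classes) >= 2) {
    c1 <- names(gene_classes)[1]; c2 <- names(gene_classes)[2]
    tests <- do.call(rbind, lapply(cats, function(ct) {
      r1 <- tab[tab$class == c1 & tab$category == ct, ]
      r2 <- tab[tab$class == c2 & tab$category == ct, ]
      if (r1$n_genes == 0 || r2$n_genes == 0) return(NULL)
      zt <- proportion_ztest(r1$count, r1$n_genes, r2$count, r2$n_genes)
      data.frame(category = ct, z = zt$z, p_two_tailed = zt$p_two_tailed)
    }))
  }
  list(table = tab, tests = tests, assignment = asg)
}
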