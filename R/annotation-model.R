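#' Gene annotation container
#'
#' A light container holding one representative transcript model per gene.
#' Coordinates are 0-based half-open genomic. For a minus-strand gene the TSS
#' is the *end* boundary and the TTS the *start* boundary, so `tss > tts`
#' exactly when `strand == "-"`; the gene body interval is always
#' `[min(tss, tts), max(tss, tts))`.
#'
#' @param genes data.frame with columns `gene_id`, `chrom`, `strand` (+/-),
#'   `start`, `end` (0-based half-open body interval).
#' @param exons data.frame with columns `gene_id`, `chrom`, `start`, `end`;
#'   sorted, non-overlapping within a gene, contained in the gene body.
#' @param chrom_lengths named numeric vector.
#' @return object of class `gene_annotation` with derived `tss`/`tts` columns.
#' @export
gene_annotation <- function(genes, exons, chrom_lengths) {
  stopifnot(all(c("gene_id", "chrom", "strand", "start", "end") %in% names(genes)))
  stopifnot(all(genes$strand %in% c("+", "-")))
  if (nrow(genes) && any(genes$start >= genes$end)) stop_input("gene start >= end")
  genes$start <- as.integer(genes$start); genes$end <- as.integer(genes$end)
  exons$start <- as.integer(exons$start); exons$end <- as.integer(exons$end)
  genes$tss <- ifelse(genes$strand == "+", genes$start, genes$end)
  genes$tts <- ifelse(genes$strand == "+", genes$end, genes$start)
  genes <- genes[order(genes$chrom, genes$start), , drop = FALSE]
  rownames(genes) <- NULL
  if (nrow(exons)) {
    exons <- exons[order(exons$gene_id, exons$start), , drop = FALSE]
    rownames(exons) <- NULL
  }
  structure(list(genes = genes, exons = exons, chrom_lengths = chrom_lengths),
            class = "gene_annotation")
}

#' @export
print.gene_annotation <- function(x, ...) {
  cat("<gene_annotation>", nrow(x$genes), "genes,", nrow(x$exons), "exons,",
      length(x$chrom_lengths), "chromosomes\n")
  invisible(x)
}

# Feature window tables in precedence order. Each element is a data.frame
# (chrom, start, end, gene_id, tss) of 0-based half-open windows.
feature_windows <- function(anno, refined = FALSE) {
  g <- anno$genes
  ex <- anno$exons
  mk <- function(chrom, start, end, gene_id, tss) {
    if (!length(chrom))
      return(data.frame(chrom = character(0), start = numeric(0),
                        end = numeric(0), gene_id = character(0),
                        tss = numeric(0), stringsAsFactors = FALSE))
    d <- data.frame(chrom = chrom, start = pmax(0, start), end = end,
                    gene_id = gene_id, tss = tss, stringsAsFactors = FALSE)
    d[d$start < d$end, , drop = FALSE]
  }
  tssmap <- stats::setNames(g$tss, g$gene_id)
  exon <- if (nrow(ex)) mk(ex$chrom, ex$start, ex$end, ex$gene_id,
                           tssmap[ex$gene_id]) else mk(character(0), 0, 0, character(0), 0)
  body <- mk(g$chrom, pmin(g$tss, g$tts), pmax(g$tss, g$tts), g$gene_id, g$tss)
  up1k <- mk(g$chrom,
             ifelse(g$strand == "+", g$tss - 1000, g$tss),
             ifelse(g$strand == "+", g$tss, g$tss + 1000),
             g$gene_id, g$tss)
  dn1k <- mk(g$chrom,
             ifelse(g$strand == "+", g$tts, g$tts - 1000),
             ifelse(g$strand == "+", g$tts + 1000, g$tts),
             g$gene_id, g$tss)
  out <- list(exon = exon, intron = body, upstream1k = up1k, downstream1k = dn1k)
  if (refined) {
    tss200 <- mk(g$chrom,
                 ifelse(g$strand == "+", g$tss - 200, g$tss),
                 ifelse(g$strand == "+", g$tss, g$tss + 200),
                 g$gene_id, g$tss)
    tts200 <- mk(g$chrom,
                 ifelse(g$strand == "+", g$tts, g$tts - 200),
                 ifelse(g$strand == "+", g$tts + 200, g$tts),
                 g$gene_id, g$tss)
    ig5k_up <- mk(g$chrom,
                  ifelse(g$strand == "+", g$tss - 5000, g$tss + 1000),
                  ifelse(g$strand == "+", g$tss - 1000, g$tss + 5000),
                  g$gene_id, g$tss)
    ig5k_dn <- mk(g$chrom,
                  ifelse(g$strand == "+", g$tts + 1000, g$tts - 5000),
                  ifelse(g$strand == "+", g$tts + 5000, g$tts - 1000),
                  g$gene_id, g$tss)
    out <- list(exon = exon, intron = body, TSS200 = tss200, upstream1k = up1k,
                TTS200 = tts200, downstream1k = dn1k,
                intergenic_1to5k = rbind(ig5k_up, ig5k_dn))
  }
  out
}

# For positions inside the gene body, exon windows take precedence and the
# remainder is intron; the "intron" table above is the whole body, so exon
# membership must be checked first (it is, by list order).

#' Classify genomic positions against gene features
#'
#' Assigns each position the highest-precedence feature it falls in:
#' exon > intron > 1 kb upstream of a TSS > 1 kb downstream of a TTS >
#' intergenic (more than 1 kb from every TSS and TTS). Windows are
#' strand-aware (upstream means 5' of the TSS in transcription orientation).
#' When windows of equal rank from several genes overlap a position, the gene
#' with the nearest TSS wins; remaining ties break lexicographically on
#' `gene_id`.
#'
#' @param anno `gene_annotation`.
#' @param chrom chromosome id (scalar).
#' @param pos integer vector of 0-based positions.
#' @param refined if TRUE use the refined category set
#'   (exon, intron, TSS200, upstream1k, TTS200, downstream1k,
#'   intergenic_1to5k, intergenic).
#' @param detail if TRUE return a data.frame with the assigned `gene_id`
#'   (NA for intergenic) alongside the label.
#' @return character vector of labels, or a data.frame when `detail = TRUE`.
#' @export
classify_position <- function(anno, chrom, pos, refined = FALSE, detail = FALSE) {
  if (!chrom %in% names(anno$chrom_lengths)) stop_input("unknown chrom: ", chrom)
  wins <- feature_windows(anno, refined = refined)
  n <- length(pos)
  label <- rep("intergenic", n)
  gene <- rep(NA_character_, n)
  unassigned <- rep(TRUE, n)
  q <- IRanges::IRanges(start = pos + 1L, width = 1L)
  for (lab in names(wins)) {
    if (!any(unassigned)) break
    w <- wins[[lab]]
    w <- w[w$chrom == chrom, , drop = FALSE]
    if (!nrow(w)) next
    s <- IRanges::IRanges(start = w$start + 1L, end = w$end)
    hits <- IRanges::findOverlaps(q, s)
    if (!length(hits)) next
    qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
    keep <- qh[unassigned[qh]]
    if (!length(keep)) next
    sel <- unassigned[qh]
    qh <- qh[sel]; sh <- sh[sel]
    # tie-break among candidate genes: nearest TSS, then gene_id
    d <- abs(pos[qh] - w$tss[sh])
    ord <- order(qh, d, w$gene_id[sh])
    qh <- qh[ord]; sh <- sh[ord]
    first <- !duplicated(qh)
    idx <- qh[first]
    label[idx] <- if (lab == "intron") "intron" else lab
    gene[idx] <- w$gene_id[sh[first]]
    unassigned[idx] <- FALSE
  }
  if (detail) data.frame(pos = pos, label = label, gene_id = gene,
                         stringsAsFactors = FALSE)
  else label
}

#' Assign a DHS to a genomic feature by its summit
#'
#' A DHS is placed in the feature containing its single-bp summit (the most
#' frequent cut site), regardless of where the rest of the interval falls.
#'
#' @param anno `gene_annotation`.
#' @param dhs data.frame of DHS calls with columns `chrom`, `summit`.
#' @param refined,detail passed to [classify_position()].
#' @return character labels (or data.frame when `detail = TRUE`) per DHS.
#' @export
assign_dhs_feature <- function(anno, dhs, refined = FALSE, detail = FALSE) {
  if (!nrow(dhs)) {
    if (detail) return(data.frame(pos = integer(0), label = character(0),
                                  gene_id = character(0)))
    return(character(0))
  }
  out <- vector(if (detail) "list" else "character", 0)
  res_label <- rep(NA_character_, nrow(dhs))
  res_gene <- rep(NA_character_, nrow(dhs))
  for (ch in unique(dhs$chrom)) {
    i <- which(dhs$chrom == ch)
    r <- classify_position(anno, ch, dhs$summit[i], refined = refined, detail = TRUE)
    res_label[i] <- r$label
    res_gene[i] <- r$gene_id
  }
  if (detail) data.frame(chrom = dhs$chrom, summit = dhs$summit,
                         label = res_label, gene_id = res_gene,
                         stringsAsFactors = FALSE)
  else res_label
}

#' Gene-body and flank bins for metagene profiles
#'
#' Splits a gene into `n_bins` body bins covering \[TSS, TTS) exactly (widths
#' differing by at most 1 bp) plus `n_bins` upstream-flank and `n_bins`
#' downstream-flank bins of `flank / n_bins` bp each. Bins are ordered 5' to
#' 3' in transcription orientation, so for a minus-strand gene bin 1 sits at
#' the highest genomic coordinate.
#'
#' @param gene one row of the `genes` table (with `strand`, `tss`, `tts`).
#' @param n_bins bins per segment (default 100).
#' @param flank flank width in bp (default 1000).
#' @return data.frame with `start`, `end` (0-based half-open, genomic),
#'   `bin` (1..3*n_bins, transcription order) and
#'   `segment` (upstream/body/downstream).
#' @export
gene_body_bins <- function(gene, n_bins = 100, flank = 1000) {
  len <- abs(gene$tss - gene$tts)
  if (len < n_bins)
    stop_input("gene ", gene$gene_id, " shorter than n_bins (", len, " bp)")
  lo <- min(gene$tss, gene$tts); hi <- max(gene$tss, gene$tts)
  body_bounds <- lo + round(seq(0, len, length.out = n_bins + 1))
  w <- flank / n_bins
  upg_bounds <- round(seq(lo - flank, lo, length.out = n_bins + 1))
  dng_bounds <- round(seq(hi, hi + flank, length.out = n_bins + 1))
  seg <- function(b, name) data.frame(start = b[-length(b)], end = b[-1],
                                      segment = name, stringsAsFactors = FALSE)
  d <- rbind(seg(upg_bounds, "left"), seg(body_bounds, "body"),
             seg(dng_bounds, "right"))
  if (gene$strand == "+") {
    d$segment <- c(rep("upstream", n_bins), rep("body", n_bins),
                   rep("downstream", n_bins))
    d$bin <- seq_len(3 * n_bins)
  } else {
    d <- d[rev(seq_len(nrow(d))), , drop = FALSE]
    d$segment <- c(rep("upstream", n_bins), rep("body", n_bins),
                   rep("downstream", n_bins))
    d$bin <- seq_len(3 * n_bins)
  }
  rownames(d) <- NULL
  d
}

#' Random length-matched intergenic control intervals
#'
#' Draws intervals at least `min_dist` bp away from every annotated gene,
#' with lengths matching `template_lengths` one-to-one (the control
#' construction used against constitutively silenced genes). Placement is
#' uniform over all eligible start positions and deterministic per seed.
#'
#' @param anno `gene_annotation`.
#' @param template_lengths integer vector of interval lengths to match.
#' @param min_dist minimum distance from any gene (default 2000).
#' @param seed integer seed.
#' @return data.frame `chrom`, `start`, `end`.
#' @export
select_random_intergenic <- function(anno, template_lengths, min_dist = 2000,
                                     seed = 1) {
  if (!length(template_lengths))
    return(data.frame(chrom = character(0), start = integer(0), end = integer(0)))
  g <- anno$genes
  blocks <- do.call(rbind, lapply(names(anno$chrom_lengths), function(ch) {
    L <- anno$chrom_lengths[[ch]]
    gi <- g[g$chrom == ch, , drop = FALSE]
    if (!nrow(gi)) return(data.frame(chrom = ch, start = 0, end = L))
    grown <- IRanges::reduce(IRanges::IRanges(
      start = pmax(1, gi$start - min_dist + 1), end = pmin(L, gi$end + min_dist)))
    gaps <- IRanges::gaps(grown, start = 1, end = L)
    if (!length(gaps)) return(NULL)
    data.frame(chrom = ch, start = IRanges::start(gaps) - 1,
               end = IRanges::end(gaps))
  }))
  with_seed(seed, {
    out <- lapply(as.integer(template_lengths), function(len) {
      ok <- blocks[(blocks$end - blocks$start) >= len, , drop = FALSE]
      if (!nrow(ok))
        stop_input("no eligible intergenic space for a ", len, " bp control")
      cap <- ok$end - ok$start - len + 1
      pick <- sample.int(nrow(ok), 1, prob = cap)
      off <- sample.int(cap[pick], 1) - 1L
      data.frame(chrom = ok$chrom[pick], start = ok$start[pick] + off,
                 end = ok$start[pick] + off + len)
    })
    do.call(rbind, out)
  })
}
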