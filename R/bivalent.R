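#' Input-normalized ChIP signal over intervals
#'
#' Fragment-midpoint density in each interval normalized per bp per million
#' mapped reads, divided by the same quantity in the input (floored at
#' `eps`), the triple normalization used for all histone-mark levels.
#'
#' @param track `fragment_track` for the mark.
#' @param intervals data.frame `chrom`, `start`, `end`.
#' @param input_track `fragment_track` for input (same condition).
#' @param eps denominator floor (default 0.01).
#' @return numeric vector, one signal per interval.
#' @export
chip_signal <- function(track, intervals, input_track, eps = 0.01) {
  if (track$library_size == 0 || input_track$library_size == 0)
    stop_input("zero library size")
  n <- nrow(intervals)
  s <- numeric(n); s0 <- numeric(n)
  for (ch in unique(intervals$chrom)) {
    i <- which(intervals$chrom == ch)
    len <- intervals$end[i] - intervals$start[i]
    s[i] <- normalize_signal(
      count_events(track, ch, intervals$start[i], intervals$end[i]),
      len, track$library_size)
    s0[i] <- normalize_signal(
      count_events(input_track, ch, intervals$start[i], intervals$end[i]),
      len, input_track$library_size)
  }
  s / pmax(s0, eps)
}

#' Cold/RT ChIP signal ratio
#'
#' Ratio of input-normalized signal between two conditions over the same
#' intervals, with the RT signal floored at `eps`.
#'
#' @param track_cold,track_rt mark tracks for the two conditions.
#' @param input_cold,input_rt matching input tracks.
#' @param intervals data.frame `chrom`, `start`, `end`.
#' @param eps floor (default 0.01).
#' @return numeric ratio vector.
#' @export
signal_ratio <- function(track_cold, track_rt, input_cold, input_rt,
                         intervals, eps = 0.01) {
  a <- chip_signal(track_cold, intervals, input_cold, eps = eps)
  b <- chip_signal(track_rt, intervals, input_rt, eps = eps)
  a / pmax(b, eps)
}

.noab_partner <- c("K4-K27" = "K4-noAb", "K27-K4" = "K27-noAb")

#' Bivalent mark score of a gene body
#'
#' Sequential-ChIP signal over \[TSS, TTS) normalized to the matching
#' no-antibody control of the same first antibody (K4-K27 with K4-noAb,
#' K27-K4 with K27-noAb), per bp and per million mapped reads.
#'
#' @param seq_track sequential-ChIP `fragment_track` (K4-K27 or K27-K4).
#' @param noab_track matching no-antibody control track, same condition.
#' @param genes one or more rows of the `genes` table.
#' @param eps denominator floor (default 0.01).
#' @return numeric score per gene.
#' @export
bivalent_score <- function(seq_track, noab_track, genes, eps = 0.01) {
  want <- .noab_partner[seq_track$channel]
  if (is.na(want) || !identical(noab_track$channel, unname(want)))
    stop_input("channel pairing must be K4-K27/K4-noAb or K27-K4/K27-noAb; got ",
               seq_track$channel, " with ", noab_track$channel)
  if (!identical(seq_track$condition, noab_track$condition))
    stop_input("sequential and control tracks are from different conditions")
  iv <- data.frame(chrom = genes$chrom,
                   start = pmin(genes$tss, genes$tts),
                   end = pmax(genes$tss, genes$tts))
  chip_signal(seq_track, iv, noab_track, eps = eps)
}

#' Compute dual-order bivalent scores for a gene set
#'
#' Convenience wrapper producing the score table consumed by
#' [call_bivalent()]: K4-K27 and K27-K4 scores for both conditions.
#'
#' @param anno `gene_annotation`.
#' @param gene_ids genes to score.
#' @param tracks named list of `fragment_track`s with entries
#'   `K4-K27`, `K4-noAb`, `K27-K4`, `K27-noAb` for each of `RT` and `cold`,
#'   nested as `tracks$RT$"K4-K27"` etc.
#' @return data.frame `gene_id`, `k4k27_RT`, `k4k27_cold`, `k27k4_RT`,
#'   `k27k4_cold`.
#' @export
bivalent_scores <- function(anno, gene_ids, tracks) {
  g <- anno$genes[match(gene_ids, anno$genes$gene_id), , drop = FALSE]
  if (anyNA(g$gene_id)) stop_input("unknown gene ids")
  need <- c("K4-K27", "K4-noAb", "K27-K4", "K27-noAb")
  for (cond in c("RT", "cold")) {
    if (!all(need %in% names(tracks[[cond]])))
      stop_input("missing sequential channel(s) for ", cond, ": ",
                 paste(setdiff(need, names(tracks[[cond]])), collapse = ", "))
  }
  data.frame(
    gene_id = g$gene_id,
    k4k27_RT = bivalent_score(tracks$RT$`K4-K27`, tracks$RT$`K4-noAb`, g),
    k4k27_cold = bivalent_score(tracks$cold$`K4-K27`, tracks$cold$`K4-noAb`, g),
    k27k4_RT = bivalent_score(tracks$RT$`K27-K4`, tracks$RT$`K27-noAb`, g),
    k27k4_cold = bivalent_score(tracks$cold$`K27-K4`, tracks$cold$`K27-noAb`, g),
    stringsAsFactors = FALSE)
}

#' Call bivalent genes from dual-order sequential-ChIP scores
#'
#' A gene is called bivalent when its bivalent score increases upon cold in
#' *both* antibody orders (K4-K27 and K27-K4), the dual-order requirement
#' that excludes carry-over artifacts. "Increases" is a strict inequality;
#' `min_fold` (default 1) can demand a minimum cold/RT fold change.
#'
#' @param scores score table from [bivalent_scores()] (active genes only).
#' @param min_fold minimum fold increase (default 1 = any increase).
#' @return the `scores` data.frame with a logical `is_bivalent` column.
#' @export
call_bivalent <- function(scores, min_fold = 1) {
  stopifnot(all(c("k4k27_RT", "k4k27_cold", "k27k4_RT", "k27k4_cold")
                %in% names(scores)))
  scores$is_bivalent <- scores$k4k27_cold > min_fold * scores$k4k27_RT &
    scores$k27k4_cold > min_fold * scores$k27k4_RT
  scores
}

#' Mark class of genes from single-mark signals
#'
#' Classifies each gene by thresholding its input-normalized gene-body
#' H3K4me3 and H3K27me3 signals at `enrich_threshold`.
#'
#' @param k4_signal,k27_signal numeric vectors of input-normalized signals.
#' @param enrich_threshold enrichment cutoff (default 1.5).
#' @return character vector in \{"K4-only", "K27-only", "both", "neither"\}.
#' @export
mark_class <- function(k4_signal, k27_signal, enrich_threshold = 1.5) {
  k4 <- k4_signal >= enrich_threshold
  k27 <- k27_signal >= enrich_threshold
  out <- rep("neither", length(k4))
  out[k4 & !k27] <- "K4-only"
  out[!k4 & k27] <- "K27-only"
  out[k4 & k27] <- "both"
  out
}
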