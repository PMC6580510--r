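# Plain-text writers/readers for the interchange formats used by the
# pipeline. All internal coordinates are 0-based half-open; BED-family
# formats are written as-is, GFF3 converts to 1-based closed at the
# boundary.

.write_tab <- function(df, path, col.names = FALSE) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = col.names)
}

#' Write a TSV with header
#' @param df data.frame.
#' @param path output path.
#' @export
write_tsv <- function(df, path) .write_tab(df, path, col.names = TRUE)

#' Read a TSV with header
#' @param path input path.
#' @return data.frame.
#' @export
read_tsv <- function(path)
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)

#' Write cut sites as 6-column BED (one 1-bp record per cut)
#' @param track `cut_site_track`.
#' @param path output path.
#' @export
write_cuts_bed <- function(track, path) {
  rows <- lapply(names(track$cuts), function(ch) {
    p <- track$cuts[[ch]]
    if (!length(p)) return(NULL)
    data.frame(chrom = ch, start = p, end = p + 1L, name = track$sample,
               score = 0L, strand = ".")
  })
  df <- do.call(rbind, rows)
  if (is.null(df)) df <- data.frame()
  .write_tab(df, path)
}

#' Read cut sites from a BED file
#' @param path BED path (first two columns used: chrom, start).
#' @param chrom_lengths named chromosome lengths.
#' @param sample sample id for the track.
#' @return `cut_site_track`.
#' @export
read_cuts_bed <- function(path, chrom_lengths, sample = basename(path)) {
  df <- tryCatch(utils::read.table(path, sep = "\t", header = FALSE,
                                   stringsAsFactors = FALSE),
                 error = function(e) NULL)
  if (is.null(df) || !nrow(df))
    return(cut_site_track(list(), chrom_lengths, sample = sample))
  cuts <- split(df[[2]], df[[1]])
  cut_site_track(cuts, chrom_lengths, sample = sample)
}

#' Write a DHS set as BED6
#'
#' Score is `1000 * min(1, peak_density / threshold)` when the calling
#' threshold is attached, else 1000.
#'
#' @param dhs `dhs_set`.
#' @param path output path.
#' @export
write_dhs_bed <- function(dhs, path) {
  if (!nrow(dhs)) return(.write_tab(data.frame(), path))
  thr <- attr(dhs, "threshold")
  score <- if (!is.null(thr) && is.finite(thr))
    as.integer(round(1000 * pmin(1, dhs$peak_density / thr))) else
    rep(1000L, nrow(dhs))
  .write_tab(data.frame(dhs$chrom, dhs$start, dhs$end, dhs$sample,
                        score, "."), path)
}

#' Write DHS summits as 1-bp BED intervals
#' @param dhs `dhs_set`.
#' @param path output path.
#' @export
write_summits_bed <- function(dhs, path) {
  if (!nrow(dhs)) return(.write_tab(data.frame(), path))
  .write_tab(data.frame(dhs$chrom, dhs$summit, dhs$summit + 1L,
                        dhs$sample, dhs$summit_count, "."), path)
}

#' Write fragments as BEDPE
#'
#' Mate intervals are the outer 50 bp of each fragment; reading the file
#' back reconstructs each fragment as `[start1, end2)`.
#'
#' @param track `fragment_track`.
#' @param path output path.
#' @export
write_bedpe <- function(track, path) {
  rows <- lapply(names(track$fragments), function(ch) {
    f <- track$fragments[[ch]]
    if (!nrow(f)) return(NULL)
    data.frame(chrom1 = ch, start1 = f$start,
               end1 = pmin(f$start + 50L, f$end),
               chrom2 = ch, start2 = pmax(f$end - 50L, f$start),
               end2 = f$end,
               name = paste(track$channel, track$condition, sep = "_"),
               score = 0L, strand1 = "+", strand2 = "-")
  })
  df <- do.call(rbind, rows)
  if (is.null(df)) df <- data.frame()
  .write_tab(df, path)
}

#' Read fragments from a BEDPE file
#' @param path BEDPE path.
#' @param chrom_lengths named chromosome lengths.
#' @param channel,condition track metadata.
#' @return `fragment_track`.
#' @export
read_bedpe <- function(path, chrom_lengths, channel = "channel",
                       condition = "condition") {
  df <- tryCatch(utils::read.table(path, sep = "\t", header = FALSE,
                                   stringsAsFactors = FALSE),
                 error = function(e) NULL)
  if (is.null(df) || !nrow(df))
    return(fragment_track(list(), chrom_lengths, channel, condition))
  frag <- data.frame(chrom = df[[1]], start = df[[2]], end = df[[6]])
  frags <- lapply(split(frag, frag$chrom),
                  function(d) d[, c("start", "end"), drop = FALSE])
  fragment_track(frags, chrom_lengths, channel, condition)
}

#' Write a per-bp density profile as bedGraph
#'
#' Consecutive equal values are collapsed into runs.
#'
#' @param density numeric per-bp vector.
#' @param chrom chromosome id.
#' @param path output path.
#' @param digits value rounding (default 6).
#' @export
write_bedgraph <- function(density, chrom, path, digits = 6) {
  v <- round(density, digits)
  r <- rle(v)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  .write_tab(data.frame(chrom, starts, ends, r$values), path)
}

#' Write a gene annotation as GFF3
#'
#' Emits `gene` and `exon` features with ID/Parent attributes; internal
#' 0-based half-open coordinates become 1-based closed.
#'
#' @param anno `gene_annotation`.
#' @param path output path.
#' @export
write_gff3 <- function(anno, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (ch in names(anno$chrom_lengths))
    writeLines(sprintf("##sequence-region %s 1 %d", ch,
                       as.integer(anno$chrom_lengths[[ch]])), con)
  g <- anno$genes
  if (nrow(g)) {
    lines <- character(0)
    for (i in seq_len(nrow(g))) {
      lines <- c(lines, sprintf("%s\tcoldchrom\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                                g$chrom[i], g$start[i] + 1L, g$end[i],
                                g$strand[i], g$gene_id[i]))
      ex <- anno$exons[anno$exons$gene_id == g$gene_id[i], , drop = FALSE]
      if (nrow(ex))
        lines <- c(lines, sprintf(
          "%s\tcoldchrom\texon\t%d\t%d\t.\t%s\t.\tID=%s.exon%d;Parent=%s",
          ex$chrom, ex$start + 1L, ex$end, g$strand[i], g$gene_id[i],
          seq_len(nrow(ex)), g$gene_id[i]))
    }
    writeLines(lines, con)
  }
  invisible(path)
}

#' Read a GFF3 annotation (gene and exon features)
#'
#' @param path GFF3 path.
#' @param chrom_lengths named chromosome lengths; when NULL they are taken
#'   from `##sequence-region` pragmas.
#' @return `gene_annotation`.
#' @export
read_gff3 <- function(path, chrom_lengths = NULL) {
  lines <- readLines(path)
  if (is.null(chrom_lengths)) {
    sr <- grep("^##sequence-region", lines, value = TRUE)
    if (!length(sr)) stop_input("no chrom_lengths and no ##sequence-region")
    parts <- strsplit(sr, "\\s+")
    chrom_lengths <- stats::setNames(
      vapply(parts, function(p) as.numeric(p[4]), numeric(1)),
      vapply(parts, function(p) p[2], character(1)))
  }
  body <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (!length(body)) {
    return(gene_annotation(
      data.frame(gene_id = character(0), chrom = character(0),
                 strand = character(0), start = integer(0), end = integer(0)),
      data.frame(gene_id = character(0), chrom = character(0),
                 start = integer(0), end = integer(0)),
      chrom_lengths))
  }
  f <- strsplit(body, "\t")
  df <- data.frame(chrom = vapply(f, `[`, "", 1),
                   type = vapply(f, `[`, "", 3),
                   start = as.integer(vapply(f, `[`, "", 4)) - 1L,
                   end = as.integer(vapply(f, `[`, "", 5)),
                   strand = vapply(f, `[`, "", 7),
                   attrs = vapply(f, `[`, "", 9),
                   stringsAsFactors = FALSE)
  attr_get <- function(a, key) {
    m <- regmatches(a, regexec(paste0("(^|;)", key, "=([^;]+)"), a))
    vapply(m, function(x) if (length(x) >= 3) x[3] else NA_character_, "")
  }
  gg <- df[df$type == "gene", , drop = FALSE]
  ee <- df[df$type == "exon", , drop = FALSE]
  genes <- data.frame(gene_id = attr_get(gg$attrs, "ID"), chrom = gg$chrom,
                      strand = gg$strand, start = gg$start, end = gg$end,
                      stringsAsFactors = FALSE)
  exons <- data.frame(gene_id = attr_get(ee$attrs, "Parent"), chrom = ee$chrom,
                      start = ee$start, end = ee$end, stringsAsFactors = FALSE)
  gene_annotation(genes, exons, chrom_lengths)
}

#' Write interval windows as FASTA given chromosome sequences
#'
#' Optional sequence export for motif-scanning input: extracts each window
#' from `sequences` (a named character vector or Biostrings-like list of
#' chromosome strings).
#'
#' @param regions data.frame `chrom`, `start`, `end` (0-based half-open).
#' @param sequences named character vector of chromosome sequences.
#' @param path output path.
#' @export
write_regions_fasta <- function(regions, sequences, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(regions))) {
    ch <- regions$chrom[i]
    if (!ch %in% names(sequences)) stop_input("no sequence for ", ch)
    s <- substr(sequences[[ch]], regions$start[i] + 1L, regions$end[i])
    writeLines(c(sprintf(">%s:%d-%d", ch, regions$start[i], regions$end[i]),
                 s), con)
  }
  invisible(path)
}
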