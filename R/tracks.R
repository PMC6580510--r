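#' Cut-site track
#'
#' Container for single-end DNase-seq data reduced to per-chromosome DNase I
#' cut positions (0-based). The library size is the total number of cuts and
#' is used for per-million normalization; `effective_genome` is the mappable
#' length used when placing null reads.
#'
#' @param cuts named list, one sorted integer vector of 0-based cut positions
#'   per chromosome.
#' @param chrom_lengths named numeric vector of chromosome lengths (bp).
#' @param sample sample identifier.
#' @param effective_genome mappable genome length; defaults to
#'   `sum(chrom_lengths)`.
#' @return object of class `cut_site_track`.
#' @export
cut_site_track <- function(cuts, chrom_lengths, sample = "sample",
                           effective_genome = sum(chrom_lengths)) {
  if (is.null(names(chrom_lengths))) stop_input("chrom_lengths must be named")
  cuts <- cuts[intersect(names(cuts), names(chrom_lengths))]
  miss <- setdiff(names(chrom_lengths), names(cuts))
  for (m in miss) cuts[[m]] <- integer(0)
  cuts <- cuts[names(chrom_lengths)]
  for (ch in names(cuts)) {
    p <- as.integer(cuts[[ch]])
    if (length(p) && (min(p) < 0 || max(p) >= chrom_lengths[[ch]]))
      stop_input("cut positions outside chromosome bounds on ", ch)
    cuts[[ch]] <- sort(p)
  }
  structure(
    list(cuts = cuts, chrom_lengths = chrom_lengths,
         library_size = sum(lengths(cuts)), sample = sample,
         effective_genome = effective_genome),
    class = "cut_site_track")
}

#' @export
print.cut_site_track <- function(x, ...) {
  cat("<cut_site_track> sample:", x$sample,
      "| chroms:", length(x$chrom_lengths),
      "| cuts:", x$library_size, "\n")
  invisible(x)
}

#' Paired-end fragment track
#'
#' Container for one ChIP / sequential-ChIP channel: per-chromosome fragment
#' records (0-based half-open). Signal position for all quantification is the
#' fragment midpoint.
#'
#' @param fragments named list of data.frames with integer columns
#'   `start`, `end` (0-based half-open), one per chromosome.
#' @param chrom_lengths named numeric vector of chromosome lengths.
#' @param channel channel id, e.g. "K4me3", "K4-K27", "input".
#' @param condition condition id, e.g. "RT", "cold".
#' @return object of class `fragment_track`.
#' @export
fragment_track <- function(fragments, chrom_lengths, channel = "channel",
                           condition = "condition") {
  if (is.null(names(chrom_lengths))) stop_input("chrom_lengths must be named")
  fragments <- fragments[intersect(names(fragments), names(chrom_lengths))]
  miss <- setdiff(names(chrom_lengths), names(fragments))
  for (m in miss) fragments[[m]] <- data.frame(start = integer(0), end = integer(0))
  fragments <- fragments[names(chrom_lengths)]
  for (ch in names(fragments)) {
    f <- fragments[[ch]]
    stopifnot(all(c("start", "end") %in% names(f)))
    if (nrow(f) && any(f$start >= f$end)) stop_input("fragment start >= end on ", ch)
    f <- f[order(f$start, f$end), c("start", "end"), drop = FALSE]
    f$start <- as.integer(f$start); f$end <- as.integer(f$end)
    f$mid <- (f$start + f$end) %/% 2L
    rownames(f) <- NULL
    fragments[[ch]] <- f
  }
  mids <- lapply(fragments, function(f) sort(f$mid))
  structure(
    list(fragments = fragments, mids = mids, chrom_lengths = chrom_lengths,
         library_size = sum(vapply(fragments, nrow, integer(1))),
         channel = channel, condition = condition),
    class = "fragment_track")
}

#' @export
print.fragment_track <- function(x, ...) {
  cat("<fragment_track>", x$channel, "/", x$condition,
      "| fragments:", x$library_size, "\n")
  invisible(x)
}

#' Event positions of a track on one chromosome
#'
#' The single-bp "event" used for counting: the cut base for DNase cut-site
#' tracks and the fragment midpoint for ChIP fragment tracks.
#'
#' @param track `cut_site_track` or `fragment_track`.
#' @param chrom chromosome id.
#' @return integer vector of 0-based positions.
#' @export
track_events <- function(track, chrom) {
  if (!chrom %in% names(track$chrom_lengths)) stop_input("unknown chrom: ", chrom)
  if (inherits(track, "cut_site_track")) track$cuts[[chrom]]
  else if (inherits(track, "fragment_track")) track$mids[[chrom]]
  else stop_input("not a track object")
}

#' Count track events in intervals
#'
#' Binary-search counting over the sorted event positions (cut bases or
#' fragment midpoints); `start`/`end` may be vectors of equal length.
#'
#' @param track a track object.
#' @param chrom chromosome id (scalar).
#' @param start,end 0-based half-open interval(s).
#' @return integer count per interval.
#' @export
count_events <- function(track, chrom, start, end) {
  p <- track_events(track, chrom)  # constructors keep events sorted
  if (!length(p)) return(integer(length(start)))
  findInterval(end - 0.5, p) - findInterval(start - 0.5, p)
}
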