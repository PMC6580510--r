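#' DHS caller parameters
#'
#' @param bandwidth Gaussian kernel sd in bp (default 300).
#' @param fdr nominal empirical false discovery rate (default 0.05).
#' @param n_null number of uniform-placement null simulations (default 20).
#' @param min_length minimum DHS length in bp (default 50).
#' @param merge_gap merge runs separated by less than this many bp (default 0).
#' @param seed integer seed for the null simulations.
#' @return list of class `caller_params`.
#' @export
caller_params <- function(bandwidth = 300, fdr = 0.05, n_null = 20,
                          min_length = 50, merge_gap = 0, seed = 1) {
  stopifnot(bandwidth > 0, fdr > 0, fdr < 1, n_null >= 1, min_length >= 1,
            merge_gap >= 0)
  structure(list(bandwidth = bandwidth, fdr = fdr, n_null = n_null,
                 min_length = min_length, merge_gap = merge_gap,
                 seed = as.integer(seed)),
            class = "caller_params")
}

# Memoised FFT of the (zero-padded) Gaussian kernel, keyed by padded length
# and bandwidth. Saves roughly a third of the work across null simulations,
# which all share the same chromosome lengths.
.kernel_cache <- new.env(parent = emptyenv())

gaussian_kernel <- function(bandwidth) {
  # 7 sd radius keeps truncation error below ~1e-12 per cut
  r <- ceiling(7 * bandwidth)
  stats::dnorm(seq(-r, r), mean = 0, sd = bandwidth)
}

# FFT convolution of a count vector with the Gaussian kernel; returns the
# per-bp density aligned with the input (index i = position i - 1).
kde_convolve <- function(counts, bandwidth) {
  L <- length(counts)
  k <- gaussian_kernel(bandwidth)
  K <- length(k); half <- (K - 1L) / 2L
  N <- stats::nextn(L + K - 1L, c(2, 3, 5))
  key <- paste0(N, "_", bandwidth)
  fb <- .kernel_cache[[key]]
  if (is.null(fb)) {
    fb <- stats::fft(c(k, numeric(N - K)))
    .kernel_cache[[key]] <- fb
  }
  fa <- stats::fft(c(counts, numeric(N - L)))
  d <- Re(stats::fft(fa * fb, inverse = TRUE)) / N
  pmax(d[(half + 1):(half + L)], 0)
}

#' Per-bp kernel density of DNase I cuts
#'
#' Sums a Gaussian kernel (sd = `bandwidth`) over every cut position and
#' evaluates the total at each bp of the chromosome, so the profile
#' integrates to the number of cuts up to boundary truncation. Computed by
#' FFT convolution of the per-bp count vector; equal to the direct
#' Gaussian-summation within floating-point error.
#'
#' @param track `cut_site_track`.
#' @param bandwidth kernel sd in bp.
#' @param chrom chromosome id.
#' @return numeric vector of length `chrom_length`, density at bp 0, 1, ...
#' @export
kde_density <- function(track, bandwidth, chrom) {
  if (!chrom %in% names(track$chrom_lengths)) stop_input("unknown chrom: ", chrom)
  L <- as.integer(track$chrom_lengths[[chrom]])
  p <- track$cuts[[chrom]]
  if (!length(p)) return(numeric(L))
  kde_convolve(tabulate(p + 1L, nbins = L), bandwidth)
}

# Histogram counts of density values on a fixed grid; values above the top
# edge are clamped into the last bin (they can only tighten the threshold).
.density_hist <- function(d, breaks) {
  idx <- findInterval(pmin(d, breaks[length(breaks)]), breaks,
                      rightmost.closed = TRUE, left.open = FALSE)
  idx[idx < 1L] <- 1L
  tabulate(idx, nbins = length(breaks) - 1L)
}

#' Monte-Carlo density threshold at a target empirical FDR
#'
#' Places `library_size` cuts uniformly on the effective genome `n_null`
#' times, computes the same kernel density as the observed track, and pools
#' the null per-bp densities. The threshold is the smallest density `t` such
#' that (expected null bases >= t) / (observed bases >= t) <= `fdr`. When no
#' such `t` exists (the observed track is indistinguishable from the null)
#' the function returns `Inf` and the caller emits no DHSs.
#'
#' @param track `cut_site_track`.
#' @param params `caller_params`.
#' @return named list: `threshold`, plus the grid diagnostics
#'   (`breaks`, `obs_ge`, `null_ge`).
#' @export
null_threshold <- function(track, params) {
  if (track$library_size == 0) stop_input("empty track")
  chroms <- names(track$chrom_lengths)
  lens <- as.numeric(track$chrom_lengths)
  obs <- lapply(chroms, function(ch) kde_density(track, params$bandwidth, ch))
  mx <- max(vapply(obs, max, numeric(1)))
  if (mx <= 0) return(list(threshold = Inf))
  nb <- 4096L
  breaks <- seq(0, mx, length.out = nb + 1L)
  obs_counts <- Reduce(`+`, lapply(obs, .density_hist, breaks = breaks))
  null_counts <- numeric(nb)
  # cuts are placed on the concatenated effective genome and split by chrom;
  # chromosomes are scaled to their share of the effective length
  eff_lens <- lens / sum(lens) * track$effective_genome
  cum <- c(0, cumsum(eff_lens))
  with_seed(params$seed, {
    for (s in seq_len(params$n_null)) {
      u <- stats::runif(track$library_size, 0, track$effective_genome)
      ci <- findInterval(u, cum, rightmost.closed = TRUE)
      ci[ci < 1L] <- 1L; ci[ci > length(chroms)] <- length(chroms)
      for (j in seq_along(chroms)) {
        L <- as.integer(lens[j])
        pos <- floor((u[ci == j] - cum[j]) / eff_lens[j] * L)
        pos[pos >= L] <- L - 1L
        cnt <- tabulate(pos + 1L, nbins = L)
        null_counts <- null_counts +
          .density_hist(kde_convolve(cnt, params$bandwidth), breaks)
      }
    }
  })
  obs_ge <- rev(cumsum(rev(obs_counts)))
  null_ge <- rev(cumsum(rev(null_counts))) / params$n_null
  ok <- obs_ge > 0 & (null_ge / pmax(obs_ge, 1)) <= params$fdr
  thr <- if (any(ok)) breaks[min(which(ok))] else Inf
  list(threshold = thr, breaks = breaks, obs_ge = obs_ge, null_ge = null_ge)
}

# Merge integer runs (start, end half-open) whose gap is < merge_gap.
.merge_runs <- function(starts, ends, merge_gap) {
  if (length(starts) <= 1 || merge_gap <= 0)
    return(list(start = starts, end = ends))
  ms <- starts[1]; me <- ends[1]
  out_s <- integer(0); out_e <- integer(0)
  for (i in seq_along(starts)[-1]) {
    if (starts[i] - me < merge_gap) {
      me <- max(me, ends[i])
    } else {
      out_s <- c(out_s, ms); out_e <- c(out_e, me)
      ms <- starts[i]; me <- ends[i]
    }
  }
  list(start = c(out_s, ms), end = c(out_e, me))
}

#' Call DNase I hypersensitive sites
#'
#' Identifies maximal runs of base pairs whose kernel density is at or above
#' the Monte-Carlo FDR threshold, merges runs closer than `merge_gap`, drops
#' runs shorter than `min_length`, and records for each DHS its summit (the
#' position with the highest cut count, leftmost on ties), summit count,
#' peak kernel density and mean read density.
#'
#' @param track `cut_site_track`.
#' @param params `caller_params`.
#' @param sample_id sample label carried into the output.
#' @return data.frame of class `dhs_set`: `chrom`, `start`, `end`, `summit`,
#'   `summit_count`, `peak_density`, `read_density`, `sample`, sorted by
#'   (chrom, start).
#' @export
call_dhs <- function(track, params, sample_id = track$sample) {
  empty <- data.frame(chrom = character(0), start = integer(0), end = integer(0),
                      summit = integer(0), summit_count = integer(0),
                      peak_density = numeric(0), read_density = numeric(0),
                      sample = character(0), stringsAsFactors = FALSE)
  class(empty) <- c("dhs_set", "data.frame")
  if (track$library_size == 0) return(empty)
  thr <- null_threshold(track, params)$threshold
  if (!is.finite(thr)) return(empty)
  out <- list()
  for (ch in names(track$chrom_lengths)) {
    d <- kde_density(track, params$bandwidth, ch)
    above <- d >= thr
    if (!any(above)) next
    r <- rle(above)
    ends_all <- cumsum(r$lengths)
    starts_all <- ends_all - r$lengths
    starts <- starts_all[r$values]          # 0-based
    ends <- ends_all[r$values]              # exclusive
    m <- .merge_runs(starts, ends, params$merge_gap)
    keep <- (m$end - m$start) >= params$min_length
    if (!any(keep)) next
    starts <- m$start[keep]; ends <- m$end[keep]
    cnt <- tabulate(track$cuts[[ch]] + 1L, nbins = length(d))
    rows <- lapply(seq_along(starts), function(i) {
      s <- starts[i]; e <- ends[i]
      seg <- cnt[(s + 1L):e]
      summit_off <- which.max(seg)          # leftmost max by which.max
      data.frame(chrom = ch, start = s, end = e,
                 summit = s + summit_off - 1L,
                 summit_count = seg[summit_off],
                 peak_density = max(d[(s + 1L):e]),
                 read_density = sum(seg) / (e - s),
                 sample = sample_id, stringsAsFactors = FALSE)
    })
    out[[ch]] <- do.call(rbind, rows)
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  res <- res[order(res$chrom, res$start), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "threshold") <- thr
  class(res) <- c("dhs_set", "data.frame")
  res
}

# findOverlaps-based pairing of two DHS tables on one chromosome.
.overlap_pairs <- function(a, b) {
  qa <- IRanges::IRanges(start = a$start + 1L, end = a$end)
  qb <- IRanges::IRanges(start = b$start + 1L, end = b$end)
  h <- IRanges::findOverlaps(qa, qb)
  data.frame(i = S4Vectors::queryHits(h), j = S4Vectors::subjectHits(h))
}

#' Replicate-consensus DHSs
#'
#' Retains each replicate-1 DHS that shares at least 1 bp with any
#' replicate-2 DHS and emits one consensus record per retained DHS: the
#' interval spans the replicate-1 DHS together with all of its overlapping
#' replicate-2 partners, and the summit (with its count and densities) is
#' taken from the replicate with the larger summit count (replicate 1 on
#' ties).
#'
#' @param rep1,rep2 `dhs_set` data.frames from two biological replicates.
#' @return consensus `dhs_set`.
#' @export
consensus_dhs <- function(rep1, rep2) {
  empty <- rep1[0, , drop = FALSE]
  if (!nrow(rep1) || !nrow(rep2)) return(empty)
  out <- list()
  for (ch in unique(rep1$chrom)) {
    a <- rep1[rep1$chrom == ch, , drop = FALSE]
    b <- rep2[rep2$chrom == ch, , drop = FALSE]
    if (!nrow(b)) next
    prs <- .overlap_pairs(a, b)
    if (!nrow(prs)) next
    rows <- lapply(unique(prs$i), function(i) {
      js <- prs$j[prs$i == i]
      best_j <- js[which.max(b$summit_count[js])]
      use2 <- b$summit_count[best_j] > a$summit_count[i]
      src <- if (use2) b[best_j, ] else a[i, ]
      data.frame(chrom = ch,
                 start = min(a$start[i], b$start[js]),
                 end = max(a$end[i], b$end[js]),
                 summit = src$summit, summit_count = src$summit_count,
                 peak_density = src$peak_density,
                 read_density = src$read_density,
                 sample = a$sample[i], stringsAsFactors = FALSE)
    })
    out[[ch]] <- do.call(rbind, rows)
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  res <- res[order(res$chrom, res$start), , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("dhs_set", "data.frame")
  res
}

#' Condition-specific DHSs
#'
#' Subset of `setA` sharing no single base pair with any DHS in `setB`.
#'
#' @param setA,setB consensus `dhs_set` data.frames.
#' @return `dhs_set` of A-specific DHSs.
#' @export
specific_dhs <- function(setA, setB) {
  if (!nrow(setA) || !nrow(setB)) return(setA)
  drop <- logical(nrow(setA))
  for (ch in unique(setA$chrom)) {
    ia <- which(setA$chrom == ch)
    b <- setB[setB$chrom == ch, , drop = FALSE]
    if (!nrow(b)) next
    prs <- .overlap_pairs(setA[ia, , drop = FALSE], b)
    drop[ia[unique(prs$i)]] <- TRUE
  }
  res <- setA[!drop, , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Top DHSs by read density
#'
#' Ranks DHSs by mean read density (ties by summit count, then coordinate),
#' keeps the top `k`, and returns fixed-width windows of `2 * halfwidth` bp
#' centred on each summit — the regions used as motif-scanning input.
#'
#' @param dhs `dhs_set`.
#' @param k number of DHSs to keep (default 1000).
#' @param halfwidth half window width around the summit (default 50).
#' @return data.frame `chrom`, `start`, `end`, `summit`, `read_density`.
#' @export
top_dhs_regions <- function(dhs, k = 1000, halfwidth = 50) {
  if (!nrow(dhs)) stop_input("empty DHS set")
  ord <- order(-dhs$read_density, -dhs$summit_count, dhs$chrom, dhs$start)
  top <- dhs[ord[seq_len(min(k, nrow(dhs)))], , drop = FALSE]
  out <- data.frame(chrom = top$chrom,
                    start = pmax(0L, top$summit - as.integer(halfwidth)),
                    end = top$summit + as.integer(halfwidth),
                    summit = top$summit, read_density = top$read_density,
                    stringsAsFactors = FALSE)
  # keep exact width even at the chromosome start
  short <- (out$end - out$start) < 2 * halfwidth
  out$end[short] <- out$start[short] + 2L * as.integer(halfwidth)
  rownames(out) <- NULL
  out
}
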