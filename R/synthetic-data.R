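#' Simulation configuration
#'
#' Knobs for the synthetic study: a toy genome with the library structure of
#' the real experiment (two biological replicates of DNase-seq for each of
#' RT tubers, cold tubers and leaves; ChIP and dual-order sequential-ChIP
#' channels for the tuber conditions; an expression table with two DE caller
#' outputs). Defaults are sized so a full synthetic run takes a few minutes
#' on one CPU while every planted feature stays well above background.
#'
#' @param n_chroms number of chromosomes (default 2).
#' @param chrom_length chromosome length in bp (default 2e6).
#' @param n_genes total genes (default 400), split evenly across chromosomes.
#' @param gene_length_range min/max gene length in bp (default 1500-4000).
#' @param nucleosome_spacing fixed nucleosome grid spacing in bp (default 180).
#' @param dnase_depth DNase cuts per library (default 2e5).
#' @param chip_depth fragments per ChIP channel (default 2e5).
#' @param carryover_rate fraction of a no-antibody control library emitted
#'   from the first antibody's nucleosomes (default 0.1; must be < 0.5).
#' @param fdr_nominal nominal FDR used downstream (default 0.05).
#' @param seed master seed; all streams derive from it via [sub_seed()].
#' @param class_probs expression-class probabilities
#'   (up, down, constitutive, silenced).
#' @param bivalent_frac fraction of active genes planted bivalent upon cold
#'   (default 0.3).
#' @param body_open_frac fraction of non-bivalent active genes that gain
#'   cold-only gene-body hotspots (default 0.55).
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_chroms = 2, chrom_length = 2e6, n_genes = 400,
                       gene_length_range = c(1500, 4000),
                       nucleosome_spacing = 180,
                       dnase_depth = 2e5, chip_depth = 2e5,
                       carryover_rate = 0.1, fdr_nominal = 0.05, seed = 1,
                       class_probs = c(up = 0.2, down = 0.2,
                                       constitutive = 0.4, silenced = 0.2),
                       bivalent_frac = 0.3, body_open_frac = 0.55) {
  stopifnot(n_chroms >= 1, chrom_length > 0, n_genes >= 0,
            length(gene_length_range) == 2,
            gene_length_range[1] <= gene_length_range[2],
            nucleosome_spacing > 0, dnase_depth >= 0, chip_depth >= 0,
            carryover_rate >= 0, carryover_rate < 0.5,
            fdr_nominal > 0, fdr_nominal < 1,
            abs(sum(class_probs) - 1) < 1e-8)
  structure(list(n_chroms = n_chroms, chrom_length = chrom_length,
                 n_genes = n_genes, gene_length_range = gene_length_range,
                 nucleosome_spacing = nucleosome_spacing,
                 dnase_depth = dnase_depth, chip_depth = chip_depth,
                 carryover_rate = carryover_rate, fdr_nominal = fdr_nominal,
                 seed = as.integer(seed), class_probs = class_probs,
                 bivalent_frac = bivalent_frac,
                 body_open_frac = body_open_frac),
            class = "sim_config")
}

sim_chrom_lengths <- function(cfg) {
  stats::setNames(rep(cfg$chrom_length, cfg$n_chroms),
                  paste0("chr", seq_len(cfg$n_chroms)))
}

.sim_conditions <- c("RT", "cold", "leaf")
.chip_channels <- c("K4me3", "K27me3", "K4me1", "H4ac", "input",
                    "K4-K27", "K4-noAb", "K27-K4", "K27-noAb")

#' Generate a toy annotation with planted truth labels
#'
#' Places non-overlapping genes on both strands with at least 2 kb between
#' neighbours (each gene sits in its own slot with random jitter, so
#' intergenic control regions always exist), gives each gene 1-4 exons, and
#' plants the ground truth used by every downstream recovery test:
#' expression class, a latent expression level, a bivalent flag among active
#' genes, per-condition promoter-DHS flags, and a cold-only gene-body
#' hotspot flag (all bivalent genes plus a sampled subset of the remaining
#' active genes).
#'
#' @param cfg `sim_config`.
#' @return list with `annotation` (a [gene_annotation()]) and `labels`
#'   (data.frame of per-gene truth).
#' @export
generate_annotation <- function(cfg) {
  chrom_lengths <- sim_chrom_lengths(cfg)
  if (cfg$n_genes == 0) {
    anno <- gene_annotation(
      data.frame(gene_id = character(0), chrom = character(0),
                 strand = character(0), start = integer(0), end = integer(0)),
      data.frame(gene_id = character(0), chrom = character(0),
                 start = integer(0), end = integer(0)),
      chrom_lengths)
    return(list(annotation = anno, labels = data.frame(gene_id = character(0))))
  }
  per_chrom <- diff(round(seq(0, cfg$n_genes, length.out = cfg$n_chroms + 1)))
  margin <- 3000
  max_len <- cfg$gene_length_range[2]
  with_seed(sub_seed(cfg$seed, "annotation"), {
    genes <- list(); exons <- list()
    gid <- 0
    for (ci in seq_len(cfg$n_chroms)) {
      ch <- names(chrom_lengths)[ci]
      n <- per_chrom[ci]
      if (n == 0) next
      slot <- floor((cfg$chrom_length - 2 * margin) / n)
      if (slot < max_len + 2000)
        stop_input("chromosome too short to place ", n,
                   " genes at 2 kb spacing (slot ", slot, " bp)")
      for (i in seq_len(n)) {
        gid <- gid + 1
        len <- sample(seq(cfg$gene_length_range[1], max_len), 1)
        off <- sample.int(slot - len - 2000 + 1, 1) - 1
        s <- margin + (i - 1) * slot + off
        id <- sprintf("gene%04d", gid)
        genes[[gid]] <- data.frame(
          gene_id = id, chrom = ch, strand = sample(c("+", "-"), 1),
          start = s, end = s + len, stringsAsFactors = FALSE)
        n_ex <- sample(1:4, 1)
        if (n_ex == 1 || len < 400) {
          exons[[gid]] <- data.frame(gene_id = id, chrom = ch,
                                     start = s, end = s + len)
        } else {
          br <- sort(sample(seq(s + 100, s + len - 100), 2 * n_ex - 2))
          bounds <- c(s, br, s + len)
          starts <- bounds[seq(1, length(bounds) - 1, by = 2)]
          ends <- bounds[seq(2, length(bounds), by = 2)]
          exons[[gid]] <- data.frame(gene_id = id, chrom = ch,
                                     start = starts, end = ends)
        }
      }
    }
    genes <- do.call(rbind, genes)
    exons <- do.call(rbind, exons)
    cls <- sample(names(cfg$class_probs), nrow(genes), replace = TRUE,
                  prob = cfg$class_probs)
    active <- cls != "silenced"
    bivalent <- active & stats::runif(nrow(genes)) < cfg$bivalent_frac
    body_open <- bivalent |
      (active & stats::runif(nrow(genes)) < cfg$body_open_frac)
    labels <- data.frame(
      gene_id = genes$gene_id,
      expression_class = cls,
      expr_level = pmax(2, exp(stats::rnorm(nrow(genes), log(10), 0.8))),
      fold_change = stats::runif(nrow(genes), 1.6, 3.5),
      bivalent_planted = bivalent,
      # ~8% per-condition promoter dropout so each temperature also has
      # promoter DHSs specific to it
      promoter_dhs_RT = active & stats::runif(nrow(genes)) > 0.08,
      promoter_dhs_cold = active & stats::runif(nrow(genes)) > 0.08,
      promoter_dhs_leaf = active & stats::runif(nrow(genes)) > 0.1,
      genic_dhs_cold_only = body_open,
      stringsAsFactors = FALSE)
    labels$expr_level[!active] <- 0
    list(annotation = gene_annotation(genes, exons, chrom_lengths),
         labels = labels)
  })
}

# Expression quartile (1-4) of active genes by latent level; 0 for silenced.
.expr_quartile <- function(labels) {
  q <- integer(nrow(labels))
  act <- labels$expression_class != "silenced"
  if (any(act)) {
    r <- rank(labels$expr_level[act], ties.method = "min")
    q[act] <- as.integer(ceiling(4 * r / length(r)))
  }
  q
}

#' Simulate a DNase-seq cut-site library
#'
#' Cuts are a mixture of a uniform Poisson background (half the library) and
#' Gaussian-shaped hotspots (sd 75 bp): promoter hotspots centred 100 bp
#' upstream of the TSS in transcription orientation for every gene carrying
#' a promoter DHS in the condition, with intensity scaled by expression
#' quartile, plus gene-body hotspots centred on fixed internal nucleosomes —
#' emitted only in the cold condition for genes flagged
#' `genic_dhs_cold_only`, with extra weight on bivalent-planted genes.
#' Replicates draw from independent sub-seeded streams. Exactly
#' `dnase_depth` cuts are emitted.
#'
#' @param cfg `sim_config`.
#' @param anno `gene_annotation` from [generate_annotation()].
#' @param labels truth labels from [generate_annotation()].
#' @param condition one of "RT", "cold", "leaf".
#' @param replicate replicate id (1 or 2, any label allowed).
#' @return `cut_site_track`.
#' @export
simulate_dnase <- function(cfg, anno, labels, condition, replicate = 1) {
  if (!condition %in% .sim_conditions)
    stop_input("unknown condition: ", condition)
  chrom_lengths <- sim_chrom_lengths(cfg)
  sample_id <- paste0(condition, "_rep", replicate)
  if (cfg$dnase_depth == 0)
    return(cut_site_track(list(), chrom_lengths, sample = sample_id))
  g <- anno$genes
  lab <- labels[match(g$gene_id, labels$gene_id), , drop = FALSE]
  quart <- .expr_quartile(lab)
  prom_flag <- lab[[paste0("promoter_dhs_", condition)]] %||% rep(FALSE, nrow(g))
  spots <- list()
  if (nrow(g)) {
    prom_center <- ifelse(g$strand == "+", g$tss - 100, g$tss + 100)
    pi <- which(prom_flag)
    if (length(pi))
      spots$prom <- data.frame(chrom = g$chrom[pi], center = prom_center[pi],
                               weight = 1 + 0.5 * quart[pi])
    if (condition == "cold") {
      bi <- which(lab$genic_dhs_cold_only)
      if (length(bi)) {
        body <- lapply(bi, function(i) {
          # fixed genome property: body hotspot nucleosomes per gene
          lo <- min(g$tss[i], g$tts[i]); hi <- max(g$tss[i], g$tts[i])
          grid <- seq(lo + 90, hi - 90, by = cfg$nucleosome_spacing)
          n_spots <- max(1, round((hi - lo) / 800))
          ctr <- with_seed(sub_seed(cfg$seed, "bodyspots", g$gene_id[i]),
                           sample(grid, min(n_spots, length(grid))))
          w <- if (lab$bivalent_planted[i]) 1.8 else 1.0
          data.frame(chrom = g$chrom[i], center = ctr, weight = w / length(ctr))
        })
        spots$body <- do.call(rbind, body)
      }
    }
  }
  spots <- do.call(rbind, spots)
  with_seed(sub_seed(cfg$seed, "dnase", condition, replicate), {
    n_bg <- round(cfg$dnase_depth * 0.5)
    n_hot <- cfg$dnase_depth - n_bg
    if (is.null(spots) || !nrow(spots)) { n_bg <- cfg$dnase_depth; n_hot <- 0 }
    total_len <- sum(chrom_lengths)
    u <- stats::runif(n_bg, 0, total_len)
    cum <- c(0, cumsum(chrom_lengths))
    cuts <- lapply(seq_along(chrom_lengths), function(j)
      floor(u[u >= cum[j] & u < cum[j + 1]] - cum[j]))
    names(cuts) <- names(chrom_lengths)
    if (n_hot > 0) {
      alloc <- stats::rmultinom(1, n_hot, spots$weight)[, 1]
      for (k in which(alloc > 0)) {
        p <- round(stats::rnorm(alloc[k], spots$center[k], 75))
        p <- pmin(pmax(p, 0), chrom_lengths[[spots$chrom[k]]] - 1)
        cuts[[spots$chrom[k]]] <- c(cuts[[spots$chrom[k]]], p)
      }
    }
    cut_site_track(cuts, chrom_lengths, sample = sample_id)
  })
}

# Nucleosome grid (fixed genome property shared by all channels).
nucleosome_grid <- function(cfg, chrom_lengths = sim_chrom_lengths(cfg)) {
  lapply(chrom_lengths, function(L) seq(90, L - 91, by = cfg$nucleosome_spacing))
}

# Marked-nucleosome index sets per (mark, condition); indexes into the
# concatenated grid. K4 sits on the 5' nucleosomes of active genes and
# spreads over bivalent gene bodies upon cold; K27 covers silenced gene
# bodies and gains bivalent bodies upon cold; the bivalent set itself exists
# only in cold.
.mark_sets <- function(cfg, anno, labels, condition) {
  grid <- nucleosome_grid(cfg)
  offs <- c(0, cumsum(lengths(grid)))
  names(offs) <- c(names(grid), "end")
  g <- anno$genes
  lab <- labels[match(g$gene_id, labels$gene_id), , drop = FALSE]
  body_idx <- function(i) {
    lo <- min(g$tss[i], g$tts[i]); hi <- max(g$tss[i], g$tts[i])
    gr <- grid[[g$chrom[i]]]
    offs[[g$chrom[i]]] + which(gr >= lo & gr < hi)
  }
  five_prime_idx <- function(i) {
    # K4me3/H4ac occupy the 5' half of the body (at least 5 nucleosomes)
    b <- body_idx(i)
    if (!length(b)) return(b)
    k <- min(length(b), max(5L, ceiling(length(b) / 2)))
    if (g$strand[i] == "+") utils::head(b, k) else utils::tail(b, k)
  }
  active <- lab$expression_class != "silenced"
  silenced <- !active
  biv <- lab$bivalent_planted & condition == "cold"
  k4 <- unlist(lapply(which(active), five_prime_idx))
  if (any(biv)) k4 <- unique(c(k4, unlist(lapply(which(biv), body_idx))))
  k27 <- unlist(lapply(which(silenced), body_idx))
  if (any(biv)) k27 <- unique(c(k27, unlist(lapply(which(biv), body_idx))))
  bivalent <- if (any(biv)) unlist(lapply(which(biv), body_idx)) else integer(0)
  k4me1 <- bivalent
  h4ac <- k4
  list(grid = grid, offsets = offs,
       sets = list(K4me3 = sort(unique(k4)), K27me3 = sort(unique(k27)),
                   K4me1 = sort(unique(k4me1)), H4ac = sort(unique(h4ac)),
                   bivalent = sort(unique(bivalent))))
}

# Channel composition: list of (component weight, nucleosome index set or
# NULL for uniform background over the whole grid).
.channel_mix <- function(channel, sets, carryover_rate) {
  seq_frac <- 0.25   # sequential-ChIP depth fraction claimed by true signal
  mark_frac <- 0.7   # single-mark depth fraction claimed by marked nucleosomes
  first_mark <- c("K4-K27" = "K4me3", "K4-noAb" = "K4me3",
                  "K27-K4" = "K27me3", "K27-noAb" = "K27me3")
  comp <- switch(channel,
    input = list(list(w = 1, idx = NULL)),
    K4me3 = , K27me3 = , K4me1 = , H4ac = list(
      list(w = mark_frac, idx = sets[[channel]]),
      list(w = 1 - mark_frac, idx = NULL)),
    `K4-K27` = , `K27-K4` = list(
      list(w = seq_frac, idx = sets$bivalent),
      list(w = (1 - seq_frac) * carryover_rate,
           idx = sets[[first_mark[channel]]]),
      list(w = (1 - seq_frac) * (1 - carryover_rate), idx = NULL)),
    `K4-noAb` = , `K27-noAb` = list(
      list(w = carryover_rate, idx = sets[[first_mark[channel]]]),
      list(w = 1 - carryover_rate, idx = NULL)),
    stop_input("unknown channel: ", channel))
  # drop components whose nucleosome set is empty and renormalize
  comp <- Filter(function(cm) is.null(cm$idx) || length(cm$idx) > 0, comp)
  tot <- sum(vapply(comp, `[[`, numeric(1), "w"))
  lapply(comp, function(cm) { cm$w <- cm$w / tot; cm })
}

#' Simulate a ChIP / sequential-ChIP fragment library
#'
#' Emits ~150 bp fragments centred on a fixed 180 bp nucleosome grid shared
#' by all channels. Marked-nucleosome sets follow the planted truth: active
#' genes carry H3K4me3 (and H4ac) on their 5' nucleosomes, silenced genes
#' carry H3K27me3 over the body, and bivalent-planted genes gain both marks
#' (and H3K4me1) across the body upon cold — the sequential channels K4-K27
#' and K27-K4 emit their true-signal component only from those dual-marked
#' nucleosomes. No-antibody controls emit from the first antibody's
#' nucleosomes at `carryover_rate` plus uniform background; input is uniform
#' over the grid. Exactly `chip_depth` fragments are emitted.
#'
#' @param cfg `sim_config`.
#' @param anno,labels output of [generate_annotation()].
#' @param channel one of K4me3, K27me3, K4me1, H4ac, input, K4-K27, K4-noAb,
#'   K27-K4, K27-noAb.
#' @param condition "RT" or "cold".
#' @return `fragment_track`.
#' @export
simulate_chip <- function(cfg, anno, labels, channel, condition) {
  if (!channel %in% .chip_channels) stop_input("unknown channel: ", channel)
  if (!condition %in% .sim_conditions)
    stop_input("unknown condition: ", condition)
  chrom_lengths <- sim_chrom_lengths(cfg)
  ms <- .mark_sets(cfg, anno, labels, condition)
  comp <- .channel_mix(channel, ms$sets, cfg$carryover_rate)
  all_grid <- unlist(ms$grid, use.names = FALSE)
  grid_chrom <- rep(names(ms$grid), lengths(ms$grid))
  with_seed(sub_seed(cfg$seed, "chip", channel, condition), {
    n <- cfg$chip_depth
    alloc <- stats::rmultinom(1, n, vapply(comp, `[[`, numeric(1), "w"))[, 1]
    centers <- integer(0); chroms <- character(0)
    for (k in seq_along(comp)) {
      if (alloc[k] == 0) next
      idx <- comp[[k]]$idx %||% seq_along(all_grid)
      pick <- idx[sample.int(length(idx), alloc[k], replace = TRUE)]
      centers <- c(centers, all_grid[pick])
      chroms <- c(chroms, grid_chrom[pick])
    }
    len <- pmin(pmax(round(stats::rnorm(length(centers), 150, 12)), 100), 200)
    mid <- centers + round(stats::rnorm(length(centers), 0, 15))
    start <- mid - len %/% 2
    frags <- lapply(names(chrom_lengths), function(ch) {
      i <- chroms == ch
      L <- chrom_lengths[[ch]]
      s <- pmin(pmax(start[i], 0), L - 2)
      e <- pmin(s + len[i], L)
      data.frame(start = as.integer(s), end = as.integer(e))
    })
    names(frags) <- names(chrom_lengths)
    fragment_track(frags, chrom_lengths, channel = channel,
                   condition = condition)
  })
}

#' Simulate expression and differential-expression tables
#'
#' FPKM per condition from the planted latent level: silenced genes are 0
#' everywhere, active genes exceed 1 in RT and cold, and up/down classes
#' apply the planted fold change (>= 1.6) in the planted direction. Two DE
#' caller tables are emitted that agree exactly on the planted DEG set
#' (same direction, FDR < 0.01) and each carries its own disjoint set of
#' caller-specific false positives, so the caller-intersection rule is
#' exercised non-trivially.
#'
#' @param cfg `sim_config`.
#' @param labels truth labels.
#' @return list: `expression` (gene_id, fpkm_RT, fpkm_cold, fpkm_leaf),
#'   `de_callerA`, `de_callerB` (gene_id, direction, fdr).
#' @export
simulate_expression <- function(cfg, labels) {
  n <- nrow(labels)
  with_seed(sub_seed(cfg$seed, "expression"), {
    noise <- function() exp(stats::rnorm(n, 0, 0.1))
    lvl <- labels$expr_level
    fc <- labels$fold_change
    cls <- labels$expression_class
    rt <- ifelse(cls == "down", lvl * fc, lvl) * noise()
    cold <- ifelse(cls == "up", lvl * fc, lvl) * noise()
    leaf <- lvl * exp(stats::rnorm(n, 0, 0.5))
    sil <- cls == "silenced"
    rt[sil] <- 0; cold[sil] <- 0; leaf[sil] <- 0
    act <- !sil
    rt[act] <- pmax(rt[act], 1.01); cold[act] <- pmax(cold[act], 1.01)
    expr <- data.frame(gene_id = labels$gene_id, fpkm_RT = rt,
                       fpkm_cold = cold, fpkm_leaf = leaf,
                       stringsAsFactors = FALSE)
    planted <- labels$gene_id[cls %in% c("up", "down")]
    dirs <- cls[cls %in% c("up", "down")]
    base <- data.frame(gene_id = planted, direction = dirs,
                       fdr = stats::runif(length(planted), 0, 0.009),
                       stringsAsFactors = FALSE)
    others <- labels$gene_id[!cls %in% c("up", "down")]
    others <- sample(others)
    n_fp <- min(length(others) %/% 2, max(1, round(0.05 * n)))
    fp <- function(ids) data.frame(
      gene_id = ids, direction = sample(c("up", "down"), length(ids), TRUE),
      fdr = stats::runif(length(ids), 0, 0.009), stringsAsFactors = FALSE)
    de_a <- rbind(base, fp(utils::head(others, n_fp)))
    de_b <- rbind(base, fp(utils::tail(others, n_fp)))
    list(expression = expr,
         de_callerA = de_a[order(de_a$gene_id), , drop = FALSE],
         de_callerB = de_b[order(de_b$gene_id), , drop = FALSE])
  })
}
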