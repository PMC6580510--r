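#' Pipeline run configuration
#'
#' @param sim `sim_config` (used when `simulate = TRUE`).
#' @param caller `caller_params` for DHS calling.
#' @param out_dir output directory (created if missing); NULL disables file
#'   output and the bundle is only returned.
#' @param simulate generate inputs with the synthetic module (default TRUE);
#'   otherwise all `paths` entries must be present.
#' @param conditions DNase conditions to process (default RT and cold).
#' @param bivalent run the sequential-ChIP bivalent stage (default TRUE).
#' @param paths for real inputs: list with `gff3`, `expression`,
#'   `de_callerA`, `de_callerB`, `dnase` (nested `condition -> replicate ->
#'   BED path`) and `chip` (nested `condition -> channel -> BEDPE path`).
#' @return list of class `run_config`.
#' @export
run_config <- function(sim = sim_config(), caller = caller_params(),
                       out_dir = NULL, simulate = TRUE,
                       conditions = c("RT", "cold"), bivalent = TRUE,
                       paths = NULL) {
  cfg <- structure(list(sim = sim, caller = caller, out_dir = out_dir,
                        simulate = simulate, conditions = conditions,
                        bivalent = bivalent, paths = paths),
                   class = "run_config")
  validate_run_config(cfg)
  cfg
}

#' Validate a run configuration (pre-flight)
#'
#' Checks that every input needed by the enabled stages is declared before
#' any stage runs; missing sequential-ChIP channels are reported by name.
#'
#' @param cfg `run_config`.
#' @return invisibly TRUE, or an error naming the missing piece.
#' @export
validate_run_config <- function(cfg) {
  if (!cfg$simulate) {
    p <- cfg$paths
    if (is.null(p)) stop_input("simulate = FALSE but no paths given")
    for (k in c("gff3", "expression", "de_callerA", "de_callerB"))
      if (is.null(p[[k]])) stop_input("missing input path: ", k)
    for (cond in cfg$conditions)
      if (length(p$dnase[[cond]]) < 2)
        stop_input("need two DNase replicates for condition ", cond)
    if (cfg$bivalent) {
      need <- c("K4-K27", "K4-noAb", "K27-K4", "K27-noAb", "input")
      for (cond in c("RT", "cold")) {
        miss <- setdiff(need, names(p$chip[[cond]]))
        if (length(miss))
          stop_input("bivalent stage enabled but channel(s) missing for ",
                     cond, ": ", paste(miss, collapse = ", "))
      }
    }
  }
  invisible(TRUE)
}

.pipeline_chip_channels <- c("K4me3", "K27me3", "input",
                             "K4-K27", "K4-noAb", "K27-K4", "K27-noAb")

#' Run the full analysis pipeline
#'
#' simulate (or load) -> call DHSs per replicate -> replicate consensus ->
#' condition-specific sets -> summit feature classification -> expression
#' classes and DE intersection -> DHS/DEG association -> metagene profiles
#' and cold/RT sensitivity change -> dual-order bivalent calling ->
#' statistics bundle. Deterministic given the seeds in `cfg`; when
#' `out_dir` is set, tracks, DHS BEDs, metagene TSVs, the bivalent table, a
#' statistics JSON and a run manifest are written there.
#'
#' @param cfg `run_config`.
#' @return (invisibly) list with all intermediate and final objects.
#' @export
run_pipeline <- function(cfg) {
  validate_run_config(cfg)
  out <- list(config = cfg)
  msg <- function(...) message("[coldchrom] ", ...)

  if (cfg$simulate) {
    msg("stage: simulate")
    ann <- generate_annotation(cfg$sim)
    anno <- ann$annotation; labels <- ann$labels
    dnase <- list()
    for (cond in cfg$conditions)
      for (rep in 1:2)
        dnase[[cond]][[rep]] <-
          simulate_dnase(cfg$sim, anno, labels, cond, rep)
    ex <- simulate_expression(cfg$sim, labels)
    chip <- NULL
    if (cfg$bivalent) {
      chip <- list()
      for (cond in c("RT", "cold"))
        for (chan in .pipeline_chip_channels)
          chip[[cond]][[chan]] <-
            simulate_chip(cfg$sim, anno, labels, chan, cond)
    }
    out$labels <- labels
  } else {
    msg("stage: load inputs")
    p <- cfg$paths
    anno <- read_gff3(p$gff3, p$chrom_lengths %||% NULL)
    cl <- anno$chrom_lengths
    dnase <- lapply(stats::setNames(cfg$conditions, cfg$conditions),
                    function(cond) lapply(p$dnase[[cond]], read_cuts_bed,
                                          chrom_lengths = cl))
    ex <- list(expression = read_tsv(p$expression),
               de_callerA = read_tsv(p$de_callerA),
               de_callerB = read_tsv(p$de_callerB))
    chip <- NULL
    if (cfg$bivalent)
      chip <- lapply(stats::setNames(c("RT", "cold"), c("RT", "cold")),
                     function(cond) {
                       chans <- p$chip[[cond]]
                       stats::setNames(lapply(names(chans), function(chan)
                         read_bedpe(chans[[chan]], cl, chan, cond)),
                         names(chans))
                     })
  }
  out$annotation <- anno
  out$tracks <- list(dnase = dnase, chip = chip)
  out$expression <- ex

  msg("stage: call DHSs")
  calls <- list(); consensus <- list()
  for (cond in cfg$conditions) {
    reps <- lapply(seq_along(dnase[[cond]]), function(r) {
      pr <- cfg$caller
      pr$seed <- sub_seed(cfg$caller$seed, "call", cond, r)
      call_dhs(dnase[[cond]][[r]], pr,
               sample_id = paste0(cond, "_rep", r))
    })
    calls[[cond]] <- reps
    cons <- consensus_dhs(reps[[1]], reps[[2]])
    cons$sample <- cond
    consensus[[cond]] <- cons
  }
  specific <- list()
  if (all(c("RT", "cold") %in% cfg$conditions)) {
    specific$cold <- specific_dhs(consensus$cold, consensus$RT)
    specific$RT <- specific_dhs(consensus$RT, consensus$cold)
  }
  out$dhs <- list(replicates = calls, consensus = consensus,
                  specific = specific)

  msg("stage: classify features")
  feature_tables <- lapply(consensus, function(d) {
    lab <- assign_dhs_feature(anno, d)
    tb <- table(factor(lab, levels = c("exon", "intron", "upstream1k",
                                       "downstream1k", "intergenic")))
    data.frame(category = names(tb), count = as.integer(tb),
               percent = vapply(as.integer(tb), percent_of, numeric(1),
                                n = max(1, nrow(d))))
  })
  out$feature_distribution <- feature_tables

  msg("stage: expression classes")
  active <- active_genes(ex$expression, "RT", "cold")
  sil_samples <- intersect(c("RT", "cold", "leaf"),
                           sub("^fpkm_", "", grep("^fpkm_",
                                                  names(ex$expression),
                                                  value = TRUE)))
  silenced <- silenced_genes(ex$expression, sil_samples)
  degs <- intersect_de(ex$de_callerA, ex$de_callerB)
  up <- degs$gene_id[degs$direction == "up"]
  down <- degs$gene_id[degs$direction == "down"]
  constitutive <- setdiff(active, degs$gene_id)
  out$gene_classes <- list(up = up, down = down, constitutive = constitutive,
                           active = active, silenced = silenced)

  assoc <- NULL
  if (!is.null(specific$cold) && nrow(specific$cold)) {
    assoc <- dhs_gene_association(
      specific$cold, anno,
      list(up = up, down = down, constitutive = constitutive))
  }
  out$association <- assoc

  msg("stage: metagene and sensitivity")
  merge_reps <- function(tracks) {
    cuts <- lapply(names(tracks[[1]]$chrom_lengths), function(ch)
      sort(c(tracks[[1]]$cuts[[ch]], tracks[[2]]$cuts[[ch]])))
    names(cuts) <- names(tracks[[1]]$chrom_lengths)
    cut_site_track(cuts, tracks[[1]]$chrom_lengths,
                   sample = sub("_rep.*", "", tracks[[1]]$sample))
  }
  pooled <- lapply(dnase, merge_reps)
  keep <- intersect(active, anno$genes$gene_id)
  sub_anno <- anno
  sub_anno$genes <- anno$genes[anno$genes$gene_id %in% keep, , drop = FALSE]
  out$metagene <- lapply(pooled, metagene_profile, anno = sub_anno)
  sens <- NULL
  if (all(c("RT", "cold") %in% names(pooled)))
    sens <- sensitivity_change(pooled$cold, pooled$RT, anno, keep)
  out$sensitivity_change <- sens

  biv <- NULL
  if (cfg$bivalent) {
    msg("stage: bivalent calling")
    scores <- bivalent_scores(anno, keep, chip)
    biv <- call_bivalent(scores)
    body_iv <- data.frame(
      chrom = sub_anno$genes$chrom,
      start = pmin(sub_anno$genes$tss, sub_anno$genes$tts),
      end = pmax(sub_anno$genes$tss, sub_anno$genes$tts))
    if (all(c("K4me3", "K27me3") %in% names(chip$cold))) {
      k4 <- chip_signal(chip$cold$K4me3, body_iv, chip$cold$input)
      k27 <- chip_signal(chip$cold$K27me3, body_iv, chip$cold$input)
      biv$mark_class <- mark_class(k4, k27)[
        match(biv$gene_id, sub_anno$genes$gene_id)]
    }
  }
  out$bivalent <- biv

  msg("stage: statistics")
  stats_bundle <- list(
    n_consensus = vapply(consensus, nrow, integer(1)),
    n_specific = vapply(specific, nrow, integer(1)),
    n_active = length(active), n_silenced = length(silenced),
    n_up = length(up), n_down = length(down),
    n_constitutive = length(constitutive))
  if (!is.null(biv)) {
    stats_bundle$n_bivalent <- sum(biv$is_bivalent)
    stats_bundle$pct_bivalent_of_active <-
      percent_of(sum(biv$is_bivalent), length(active))
  }
  if (!is.null(sens)) {
    stats_bundle$median_log2_sensitivity_change <- sens$median_log2
    stats_bundle$wilcoxon_p_paired <- sens$p_paired
  }
  if (length(dnase) && length(dnase[[1]]) >= 2) {
    rc <- window_density_correlation(dnase[[1]][[1]], dnase[[1]][[2]], 100)
    stats_bundle$replicate_coverage_r <- rc$r
  }
  out$stats <- stats_bundle

  if (!is.null(cfg$out_dir)) {
    msg("stage: write outputs")
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    fp <- function(...) file.path(cfg$out_dir, ...)
    write_gff3(anno, fp("annotation.gff3"))
    for (cond in names(consensus)) {
      write_dhs_bed(consensus[[cond]], fp(paste0("dhs_consensus_", cond, ".bed")))
      write_summits_bed(consensus[[cond]],
                        fp(paste0("dhs_summits_", cond, ".bed")))
    }
    for (cond in names(specific))
      write_dhs_bed(specific[[cond]], fp(paste0("dhs_specific_", cond, ".bed")))
    for (cond in names(out$metagene))
      write_tsv(data.frame(gene_id = rownames(out$metagene[[cond]]),
                           out$metagene[[cond]], check.names = FALSE),
                fp(paste0("metagene_", cond, ".tsv")))
    if (!is.null(biv)) write_tsv(biv, fp("bivalent_calls.tsv"))
    if (!is.null(sens)) write_tsv(sens$table, fp("sensitivity_change.tsv"))
    for (tb in names(feature_tables))
      write_tsv(feature_tables[[tb]],
                fp(paste0("feature_distribution_", tb, ".tsv")))
    jsonlite::write_json(stats_bundle, fp("statistics.json"),
                         auto_unbox = TRUE, digits = 10, pretty = TRUE)
    manifest <- list(package = "coldchrom",
                     version = as.character(utils::packageVersion("coldchrom")),
                     r_version = paste(R.version$major, R.version$minor,
                                       sep = "."),
                     sim_seed = cfg$sim$seed, caller_seed = cfg$caller$seed,
                     simulate = cfg$simulate, conditions = cfg$conditions)
    jsonlite::write_json(manifest, fp("manifest.json"), auto_unbox = TRUE,
                         pretty = TRUE)
  }
  invisible(out)
}
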