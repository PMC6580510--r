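#!/usr/bin/env Rscript
# Stage 2: kernel-density DHS calling with Monte-Carlo FDR control.
#
# Calls DHSs independently in each biological replicate (FDR < 0.05),
# retains replicate-consensus DHSs (>= 1 bp overlap), and derives
# temperature-specific sets (zero overlap with the other condition).

source("analysis/00_config.R")
out <- results_dir("02_dhs")

cfg <- study_config()
ann <- generate_annotation(cfg)

consensus <- list()
for (cond in c("RT", "cold", "leaf")) {
  reps <- lapply(1:2, function(r) {
    tr <- simulate_dnase(cfg, ann$annotation, ann$labels, cond, r)
    pr <- study_caller()
    pr$seed <- sub_seed(pr$seed, "call", cond, r)
    d <- call_dhs(tr, pr, sample_id = paste0(cond, "_rep", r))
    cat(sprintf("%s rep%d: %d DHSs (threshold %.3f)\n", cond, r, nrow(d),
                attr(d, "threshold")))
    d
  })
  cons <- consensus_dhs(reps[[1]], reps[[2]])
  cons$sample <- cond
  consensus[[cond]] <- cons
  cat(sprintf("%s consensus: %d DHSs\n", cond, nrow(cons)))
  write_tsv(cons, file.path(out, paste0("dhs_consensus_", cond, ".tsv")))
  write_dhs_bed(cons, file.path(out, paste0("dhs_consensus_", cond, ".bed")))
  write_summits_bed(cons, file.path(out, paste0("dhs_summits_", cond, ".bed")))
}

specific <- list(cold = specific_dhs(consensus$cold, consensus$RT),
                 RT = specific_dhs(consensus$RT, consensus$cold))
for (cond in names(specific)) {
  cat(sprintf("%s-specific: %d of %d consensus DHSs (%.1f%%)\n", cond,
              nrow(specific[[cond]]), nrow(consensus[[cond]]),
              percent_of(nrow(specific[[cond]]), nrow(consensus[[cond]]))))
  write_tsv(specific[[cond]], file.path(out, paste0("dhs_specific_", cond,
                                                    ".tsv")))
}

# top cold-specific DHSs by read density: motif-scanning input regions
top <- top_dhs_regions(specific$cold, k = 1000, halfwidth = 50)
write_tsv(top, file.path(out, "top_cold_specific_regions.tsv"))
cat("top regions exported:", nrow(top), "(100 bp around summits)\n")
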