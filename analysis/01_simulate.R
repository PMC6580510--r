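#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study.
#
# Two chromosomes of 2 Mb carrying 400 genes; three conditions (RT tubers,
# cold tubers, leaves) with two DNase-seq replicates each; ChIP and
# dual-order sequential-ChIP channels for the tuber conditions; an
# expression table plus two DE caller outputs. Writes the annotation,
# truth labels and expression tables; tracks are regenerated on demand by
# later stages from the same seed.

source("analysis/00_config.R")
out <- results_dir("01_sim")

cfg <- study_config()
ann <- generate_annotation(cfg)
write_gff3(ann$annotation, file.path(out, "annotation.gff3"))
write_tsv(ann$labels, file.path(out, "truth_labels.tsv"))

ex <- simulate_expression(cfg, ann$labels)
write_tsv(ex$expression, file.path(out, "expression.tsv"))
write_tsv(ex$de_callerA, file.path(out, "de_callerA.tsv"))
write_tsv(ex$de_callerB, file.path(out, "de_callerB.tsv"))

cls <- table(ann$labels$expression_class)
cat("genes:", nrow(ann$annotation$genes),
    "| up:", cls[["up"]], "down:", cls[["down"]],
    "constitutive:", cls[["constitutive"]], "silenced:", cls[["silenced"]],
    "\nbivalent-planted:", sum(ann$labels$bivalent_planted),
    "| cold-only genic hotspot genes:", sum(ann$labels$genic_dhs_cold_only),
    "\n")

# one example library to show scale; later stages re-simulate as needed
tr <- simulate_dnase(cfg, ann$annotation, ann$labels, "RT", 1)
cat("DNase library size per replicate:", tr$library_size, "cuts\n")
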