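#!/usr/bin/env Rscript
# Stage 3: summit-based genomic feature assignment and DEG association.
#
# Each DHS is assigned to the feature containing its summit. The
# feature distribution is tabulated per condition, and condition-specific
# DHSs are associated with up-/down-/constitutively expressed gene classes
# with two-proportion z tests between the first two classes.

source("analysis/00_config.R")
out <- results_dir("03_classify")

cfg <- study_config()
ann <- generate_annotation(cfg)
anno <- read_gff3("results/01_sim/annotation.gff3")   # round-trip on purpose
stopifnot(identical(anno$genes$start, ann$annotation$genes$start))

read_dhs <- function(f) read_tsv(file.path("results/02_dhs", f))

for (cond in c("RT", "cold", "leaf")) {
  cons <- read_dhs(paste0("dhs_consensus_", cond, ".tsv"))
  lab <- assign_dhs_feature(anno, cons)
  tb <- table(factor(lab, levels = c("exon", "intron", "upstream1k",
                                     "downstream1k", "intergenic")))
  df <- data.frame(category = names(tb), count = as.integer(tb),
                   percent = vapply(as.integer(tb), percent_of, numeric(1),
                                    n = nrow(cons)))
  write_tsv(df, file.path(out, paste0("feature_distribution_", cond, ".tsv")))
  cat(cond, "consensus feature split: ",
      paste(sprintf("%s %.1f%%", df$category, df$percent), collapse = ", "),
      "\n")
}

expr <- read_tsv("results/01_sim/expression.tsv")
deA <- read_tsv("results/01_sim/de_callerA.tsv")
deB <- read_tsv("results/01_sim/de_callerB.tsv")
degs <- intersect_de(deA, deB)
active <- active_genes(expr, "RT", "cold")
classes <- list(up = degs$gene_id[degs$direction == "up"],
                down = degs$gene_id[degs$direction == "down"],
                constitutive = setdiff(active, degs$gene_id))
cat("DEGs by both callers:", nrow(degs),
    sprintf("(up %d / down %d)\n", length(classes$up), length(classes$down)))

spec_cold <- read_dhs("dhs_specific_cold.tsv")
assoc <- dhs_gene_association(spec_cold, anno, classes)
write_tsv(assoc$table, file.path(out, "cold_specific_deg_association.tsv"))
write_tsv(assoc$tests, file.path(out, "cold_specific_deg_ztests.tsv"))
gen <- assoc$table[assoc$table$category %in% c("exon", "intron"), ]
cat("genic cold-specific DHS association (% of class):\n")
print(gen[, c("class", "category", "count", "percent")], row.names = FALSE)
cat("z tests up vs down:\n")
print(assoc$tests, row.names = FALSE)
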