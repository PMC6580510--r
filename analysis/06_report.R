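#!/usr/bin/env Rscript
# Stage 6: collect the headline statistics of the whole run into one JSON
# and print a short narrative summary.

source("analysis/00_config.R")
out <- results_dir("06_report")

read_stage <- function(stage, f) read_tsv(file.path("results", stage, f))

cons <- lapply(c(RT = "RT", cold = "cold", leaf = "leaf"), function(cond)
  nrow(read_stage("02_dhs", paste0("dhs_consensus_", cond, ".tsv"))))
spec <- lapply(c(RT = "RT", cold = "cold"), function(cond)
  nrow(read_stage("02_dhs", paste0("dhs_specific_", cond, ".tsv"))))

expr <- read_tsv("results/01_sim/expression.tsv")
active <- active_genes(expr, "RT", "cold")
silenced <- silenced_genes(expr, c("RT", "cold", "leaf"))

sens <- read_stage("04_metagene", "sensitivity_change_active.tsv")
biv <- read_stage("05_bivalent", "bivalent_calls.tsv")

stats <- list(
  n_consensus = cons,
  n_specific = spec,
  pct_cold_specific = percent_of(spec$cold, cons$cold),
  pct_rt_specific = percent_of(spec$RT, cons$RT),
  n_active = length(active),
  n_silenced = length(silenced),
  median_log2_body_sensitivity_cold_vs_rt = median(sens$log2_ratio),
  n_bivalent_called = sum(biv$is_bivalent),
  pct_bivalent_of_active = percent_of(sum(biv$is_bivalent), length(active)))

jsonlite::write_json(stats, file.path(out, "summary_stats.json"),
                     auto_unbox = TRUE, digits = 10, pretty = TRUE)

cat("== synthetic cold-stress chromatin study ==\n")
cat(sprintf("consensus DHSs: RT %d, cold %d, leaf %d\n",
            cons$RT, cons$cold, cons$leaf))
cat(sprintf("condition-specific: cold %d (%.1f%%), RT %d (%.1f%%)\n",
            spec$cold, stats$pct_cold_specific,
            spec$RT, stats$pct_rt_specific))
cat(sprintf("active genes %d, silenced %d\n", length(active),
            length(silenced)))
cat(sprintf("median gene-body log2 sensitivity change (cold/RT): %.3f\n",
            stats$median_log2_body_sensitivity_cold_vs_rt))
cat(sprintf("bivalent-called genes: %d (%.1f%% of active)\n",
            stats$n_bivalent_called, stats$pct_bivalent_of_active))
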