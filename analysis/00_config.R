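# Shared configuration for the analysis scripts. Everything downstream is
# deterministic given these seeds, so each numbered script can regenerate
# the tracks it needs instead of shipping hundreds of megabytes of
# intermediate BED files.

library(coldchrom)

STUDY_SEED <- 20260927L

study_config <- function() sim_config(seed = STUDY_SEED)

study_caller <- function() caller_params(seed = STUDY_SEED)

results_dir <- function(stage) {
  d <- file.path("results", stage)
  dir.create(d, recursive = TRUE, showWarnings = FALSE)
  d
}
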