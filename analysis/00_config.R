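# Shared settings for the analysis scripts. Run the scripts in order from
# the repository root:  Rscript analysis/01_simulate_study.R  etc.
library(qamsfp)

study_seed <- 2026L
out_root <- "results"
study_dir <- file.path(out_root, "study")
tables_dir <- file.path(out_root, "tables")
dir.create(study_dir, showWarnings = FALSE, recursive = TRUE)
dir.create(tables_dir, showWarnings = FALSE, recursive = TRUE)

study_config <- function() sim_config(seed = study_seed)

read_tsv <- function(path) utils::read.delim(path, check.names = FALSE)
save_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  message("wrote ", path)
}
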