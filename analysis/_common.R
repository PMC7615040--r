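# Shared settings for the numbered analysis scripts. Run each script from
# the repository root, e.g.  Rscript analysis/01_simulate.R
suppressMessages(library(bnsdm))

master_seed <- 1
config <- demo_config()
results_dir <- "results"
dir.create(results_dir, recursive = TRUE, showWarnings = FALSE)

res_path <- function(...) file.path(results_dir, ...)
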