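# Shared settings for the analysis scripts. Each numbered script can be run
# on its own (stage outputs land under results/) and reads its inputs from
# the previous stage's files, so the chain is restartable.
#
# Usage: Rscript analysis/01_simulate.R [--seed N]

library(methacoex)

arg_seed <- function(default = 1L) {
  args <- commandArgs(trailingOnly = TRUE)
  i <- which(args == "--seed")
  if (length(i) && length(args) > i) as.integer(args[i + 1]) else default
}

results_dir <- function(...) {
  d <- file.path("results", ...)
  dir.create(d, recursive = TRUE, showWarnings = FALSE)
  d
}

analysis_config <- function(seed) {
  # full study-scale settings; see the methods vignette for the scaled-down
  # sizes used by the automated tests
  pipeline_config(seed = seed)
}
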