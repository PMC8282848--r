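# Shared settings for the analysis scripts. Run the scripts in order from
# the repository root: Rscript analysis/01_simulate.R, etc.
library(astromat)

ANALYSIS_SEED <- 1L
DATA_DIR <- "results/data"
RESULTS_DIR <- "results"
dir.create(DATA_DIR, showWarnings = FALSE, recursive = TRUE)

analysis_config <- function() sim_config(seed = ANALYSIS_SEED)
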