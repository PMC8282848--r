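# Reduced simulation scenario for tests that do not need full scale
small_config <- function(seed = 1) {
  sim_config(seed = seed, n_genes = 200, n_cells = 300,
             archetype_spec = data.frame(
               shape = c("early_decline", "early_peak", "mid_peak",
                         "plateau_decline", "late_rise", "late_switch"),
               count = c(15L, 13L, 10L, 12L, 12L, 8L),
               class = c(rep("immature", 4), rep("mature", 2)),
               stringsAsFactors = FALSE),
             flat_gene_count = 130L, n_peaks = 700L)
}
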