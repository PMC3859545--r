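# Shared run configuration for the analysis scripts. Every script is a pure
# function of this config: stages re-derive earlier inputs deterministically
# from the logged seed instead of parsing intermediate files.

library(plateletseq)

run_config <- simulation_config(
  n_genes = 60,        # 37 MT + PPBP/ACTB/UTY/DDX3Y + random nuclear genes
  library_size = 2e5,  # reads per sample
  lam = 0.0027638,     # per-bp oligo-dT decay rate
  mt_fraction = 0.635, # polyA+ mitochondrial read share
  mt_fraction_totrna = 0.09,
  dispersion = 0.05,
  seed = 1
)

run_design <- default_design()  # S0 polyA+ (M); S1 (M), S2 (F), S3 (M) totRNA

results_dir <- "results"
dir.create(results_dir, showWarnings = FALSE)
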