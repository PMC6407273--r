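# Shared settings for the analysis scripts: one master seed, one simulated
# discovery cohort (demo scale: 2,000 subjects, 5,000 SNPs), one results tree.
# Every script sources this file and can be run in order from the repo root:
#   Rscript analysis/01_simulate_cohort.R
#   Rscript analysis/02_classify_concordance.R
#   ...

suppressMessages(library(spirogwas))

MASTER_SEED <- 20260923L %% 1000000L
RESULTS_DIR <- "results/analysis"
DATA_DIR <- file.path(RESULTS_DIR, "data")
dir.create(DATA_DIR, showWarnings = FALSE, recursive = TRUE)

analysis_reference <- function() synthetic_lms_reference()

analysis_sim_config <- function() {
  sim_config(n_subjects = 2000, n_snps = 5000, seed = MASTER_SEED,
             missing_genotype_rate = 0.01)
}

analysis_cohort <- function() {
  simulate_cohort(analysis_sim_config(), analysis_reference())
}
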