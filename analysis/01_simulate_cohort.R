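#!/usr/bin/env Rscript
# Simulate the discovery cohort and export it in the exchange formats every
# later stage reads: PLINK binary genotypes, a covariate table, and the LMS
# coefficient table used for classification.

source("analysis/00_config.R")

ref <- analysis_reference()
coh <- analysis_cohort()
print(coh)

write_plink_bed(coh, file.path(DATA_DIR, "cohort"))
write_tsv(coh$subjects, file.path(DATA_DIR, "covariates.tsv"))
write_lms_table(ref, file.path(DATA_DIR, "lms_reference.tsv"),
                age_grid = seq(18, 95, by = 0.5))

cat(sprintf("wrote %d subjects x %d SNPs to %s\n",
            nrow(coh$subjects), ncol(coh$genotypes), DATA_DIR))
cat(sprintf("strata: %d never / %d ever smokers; %.1f%% genotypes missing\n",
            sum(coh$subjects$smoking_status == "never"),
            sum(coh$subjects$smoking_status == "ever"),
            100 * mean(is.na(coh$genotypes))))
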