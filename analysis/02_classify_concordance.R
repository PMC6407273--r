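#!/usr/bin/env Rscript
# Classify airflow obstruction under the fixed FEV1/FVC < 70% cut-off and the
# LMS-based lower limit of normal, then quantify how concordant the two
# definitions are within each smoking stratum.

source("analysis/00_config.R")

ref <- analysis_reference()
coh <- analysis_cohort()
labels <- classify_obstruction(coh, ref)
write_labels(labels, file.path(RESULTS_DIR, "labels.tsv"))

rows <- list()
for (st in c("never", "ever")) {
  cc <- cross_classification(labels, st)
  cs <- concordance_stats(cc)
  cat(sprintf("\n%s-smokers (n = %d): %d fixed-ratio cases, %d LLN cases, %d under both\n",
              st, cc$n, cc$n70, cc$nlln, cc$nboth))
  print(cs)
  rows[[st]] <- data.frame(stratum = st, n = cc$n, n70 = cc$n70,
                           nlln = cc$nlln, nboth = cc$nboth,
                           pct_concordant = cs$pct_concordant,
                           pct_discordant_among_union = cs$pct_discordant_among_union,
                           pct_case_overlap = cs$pct_overlap_cases)
}
write_tsv(do.call(rbind, rows), file.path(RESULTS_DIR, "concordance.tsv"))

# where does discordance live? (it should concentrate at the age extremes,
# with LLN-only cases young and fixed-ratio-only cases old)
d <- labels[labels$valid & labels$stratum != "excluded", ]
s <- coh$subjects[labels$valid & labels$stratum != "excluded", ]
f_only <- d$fixed70 & !d$lln_case
l_only <- !d$fixed70 & d$lln_case
cat(sprintf("\nfixed-ratio-only cases: ages %.0f-%.0f; LLN-only cases: ages %.0f-%.0f\n",
            min(s$age[f_only]), max(s$age[f_only]),
            min(s$age[l_only]), max(s$age[l_only])))
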