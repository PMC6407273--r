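# Shared fixtures, built in code and cached per test run.

.fixtures <- new.env(parent = emptyenv())

test_reference <- function() {
  if (is.null(.fixtures$ref)) .fixtures$ref <- synthetic_lms_reference()
  .fixtures$ref
}

# a constant-coefficient reference for hand-checkable classification tests:
# M = 80, S = 0.1, L = 1 everywhere -> LLN = 80 * (1 - 0.1 * qnorm(0.95))
flat_reference <- function(m = 80, s = 0.1, l = 1) {
  lms_reference(m = function(sex, age, height) rep(m, length(age)),
                s = function(sex, age, height) rep(s, length(age)),
                l = function(sex, age, height) rep(l, length(age)))
}

small_cohort <- function() {
  if (is.null(.fixtures$small)) {
    cfg <- sim_config(n_subjects = 800, n_snps = 60, seed = 42)
    .fixtures$small <- list(config = cfg,
                            cohort = simulate_cohort(cfg, test_reference()))
    .fixtures$small$labels <- classify_obstruction(.fixtures$small$cohort,
                                                   test_reference())
  }
  .fixtures$small
}

# build a subjects table by hand (spirometry given as ratio in percent)
manual_subjects <- function(ratio, sex = "male", age = 50, height = 175,
                            pack_years = 0) {
  n <- length(ratio)
  fvc <- rep(5, n)
  data.frame(id = sprintf("s%03d", seq_len(n)),
             sex = rep_len(sex, n), age = rep_len(age, n),
             height = rep_len(height, n),
             smoking_status = ifelse(rep_len(pack_years, n) == 0, "never",
                                     ifelse(rep_len(pack_years, n) > 5,
                                            "ever", "excluded")),
             pack_years = rep_len(pack_years, n),
             current_smoker = rep(FALSE, n),
             fev1 = ratio / 100 * fvc, fvc = fvc,
             stringsAsFactors = FALSE)
}

manual_cohort <- function(ratio, genotypes = NULL, ...) {
  subj <- manual_subjects(ratio, ...)
  n <- nrow(subj)
  if (is.null(genotypes))
    genotypes <- matrix(0L, n, 1, dimnames = list(subj$id, "snp1"))
  info <- data.frame(snp_id = colnames(genotypes),
                     chromosome = 1L,
                     position = seq_len(ncol(genotypes)) * 1000L,
                     allele1 = "A", allele2 = "G", stringsAsFactors = FALSE)
  cohort(subj, genotypes, info)
}

# fabricate a scan results frame directly (for overlap/agreement arithmetic)
fake_scan <- function(p, or = exp(stats::rnorm(length(p), 0, 0.1)),
                      ids = sprintf("snp%05d", seq_along(p))) {
  data.frame(snp_id = ids, p = p, or = or, stringsAsFactors = FALSE)
}
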