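test_that("genotypes follow Hardy-Weinberg proportions at fixed MAF", {
  cfg <- sim_config(n_subjects = 20000, n_snps = 3, maf_range = c(0.3, 0.3),
                    seed = 5)
  g <- simulate_genotypes(cfg)$genotypes
  freq <- prop.table(table(factor(g[, 1], levels = 0:2)))
  expect_equal(as.numeric(freq), c(0.49, 0.42, 0.09), tolerance = 0.03)
  # and the exact HWE test does not reject
  expect_gt(hwe_test(g[, 1]), 0.01)
})

test_that("missingness behaves as configured", {
  cfg0 <- sim_config(100, 50, missing_genotype_rate = 0, seed = 2)
  expect_false(anyNA(simulate_genotypes(cfg0)$genotypes))
  cfg1 <- sim_config(500, 100, missing_genotype_rate = 0.1, seed = 2)
  expect_equal(mean(is.na(simulate_genotypes(cfg1)$genotypes)), 0.1,
               tolerance = 0.01)
})

test_that("a config seed fully determines the simulated output", {
  cfg <- sim_config(100, 50, missing_genotype_rate = 0.05, seed = 99)
  g1 <- simulate_genotypes(cfg)
  g2 <- simulate_genotypes(cfg)
  expect_identical(g1, g2)
  ref <- test_reference()
  c1 <- simulate_cohort(cfg, ref)
  c2 <- simulate_cohort(cfg, ref)
  expect_identical(c1, c2)
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(10, 5, maf_range = c(0, 0.5)), "maf_range")
  expect_error(sim_config(10, 5, maf_range = c(0.1, 0.6)), "maf_range")
  expect_error(sim_config(10, 5, causal_snps = list(
    list(snp_index = 6, log_odds = 0.4, definitions = "lln"))), "out of range")
  expect_error(sim_config(10, 5, causal_snps = list(
    list(snp_index = 1, log_odds = 0.4, definitions = "ratio"))), "definitions")
})

test_that("pure never-smoker mix yields only 0 pack-year subjects", {
  cfg <- sim_config(300, 5, stratum_mix = 1, seed = 3)
  coh <- simulate_cohort(cfg, test_reference())
  expect_true(all(coh$subjects$pack_years == 0))
  expect_true(all(coh$subjects$smoking_status == "never"))
  expect_false(any(coh$subjects$current_smoker))
})

test_that("simulated cohorts satisfy the structural invariants across seeds", {
  ref <- test_reference()
  for (seed in 1:4) {
    cfg <- sim_config(250, 10, seed = seed, missing_genotype_rate = 0.02)
    coh <- simulate_cohort(cfg, ref)  # cohort() runs validate_cohort()
    expect_s3_class(coh, "cohort")
    expect_true(all(coh$subjects$fev1 <= coh$subjects$fvc))
    expect_true(all(coh$subjects$fev1 > 0))
    ev <- coh$subjects$smoking_status == "ever"
    expect_true(all(coh$subjects$pack_years[ev] > 5))
  }
})

test_that("a strong planted effect makes obstruction prevalence rise with allele count", {
  ref <- test_reference()
  cfg <- sim_config(30000, 3, maf_range = c(0.3, 0.3), stratum_mix = 1,
                    causal_snps = list(list(snp_index = 1, log_odds = log(3),
                                            definitions = c("fixed70", "lln"))),
                    seed = 17)
  coh <- simulate_cohort(cfg, ref)
  lab <- classify_obstruction(coh, ref)
  prev <- tapply(lab$lln_case, coh$genotypes[, 1], mean)
  expect_true(all(diff(prev[as.character(0:2)]) > 0))
})

test_that("liability-shift calibration recovers the requested log-odds", {
  # the induced additive log-odds on expected genotype-group prevalences
  # must equal the target by construction of the calibration
  for (b in c(log(1.5), -log(1.3), 0.8)) {
    delta <- calibrate_liability_shift(b, maf = 0.3, sd = 1)
    pg <- pnorm(qnorm(0.05) + delta * 0:2)
    fit <- fit_logistic(rep(c(1, 0), 3),
                        cbind(1, g = rep(0:2, each = 2)),
                        weights = as.vector(rbind(
                          c(0.49, 0.42, 0.09) * pg,
                          c(0.49, 0.42, 0.09) * (1 - pg))))
    expect_equal(unname(fit$beta[2]), b, tolerance = 1e-6)
  }
  expect_equal(calibrate_liability_shift(0, 0.3), 0)
})

test_that("planted eQTL slopes are recovered and nulls stay null", {
  ref <- test_reference()
  cfg <- sim_config(500, 10, seed = 8)
  coh <- simulate_cohort(cfg, ref)
  ex <- simulate_expression(coh,
                            eqtl_effects = list(list(snp_index = 3,
                                                     probe_id = "probeA",
                                                     slope = 1)),
                            noise_sd = 0.05, seed = 4, n_null_probes = 2)
  g <- coh$genotypes[, 3]
  fit <- lm(ex$expression["probeA", ] ~ g + coh$subjects$age +
              I(coh$subjects$sex == "male"))
  expect_equal(unname(coef(fit)["g"]), 1, tolerance = 0.02)
  # null probe unassociated
  fit0 <- lm(ex$expression["null_probe0001", ] ~ g)
  expect_gt(summary(fit0)$coefficients["g", 4], 0.001)
  expect_error(simulate_expression(coh, list(list(snp_index = 99,
                                                  probe_id = "x", slope = 1))),
               "out of range")
})
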