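test_that("single-study and identical-pair meta reduce to closed forms", {
  m1 <- fixed_effects_meta(beta = 0.3, se = 0.1)
  expect_equal(m1$beta_meta, 0.3)
  expect_equal(m1$se_meta, 0.1)
  expect_equal(m1$i2, 0)
  m2 <- fixed_effects_meta(beta = c(0.3, 0.3), se = c(0.1, 0.1))
  expect_equal(m2$beta_meta, 0.3)
  expect_equal(m2$se_meta, 0.1 / sqrt(2))
  expect_equal(m2$i2, 0)  # identical effects -> no heterogeneity
})

test_that("meta-analysis equals the weighted-least-squares oracle", {
  set.seed(10)
  for (i in 1:25) {
    k <- sample(2:8, 1)
    beta <- rnorm(k, 0.2, 0.3)
    se <- runif(k, 0.05, 0.5)
    m <- fixed_effects_meta(beta, se)
    wls <- lm(beta ~ 1, weights = 1 / se^2)
    expect_equal(m$beta_meta, unname(coef(wls)[1]), tolerance = 1e-10)
    # WLS se from known variances (not residual-rescaled)
    expect_equal(m$se_meta, 1 / sqrt(sum(1 / se^2)), tolerance = 1e-12)
    # heterogeneity bounded
    expect_gte(m$i2, 0)
    expect_lte(m$i2, 100)
  }
})

test_that("meta-analysis cross-checks against metafor's fixed-effects model", {
  skip_if_not_installed("metafor")
  set.seed(11)
  beta <- rnorm(5, 0.2, 0.2)
  se <- runif(5, 0.08, 0.3)
  m <- fixed_effects_meta(beta, se)
  rf <- metafor::rma(yi = beta, sei = se, method = "EE")
  expect_equal(m$beta_meta, as.numeric(rf$beta), tolerance = 1e-8)
  expect_equal(m$se_meta, as.numeric(rf$se), tolerance = 1e-8)
  expect_equal(m$q_stat, as.numeric(rf$QE), tolerance = 1e-8)
  expect_equal(m$i2, max(0, 100 * (m$q_stat - (5 - 1)) / m$q_stat))
})

test_that("meta is invariant to study order and equivariant to allele flips", {
  beta <- c(0.2, -0.1, 0.35)
  se <- c(0.1, 0.2, 0.15)
  m <- fixed_effects_meta(beta, se)
  perm <- c(3, 1, 2)
  mp <- fixed_effects_meta(beta[perm], se[perm])
  expect_equal(m$beta_meta, mp$beta_meta)
  expect_equal(m$q_stat, mp$q_stat)
  mf <- fixed_effects_meta(-beta, se)
  expect_equal(mf$beta_meta, -m$beta_meta)
  expect_equal(mf$p_meta, m$p_meta)
  expect_equal(mf$i2, m$i2)
})

test_that("direction strings follow the 0.95-1.05 no-effect band", {
  expect_equal(direction_string(1.00), "0")
  expect_equal(direction_string(0.90), "-")
  expect_equal(direction_string(c(1.36, 1.21, 1.20, 1.30, 1.25)), "+++++")
  expect_equal(direction_string(c(1.2, 0.95, 1.05, 0.9)), "+00-")
  expect_error(direction_string(c(1.2, -1)), "positive")
})

test_that("replication requires both the Bonferroni threshold and direction consistency", {
  # candidate with p = 0.034 among 2 candidates: threshold 0.025, no call
  m <- list(p_meta = 0.034, direction = "+++++")
  call <- replication_call(m, n_candidates = 2)
  expect_equal(call$threshold, 0.025)
  expect_false(call$replicated)
  # opposing signs block replication even at tiny p
  expect_false(replication_call(list(p_meta = 1e-8, direction = "++-"), 2)$replicated)
  # zeros are direction-neutral
  expect_true(replication_call(list(p_meta = 1e-8, direction = "++0"), 2)$replicated)
  expect_true(replication_call(list(p_meta = 0, direction = "+++"), 5)$replicated)
  # single candidate reduces to p < alpha plus consistency
  expect_true(replication_call(list(p_meta = 0.049, direction = "++"), 1)$replicated)
  expect_false(replication_call(list(p_meta = 0.051, direction = "++"), 1)$replicated)
})

test_that("cis-eQTL scan recovers planted slopes inside the 4 Mb window", {
  ref <- test_reference()
  cfg <- sim_config(400, 6, seed = 31)
  coh <- simulate_cohort(cfg, ref)
  probes <- data.frame(
    probe_id = c("near", "far", "edge"),
    chr = coh$snp_info$chromosome[2],
    start = coh$snp_info$position[2] + c(5e4, 2.5e6, 2e6),
    stringsAsFactors = FALSE)
  ex <- simulate_expression(coh,
                            eqtl_effects = list(list(snp_index = 2,
                                                     probe_id = "near",
                                                     slope = 1)),
                            noise_sd = 0.2, seed = 32,
                            probe_annotation = probes)
  covs <- data.frame(disease = as.numeric(classify_obstruction(coh, ref)$fixed70),
                     age = coh$subjects$age, sex = coh$subjects$sex,
                     smoking = coh$subjects$pack_years)
  res <- cis_eqtl_scan(2, coh, ex$expression, ex$probes, covariates = covs)
  # probe at 2.5 Mb excluded; 2.0 Mb edge included (closed window)
  expect_setequal(res$probe_id, c("near", "edge"))
  near <- res[res$probe_id == "near", ]
  expect_equal(near$slope, 1, tolerance = 2 * near$se)
  expect_true(near$significant)
  expect_equal(attr(res, "bonferroni"), 0.05 / 2)
  # a SNP with no probes nearby gives an empty, non-error result
  res0 <- cis_eqtl_scan(1, coh, ex$expression, ex$probes)
  expect_equal(nrow(res0), 0)
})

test_that("null expression keeps the Bonferroni-controlled call rate", {
  ref <- test_reference()
  cfg <- sim_config(300, 4, seed = 41)
  coh <- simulate_cohort(cfg, ref)
  # 30 null probes clustered around SNP 1
  probes <- data.frame(probe_id = sprintf("p%02d", 1:30),
                       chr = coh$snp_info$chromosome[1],
                       start = coh$snp_info$position[1] +
                         seq(-1.4e6, 1.5e6, length.out = 30),
                       stringsAsFactors = FALSE)
  probes$start <- pmax(round(probes$start), 1)
  ex <- simulate_expression(coh, eqtl_effects = list(), noise_sd = 1,
                            seed = 42, probe_annotation = probes)
  res <- cis_eqtl_scan(1, coh, ex$expression, ex$probes)
  expect_equal(nrow(res), 30)
  expect_equal(sum(res$significant), 0)
})
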