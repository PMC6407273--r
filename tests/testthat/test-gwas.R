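# closed-form oracle for a single binary predictor: 2x2 table (a,b,c,d) =
# (cases|x=1, controls|x=1, cases|x=0, controls|x=0)
table_2x2_fit <- function(a, b, c, d) {
  list(beta = log(a * d / (b * c)), se = sqrt(1 / a + 1 / b + 1 / c + 1 / d))
}

test_that("no association in a balanced 2x2 table gives OR exactly 1", {
  y <- rep(c(1, 0, 1, 0), each = 10)
  x <- rep(c(1, 1, 0, 0), each = 10)
  fit <- fit_logistic(y, cbind(1, x = x))
  expect_equal(unname(fit$beta["x"]), 0, tolerance = 1e-8)
})

test_that("IRLS reproduces the closed-form 2x2 OR and SE", {
  set.seed(20)
  for (i in 1:40) {
    cells <- sample(1:25, 4, replace = TRUE)
    a <- cells[1]; b <- cells[2]; c <- cells[3]; d <- cells[4]
    y <- rep(c(1, 0, 1, 0), times = c(a, b, c, d))
    x <- rep(c(1, 1, 0, 0), times = c(a, b, c, d))
    fit <- fit_logistic(y, cbind(1, x = x))
    oracle <- table_2x2_fit(a, b, c, d)
    expect_equal(unname(fit$beta["x"]), oracle$beta, tolerance = 1e-8)
    expect_equal(unname(fit$se["x"]), oracle$se, tolerance = 1e-8)
  }
})

test_that("weighted IRLS equals the expanded-data fit", {
  y <- c(1, 0, 1, 0)
  x <- c(1, 1, 0, 0)
  w <- c(7, 11, 3, 19)
  fit_w <- fit_logistic(y, cbind(1, x = x), weights = w)
  fit_e <- fit_logistic(rep(y, w), cbind(1, x = rep(x, w)))
  expect_equal(fit_w$beta, fit_e$beta, tolerance = 1e-9)
  expect_equal(fit_w$se, fit_e$se, tolerance = 1e-9)
})

test_that("the IRLS optimum dominates a surrounding parameter grid", {
  set.seed(33)
  n <- 30
  X <- cbind(1, x1 = rnorm(n), x2 = rbinom(n, 1, 0.5))
  y <- rbinom(n, 1, plogis(-0.3 + 0.8 * X[, 2] - 0.5 * X[, 3]))
  fit <- fit_logistic(y, X)
  ll <- function(b) sum(y * (X %*% b) - log1p(exp(X %*% b)))
  for (i in 1:50) {
    probe <- fit$beta + runif(3, -0.5, 0.5)
    expect_lte(ll(probe), fit$loglik + 1e-8)
  }
})

test_that("IRLS agrees with an independent maximum-likelihood fit", {
  set.seed(12)
  for (i in 1:5) {
    n <- 200
    X <- cbind(1, g = rbinom(n, 2, 0.3), age = rnorm(n, 50, 10))
    y <- rbinom(n, 1, plogis(-2 + 0.4 * X[, "g"] + 0.02 * X[, "age"]))
    fit <- fit_logistic(y, X)
    gf <- glm(y ~ X[, -1], family = binomial())
    expect_equal(unname(fit$beta), unname(coef(gf)), tolerance = 1e-7)
    expect_equal(unname(fit$se), unname(sqrt(diag(vcov(gf)))), tolerance = 1e-6)
  }
})

test_that("degenerate designs are reported, not silently fitted", {
  y <- rep(c(0, 1), 20)
  expect_error(fit_logistic(y, cbind(1, bad = rep(2, 40))), "bad")
  x <- rnorm(40)
  expect_error(fit_logistic(y, cbind(1, a = x, b = 2 * x)), "collinear")
  # perfect separation: flagged via converged = FALSE
  ys <- rep(c(0, 1), each = 20)
  xs <- ys + rnorm(40, 0, 1e-4)
  fit <- fit_logistic(ys, cbind(1, x = xs))
  expect_false(fit$converged)
})

test_that("Wald p-values match their defining distribution", {
  expect_equal(wald_test(0, 1), 1)
  expect_equal(wald_test(1.959964, 1), 0.05, tolerance = 1e-6)
  expect_error(wald_test(1, 0), "positive")
  # independent CDF evaluation: two-sided normal tail
  set.seed(2)
  for (i in 1:30) {
    beta <- rnorm(1); se <- runif(1, 0.1, 2)
    expect_equal(wald_test(beta, se), 2 * pnorm(-abs(beta / se)),
                 tolerance = 1e-12)
  }
})

test_that("scan results are invariant to subject and SNP order", {
  fix <- small_cohort()
  coh <- fix$cohort
  lab <- fix$labels
  s1 <- run_scan(coh, lab, scan_spec("fixed70", "never"))
  # permute subjects
  set.seed(9)
  perm <- sample(nrow(coh$subjects))
  coh2 <- cohort(coh$subjects[perm, ], coh$genotypes[perm, , drop = FALSE],
                 coh$snp_info)
  lab2 <- classify_obstruction(coh2, test_reference())
  s2 <- run_scan(coh2, lab2, scan_spec("fixed70", "never"))
  expect_equal(s1$results$beta, s2$results$beta, tolerance = 1e-8)
  expect_equal(s1$results$p, s2$results$p, tolerance = 1e-8)
  # permute SNPs
  sperm <- sample(ncol(coh$genotypes))
  coh3 <- cohort(coh$subjects, coh$genotypes[, sperm, drop = FALSE],
                 coh$snp_info[sperm, ])
  s3 <- run_scan(coh3, lab, scan_spec("fixed70", "never"))
  ord <- match(s1$results$snp_id, s3$results$snp_id)
  expect_equal(s1$results$beta, s3$results$beta[ord], tolerance = 1e-10)
})

test_that("rescaling a covariate leaves the genotype estimate unchanged", {
  fix <- small_cohort()
  coh <- fix$cohort
  lab <- fix$labels
  s1 <- run_scan(coh, lab, scan_spec("fixed70", "never"))
  coh2 <- coh
  coh2$subjects$height <- coh2$subjects$height / 100  # cm -> m
  s2 <- run_scan(coh2, lab, scan_spec("fixed70", "never"))
  expect_equal(s1$results$beta, s2$results$beta, tolerance = 1e-8)
  expect_equal(s1$results$se, s2$results$se, tolerance = 1e-8)
  expect_equal(s1$results$p, s2$results$p, tolerance = 1e-8)
})

test_that("the effect allele is the minor allele in the analysed sample", {
  fix <- small_cohort()
  s <- run_scan(fix$cohort, fix$labels, scan_spec("lln", "never"))
  expect_true(all(s$results$eaf <= 0.5 + 1e-12, na.rm = TRUE))
  expect_equal(s$results$or, exp(s$results$beta))
})

test_that("default covariate sets follow the definition/stratum conventions", {
  expect_equal(scan_spec("fixed70", "never")$covariates, c("sex", "age", "height"))
  expect_equal(scan_spec("lln", "never")$covariates, character(0))
  expect_equal(scan_spec("fixed70", "ever")$covariates,
               c("sex", "age", "height", "pack_years", "current_smoker"))
  expect_equal(scan_spec("lln", "ever")$covariates,
               c("pack_years", "current_smoker"))
  expect_equal(scan_spec("lln", "never", covariates = c("age"))$covariates, "age")
})

test_that("genomic lambda matches its definition and monotonicity", {
  expect_equal(genomic_lambda(rep(0.5, 100)), 1.0)
  set.seed(4)
  p <- runif(1e5)
  expect_equal(genomic_lambda(p), 1.0, tolerance = 0.02)
  expect_gt(genomic_lambda(p / 2), 1)
  expect_error(genomic_lambda(numeric(0)), "no p-values")
  expect_error(genomic_lambda(c(0.5, 0)), "0, 1")
})

test_that("interaction scan detects stratum-specific effects and degenerate designs", {
  ref <- test_reference()
  # plant a latent effect, then analyse an outcome where only never-smokers
  # carry it by restricting the comparison to a constructed label set
  cfg <- sim_config(3000, 5, maf_range = c(0.3, 0.4), seed = 21)
  coh <- simulate_cohort(cfg, ref)
  lab <- classify_obstruction(coh, ref)
  # construct labels: in never-smokers, case status tracks genotype 1 strongly;
  # in ever-smokers it is random with the same prevalence
  set.seed(22)
  g <- coh$genotypes[, 1]
  nev <- lab$stratum == "never"
  p_nev <- plogis(-2.5 + 1.2 * g)
  p_ev <- plogis(-2.5 + 1.2 * mean(g))
  lab$fixed70 <- ifelse(nev, runif(length(g)) < p_nev, runif(length(g)) < p_ev)
  res <- interaction_scan(coh, lab, "fixed70", snps = 1)
  expect_true(res$converged)
  expect_lt(res$p_int, 0.05)
  # no ever-smokers -> product column collinear -> error
  cfg1 <- sim_config(300, 3, stratum_mix = 1, seed = 23)
  coh1 <- simulate_cohort(cfg1, ref)
  lab1 <- classify_obstruction(coh1, ref)
  expect_error(interaction_scan(coh1, lab1, "fixed70"), "both never- and ever")
})

test_that("null interactions give calibrated p-values across seeds", {
  ref <- test_reference()
  pvals <- numeric(6)
  for (s in 1:6) {
    cfg <- sim_config(1200, 2, seed = 100 + s)
    coh <- simulate_cohort(cfg, ref)
    lab <- classify_obstruction(coh, ref)
    pvals[s] <- interaction_scan(coh, lab, "fixed70", snps = 1)$p_int
  }
  # under the null, interaction p-values should not be systematically tiny
  expect_gt(mean(pvals > 0.05), 0.5)
})

test_that("a scan without cases errors out", {
  fix <- small_cohort()
  lab <- fix$labels
  lab$fixed70[lab$stratum == "never"] <- FALSE
  expect_error(run_scan(fix$cohort, lab, scan_spec("fixed70", "never")),
               "at least one case")
})
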