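test_that("union-fraction percentage reproduces hand arithmetic", {
  expect_equal(overlap_pct(11377, 11475, 4755), 100 * 4755 / 18097)
  expect_equal(pct_display(overlap_pct(11377, 11475, 4755)), 26)
  expect_equal(pct_display(overlap_pct(31, 27, 2), 1), 3.6)
  expect_true(is.na(overlap_pct(0, 0, 0)))
  expect_error(overlap_pct(3, 2, 4), "exceed")
})

test_that("identical scans overlap 100% at every threshold", {
  set.seed(1)
  a <- fake_scan(runif(500))
  ov <- threshold_overlap(a, a, c(0.5, 0.05, 0.005))
  expect_true(all(ov$pct_overlap_of_union == 100))
  expect_equal(ov$n_hits_a, ov$n_overlap)
})

test_that("overlap is symmetric and monotone over nested thresholds", {
  set.seed(2)
  a <- fake_scan(runif(2000))
  b <- fake_scan(runif(2000))
  t <- c(0.2, 0.05, 0.01, 0.001)
  ov_ab <- threshold_overlap(a, b, t)
  ov_ba <- threshold_overlap(b, a, t)
  expect_equal(ov_ab$pct_overlap_of_union, ov_ba$pct_overlap_of_union)
  # thresholds given largest-first: hit sets shrink, overlaps non-increasing
  expect_true(all(diff(ov_ab$n_overlap) <= 0))
  expect_true(all(diff(ov_ab$n_hits_a) <= 0))
  # hit sets nested
  h <- attr(ov_ab, "hits")
  expect_true(all(h[["0.01"]]$a %in% h[["0.05"]]$a))
})

test_that("ties at exactly p = t are excluded (strict inequality)", {
  a <- fake_scan(c(0.05, 0.049, 0.2))
  b <- fake_scan(c(0.05, 0.01, 0.3))
  ov <- threshold_overlap(a, b, 0.05)
  expect_equal(ov$n_hits_a, 1)
  expect_equal(ov$n_hits_b, 1)
  expect_equal(ov$n_overlap, 1)
})

test_that("independent null scans overlap near the t^2 expectation", {
  set.seed(3)
  n <- 10000
  reps <- vapply(1:20, function(i) {
    a <- fake_scan(runif(n))
    b <- fake_scan(runif(n))
    threshold_overlap(a, b, 0.05)$n_overlap
  }, numeric(1))
  expect_equal(mean(reps), n * 0.05^2, tolerance = 0.1)
})

test_that("Bonferroni threshold arithmetic", {
  expect_equal(bonferroni_threshold(0.05, 227981), 0.05 / 227981)
  expect_equal(bonferroni_threshold(0.05, 2), 0.025)
  expect_equal(bonferroni_threshold(0.01, 1), 0.01)
  expect_error(bonferroni_threshold(0.05, 0), "at least 1")
})

test_that("agreement equals the textbook Pearson formula", {
  a <- fake_scan(p = c(0.9, 0.5, 0.3, 0.12, 0.01),
                 or = c(1.0, 1.1, 0.8, 1.4, 2.1))
  b <- fake_scan(p = c(0.7, 0.6, 0.2, 0.09, 0.05),
                 or = c(0.9, 1.2, 0.9, 1.2, 1.8))
  ag <- agreement(a, b)
  r_hand <- function(x, y) {
    sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  }
  expect_equal(ag$r_pvalue, r_hand(a$p, b$p), tolerance = 1e-12)
  expect_equal(ag$r_or, r_hand(a$or, b$or), tolerance = 1e-12)
  expect_equal(ag$n_snps, 5)
  # self-agreement is exactly 1
  self <- agreement(a, a)
  expect_equal(self$r_pvalue, 1)
  expect_equal(self$r_or, 1)
})

test_that("independent null scans have near-zero agreement", {
  set.seed(5)
  a <- fake_scan(runif(10000), or = exp(rnorm(10000, 0, 0.2)))
  b <- fake_scan(runif(10000), or = exp(rnorm(10000, 0, 0.2)))
  ag <- agreement(a, b)
  expect_lt(abs(ag$r_pvalue), 0.05)
  expect_lt(abs(ag$r_or), 0.05)
})

test_that("zero-variance inputs are flagged, not silently NaN", {
  a <- fake_scan(rep(0.5, 5), or = rep(1, 5))
  b <- fake_scan(runif(5), or = exp(rnorm(5)))
  ag <- agreement(a, b)
  expect_true(is.na(ag$r_pvalue))
  expect_true("p-values" %in% ag$flagged)
})

test_that("log-scale agreement is exposed as an option", {
  set.seed(6)
  a <- fake_scan(runif(100), or = exp(rnorm(100, 0, 0.2)))
  b <- fake_scan(runif(100), or = exp(rnorm(100, 0, 0.2)))
  ag <- agreement(a, b, scale = "log")
  expect_equal(ag$scale, "log")
  expect_true(is.finite(ag$r_or))
})

test_that("cross-stratum report emits all six unordered pairs", {
  fix <- small_cohort()
  qc <- apply_qc(fix$cohort)
  scans <- list()
  for (def in c("fixed70", "lln")) for (st in c("never", "ever"))
    scans[[paste(def, st, sep = ".")]] <-
      run_scan(qc$cohort, fix$labels, scan_spec(def, st))
  rep6 <- cross_stratum_overlap(scans, thresholds = c(0.05, 0.01))
  expect_length(rep6, 6)
  expect_setequal(
    names(rep6),
    combn(names(scans), 2, FUN = paste, collapse = " vs ", simplify = TRUE))
})

test_that("concordant definitions overlap far beyond the independence expectation", {
  ref <- test_reference()
  cfg <- sim_config(1200, 400, stratum_mix = 1, seed = 71)
  coh <- simulate_cohort(cfg, ref)
  lab <- classify_obstruction(coh, ref)
  s70 <- run_scan(coh, lab, scan_spec("fixed70", "never"))
  slln <- run_scan(coh, lab, scan_spec("lln", "never"))
  ov <- threshold_overlap(s70, slln, 0.05)
  expect_gt(ov$n_overlap, 400 * 0.05^2)  # independence would give ~1
  expect_gt(agreement(s70, slln)$r_or, 0.3)
})

test_that("disjoint SNP universes error out", {
  a <- fake_scan(runif(5), ids = paste0("a", 1:5))
  b <- fake_scan(runif(5), ids = paste0("b", 1:5))
  expect_error(threshold_overlap(a, b, 0.05), "share no SNPs")
})
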