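#' SNP quality-control thresholds
#'
#' Defaults are the conventional array-GWAS filters: call rate at least 95%,
#' minor allele frequency at least 1%, exact Hardy-Weinberg p-value at least
#' 1e-4.
#'
#' @param min_call_rate Minimum per-SNP genotype call rate.
#' @param min_maf Minimum minor allele frequency.
#' @param min_hwe_p Minimum Hardy-Weinberg p-value.
#' @return A `qc_thresholds` object.
#' @export
qc_thresholds <- function(min_call_rate = 0.95, min_maf = 0.01,
                          min_hwe_p = 1e-4) {
  stopifnot(min_call_rate >= 0, min_call_rate <= 1,
            min_maf >= 0, min_maf <= 1,
            min_hwe_p >= 0, min_hwe_p <= 1)
  structure(list(min_call_rate = min_call_rate, min_maf = min_maf,
                 min_hwe_p = min_hwe_p), class = "qc_thresholds")
}

#' Per-SNP genotype call rate
#'
#' @param g Genotype column (0/1/2 with NA for missing).
#' @return Fraction of non-missing genotypes.
#' @export
snp_call_rate <- function(g) {
  if (length(g) < 1) stop("empty genotype column")
  mean(!is.na(g))
}

#' Minor allele frequency of a genotype column
#'
#' Allele-count frequency of the rarer allele among non-missing genotypes;
#' at most 0.5 by construction.
#'
#' @param g Genotype column (counts of one allele, 0/1/2, NA missing).
#' @return Frequency in [0, 0.5].
#' @export
minor_allele_frequency <- function(g) {
  g <- g[!is.na(g)]
  if (length(g) == 0) stop("no non-missing genotypes")
  f <- sum(g) / (2 * length(g))
  min(f, 1 - f)
}

#' Exact Hardy-Weinberg equilibrium test
#'
#' Conditional exact test: given the observed allele counts, the p-value is
#' the sum of probabilities of all heterozygote counts no more probable than
#' the observed one. Probabilities follow the Levene-Haldane distribution of
#' heterozygote counts given allele counts, computed by recurrence.
#' Monomorphic SNPs return p = 1 by convention. For samples larger than
#' `max_exact` genotypes the chi-square goodness-of-fit test (1 df) is used
#' instead.
#'
#' @param g Genotype column (0/1/2, NA missing) or a length-3 vector of
#'   genotype counts `c(n_hom_ref, n_het, n_hom_alt)` when `counts = TRUE`.
#' @param counts Interpret `g` as genotype counts.
#' @param max_exact Sample-size bound above which the chi-square
#'   approximation is used (default 100000).
#' @return Hardy-Weinberg p-value.
#' @export
hwe_test <- function(g, counts = FALSE, max_exact = 1e5) {
  if (counts) {
    stopifnot(length(g) == 3, all(g >= 0))
    n0 <- g[1]; n1 <- g[2]; n2 <- g[3]
  } else {
    g <- g[!is.na(g)]
    if (length(g) == 0) stop("no non-missing genotypes")
    n0 <- sum(g == 0); n1 <- sum(g == 1); n2 <- sum(g == 2)
  }
  n <- n0 + n1 + n2
  na <- 2 * n2 + n1            # copies of the allele counted by g
  nb <- 2 * n0 + n1
  if (na == 0 || nb == 0) return(1)  # monomorphic
  if (n > max_exact) {
    p_allele <- na / (2 * n)
    expd <- n * c((1 - p_allele)^2, 2 * p_allele * (1 - p_allele), p_allele^2)
    stat <- sum((c(n0, n1, n2) - expd)^2 / expd)
    return(stats::pchisq(stat, df = 1, lower.tail = FALSE))
  }
  rare <- min(na, nb)
  # heterozygote count shares the parity of the rare-allele count
  hets <- seq(rare %% 2, rare, by = 2)
  # unnormalised log-probabilities by recurrence:
  # P(h+2)/P(h) = (nrare - h)(ncommon - h) / ((h+2)(h+1) / 4) ... use direct ratio
  logp <- numeric(length(hets))
  for (i in seq_along(hets)[-1]) {
    h <- hets[i - 1]
    # ratio P(h+2)/P(h) = ((rare - h)/2 * (common - h)/2 * 4) / ((h+2)(h+1))
    common <- max(na, nb)
    ratio <- ((rare - h) * (common - h)) / ((h + 2) * (h + 1))
    logp[i] <- logp[i - 1] + log(ratio)
  }
  logp <- logp - max(logp)
  prob <- exp(logp) / sum(exp(logp))
  obs <- match(n1, hets)
  if (is.na(obs)) stop("observed heterozygote count inconsistent with allele counts")
  sum(prob[prob <= prob[obs] * (1 + 1e-12)])
}

#' Apply SNP-level quality control to a cohort
#'
#' Removes SNPs failing any of the call-rate, MAF or Hardy-Weinberg filters.
#' QC is computed once on the full (unstratified) cohort; the subject set is
#' never altered. The report records each SNP's statistics and per-filter
#' pass/fail flags.
#'
#' @param cohort A [cohort()].
#' @param thresholds A [qc_thresholds()].
#' @param hwe_subset Optional logical vector (one per subject) restricting
#'   the Hardy-Weinberg test to a subset, e.g. non-cases; default all
#'   subjects.
#' @return List with `cohort` (filtered), `report` (data frame `snp_id,
#'   call_rate, maf, hwe_p, fail_call_rate, fail_maf, fail_hwe, pass`) and
#'   `summary` (per-filter failure counts).
#' @export
apply_qc <- function(cohort, thresholds = qc_thresholds(), hwe_subset = NULL) {
  stopifnot(inherits(thresholds, "qc_thresholds"))
  G <- cohort$genotypes
  Gh <- if (is.null(hwe_subset)) G else {
    stopifnot(length(hwe_subset) == nrow(G))
    G[hwe_subset, , drop = FALSE]
  }
  m <- ncol(G)
  cr <- colMeans(!is.na(G))
  maf <- vapply(seq_len(m), function(j) {
    g <- G[, j][!is.na(G[, j])]
    if (length(g) == 0) return(0)
    f <- sum(g) / (2 * length(g))
    min(f, 1 - f)
  }, numeric(1))
  hwe <- vapply(seq_len(m), function(j) {
    g <- Gh[, j]
    if (all(is.na(g))) return(1)
    hwe_test(g)
  }, numeric(1))
  fail_cr <- cr < thresholds$min_call_rate
  fail_maf <- maf < thresholds$min_maf
  fail_hwe <- hwe < thresholds$min_hwe_p
  pass <- !(fail_cr | fail_maf | fail_hwe)
  report <- data.frame(snp_id = cohort$snp_info$snp_id,
                       call_rate = cr, maf = maf, hwe_p = hwe,
                       fail_call_rate = fail_cr, fail_maf = fail_maf,
                       fail_hwe = fail_hwe, pass = pass,
                       stringsAsFactors = FALSE)
  if (!any(pass)) warning("all SNPs removed by QC; downstream scans will be empty")
  out <- cohort
  out$genotypes <- G[, pass, drop = FALSE]
  out$snp_info <- cohort$snp_info[pass, , drop = FALSE]
  list(cohort = out, report = report,
       summary = c(n_input = m,
                   fail_call_rate = sum(fail_cr),
                   fail_maf = sum(fail_maf),
                   fail_hwe = sum(fail_hwe),
                   n_pass = sum(pass)))
}

#' Write a QC report to a tab-separated file
#'
#' @param qc Result of [apply_qc()].
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_qc_report <- function(qc, path) {
  write_tsv(qc$report, path)
}
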