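#' Expand a cohort k-fold by verbatim duplication
#'
#' Every subject (genotypes, covariates, labels) is duplicated `k` times with
#' fresh ids, emulating the thought experiment of collecting the same cohort
#' `k` times: point estimates are unchanged while standard errors shrink by
#' about `1/sqrt(k)`.
#'
#' @param cohort A [cohort()].
#' @param labels Matching `obstruction_labels`.
#' @param k Expansion factor (integer >= 2).
#' @return List with expanded `cohort` and `labels`.
#' @export
expand_cohort <- function(cohort, labels, k) {
  if (k < 2 || k != round(k)) stop("k must be an integer >= 2")
  n <- nrow(cohort$subjects)
  idx <- rep(seq_len(n), times = k)
  rep_tag <- rep(seq_len(k), each = n)
  subjects <- cohort$subjects[idx, , drop = FALSE]
  subjects$id <- paste0(subjects$id, "_d", rep_tag)
  rownames(subjects) <- NULL
  G <- cohort$genotypes[idx, , drop = FALSE]
  rownames(G) <- subjects$id
  lab <- labels[idx, , drop = FALSE]
  lab$id <- subjects$id
  rownames(lab) <- NULL
  class(lab) <- class(labels)
  list(cohort = cohort(subjects, G, cohort$snp_info), labels = lab)
}

#' Randomly re-allocate obstruction cases with fixed margins
#'
#' Within one stratum, case status under both definitions is re-assigned
#' uniformly at random over subjects while preserving the observed counts
#' exactly: `nboth` subjects receive both labels, `n70 - nboth` the fixed-ratio
#' label only, `nlln - nboth` the LLN label only, and the remainder neither.
#' Genotypes and covariates are untouched, so any genotype-phenotype
#' association is null in expectation. The preserved margins are re-checked
#' on every call (hard assertion).
#'
#' @param labels `obstruction_labels` for the cohort.
#' @param stratum Stratum to permute (`"never"` or `"ever"`).
#' @param seed Integer seed.
#' @return New `obstruction_labels` with permuted case status in `stratum`.
#' @export
random_case_allocation <- function(labels, stratum = c("never", "ever"), seed) {
  stratum <- match.arg(stratum)
  cc <- cross_classification(labels, stratum)
  if (cc$n_union > cc$n) stop("case counts infeasible for stratum size")
  set.seed(as.integer(seed))
  rows <- which(labels$stratum == stratum & labels$valid)
  picked <- sample(rows, cc$n_union)
  both <- picked[seq_len(cc$nboth)]
  only70 <- picked[cc$nboth + seq_len(cc$n70 - cc$nboth)]
  onlylln <- picked[cc$n70 + seq_len(cc$nlln - cc$nboth)]
  out <- labels
  out$fixed70[rows] <- FALSE
  out$lln_case[rows] <- FALSE
  out$fixed70[c(both, only70)] <- TRUE
  out$lln_case[c(both, onlylln)] <- TRUE
  cc2 <- cross_classification(out, stratum)
  stopifnot(cc2$n70 == cc$n70, cc2$nlln == cc$nlln, cc2$nboth == cc$nboth,
            cc2$n == cc$n)
  out
}

#' Null-overlap experiment by repeated random case allocation
#'
#' Repeats, `replicates` times: re-allocate case labels at random with fixed
#' margins, rerun the two definition scans with their default covariate
#' conventions, and record the union-fraction overlap percentage at each
#' threshold. A replicate with no hits in either scan at a threshold
#' contributes 0% overlap (no overlapping hits); the count of such empty
#' unions is reported alongside.
#'
#' @param cohort A QC'd [cohort()].
#' @param labels Matching `obstruction_labels`.
#' @param stratum Stratum to study.
#' @param replicates Number of random allocations (default 10).
#' @param thresholds p-value thresholds.
#' @param seed Integer seed; replicate seeds are derived deterministically.
#' @return List of class `null_overlap_distribution`, one element per
#'   threshold: `threshold, replicates, overlap_pcts, n_empty_union, min,
#'   max, mean, seed`.
#' @export
null_overlap_experiment <- function(cohort, labels, stratum = c("never", "ever"),
                                    replicates = 10,
                                    thresholds = c(0.05, 1e-2, 1e-3, 1e-4),
                                    seed = 1L) {
  stratum <- match.arg(stratum)
  rep_seeds <- derive_seeds(seed, replicates)
  pcts <- matrix(NA_real_, nrow = replicates, ncol = length(thresholds))
  empty <- matrix(FALSE, nrow = replicates, ncol = length(thresholds))
  for (r in seq_len(replicates)) {
    perm <- random_case_allocation(labels, stratum, seed = rep_seeds[r])
    s70 <- run_scan(cohort, perm, scan_spec("fixed70", stratum))
    slln <- run_scan(cohort, perm, scan_spec("lln", stratum))
    ov <- threshold_overlap(s70, slln, thresholds)
    p <- ov$pct_overlap_of_union
    empty[r, ] <- is.na(p)
    p[is.na(p)] <- 0
    pcts[r, ] <- p
  }
  out <- lapply(seq_along(thresholds), function(i) {
    v <- pcts[, i]
    list(threshold = thresholds[i], replicates = replicates,
         overlap_pcts = v, n_empty_union = sum(empty[, i]),
         min = min(v), max = max(v), mean = mean(v), seed = seed)
  })
  names(out) <- as.character(thresholds)
  class(out) <- "null_overlap_distribution"
  out
}

#' @export
print.null_overlap_distribution <- function(x, ...) {
  for (d in x)
    cat(sprintf("t = %g: overlap %% over %d replicates: min %.1f, mean %.1f, max %.1f (%d empty unions)\n",
                d$threshold, d$replicates, d$min, d$mean, d$max, d$n_empty_union))
  invisible(x)
}
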