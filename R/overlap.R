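#' Union-fraction overlap percentage from hit counts
#'
#' The overlap between two hit sets is reported as the intersection divided
#' by the union, in percent: `100 * n_overlap / (n_a + n_b - n_overlap)`.
#' This is the denominator that reproduces published overlap percentages
#' from their printed hit counts.
#'
#' @param n_a,n_b Hit counts in the two scans.
#' @param n_overlap Size of the intersection.
#' @return Percentage (NA when the union is empty).
#' @export
#' @examples
#' overlap_pct(11377, 11475, 4755)  # 26.3 -> printed 26%
overlap_pct <- function(n_a, n_b, n_overlap) {
  if (n_overlap > min(n_a, n_b)) stop("overlap cannot exceed either hit count")
  u <- n_a + n_b - n_overlap
  if (u == 0) return(NA_real_)
  100 * n_overlap / u
}

#' Thresholded hit-set overlap between two scans
#'
#' For each p-value threshold `t`, the hit set of a scan is the SNPs with
#' `p < t` (strict); the report gives both scans' hit counts, the
#' intersection, and the union-fraction percentage. Scans are compared on
#' their common SNP universe; a mismatch is reported via the
#' `n_dropped` attribute.
#'
#' @param scan_a,scan_b `scan_summary` objects (or their `results` frames).
#' @param thresholds Numeric vector of p-value cutoffs.
#' @return Data frame of class `overlap_report` with one row per threshold:
#'   `threshold, n_hits_a, n_hits_b, n_overlap, pct_overlap_of_union`, and
#'   attribute `hits` (list of per-threshold snp_id lists).
#' @export
threshold_overlap <- function(scan_a, scan_b, thresholds = c(0.05, 0.01, 1e-3,
                                                             1e-4, 1e-5, 1e-6)) {
  a <- if (inherits(scan_a, "scan_summary")) scan_a$results else scan_a
  b <- if (inherits(scan_b, "scan_summary")) scan_b$results else scan_b
  common <- intersect(a$snp_id, b$snp_id)
  if (length(common) == 0) stop("scans share no SNPs")
  n_dropped <- (nrow(a) - length(common)) + (nrow(b) - length(common))
  pa <- a$p[match(common, a$snp_id)]
  pb <- b$p[match(common, b$snp_id)]
  ok <- !is.na(pa) & !is.na(pb)
  common <- common[ok]; pa <- pa[ok]; pb <- pb[ok]
  hits <- list()
  rows <- lapply(thresholds, function(t) {
    ha <- common[pa < t]
    hb <- common[pb < t]
    ov <- intersect(ha, hb)
    hits[[as.character(t)]] <<- list(a = ha, b = hb, overlap = ov)
    data.frame(threshold = t, n_hits_a = length(ha), n_hits_b = length(hb),
               n_overlap = length(ov),
               pct_overlap_of_union = overlap_pct(length(ha), length(hb),
                                                  length(ov)))
  })
  out <- do.call(rbind, rows)
  attr(out, "hits") <- hits
  attr(out, "n_dropped") <- n_dropped
  class(out) <- c("overlap_report", "data.frame")
  out
}

#' Bonferroni-corrected p-value threshold
#'
#' @param alpha Family-wise error rate (default 0.05).
#' @param n_tests Number of tests (>= 1).
#' @return `alpha / n_tests`.
#' @export
#' @examples
#' bonferroni_threshold(0.05, 227981)  # 2.19e-7
bonferroni_threshold <- function(alpha = 0.05, n_tests) {
  if (n_tests < 1) stop("n_tests must be at least 1")
  stopifnot(alpha > 0, alpha <= 1)
  alpha / n_tests
}

#' Agreement between two scans: correlation of p-values and ORs
#'
#' Pearson correlations of the per-SNP p-values and of the per-SNP odds
#' ratios across the common SNP universe. Raw scales are the default (the
#' convention the comparison is defined on); `scale = "log"` correlates
#' -log10 p-values and log ORs instead, which is less dominated by extreme
#' ORs (documented caveat of the raw scale).
#'
#' @param scan_a,scan_b `scan_summary` objects (or results frames).
#' @param scale `"raw"` or `"log"`.
#' @return List of class `agreement_report`: `r_pvalue`, `r_or`, `n_snps`,
#'   `scale`, plus `flagged` naming any zero-variance input.
#' @export
agreement <- function(scan_a, scan_b, scale = c("raw", "log")) {
  scale <- match.arg(scale)
  a <- if (inherits(scan_a, "scan_summary")) scan_a$results else scan_a
  b <- if (inherits(scan_b, "scan_summary")) scan_b$results else scan_b
  common <- intersect(a$snp_id, b$snp_id)
  ia <- match(common, a$snp_id); ib <- match(common, b$snp_id)
  ok <- !is.na(a$p[ia]) & !is.na(b$p[ib]) & !is.na(a$or[ia]) & !is.na(b$or[ib])
  if (sum(ok) < 3) stop("need at least 3 SNPs with complete results")
  pa <- a$p[ia][ok]; pb <- b$p[ib][ok]
  oa <- a$or[ia][ok]; ob <- b$or[ib][ok]
  if (scale == "log") {
    pa <- -log10(pa); pb <- -log10(pb)
    oa <- log(oa); ob <- log(ob)
  }
  flagged <- character(0)
  r_of <- function(x, y, what) {
    if (stats::sd(x) == 0 || stats::sd(y) == 0) {
      flagged <<- c(flagged, what)
      return(NA_real_)
    }
    stats::cor(x, y)
  }
  structure(list(r_pvalue = r_of(pa, pb, "p-values"),
                 r_or = r_of(oa, ob, "ORs"),
                 n_snps = sum(ok), scale = scale, flagged = flagged),
            class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf("agreement over %d SNPs (%s scale): r(p) = %.3f, r(OR) = %.3f\n",
              x$n_snps, x$scale, x$r_pvalue, x$r_or))
  invisible(x)
}

#' All pairwise overlap and agreement reports across four scans
#'
#' Given the four definition-by-stratum scans, emits the six unordered pairs'
#' overlap and agreement reports, labelled by the pair.
#'
#' @param scans Named list of four `scan_summary` objects; names like
#'   `"fixed70.never"`.
#' @param thresholds Threshold ladder for the overlap reports.
#' @return List with one element per pair: `list(pair, overlap, agreement)`.
#' @export
cross_stratum_overlap <- function(scans, thresholds = c(0.05, 0.01, 1e-3,
                                                        1e-4, 1e-5, 1e-6)) {
  if (length(scans) != 4) stop("expected four scans (definition x stratum)")
  if (is.null(names(scans)))
    names(scans) <- vapply(scans, function(s)
      paste(s$spec$definition, s$spec$stratum, sep = "."), character(1))
  pairs <- utils::combn(names(scans), 2, simplify = FALSE)
  out <- lapply(pairs, function(pr) {
    list(pair = pr,
         overlap = threshold_overlap(scans[[pr[1]]], scans[[pr[2]]], thresholds),
         agreement = agreement(scans[[pr[1]]], scans[[pr[2]]]))
  })
  names(out) <- vapply(pairs, paste, character(1), collapse = " vs ")
  out
}
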