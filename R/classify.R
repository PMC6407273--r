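#' Classify airflow obstruction under the fixed-ratio and LLN definitions
#'
#' For every subject with valid spirometry, computes the FEV1/FVC ratio in
#' percent at full floating precision and labels obstruction under both
#' definitions with strict inequalities: `fixed70 = ratio < 70` and
#' `lln = ratio < LLN(sex, age, height)`. Smoking strata follow the pack-year
#' convention of population spirometry studies: never-smokers have exactly
#' 0 pack-years, ever-smokers more than 5, and subjects with more than 0 but
#' at most 5 pack-years are excluded from the stratified analyses.
#'
#' @param cohort A [cohort()] object.
#' @param reference An [lms_reference()] for FEV1/FVC in percent.
#' @param percentile Reference percentile defining the LLN (default 0.05).
#' @return A data frame of class `obstruction_labels` with columns
#'   `id`, `stratum` (`never`/`ever`/`excluded`), `ratio` (percent),
#'   `lln` (threshold), `fixed70` (logical), `lln_case` (logical) and
#'   `valid` (FALSE when spirometry is missing; such subjects carry NA labels).
#' @export
classify_obstruction <- function(cohort, reference, percentile = 0.05) {
  s <- cohort$subjects
  valid <- !(is.na(s$fev1) | is.na(s$fvc)) & s$fvc > 0
  ratio <- ifelse(valid, 100 * s$fev1 / s$fvc, NA_real_)
  lln <- rep(NA_real_, nrow(s))
  if (any(valid))
    lln[valid] <- lms_lln(reference, s$sex[valid], s$age[valid],
                          s$height[valid], percentile = percentile)
  stratum <- ifelse(s$pack_years == 0, "never",
                    ifelse(s$pack_years > 5, "ever", "excluded"))
  out <- data.frame(id = s$id,
                    stratum = stratum,
                    ratio = ratio,
                    lln = lln,
                    fixed70 = ifelse(valid, ratio < 70, NA),
                    lln_case = ifelse(valid, ratio < lln, NA),
                    valid = valid,
                    stringsAsFactors = FALSE)
  class(out) <- c("obstruction_labels", "data.frame")
  out
}

#' Cross-classify case status under the two obstruction definitions
#'
#' Counts, within one smoking stratum, the subjects labelled obstructed under
#' the fixed ratio (`n70`), under the LLN (`nlln`), and under both (`nboth`),
#' and derives the union (`n_union = n70 + nlln - nboth`) and the discordant
#' count (`n_discordant = n70 + nlln - 2*nboth`).
#'
#' @param labels An `obstruction_labels` data frame from
#'   [classify_obstruction()].
#' @param stratum `"never"` or `"ever"`.
#' @return A `cross_classification` object.
#' @export
cross_classification <- function(labels, stratum = c("never", "ever")) {
  stratum <- match.arg(stratum)
  d <- labels[labels$stratum == stratum & labels$valid, , drop = FALSE]
  if (nrow(d) == 0) stop("no labelled subjects in stratum '", stratum, "'")
  new_cross_classification(n = nrow(d),
                           n70 = sum(d$fixed70),
                           nlln = sum(d$lln_case),
                           nboth = sum(d$fixed70 & d$lln_case))
}

#' Construct a cross-classification from printed counts
#'
#' Builds the same object as [cross_classification()] directly from published
#' table counts, so concordance arithmetic can be reproduced without
#' individual-level data.
#'
#' @param n Total subjects in the stratum.
#' @param n70 Cases under FEV1/FVC < 70%.
#' @param nlln Cases under FEV1/FVC < LLN.
#' @param nboth Cases under both definitions.
#' @return A `cross_classification` object.
#' @export
#' @examples
#' cc <- new_cross_classification(5070, 548, 401, 371)
#' cc$n_union       # 578
#' cc$n_discordant  # 207
new_cross_classification <- function(n, n70, nlln, nboth) {
  stopifnot(n >= 0, n70 >= 0, nlln >= 0, nboth >= 0)
  if (nboth > min(n70, nlln))
    stop("nboth cannot exceed min(n70, nlln)")
  n_union <- n70 + nlln - nboth
  if (n_union > n) stop("union of cases exceeds stratum size")
  structure(list(n = n, n70 = n70, nlln = nlln, nboth = nboth,
                 n_union = n_union,
                 n_discordant = n70 + nlln - 2 * nboth),
            class = "cross_classification")
}

#' @export
print.cross_classification <- function(x, ...) {
  cat(sprintf("cross-classification: n=%d, <70%%: %d, <LLN: %d, both: %d (union %d, discordant %d)\n",
              x$n, x$n70, x$nlln, x$nboth, x$n_union, x$n_discordant))
  invisible(x)
}

#' Concordance statistics for the two obstruction definitions
#'
#' From a [cross_classification()], computes the percentage of subjects
#' classified concordantly, the percentage classified discordantly, and among
#' subjects obstructed under at least one definition the percentage discordant
#' and the percentage obstructed under both. Values are returned at full
#' precision; `display` holds the nearest-integer rounded form used in tables.
#'
#' @param cc A `cross_classification`.
#' @return A list of class `concordance_stats` with elements `pct_concordant`,
#'   `pct_discordant`, `pct_discordant_among_union`, `pct_overlap_cases`,
#'   `union_defined` and `display` (rounded percentages).
#' @export
concordance_stats <- function(cc) {
  stopifnot(inherits(cc, "cross_classification"))
  if (cc$n == 0) stop("empty cross-classification")
  pc <- 100 * (cc$n - cc$n_discordant) / cc$n
  pd <- 100 * cc$n_discordant / cc$n
  union_defined <- cc$n_union > 0
  pdu <- if (union_defined) 100 * cc$n_discordant / cc$n_union else NA_real_
  pov <- if (union_defined) 100 * cc$nboth / cc$n_union else NA_real_
  out <- list(pct_concordant = pc, pct_discordant = pd,
              pct_discordant_among_union = pdu,
              pct_overlap_cases = pov,
              union_defined = union_defined,
              display = c(pct_concordant = pct_display(pc),
                          pct_discordant = pct_display(pd),
                          pct_discordant_among_union = pct_display(pdu),
                          pct_overlap_cases = pct_display(pov)))
  class(out) <- "concordance_stats"
  out
}

#' @export
print.concordance_stats <- function(x, ...) {
  d <- x$display
  cat(sprintf("concordant %g%%, discordant %g%%", d[1], d[2]))
  if (x$union_defined)
    cat(sprintf("; among obstructed: %g%% discordant, %g%% under both definitions",
                d[3], d[4]))
  else
    cat("; no obstructed subjects (union-based statistics undefined)")
  cat("\n")
  invisible(x)
}

#' Write obstruction labels to a tab-separated file
#'
#' @param labels An `obstruction_labels` data frame.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_labels <- function(labels, path) {
  write_tsv(labels[, c("id", "stratum", "fixed70", "lln_case")], path)
}
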