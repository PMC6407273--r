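#' Derive deterministic sub-seeds from a master seed
#'
#' Each pipeline stage (genotypes, covariates, spirometry, missingness, label
#' flips, ...) consumes its own RNG stream derived once from the master seed,
#' so adding a stage never perturbs the draws of another.
#'
#' @param seed Master integer seed.
#' @param n Number of sub-seeds to derive.
#' @return Integer vector of length `n`, each in `[1, 2^31 - 1]`.
#' @keywords internal
derive_seeds <- function(seed, n) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  sample.int(.Machine$integer.max, n)
}

#' Round a percentage for display
#'
#' Internal values are kept at full precision; printed values use nearest-integer
#' rounding (half away from zero), matching how epidemiological tables report
#' percentages.
#'
#' @param x Numeric percentage.
#' @param digits Decimal digits to keep (default 0).
#' @return Rounded numeric.
#' @export
pct_display <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Format a p-value threshold in scientific display form
#'
#' Formats e.g. `0.05 / 227981` as `"2.19 x 10^-7"` (three significant digits),
#' the conventional display for Bonferroni-corrected genome-wide thresholds.
#'
#' @param p Numeric threshold in (0, 1).
#' @return Character scalar.
#' @export
format_p_threshold <- function(p) {
  stopifnot(is.numeric(p), p > 0)
  if (p >= 1e-3) return(format(signif(p, 3), scientific = FALSE))
  e <- floor(log10(p))
  mant <- signif(p / 10^e, 3)
  sprintf("%s x 10^%d", format(mant), e)
}

#' Write/read a tab-separated table with the package's conventions
#'
#' Plain `write.table`/`read.table` wrappers (tab separator, header, no
#' quoting, no row names) used for every report the pipeline writes, exported
#' so downstream scripts can round-trip the files.
#'
#' @param x Data frame to write.
#' @param path File path.
#' @param ... Passed to [utils::read.table()].
#' @return `write_tsv`: the path, invisibly. `read_tsv`: a data frame.
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE, na = "NA")
  invisible(path)
}

#' @rdname write_tsv
#' @export
read_tsv <- function(path, ...) {
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                    check.names = FALSE, ...)
}
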