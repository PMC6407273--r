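#' LMS reference equations for a spirometric index
#'
#' An `lms_reference` bundles, for each sex, the median (M), coefficient of
#' variation (S) and Box-Cox power (L) of a spirometric index as smooth
#' functions of age and height, together with the valid covariate domain.
#' Quantiles of the index at a standard-normal deviate `z` are
#' `M * (1 + L*S*z)^(1/L)` when `L != 0` and `M * exp(S*z)` when `L = 0`;
#' the lower limit of normal (LLN) is the 5th percentile (`z = qnorm(0.05)`).
#'
#' @param m,s,l Functions of `(sex, age, height)` returning the M, S and L
#'   coefficients. `sex` is `"male"`/`"female"`; `age` in years; `height` in cm.
#'   All three must be vectorised over their arguments.
#' @param age_range,height_range Length-2 numeric vectors giving the valid
#'   domain (years, cm).
#' @param index Label of the index the equations describe.
#' @return An object of class `lms_reference`.
#' @export
lms_reference <- function(m, s, l, age_range = c(18, 95),
                          height_range = c(140, 210),
                          index = "FEV1/FVC (%)") {
  stopifnot(is.function(m), is.function(s), is.function(l),
            length(age_range) == 2, length(height_range) == 2,
            age_range[1] < age_range[2], height_range[1] < height_range[2])
  structure(list(m = m, s = s, l = l,
                 age_range = as.numeric(age_range),
                 height_range = as.numeric(height_range),
                 index = index),
            class = "lms_reference")
}

#' @export
print.lms_reference <- function(x, ...) {
  cat("LMS reference for", x$index, "\n")
  cat(sprintf("  age domain: %g-%g yrs; height domain: %g-%g cm\n",
              x$age_range[1], x$age_range[2],
              x$height_range[1], x$height_range[2]))
  invisible(x)
}

check_lms_domain <- function(reference, sex, age, height) {
  sex <- as.character(sex)
  if (!all(sex %in% c("male", "female")))
    stop("sex must be 'male' or 'female'")
  bad <- age < reference$age_range[1] | age > reference$age_range[2] |
    height < reference$height_range[1] | height > reference$height_range[2]
  if (any(bad, na.rm = TRUE))
    stop(sprintf("%d subject(s) outside the reference domain (age %g-%g, height %g-%g)",
                 sum(bad, na.rm = TRUE), reference$age_range[1], reference$age_range[2],
                 reference$height_range[1], reference$height_range[2]))
  invisible(sex)
}

lms_coefs <- function(reference, sex, age, height) {
  sex <- check_lms_domain(reference, sex, age, height)
  m <- reference$m(sex, age, height)
  s <- reference$s(sex, age, height)
  l <- reference$l(sex, age, height)
  if (any(m <= 0) || any(s <= 0))
    stop("invalid LMS coefficients: M and S must be positive over the domain")
  list(m = m, s = s, l = l)
}

#' Evaluate an LMS quantile at a standard-normal deviate
#'
#' @inheritParams lms_lln
#' @param z Standard-normal deviate(s).
#' @return Index value(s) at the requested deviate.
#' @export
lms_quantile <- function(reference, sex, age, height, z) {
  k <- lms_coefs(reference, sex, age, height)
  n <- max(length(k$m), length(k$s), length(k$l), length(z))
  m <- rep_len(k$m, n); s <- rep_len(k$s, n); l <- rep_len(k$l, n)
  z <- rep_len(z, n)
  ifelse(abs(l) < 1e-12, m * exp(s * z), m * (1 + l * s * z)^(1 / l))
}

#' Standard-normal deviate (z-score) of an observed index value
#'
#' Inverse of [lms_quantile()].
#'
#' @inheritParams lms_lln
#' @param observed Observed index value(s).
#' @return z-score(s).
#' @export
lms_zscore <- function(reference, sex, age, height, observed) {
  k <- lms_coefs(reference, sex, age, height)
  n <- max(length(k$m), length(k$s), length(k$l), length(observed))
  m <- rep_len(k$m, n); s <- rep_len(k$s, n); l <- rep_len(k$l, n)
  observed <- rep_len(observed, n)
  ifelse(abs(l) < 1e-12,
         log(observed / m) / s,
         ((observed / m)^l - 1) / (l * s))
}

#' Lower limit of normal of a spirometric index
#'
#' The LLN is the lower fifth percentile of the index in the healthy reference
#' population for given sex, age and height: `M*(1 + L*S*z_p)^(1/L)` for
#' `L != 0` and `M*exp(S*z_p)` for `L = 0`, with `z_p = qnorm(percentile)`.
#'
#' @param reference An [lms_reference()].
#' @param sex `"male"` or `"female"` (vectorised).
#' @param age Age in years.
#' @param height Height in cm.
#' @param percentile Reference percentile defining the limit (default 0.05).
#' @return LLN value(s) in the units of the index.
#' @export
#' @examples
#' ref <- lms_reference(m = function(sex, age, height) 80,
#'                      s = function(sex, age, height) 0.1,
#'                      l = function(sex, age, height) 1)
#' lms_lln(ref, "male", 50, 175)  # 80 * (1 - 0.1 * 1.6449) = 66.84
lms_lln <- function(reference, sex, age, height, percentile = 0.05) {
  stopifnot(percentile > 0, percentile < 1)
  lms_quantile(reference, sex, age, height, stats::qnorm(percentile))
}

#' Percent of the predicted (median) index value
#'
#' @inheritParams lms_lln
#' @param observed Observed index value(s).
#' @return `100 * observed / M(sex, age, height)`.
#' @export
percent_predicted <- function(reference, sex, age, height, observed) {
  k <- lms_coefs(reference, sex, age, height)
  100 * observed / k$m
}

#' Read an LMS coefficient table
#'
#' The table format is tab-separated with columns `sex` (`male`/`female`),
#' `age` (years, grid points), `M`, `S`, `L`; coefficients are linearly
#' interpolated between age grid points. Table-backed references do not vary
#' with height (for the FEV1/FVC ratio the height dependence of the reference
#' value is negligible relative to age); users may instead construct an
#' [lms_reference()] from arbitrary `f(sex, age, height)`.
#'
#' @param path Path to the TSV file.
#' @param height_range Declared valid height range (cm).
#' @param index Index label.
#' @return An [lms_reference()].
#' @export
read_lms_table <- function(path, height_range = c(140, 210),
                           index = "FEV1/FVC (%)") {
  tab <- read_tsv(path)
  lms_reference_from_table(tab, height_range = height_range, index = index)
}

#' Build an LMS reference from a coefficient data frame
#'
#' @param tab Data frame with columns `sex`, `age`, `M`, `S`, `L`.
#' @inheritParams read_lms_table
#' @return An [lms_reference()].
#' @export
lms_reference_from_table <- function(tab, height_range = c(140, 210),
                                     index = "FEV1/FVC (%)") {
  need <- c("sex", "age", "M", "S", "L")
  if (!all(need %in% names(tab)))
    stop("LMS table must have columns: ", paste(need, collapse = ", "))
  if (!all(tab$sex %in% c("male", "female")))
    stop("LMS table sex column must be 'male'/'female'")
  funs <- lapply(split(tab, tab$sex), function(d) {
    d <- d[order(d$age), ]
    if (anyDuplicated(d$age)) stop("duplicated age grid point in LMS table")
    list(m = stats::approxfun(d$age, d$M, rule = 2),
         s = stats::approxfun(d$age, d$S, rule = 2),
         l = stats::approxfun(d$age, d$L, rule = 2))
  })
  if (!all(c("male", "female") %in% names(funs)))
    stop("LMS table must cover both sexes")
  per_sex <- function(which) {
    function(sex, age, height) {
      out <- numeric(length(age))
      for (sx in unique(sex)) {
        i <- sex == sx
        out[i] <- funs[[sx]][[which]](age[i])
      }
      out
    }
  }
  lms_reference(m = per_sex("m"), s = per_sex("s"), l = per_sex("l"),
                age_range = range(tab$age), height_range = height_range,
                index = index)
}

#' Write an LMS reference's coefficient table
#'
#' Evaluates the reference on an age grid at a fixed height and writes the
#' tab-separated `{sex, age, M, S, L}` exchange format.
#'
#' @param reference An [lms_reference()].
#' @param path Output path.
#' @param age_grid Ages at which to tabulate.
#' @param height Height (cm) at which to evaluate (table format is age-only).
#' @return Invisibly, the path.
#' @export
write_lms_table <- function(reference, path,
                            age_grid = seq(reference$age_range[1],
                                           reference$age_range[2], by = 1),
                            height = 170) {
  rows <- do.call(rbind, lapply(c("male", "female"), function(sx) {
    sex <- rep(sx, length(age_grid))
    h <- rep(height, length(age_grid))
    data.frame(sex = sex, age = age_grid,
               M = reference$m(sex, age_grid, h),
               S = reference$s(sex, age_grid, h),
               L = reference$l(sex, age_grid, h))
  }))
  write_tsv(rows, path)
}

#' Synthetic-but-plausible LMS reference for FEV1/FVC
#'
#' A smooth reference for the FEV1/FVC ratio (in percent) whose median declines
#' with age and whose dispersion grows slightly with age, so that the LLN
#' crosses the fixed 70% cut-off in midlife: below roughly age 42 the LLN lies
#' above 70% and above it the LLN lies below 70%. This reproduces the key
#' structural feature of real spirometric references — discordance between the
#' fixed-ratio and LLN definitions concentrates in the young (LLN-only cases)
#' and the old (fixed-ratio-only cases). It is a synthetic stand-in, not a
#' published reference equation.
#'
#' @return An [lms_reference()] for FEV1/FVC in percent.
#' @export
synthetic_lms_reference <- function() {
  s <- function(sex, age, height) 0.058 + 0.00035 * age
  m <- function(sex, age, height) {
    # parametrised through the LLN: it declines ~0.12 %/yr and crosses the
    # fixed 70% cut-off near age 42 (slightly later in women)
    lln <- 70 + 0.12 * (42 - age) + ifelse(sex == "female", 0.8, 0)
    lln / (1 - stats::qnorm(0.95) * s(sex, age, height)) -
      0.015 * (height - 170)
  }
  l <- function(sex, age, height) rep(1, length(age))
  lms_reference(m = m, s = s, l = l, age_range = c(18, 95),
                height_range = c(140, 210),
                index = "FEV1/FVC (%) [synthetic reference]")
}
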