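#' Inverse-variance fixed-effects meta-analysis of one SNP
#'
#' Pools per-cohort log-odds estimates with weights `w_i = 1/se_i^2`:
#' `beta_meta = sum(w*beta)/sum(w)`, `se_meta = 1/sqrt(sum(w))`, Wald p-value
#' from `beta_meta/se_meta`. Heterogeneity: Cochran's
#' `Q = sum(w*(beta - beta_meta)^2)` with `df = k - 1` and
#' `I2 = max(0, 100*(Q - df)/Q)` (0 when `Q = 0`).
#'
#' @param beta Per-cohort log-odds estimates (same effect-allele orientation;
#'   resolve flips before calling).
#' @param se Per-cohort standard errors (> 0).
#' @param cohorts Optional cohort identifiers, in declared order.
#' @param snp_id Optional SNP identifier carried into the result.
#' @return A `meta_result`: `snp_id, k, beta_meta, se_meta, p_meta, q_stat,
#'   df, i2, direction` (direction string from the per-cohort ORs).
#' @export
fixed_effects_meta <- function(beta, se, cohorts = NULL, snp_id = NA_character_) {
  if (length(beta) == 0) stop("no estimates supplied")
  if (length(se) != length(beta)) stop("beta and se lengths differ")
  if (any(!is.finite(se) | se <= 0)) stop("all standard errors must be positive")
  w <- 1 / se^2
  bm <- sum(w * beta) / sum(w)
  sm <- 1 / sqrt(sum(w))
  q <- sum(w * (beta - bm)^2)
  df <- length(beta) - 1
  i2 <- if (q > 0) max(0, 100 * (q - df) / q) else 0
  structure(list(snp_id = snp_id, k = length(beta),
                 beta_meta = bm, se_meta = sm,
                 p_meta = wald_test(bm, sm),
                 q_stat = q, df = df, i2 = i2,
                 direction = direction_string(exp(beta)),
                 cohorts = cohorts),
            class = "meta_result")
}

#' @export
print.meta_result <- function(x, ...) {
  cat(sprintf("meta (%d cohorts): beta = %.4f (se %.4f), OR = %.3f, p = %.3g, I2 = %.1f%%, direction %s\n",
              x$k, x$beta_meta, x$se_meta, exp(x$beta_meta), x$p_meta, x$i2,
              x$direction))
  invisible(x)
}

#' Direction-of-effect string across cohorts
#'
#' One character per cohort, in the declared order: `"0"` for an OR in the
#' closed no-effect band [0.95, 1.05], `"+"` for OR > 1.05, `"-"` for
#' OR < 0.95.
#'
#' @param or Positive per-cohort odds ratios.
#' @return Character scalar, one symbol per cohort.
#' @export
direction_string <- function(or) {
  if (any(!is.finite(or) | or <= 0)) stop("odds ratios must be positive")
  paste(ifelse(or >= 0.95 & or <= 1.05, "0",
               ifelse(or > 1.05, "+", "-")), collapse = "")
}

#' Replication call for a meta-analysed candidate SNP
#'
#' A candidate replicates when its meta-analysis p-value falls below the
#' Bonferroni-corrected threshold `alpha / n_candidates` and its per-cohort
#' directions contain no opposing signs. A `"0"` (no-effect band) is treated
#' as consistent with either sign.
#'
#' @param meta A `meta_result`, or a list with `p_meta` and `direction`.
#' @param n_candidates Number of candidate SNPs tested (>= 1).
#' @param alpha Family-wise alpha (default 0.05).
#' @param directions Optional direction string overriding `meta$direction`.
#' @return List `replicated` (logical), `threshold`, `p_meta`, `direction`.
#' @export
replication_call <- function(meta, n_candidates, alpha = 0.05,
                             directions = NULL) {
  thr <- bonferroni_threshold(alpha, n_candidates)
  dir <- if (is.null(directions)) meta$direction else directions
  consistent <- !(grepl("+", dir, fixed = TRUE) && grepl("-", dir, fixed = TRUE))
  list(replicated = meta$p_meta < thr && consistent,
       threshold = thr, p_meta = meta$p_meta, direction = dir)
}

#' cis-eQTL scan around one SNP
#'
#' Ordinary least squares of probe expression on the additive allele count
#' plus covariates, for every probe whose annotated position lies within
#' `window` bp of the SNP (4 Mb window: 2 Mb on either side, by default).
#' Significance uses the Bonferroni threshold `alpha / number of probes
#' tested in the window`.
#'
#' @param snp SNP identifier (matched in `cohort$snp_info`) or column index.
#' @param cohort A [cohort()] whose subjects match the expression columns.
#' @param expression Probes x subjects matrix (column names = subject ids).
#' @param probes Annotation data frame `probe_id, chr, start`.
#' @param covariates Data frame (or NULL) of per-subject adjustment
#'   covariates, e.g. disease status, age, sex, smoking; rows matched to
#'   expression columns.
#' @param window Bp on either side of the SNP (default 2e6).
#' @param alpha Family-wise alpha for the Bonferroni call (default 0.05).
#' @return Data frame of class `eqtl_result`: `snp_id, probe_id, distance,
#'   slope, se, p, n, significant`; attribute `bonferroni` holds the
#'   threshold. Zero rows (no probes in the window) is not an error.
#' @export
cis_eqtl_scan <- function(snp, cohort, expression, probes, covariates = NULL,
                          window = 2e6, alpha = 0.05) {
  j <- if (is.character(snp)) match(snp, cohort$snp_info$snp_id) else as.integer(snp)
  if (is.na(j) || j < 1 || j > nrow(cohort$snp_info)) stop("unknown SNP: ", snp)
  si <- cohort$snp_info[j, ]
  ids <- colnames(expression)
  sub <- match(ids, cohort$subjects$id)
  if (anyNA(sub)) stop("expression columns do not match cohort subject ids")
  g <- cohort$genotypes[sub, j]
  in_win <- probes$chr == si$chromosome &
    abs(probes$start - si$position) <= window
  out <- data.frame(snp_id = character(0), probe_id = character(0),
                    distance = numeric(0), slope = numeric(0), se = numeric(0),
                    p = numeric(0), n = integer(0), significant = logical(0),
                    stringsAsFactors = FALSE)
  if (!any(in_win)) {
    attr(out, "bonferroni") <- NA_real_
    class(out) <- c("eqtl_result", "data.frame")
    return(out)
  }
  tested <- probes[in_win, , drop = FALSE]
  thr <- bonferroni_threshold(alpha, nrow(tested))
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    covariates[] <- lapply(covariates, function(v) {
      if (is.character(v)) as.numeric(factor(v)) else as.numeric(v)
    })
  }
  rows <- lapply(seq_len(nrow(tested)), function(i) {
    e <- expression[tested$probe_id[i], ]
    dat <- data.frame(expr = as.numeric(e), g = g)
    if (!is.null(covariates)) dat <- cbind(dat, covariates)
    dat <- dat[stats::complete.cases(dat), , drop = FALSE]
    fit <- stats::lm(expr ~ ., data = dat)
    co <- summary(fit)$coefficients
    data.frame(snp_id = si$snp_id, probe_id = tested$probe_id[i],
               distance = tested$start[i] - si$position,
               slope = co["g", 1], se = co["g", 2], p = co["g", 4],
               n = nrow(dat), significant = co["g", 4] < thr,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "bonferroni") <- thr
  class(out) <- c("eqtl_result", "data.frame")
  out
}

#' Write meta-analysis results to a tab-separated file
#'
#' @param metas List of `meta_result` objects.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_meta <- function(metas, path) {
  rows <- do.call(rbind, lapply(metas, function(m)
    data.frame(snp_id = m$snp_id, k = m$k, beta = m$beta_meta,
               se = m$se_meta, p = m$p_meta, q = m$q_stat, i2 = m$i2,
               direction = m$direction, stringsAsFactors = FALSE)))
  write_tsv(rows, path)
}
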