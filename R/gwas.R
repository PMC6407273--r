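#' Logistic regression by iteratively reweighted least squares
#'
#' Maximum-likelihood logistic regression written from first principles, the
#' workhorse behind every association scan in the package. Convergence is
#' declared when the relative change in log-likelihood falls below `tol`
#' (default 1e-10) or after `max_iter` iterations; the covariance matrix is
#' the inverse of the observed Fisher information at the optimum. Suspected
#' perfect separation (diverging linear predictor) is reported through
#' `converged = FALSE` with a diagnostic, never silently.
#'
#' @param y Binary outcome vector (0/1 or logical).
#' @param X Design matrix including the intercept column.
#' @param weights Optional non-negative case weights (e.g. aggregated
#'   contingency rows); default 1.
#' @param start Optional starting coefficient vector.
#' @param tol Relative log-likelihood convergence tolerance.
#' @param max_iter Maximum IRLS iterations.
#' @return List with `beta` (named coefficients), `vcov`, `se`, `converged`,
#'   `loglik`, `n_iter` and `message`.
#' @export
fit_logistic <- function(y, X, weights = NULL, start = NULL,
                         tol = 1e-10, max_iter = 50L) {
  y <- as.numeric(y)
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (length(y) != n) stop("length(y) must match nrow(X)")
  if (is.null(weights)) weights <- rep(1, n)
  if (n <= p || sum(weights > 0) <= p)
    stop("need more observations than parameters")
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(p))
  # constant non-intercept columns / rank deficiency: name the culprits
  if (p > 1) {
    sds <- apply(X[, -1, drop = FALSE], 2, stats::sd)
    if (any(sds == 0))
      stop("constant non-intercept column(s): ",
           paste(colnames(X)[-1][sds == 0], collapse = ", "))
  }
  qx <- qr(X)
  if (qx$rank < p)
    stop("singular design matrix; collinear column(s): ",
         paste(colnames(X)[qx$pivot[(qx$rank + 1):p]], collapse = ", "))

  beta <- if (is.null(start)) {
    b0 <- numeric(p)
    mu0 <- sum(weights * y) / sum(weights)
    mu0 <- min(max(mu0, 1e-6), 1 - 1e-6)
    b0[1] <- stats::qlogis(mu0)
    b0
  } else as.numeric(start)

  loglik <- function(b) {
    eta <- drop(X %*% b)
    # numerically stable log(1 + exp(eta))
    sum(weights * (y * eta - (pmax(eta, 0) + log1p(exp(-abs(eta))))))
  }
  ll <- loglik(beta)
  converged <- FALSE
  msg <- "ok"
  iter <- 0L
  repeat {
    iter <- iter + 1L
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    w <- weights * mu * (1 - mu)
    w <- pmax(w, 1e-12)
    z <- eta + (y - mu) / pmax(mu * (1 - mu), 1e-12)
    xtwx <- crossprod(X, X * w)
    xtwz <- crossprod(X, w * z)
    beta_new <- tryCatch(drop(solve(xtwx, xtwz)), error = function(e) NULL)
    if (is.null(beta_new)) {
      msg <- "information matrix numerically singular"
      break
    }
    ll_new <- loglik(beta_new)
    # step-halving keeps IRLS monotone on hard designs
    step <- 1
    while (is.finite(ll) && (!is.finite(ll_new) || ll_new < ll - 1e-12) && step > 1e-4) {
      step <- step / 2
      beta_new <- beta + step * (beta_new - beta)
      ll_new <- loglik(beta_new)
    }
    done <- is.finite(ll_new) && is.finite(ll) &&
      abs(ll_new - ll) < tol * (abs(ll) + tol)
    beta <- beta_new
    ll <- ll_new
    if (done) { converged <- TRUE; break }
    if (iter >= max_iter) { msg <- "max iterations reached"; break }
  }
  if (converged && max(abs(drop(X %*% beta))) > 25) {
    converged <- FALSE
    msg <- "suspected perfect separation (diverging linear predictor)"
  }
  eta <- drop(X %*% beta)
  mu <- stats::plogis(eta)
  w <- pmax(weights * mu * (1 - mu), 1e-12)
  vcov <- tryCatch(solve(crossprod(X, X * w)), error = function(e) {
    converged <<- FALSE
    msg <<- "information matrix numerically singular"
    matrix(NA_real_, p, p)
  })
  names(beta) <- colnames(X)
  dimnames(vcov) <- list(colnames(X), colnames(X))
  list(beta = beta, vcov = vcov, se = sqrt(diag(vcov)),
       converged = converged, loglik = ll, n_iter = iter, message = msg)
}

#' Two-sided Wald test of a single coefficient
#'
#' `(beta/se)^2` referred to the chi-square distribution with 1 degree of
#' freedom — the per-SNP inference convention of standard GWAS tooling.
#'
#' @param beta Coefficient estimate.
#' @param se Standard error (> 0).
#' @return Two-sided p-value.
#' @export
wald_test <- function(beta, se) {
  if (any(se <= 0 | !is.finite(se))) stop("se must be positive and finite")
  stats::pchisq((beta / se)^2, df = 1, lower.tail = FALSE)
}

#' Specify one association scan
#'
#' A scan is defined by the obstruction definition it tests, the smoking
#' stratum it runs in, and its covariate set. Defaults follow the convention
#' that the fixed-ratio model adjusts for sex, age and height while the LLN
#' model does not (sex, age and height already enter the LLN itself), and
#' ever-smoker models additionally adjust for pack-years and current smoking.
#'
#' @param definition `"fixed70"` or `"lln"`.
#' @param stratum `"never"` or `"ever"`.
#' @param covariates Character vector of subject columns to adjust for;
#'   `NULL` selects the definition/stratum default above.
#' @return A `scan_spec` object.
#' @export
scan_spec <- function(definition = c("fixed70", "lln"),
                      stratum = c("never", "ever"),
                      covariates = NULL) {
  definition <- match.arg(definition)
  stratum <- match.arg(stratum)
  if (is.null(covariates)) {
    covariates <- if (definition == "fixed70") c("sex", "age", "height") else character(0)
    if (stratum == "ever") covariates <- c(covariates, "pack_years", "current_smoker")
  }
  structure(list(definition = definition, stratum = stratum,
                 covariates = covariates, model = "additive"),
            class = "scan_spec")
}

covariate_matrix <- function(subjects, covariates) {
  if (length(covariates) == 0)
    return(matrix(numeric(0), nrow = nrow(subjects), ncol = 0))
  cols <- lapply(covariates, function(cv) {
    if (!cv %in% names(subjects)) stop("unknown covariate: ", cv)
    v <- subjects[[cv]]
    if (cv == "sex") as.numeric(v == "male")
    else if (is.logical(v)) as.numeric(v)
    else as.numeric(v)
  })
  out <- do.call(cbind, cols)
  colnames(out) <- covariates
  out
}

#' Run a per-SNP additive-model logistic association scan
#'
#' Fits, for every SNP, a logistic regression of case status on the additive
#' allele count (0/1/2) plus the scan's covariates, within the scan's smoking
#' stratum. Missing genotypes are removed listwise per SNP. The effect allele
#' is the minor allele in the analysed sample (allele flips negate the count).
#' The genomic inflation factor is computed from the converged SNPs' p-values.
#'
#' @param cohort A [cohort()].
#' @param labels Labels from [classify_obstruction()].
#' @param spec A [scan_spec()].
#' @return A `scan_summary`: list with `spec`, `results` (one row per SNP:
#'   `snp_id, chr, pos, effect_allele, other_allele, eaf, n, beta, se, or, p,
#'   converged`), `lambda_gc`, `n_cases`, `n_controls`.
#' @export
run_scan <- function(cohort, labels, spec) {
  stopifnot(inherits(spec, "scan_spec"))
  keep <- labels$stratum == spec$stratum & labels$valid
  if (!any(keep)) stop("stratum '", spec$stratum, "' is empty")
  subj <- cohort$subjects[keep, , drop = FALSE]
  G <- cohort$genotypes[keep, , drop = FALSE]
  y_all <- if (spec$definition == "fixed70") labels$fixed70[keep] else labels$lln_case[keep]
  y_all <- as.numeric(y_all)
  n_cases <- sum(y_all == 1)
  n_controls <- sum(y_all == 0)
  if (n_cases < 1 || n_controls < 1)
    stop("scan needs at least one case and one control (cases=", n_cases,
         ", controls=", n_controls, ")")

  C <- covariate_matrix(subj, spec$covariates)
  Xfull <- cbind(intercept = 1, C, genotype = 0)
  gcol <- ncol(Xfull)
  # covariate-only fit supplies warm starts for every SNP
  base <- fit_logistic(y_all, Xfull[, -gcol, drop = FALSE])
  start <- c(base$beta, 0)

  info <- cohort$snp_info
  m <- ncol(G)
  res <- data.frame(snp_id = info$snp_id, chr = info$chromosome,
                    pos = info$position,
                    effect_allele = info$allele1, other_allele = info$allele2,
                    eaf = NA_real_, n = NA_integer_, beta = NA_real_,
                    se = NA_real_, or = NA_real_, p = NA_real_,
                    converged = FALSE, stringsAsFactors = FALSE)
  for (j in seq_len(m)) {
    g <- G[, j]
    ok <- !is.na(g)
    n_ok <- sum(ok)
    res$n[j] <- n_ok
    if (n_ok < ncol(Xfull) + 1) next
    af <- sum(g[ok]) / (2 * n_ok)
    if (af > 0.5) {  # flip so the effect allele is the minor allele
      g <- 2 - g
      af <- 1 - af
      res$effect_allele[j] <- info$allele2[j]
      res$other_allele[j] <- info$allele1[j]
    }
    res$eaf[j] <- af
    if (af == 0) next  # monomorphic in the analysed sample
    if (all(ok)) {
      X <- Xfull; X[, gcol] <- g
      fit <- fit_logistic(y_all, X, start = start)
    } else {
      X <- Xfull[ok, , drop = FALSE]; X[, gcol] <- g[ok]
      fit <- fit_logistic(y_all[ok], X)
    }
    b <- unname(fit$beta[gcol]); s <- unname(fit$se[gcol])
    res$beta[j] <- b
    res$se[j] <- s
    res$or[j] <- exp(b)
    res$p[j] <- if (is.finite(s) && s > 0) wald_test(b, s) else NA_real_
    res$converged[j] <- fit$converged
  }
  pv <- res$p[res$converged & !is.na(res$p)]
  lambda <- if (length(pv)) genomic_lambda(pv) else NA_real_
  structure(list(spec = spec, results = res, lambda_gc = lambda,
                 n_cases = n_cases, n_controls = n_controls),
            class = "scan_summary")
}

#' @export
print.scan_summary <- function(x, ...) {
  cat(sprintf("scan: %s / %s-smokers (%d cases, %d controls), %d SNPs, lambda = %.4f\n",
              x$spec$definition, x$spec$stratum, x$n_cases, x$n_controls,
              nrow(x$results), x$lambda_gc))
  invisible(x)
}

#' SNP-by-ever-smoking interaction scan
#'
#' Pools the never and ever strata and fits, per SNP, a logistic model with
#' the allele count, an ever-smoking indicator, their product, and the union
#' covariate set; reports Wald inference on the product term.
#'
#' @param cohort A [cohort()].
#' @param labels Labels from [classify_obstruction()].
#' @param definition `"fixed70"` or `"lln"`.
#' @param snps Indices or snp_ids of the SNPs to test (default all).
#' @param covariates Covariates for the pooled model (default sex, age,
#'   height, pack-years, current smoking).
#' @return Data frame with `snp_id`, `beta_int`, `se_int`, `p_int`,
#'   `converged`, `n`.
#' @export
interaction_scan <- function(cohort, labels, definition = c("fixed70", "lln"),
                             snps = NULL,
                             covariates = c("sex", "age", "height",
                                            "pack_years", "current_smoker")) {
  definition <- match.arg(definition)
  keep <- labels$stratum %in% c("never", "ever") & labels$valid
  subj <- cohort$subjects[keep, , drop = FALSE]
  G <- cohort$genotypes[keep, , drop = FALSE]
  ever <- as.numeric(labels$stratum[keep] == "ever")
  if (length(unique(ever)) < 2)
    stop("interaction model needs both never- and ever-smokers (product column is collinear otherwise)")
  y <- as.numeric(if (definition == "fixed70") labels$fixed70[keep] else labels$lln_case[keep])
  C <- covariate_matrix(subj, covariates)
  if (is.null(snps)) snps <- seq_len(ncol(G))
  if (is.character(snps)) snps <- match(snps, cohort$snp_info$snp_id)
  if (anyNA(snps) || any(snps < 1 | snps > ncol(G))) stop("unknown SNP requested")
  out <- data.frame(snp_id = cohort$snp_info$snp_id[snps],
                    beta_int = NA_real_, se_int = NA_real_, p_int = NA_real_,
                    converged = FALSE, n = NA_integer_,
                    stringsAsFactors = FALSE)
  for (i in seq_along(snps)) {
    g <- G[, snps[i]]
    ok <- !is.na(g)
    X <- cbind(intercept = 1, genotype = g[ok], ever = ever[ok],
               gxe = g[ok] * ever[ok], C[ok, , drop = FALSE])
    fit <- fit_logistic(y[ok], X)
    out$n[i] <- sum(ok)
    out$beta_int[i] <- unname(fit$beta["gxe"])
    out$se_int[i] <- unname(fit$se["gxe"])
    out$p_int[i] <- if (is.finite(out$se_int[i]) && out$se_int[i] > 0)
      wald_test(out$beta_int[i], out$se_int[i]) else NA_real_
    out$converged[i] <- fit$converged
  }
  out
}

#' Genomic inflation factor
#'
#' Converts p-values to chi-square(1) quantiles and divides their median by
#' the null chi-square(1) median (about 0.4549). Values near 1 indicate no
#' stratification artifact.
#'
#' @param p Vector of p-values in (0, 1].
#' @return Lambda (positive scalar).
#' @export
genomic_lambda <- function(p) {
  p <- p[!is.na(p)]
  if (length(p) == 0) stop("no p-values supplied")
  if (any(p <= 0 | p > 1)) stop("p-values must lie in (0, 1]")
  chi <- stats::qchisq(p, df = 1, lower.tail = FALSE)
  stats::median(chi) / stats::qchisq(0.5, df = 1)
}

#' Write a scan's summary statistics to a tab-separated file
#'
#' @param scan A `scan_summary`.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_scan <- function(scan, path) {
  write_tsv(scan$results, path)
}
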