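#' Configuration for the synthetic cohort generator
#'
#' Defines a population-based spirometry cohort with two smoking strata
#' (never-smokers with 0 pack-years, ever-smokers with more than 5), biallelic
#' SNPs in Hardy-Weinberg proportions, and an FEV1/FVC ratio generated through
#' an LMS reference so both obstruction definitions can be applied downstream.
#'
#' @param n_subjects Number of subjects.
#' @param n_snps Number of SNPs.
#' @param maf_range Length-2 vector in (0, 0.5]; each SNP's minor allele
#'   frequency is drawn uniformly from this interval.
#' @param causal_snps List of effect descriptors, each a list with
#'   `snp_index` (1-based, `<= n_snps`), `log_odds` (per-allele log odds of
#'   obstruction) and `definitions` (subset of `c("fixed70","lln")`). Effects
#'   naming both definitions act on the latent ratio; single-definition
#'   effects act through a definition-specific discordance channel.
#' @param stratum_mix Fraction of never-smokers (default 0.51, the balance of
#'   a population cohort of roughly 5070 never- and 4855 ever-smokers).
#' @param pack_years_model For ever-smokers: `offset + Gamma(shape, scale)`
#'   pack-years; defaults give mean about 17 and SD about 9, in the range
#'   reported for population ever-smokers.
#' @param covariate_ranges List with `age` (truncation range, years),
#'   `age_mean`/`age_sd` (the age distribution is a truncated normal, matching
#'   the bell-shaped age structure of population cohorts), `height_mean`
#'   (named vector, cm, per sex), `height_sd` (cm), `sex_male_frac`,
#'   `current_smoker_frac` (among ever-smokers), `asthma_frac`, and
#'   `smoking_z_per_pack_year` (downward latent ratio z-shift per pack-year,
#'   so ever-smokers show the elevated obstruction prevalence real cohorts
#'   do).
#' @param spirometry_noise SD of the latent ratio z-score; 1 reproduces the
#'   reference population (LLN-case prevalence 5%), larger values widen the
#'   ratio distribution.
#' @param missing_genotype_rate Independent genotype missingness in [0, 1).
#' @param seed Integer seed; fully determines every draw.
#' @return A validated `sim_config` object.
#' @export
sim_config <- function(n_subjects, n_snps,
                       maf_range = c(0.05, 0.5),
                       causal_snps = list(),
                       stratum_mix = 0.51,
                       pack_years_model = list(offset = 5, shape = 1.8, scale = 6.7),
                       covariate_ranges = list(
                         age = c(20, 85),
                         age_mean = 46, age_sd = 13,
                         height_mean = c(male = 179, female = 167),
                         height_sd = 7,
                         sex_male_frac = 0.43,
                         current_smoker_frac = 0.45,
                         asthma_frac = 0.08,
                         smoking_z_per_pack_year = 0.035),
                       spirometry_noise = 1,
                       missing_genotype_rate = 0,
                       seed = 1L) {
  stopifnot(n_subjects >= 1, n_snps >= 1)
  if (length(maf_range) != 2 || maf_range[1] > maf_range[2] ||
      maf_range[1] <= 0 || maf_range[2] > 0.5)
    stop("maf_range must lie within (0, 0.5]")
  for (cs in causal_snps) {
    if (!all(c("snp_index", "log_odds", "definitions") %in% names(cs)))
      stop("each causal SNP needs snp_index, log_odds, definitions")
    if (cs$snp_index < 1 || cs$snp_index > n_snps)
      stop("causal snp_index out of range")
    if (!all(cs$definitions %in% c("fixed70", "lln")) || length(cs$definitions) == 0)
      stop("causal definitions must be a non-empty subset of fixed70/lln")
  }
  stopifnot(stratum_mix >= 0, stratum_mix <= 1,
            spirometry_noise > 0,
            missing_genotype_rate >= 0, missing_genotype_rate < 1)
  structure(list(n_subjects = as.integer(n_subjects),
                 n_snps = as.integer(n_snps),
                 maf_range = maf_range, causal_snps = causal_snps,
                 stratum_mix = stratum_mix,
                 pack_years_model = pack_years_model,
                 covariate_ranges = covariate_ranges,
                 spirometry_noise = spirometry_noise,
                 missing_genotype_rate = missing_genotype_rate,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Construct a cohort object
#'
#' The unit every analysis stage consumes: a subject table, an additive
#' genotype matrix (rows = subjects, in order; entries 0/1/2 count copies of
#' `allele1`, NA = missing), and a SNP annotation table.
#'
#' @param subjects Data frame with columns `id, sex, age, height,
#'   smoking_status, pack_years, current_smoker, fev1, fvc` (optionally
#'   `asthma`).
#' @param genotypes Integer matrix, subjects x SNPs.
#' @param snp_info Data frame with `snp_id, chromosome, position, allele1,
#'   allele2`.
#' @return A `cohort` object.
#' @export
cohort <- function(subjects, genotypes, snp_info) {
  obj <- structure(list(subjects = subjects, genotypes = genotypes,
                        snp_info = snp_info), class = "cohort")
  validate_cohort(obj)
}

#' Validate a cohort's structural invariants
#'
#' Checks subject/genotype row correspondence, spirometry positivity and
#' ordering (`0 < fev1 <= fvc`), and the never-smoker convention
#' (0 pack-years, not a current smoker).
#'
#' @param x A `cohort`.
#' @return The cohort, invisibly usable in pipelines.
#' @export
validate_cohort <- function(x) {
  s <- x$subjects
  need <- c("id", "sex", "age", "height", "smoking_status", "pack_years",
            "current_smoker", "fev1", "fvc")
  if (!all(need %in% names(s)))
    stop("subjects table missing column(s): ",
         paste(setdiff(need, names(s)), collapse = ", "))
  if (nrow(s) != nrow(x$genotypes))
    stop("subjects and genotype rows must correspond one-to-one")
  if (ncol(x$genotypes) != nrow(x$snp_info))
    stop("genotype columns and snp_info rows must correspond one-to-one")
  sp <- !is.na(s$fev1) & !is.na(s$fvc)
  if (any(s$fev1[sp] <= 0 | s$fvc[sp] <= 0))
    stop("fev1 and fvc must be strictly positive")
  if (any(s$fev1[sp] > s$fvc[sp]))
    stop("fev1 must not exceed fvc")
  nev <- s$smoking_status == "never"
  if (any(s$pack_years[nev] != 0) || any(s$current_smoker[nev]))
    stop("never-smokers must have 0 pack-years and not smoke currently")
  g <- x$genotypes
  if (!all(is.na(g) | (g %in% 0:2)))
    stop("genotypes must be additive allele counts 0/1/2 or NA")
  x
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("cohort: %d subjects (%d never / %d ever / %d excluded), %d SNPs\n",
              nrow(x$subjects),
              sum(x$subjects$smoking_status == "never"),
              sum(x$subjects$smoking_status == "ever"),
              sum(x$subjects$smoking_status == "excluded"),
              ncol(x$genotypes)))
  invisible(x)
}

#' Simulate genotypes in Hardy-Weinberg proportions
#'
#' Each SNP's minor allele frequency is drawn uniformly from
#' `config$maf_range`; genotypes are independent Binomial(2, maf) counts of
#' `allele1`, with missingness applied independently at
#' `config$missing_genotype_rate`.
#'
#' @param config A [sim_config()].
#' @return List with `genotypes` (matrix) and `snp_info` (data frame).
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  seeds <- derive_seeds(config$seed, 6)
  set.seed(seeds[1])
  n <- config$n_subjects; m <- config$n_snps
  maf <- stats::runif(m, config$maf_range[1], config$maf_range[2])
  G <- matrix(stats::rbinom(n * m, 2L, rep(maf, each = n)), nrow = n, ncol = m)
  if (config$missing_genotype_rate > 0) {
    set.seed(seeds[4])
    G[stats::runif(n * m) < config$missing_genotype_rate] <- NA_integer_
  }
  chr <- rep_len(1:22, m)
  pos <- integer(m)
  for (c22 in 1:22) {
    i <- which(chr == c22)
    pos[i] <- seq_along(i) * 50000L
  }
  snp_info <- data.frame(snp_id = sprintf("snp%05d", seq_len(m)),
                         chromosome = chr, position = pos,
                         allele1 = "A", allele2 = "G", maf_true = maf,
                         stringsAsFactors = FALSE)
  colnames(G) <- snp_info$snp_id
  list(genotypes = G, snp_info = snp_info)
}

#' Calibrate a latent-ratio shift to a target marginal log-odds
#'
#' Planted effects are specified on the log-odds scale of obstruction. The
#' generator shifts the latent ratio z-score, so the per-allele latent shift
#' `delta` is chosen numerically such that an additive logistic model fitted
#' to the expected genotype-group prevalences (HWE weights at the SNP's MAF)
#' recovers exactly the requested log-odds per allele.
#'
#' @param log_odds Target per-allele log-odds.
#' @param maf Minor allele frequency of the SNP.
#' @param sd Latent z-score SD (`spirometry_noise`).
#' @param base_q Reference percentile defining case status (default 0.05, the
#'   LLN percentile); the case threshold on the latent scale is
#'   `qnorm(base_q)`, so the genotype-0 prevalence is `pnorm(qnorm(base_q)/sd)`.
#' @return Latent shift per allele (same sign as `log_odds`).
#' @export
calibrate_liability_shift <- function(log_odds, maf, sd = 1, base_q = 0.05) {
  if (log_odds == 0) return(0)
  zstar <- stats::qnorm(base_q)
  wg <- c((1 - maf)^2, 2 * maf * (1 - maf), maf^2)
  induced_slope <- function(delta) {
    pg <- stats::pnorm((zstar + delta * 0:2) / sd)
    pg <- pmin(pmax(pg, 1e-12), 1 - 1e-12)
    # six weighted rows: (g, case) with weight w_g * P_g or w_g * (1 - P_g)
    X <- cbind(intercept = 1, g = rep(0:2, each = 2))
    y <- rep(c(1, 0), times = 3)
    w <- as.vector(rbind(wg * pg, wg * (1 - pg)))
    fit <- fit_logistic(y, X, weights = w)
    unname(fit$beta["g"])
  }
  f <- function(d) induced_slope(d) - log_odds
  hi <- 5 * abs(log_odds) * sd + 0.5
  root <- stats::uniroot(f, interval = sort(c(0, sign(log_odds) * hi)),
                         extendInt = "yes", tol = 1e-8)
  root$root
}

#' Simulate a full spirometry cohort
#'
#' Covariates are drawn within the configured ranges; each subject's latent
#' ratio z-score is `Normal(0, spirometry_noise^2)` minus the summed
#' allele-count x calibrated latent shifts of causal SNPs targeting both
#' definitions, then mapped through the LMS reference quantile function to an
#' FEV1/FVC value. FVC is drawn from a plausible height/age/sex model and
#' FEV1 set consistent with the ratio. Strata follow `stratum_mix`, with
#' ever-smoker pack-years strictly above 5. Definition-specific effects are
#' applied afterwards by moving eligible subjects' ratios into the
#' discordance window between 70% and their LLN.
#'
#' @param config A [sim_config()].
#' @param reference An [lms_reference()] covering the simulated ranges.
#' @return A [cohort()].
#' @export
simulate_cohort <- function(config, reference) {
  stopifnot(inherits(config, "sim_config"), inherits(reference, "lms_reference"))
  cr <- config$covariate_ranges
  if (cr$age[1] < reference$age_range[1] || cr$age[2] > reference$age_range[2])
    stop("simulated age range outside the reference domain")
  gen <- simulate_genotypes(config)
  seeds <- derive_seeds(config$seed, 6)
  n <- config$n_subjects

  set.seed(seeds[2])
  sex <- ifelse(stats::runif(n) < cr$sex_male_frac, "male", "female")
  # truncated-normal age via inverse CDF (bell-shaped, like population cohorts)
  plo <- stats::pnorm(cr$age[1], cr$age_mean, cr$age_sd)
  phi <- stats::pnorm(cr$age[2], cr$age_mean, cr$age_sd)
  age <- stats::qnorm(stats::runif(n, plo, phi), cr$age_mean, cr$age_sd)
  height <- stats::rnorm(n, cr$height_mean[sex], cr$height_sd)
  height <- pmin(pmax(height, reference$height_range[1]), reference$height_range[2])
  never <- stats::runif(n) < config$stratum_mix
  pym <- config$pack_years_model
  pack_years <- ifelse(never, 0,
                       pym$offset + stats::rgamma(n, shape = pym$shape,
                                                  scale = pym$scale))
  current_smoker <- !never & stats::runif(n) < cr$current_smoker_frac
  asthma <- stats::runif(n) < cr$asthma_frac

  set.seed(seeds[3])
  z <- stats::rnorm(n, 0, config$spirometry_noise)
  smk <- if (is.null(cr$smoking_z_per_pack_year)) 0 else cr$smoking_z_per_pack_year
  z <- z - smk * pack_years
  latent <- Filter(function(cs) setequal(cs$definitions, c("fixed70", "lln")),
                   config$causal_snps)
  for (cs in latent) {
    g <- gen$genotypes[, cs$snp_index]
    maf <- gen$snp_info$maf_true[cs$snp_index]
    g[is.na(g)] <- 2 * maf  # mean imputation for the latent shift only
    delta <- calibrate_liability_shift(cs$log_odds, maf,
                                       sd = config$spirometry_noise)
    z <- z - g * delta
  }
  ratio <- lms_quantile(reference, sex, age, height, z)
  ratio <- pmin(pmax(ratio, 25), 99.5)

  # definition-specific channel: move eligible subjects into the window where
  # only the targeted definition calls obstruction
  flips <- Filter(function(cs) length(cs$definitions) == 1, config$causal_snps)
  if (length(flips) > 0) {
    set.seed(seeds[5])
    lln <- lms_lln(reference, sex, age, height)
    for (cs in flips) {
      g <- gen$genotypes[, cs$snp_index]
      g[is.na(g)] <- 0
      p0 <- 0.02
      pflip <- pmin(p0 * exp(cs$log_odds * g), 1)
      if (cs$definitions == "lln") {
        eligible <- lln > 70 & ratio >= lln          # can become LLN-only case
        target <- 70 + 0.5 * (lln - 70)
      } else {
        eligible <- lln < 70 & ratio >= 70           # can become fixed-only case
        target <- lln + 0.5 * (70 - lln)
      }
      do_flip <- eligible & stats::runif(n) < pflip
      ratio[do_flip] <- target[do_flip]
    }
  }

  set.seed(seeds[6])
  h_m <- height / 100
  fvc_pred <- ifelse(sex == "male",
                     5.76 * h_m - 0.026 * age - 4.34,
                     4.43 * h_m - 0.026 * age - 2.89)
  fvc <- pmax(fvc_pred + stats::rnorm(n, 0, 0.45), 1)
  fev1 <- ratio / 100 * fvc

  subjects <- data.frame(id = sprintf("subj%06d", seq_len(n)),
                         sex = sex, age = age, height = height,
                         smoking_status = ifelse(never, "never", "ever"),
                         pack_years = pack_years,
                         current_smoker = current_smoker,
                         fev1 = fev1, fvc = fvc, asthma = asthma,
                         stringsAsFactors = FALSE)
  rownames(gen$genotypes) <- subjects$id
  cohort(subjects, gen$genotypes, gen$snp_info)
}

#' Simulate a lung expression matrix with planted cis-eQTL effects
#'
#' Expression of each probe is `intercept + slope * allele count + covariate
#' effects + Normal(0, noise_sd^2)` noise, with small fixed age and sex
#' effects so eQTL models have something to adjust for. Probes named in
#' `eqtl_effects` are placed near their SNP (same chromosome, within 100 kb)
#' unless an annotation is supplied; optional null probes are scattered over
#' the genome.
#'
#' @param cohort A [cohort()].
#' @param eqtl_effects List of lists with `snp_index`, `probe_id`, `slope`.
#' @param noise_sd Residual SD of expression (> 0).
#' @param seed Integer seed.
#' @param probe_annotation Optional data frame `probe_id, chr, start`
#'   overriding the default placement.
#' @param n_null_probes Number of additional zero-effect probes.
#' @return List with `expression` (probes x subjects matrix) and `probes`
#'   (annotation data frame `probe_id, chr, start`).
#' @export
simulate_expression <- function(cohort, eqtl_effects = list(), noise_sd = 1,
                                seed = 1L, probe_annotation = NULL,
                                n_null_probes = 0) {
  stopifnot(noise_sd > 0)
  for (ef in eqtl_effects) {
    if (ef$snp_index < 1 || ef$snp_index > ncol(cohort$genotypes))
      stop("eqtl snp_index out of range")
  }
  set.seed(as.integer(seed))
  s <- cohort$subjects
  n <- nrow(s)
  if (is.null(probe_annotation)) {
    probe_annotation <- do.call(rbind, lapply(eqtl_effects, function(ef) {
      si <- cohort$snp_info[ef$snp_index, ]
      data.frame(probe_id = ef$probe_id, chr = si$chromosome,
                 start = si$position + sample(-100000:100000, 1),
                 stringsAsFactors = FALSE)
    }))
    if (n_null_probes > 0) {
      nulls <- data.frame(probe_id = sprintf("null_probe%04d", seq_len(n_null_probes)),
                          chr = sample(1:22, n_null_probes, replace = TRUE),
                          start = sample.int(5e7, n_null_probes),
                          stringsAsFactors = FALSE)
      probe_annotation <- rbind(probe_annotation, nulls)
    }
    if (is.null(probe_annotation))
      stop("no probes to simulate: supply eqtl_effects, n_null_probes or an annotation")
    probe_annotation$start <- pmax(probe_annotation$start, 1)
  }
  slopes <- stats::setNames(rep(0, nrow(probe_annotation)), probe_annotation$probe_id)
  snp_of <- stats::setNames(rep(NA_integer_, nrow(probe_annotation)),
                            probe_annotation$probe_id)
  for (ef in eqtl_effects) {
    slopes[ef$probe_id] <- ef$slope
    snp_of[ef$probe_id] <- ef$snp_index
  }
  age_eff <- 0.01; sex_eff <- 0.2
  expr <- matrix(NA_real_, nrow = nrow(probe_annotation), ncol = n,
                 dimnames = list(probe_annotation$probe_id, s$id))
  for (i in seq_len(nrow(probe_annotation))) {
    pid <- probe_annotation$probe_id[i]
    g <- if (is.na(snp_of[pid])) 0 else {
      gg <- cohort$genotypes[, snp_of[pid]]
      gg[is.na(gg)] <- 0
      gg
    }
    expr[i, ] <- 8 + slopes[pid] * g + age_eff * (s$age - 50) +
      sex_eff * (s$sex == "male") + stats::rnorm(n, 0, noise_sd)
  }
  list(expression = expr, probes = probe_annotation)
}
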