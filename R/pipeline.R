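#' Configuration for an end-to-end comparison run
#'
#' Bundles either a simulation configuration or input file paths with the QC
#' thresholds, the scan plan (all four definition-by-stratum scans), the
#' overlap threshold ladder, and optional simulation-study settings.
#'
#' @param sim A [sim_config()] (simulated input), or NULL when reading files.
#' @param plink_prefix,covariate_path,lms_table_path Input paths used when
#'   `sim` is NULL: PLINK prefix (binary triple preferred, text pair
#'   otherwise), tab-separated subject table, and LMS coefficient table
#'   (NULL = bundled synthetic reference).
#' @param qc A [qc_thresholds()].
#' @param thresholds Overlap p-value ladder (strictly decreasing after
#'   sorting); the Bonferroni threshold for the post-QC SNP count is appended
#'   at run time.
#' @param percentile LLN percentile (default 0.05).
#' @param expansion_k Integer vector of cohort-expansion factors to run
#'   (empty = skip).
#' @param null_replicates Random case-allocation replicates (0 = skip).
#' @param seed Master seed for every stochastic stage.
#' @return A `pipeline_config`.
#' @export
pipeline_config <- function(sim = NULL, plink_prefix = NULL,
                            covariate_path = NULL, lms_table_path = NULL,
                            qc = qc_thresholds(),
                            thresholds = c(0.05, 0.01, 1e-3, 1e-4, 1e-5, 1e-6),
                            percentile = 0.05,
                            expansion_k = integer(0),
                            null_replicates = 0,
                            seed = 1L) {
  if (is.null(sim) && is.null(plink_prefix))
    stop("supply either a simulation config or input paths")
  if (length(thresholds) == 0) stop("thresholds must be non-empty")
  st <- sort(thresholds, decreasing = TRUE)
  if (any(diff(st) == 0)) stop("thresholds must be distinct")
  structure(list(sim = sim, plink_prefix = plink_prefix,
                 covariate_path = covariate_path,
                 lms_table_path = lms_table_path, qc = qc,
                 thresholds = st, percentile = percentile,
                 expansion_k = expansion_k,
                 null_replicates = null_replicates,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Bundled demonstration configuration
#'
#' A self-contained simulated run — 2,000 subjects, 5,000 SNPs, default QC
#' and threshold ladder — sized so the full four-scan pipeline completes in a
#' few minutes on one CPU. Used by the analysis scripts and the smoke tests.
#'
#' @param seed Master seed.
#' @return A [pipeline_config()].
#' @export
demo_pipeline_config <- function(seed = 1L) {
  pipeline_config(sim = sim_config(n_subjects = 2000, n_snps = 5000,
                                   seed = seed),
                  seed = seed)
}

#' Read a pipeline configuration from YAML or JSON
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file whose keys mirror the
#'   arguments of [pipeline_config()] (with `sim` holding [sim_config()]
#'   arguments).
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(raw$sim)) raw$sim <- do.call(sim_config, raw$sim)
  if (!is.null(raw$qc)) raw$qc <- do.call(qc_thresholds, raw$qc)
  do.call(pipeline_config, raw)
}

load_pipeline_inputs <- function(config) {
  reference <- if (is.null(config$lms_table_path)) synthetic_lms_reference()
  else read_lms_table(config$lms_table_path)
  if (!is.null(config$sim)) {
    return(list(cohort = simulate_cohort(config$sim, reference),
                reference = reference))
  }
  gen <- if (file.exists(paste0(config$plink_prefix, ".bed")))
    read_plink_bed(config$plink_prefix)
  else read_plink_text(config$plink_prefix)
  cov <- read_tsv(config$covariate_path)
  idx <- match(rownames(gen$genotypes), cov$id)
  if (anyNA(idx)) stop("covariate table does not cover all genotyped subjects")
  list(cohort = cohort(cov[idx, , drop = FALSE], gen$genotypes, gen$snp_info),
       reference = reference)
}

#' Run the full two-definition comparison pipeline
#'
#' Stages: build or load the cohort; classify obstruction under both
#' definitions; SNP QC; the four definition-by-stratum logistic scans;
#' within-stratum and cross-stratum overlap and agreement reports; optional
#' cohort-expansion scans and the random case-allocation null-overlap
#' experiment. All outputs are written as tab-separated files (plus JSON
#' summaries) under `out_dir`, together with a provenance manifest; the run
#' is deterministic given the config seed.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the in-memory stage results.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- Sys.time()
  log_stage <- function(...) message(sprintf("[%s] ", format(Sys.time(), "%H:%M:%S")), ...)

  log_stage("loading inputs")
  inp <- load_pipeline_inputs(config)
  coh <- inp$cohort

  log_stage("classifying obstruction")
  labels <- classify_obstruction(coh, inp$reference, percentile = config$percentile)
  write_labels(labels, file.path(out_dir, "labels.tsv"))
  conc <- lapply(c(never = "never", ever = "ever"), function(st) {
    cc <- tryCatch(cross_classification(labels, st), error = function(e) NULL)
    if (is.null(cc)) NULL else list(counts = unclass(cc)[1:6],
                                    stats = unclass(concordance_stats(cc))[1:4])
  })
  jsonlite::write_json(conc, file.path(out_dir, "concordance.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  log_stage("SNP quality control")
  qc <- apply_qc(coh, config$qc)
  write_qc_report(qc, file.path(out_dir, "qc_report.tsv"))
  coh <- qc$cohort

  thresholds <- c(config$thresholds,
                  bonferroni_threshold(0.05, ncol(coh$genotypes)))

  log_stage("running the four association scans")
  scans <- list()
  for (def in c("fixed70", "lln")) for (st in c("never", "ever")) {
    key <- paste(def, st, sep = ".")
    scans[[key]] <- run_scan(coh, labels, scan_spec(def, st))
    write_scan(scans[[key]], file.path(out_dir, paste0("scan_", def, "_", st, ".tsv")))
  }

  log_stage("overlap and agreement reports")
  reports <- cross_stratum_overlap(scans, thresholds)
  ovl_rows <- do.call(rbind, lapply(names(reports), function(nm) {
    cbind(pair = nm, as.data.frame(reports[[nm]]$overlap))
  }))
  write_tsv(ovl_rows, file.path(out_dir, "overlap.tsv"))
  agr_rows <- do.call(rbind, lapply(names(reports), function(nm) {
    a <- reports[[nm]]$agreement
    data.frame(pair = nm, r_pvalue = a$r_pvalue, r_or = a$r_or,
               n_snps = a$n_snps)
  }))
  write_tsv(agr_rows, file.path(out_dir, "agreement.tsv"))

  expansion <- NULL
  if (length(config$expansion_k) > 0) {
    log_stage("cohort-expansion scans")
    expansion <- lapply(config$expansion_k, function(k) {
      ex <- expand_cohort(coh, labels, k)
      s70 <- run_scan(ex$cohort, ex$labels, scan_spec("fixed70", "never"))
      slln <- run_scan(ex$cohort, ex$labels, scan_spec("lln", "never"))
      ov <- threshold_overlap(s70, slln, thresholds)
      cbind(k = k, as.data.frame(ov))
    })
    write_tsv(do.call(rbind, expansion), file.path(out_dir, "expansion_overlap.tsv"))
  }

  null_dist <- NULL
  if (config$null_replicates > 0) {
    log_stage("null-overlap experiment (random case allocation)")
    null_dist <- null_overlap_experiment(coh, labels, "never",
                                         replicates = config$null_replicates,
                                         thresholds = thresholds,
                                         seed = config$seed)
    rows <- do.call(rbind, lapply(null_dist, function(d)
      data.frame(threshold = d$threshold, replicate = seq_len(d$replicates),
                 overlap_pct = d$overlap_pcts)))
    write_tsv(rows, file.path(out_dir, "null_overlap.tsv"))
  }

  log_stage("writing manifest")
  cfg_json <- jsonlite::serializeJSON(config)
  cfg_path <- file.path(out_dir, "config.json")
  writeLines(cfg_json, cfg_path)
  manifest <- list(
    package = "spirogwas",
    package_version = as.character(utils::packageVersion("spirogwas")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$seed,
    config_hash = unname(tools::md5sum(cfg_path)),
    n_subjects = nrow(coh$subjects),
    n_snps_input = unname(qc$summary["n_input"]),
    n_snps_pass = unname(qc$summary["n_pass"]),
    thresholds = thresholds,
    scans = lapply(scans, function(s)
      list(definition = s$spec$definition, stratum = s$spec$stratum,
           n_cases = s$n_cases, n_controls = s$n_controls,
           lambda = s$lambda_gc)),
    elapsed_sec = as.numeric(difftime(Sys.time(), t0, units = "secs")))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(cohort = coh, labels = labels, qc = qc, scans = scans,
                 reports = reports, expansion = expansion,
                 null_overlap = null_dist, manifest = manifest))
}
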