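#' Write a cohort's genotypes in PLINK text format (.ped/.map)
#'
#' One line per subject in the .ped file (`FID IID PAT MAT SEX PHENO` then two
#' alleles per SNP; missing genotypes written `0 0`), and one line per SNP in
#' the .map file (`chr snp_id 0 pos`). The genotype value counts copies of
#' `snp_info$allele1`.
#'
#' @param cohort A [cohort()].
#' @param prefix Output path prefix (writes `<prefix>.ped`, `<prefix>.map`).
#' @param phenotype Optional numeric phenotype column (default -9, missing).
#' @return Invisibly, the prefix.
#' @export
write_plink_text <- function(cohort, prefix, phenotype = NULL) {
  s <- cohort$subjects
  G <- cohort$genotypes
  info <- cohort$snp_info
  n <- nrow(s); m <- ncol(G)
  if (is.null(phenotype)) phenotype <- rep(-9, n)
  sexcode <- ifelse(s$sex == "male", 1L, 2L)
  ped <- file(paste0(prefix, ".ped"), "w")
  on.exit(close(ped))
  a1 <- info$allele1; a2 <- info$allele2
  for (i in seq_len(n)) {
    g <- G[i, ]
    al1 <- ifelse(is.na(g), "0", ifelse(g >= 1, a1, a2))
    al2 <- ifelse(is.na(g), "0", ifelse(g == 2, a1, a2))
    cat(s$id[i], s$id[i], 0, 0, sexcode[i], phenotype[i],
        rbind(al1, al2), "\n", file = ped, sep = " ")
  }
  map <- data.frame(info$chromosome, info$snp_id, 0L, info$position)
  utils::write.table(map, paste0(prefix, ".map"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(prefix)
}

#' Read PLINK text genotypes (.ped/.map)
#'
#' Genotypes are returned as additive counts of the effect allele per SNP:
#' the supplied `a1` alleles if given, otherwise the minor allele in the file
#' (ties broken alphabetically).
#'
#' @param prefix Path prefix of the `.ped`/`.map` pair.
#' @param a1 Optional character vector (one per SNP) pinning the counted
#'   allele.
#' @return List with `genotypes`, `snp_info` (`snp_id, chromosome, position,
#'   allele1, allele2`), `subjects` (`id, sex`).
#' @export
read_plink_text <- function(prefix, a1 = NULL) {
  map_path <- paste0(prefix, ".map")
  ped_path <- paste0(prefix, ".ped")
  for (p in c(map_path, ped_path))
    if (!file.exists(p)) stop("missing PLINK file: ", p)
  map <- utils::read.table(map_path, header = FALSE,
                           col.names = c("chromosome", "snp_id", "cm", "position"),
                           stringsAsFactors = FALSE)
  m <- nrow(map)
  lines <- readLines(ped_path)
  fields <- strsplit(trimws(lines), "[ \t]+")
  n <- length(fields)
  if (any(lengths(fields) != 6 + 2 * m))
    stop("truncated or malformed .ped line (expected ", 6 + 2 * m, " fields): ",
         ped_path)
  ids <- vapply(fields, `[[`, character(1), 2)
  sexcode <- vapply(fields, `[[`, character(1), 5)
  A <- matrix(vapply(fields, function(f) f[-(1:6)], character(2 * m)),
              nrow = 2 * m, ncol = n)
  al1 <- A[seq(1, 2 * m, by = 2), , drop = FALSE]
  al2 <- A[seq(2, 2 * m, by = 2), , drop = FALSE]
  G <- matrix(NA_integer_, nrow = n, ncol = m)
  eff <- character(m); oth <- character(m)
  for (j in seq_len(m)) {
    obs <- c(al1[j, ], al2[j, ])
    obs <- obs[obs != "0"]
    alleles <- sort(unique(obs))
    if (length(alleles) > 2) stop("more than two alleles for SNP ", map$snp_id[j])
    if (length(alleles) == 0) alleles <- c("0", "0")
    if (!is.null(a1)) {
      eff[j] <- a1[j]
      oth[j] <- setdiff(alleles, a1[j])[1]
      if (is.na(oth[j])) oth[j] <- eff[j]
    } else if (length(alleles) == 1) {
      eff[j] <- alleles[1]; oth[j] <- alleles[1]
    } else {
      counts <- table(factor(obs, levels = alleles))
      eff[j] <- alleles[which.min(counts)]  # minor; ties -> alphabetical first
      oth[j] <- setdiff(alleles, eff[j])
    }
    miss <- al1[j, ] == "0" | al2[j, ] == "0"
    cnt <- (al1[j, ] == eff[j]) + (al2[j, ] == eff[j])
    cnt[miss] <- NA_integer_
    G[, j] <- cnt
  }
  colnames(G) <- map$snp_id
  rownames(G) <- ids
  list(genotypes = G,
       snp_info = data.frame(snp_id = map$snp_id, chromosome = map$chromosome,
                             position = map$position, allele1 = eff,
                             allele2 = oth, stringsAsFactors = FALSE),
       subjects = data.frame(id = ids,
                             sex = ifelse(sexcode == "1", "male", "female"),
                             stringsAsFactors = FALSE))
}

PLINK_BED_MAGIC <- as.raw(c(0x6c, 0x1b))
PLINK_BED_SNP_MAJOR <- as.raw(0x01)

#' Write a cohort's genotypes in PLINK binary format (.bed/.bim/.fam)
#'
#' SNP-major .bed with the standard magic bytes; two bits per genotype
#' (00 = homozygous A1, 01 = missing, 10 = heterozygous, 11 = homozygous A2),
#' four genotypes per byte, least-significant bits first. A1 is
#' `snp_info$allele1`, the counted allele.
#'
#' @inheritParams write_plink_text
#' @return Invisibly, the prefix.
#' @export
write_plink_bed <- function(cohort, prefix, phenotype = NULL) {
  s <- cohort$subjects
  G <- cohort$genotypes
  info <- cohort$snp_info
  n <- nrow(s); m <- ncol(G)
  if (is.null(phenotype)) phenotype <- rep(-9, n)
  # g (copies of A1): 2 -> 00, NA -> 01, 1 -> 10, 0 -> 11
  code <- matrix(3L, n, m)
  code[G == 2] <- 0L
  code[G == 1] <- 2L
  code[is.na(G)] <- 1L
  bytes_per_snp <- ceiling(n / 4)
  pad <- bytes_per_snp * 4 - n
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(c(PLINK_BED_MAGIC, PLINK_BED_SNP_MAJOR), con)
  mult <- 4L^(0:3)
  for (j in seq_len(m)) {
    v <- c(code[, j], rep(0L, pad))
    dim(v) <- c(4, bytes_per_snp)
    writeBin(as.raw(colSums(v * mult)), con)
  }
  bim <- data.frame(info$chromosome, info$snp_id, 0L, info$position,
                    info$allele1, info$allele2)
  utils::write.table(bim, paste0(prefix, ".bim"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  fam <- data.frame(s$id, s$id, 0L, 0L, ifelse(s$sex == "male", 1L, 2L),
                    phenotype)
  utils::write.table(fam, paste0(prefix, ".fam"), sep = " ", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(prefix)
}

#' Read PLINK binary genotypes (.bed/.bim/.fam)
#'
#' Validates the magic bytes and SNP-major mode, checks the file length
#' against the .bim/.fam dimensions, and returns additive counts of the .bim
#' A1 allele (NA for missing).
#'
#' @param prefix Path prefix of the `.bed`/`.bim`/`.fam` triple.
#' @return List with `genotypes`, `snp_info`, `subjects`.
#' @export
read_plink_bed <- function(prefix) {
  paths <- paste0(prefix, c(".bed", ".bim", ".fam"))
  for (p in paths) if (!file.exists(p)) stop("missing PLINK file: ", p)
  bim <- utils::read.table(paths[2], header = FALSE,
                           col.names = c("chromosome", "snp_id", "cm",
                                         "position", "allele1", "allele2"),
                           stringsAsFactors = FALSE)
  fam <- utils::read.table(paths[3], header = FALSE, stringsAsFactors = FALSE)
  n <- nrow(fam); m <- nrow(bim)
  bytes_per_snp <- ceiling(n / 4)
  raw <- readBin(paths[1], "raw", n = file.size(paths[1]))
  if (length(raw) < 3 || !identical(raw[1:2], PLINK_BED_MAGIC))
    stop("not a PLINK .bed file (bad magic bytes): ", paths[1])
  if (raw[3] != PLINK_BED_SNP_MAJOR)
    stop("only SNP-major .bed files are supported: ", paths[1])
  body <- raw[-(1:3)]
  if (length(body) != bytes_per_snp * m)
    stop("truncated .bed file (expected ", bytes_per_snp * m, " body bytes, found ",
         length(body), "): ", paths[1])
  ints <- as.integer(body)
  dim(ints) <- c(bytes_per_snp, m)
  G <- matrix(NA_integer_, n, m)
  lookup <- c(2L, NA_integer_, 1L, 0L)  # codes 00,01,10,11 -> A1 count
  for (j in seq_len(m)) {
    b <- ints[, j]
    codes <- c(b %% 4, (b %/% 4) %% 4, (b %/% 16) %% 4, (b %/% 64) %% 4)
    dim(codes) <- c(bytes_per_snp, 4)
    codes <- as.vector(t(codes))[seq_len(n)]
    G[, j] <- lookup[codes + 1L]
  }
  colnames(G) <- bim$snp_id
  rownames(G) <- as.character(fam[[2]])
  list(genotypes = G,
       snp_info = bim[, c("snp_id", "chromosome", "position", "allele1", "allele2")],
       subjects = data.frame(id = as.character(fam[[2]]),
                             sex = ifelse(fam[[5]] == 1, "male", "female"),
                             stringsAsFactors = FALSE))
}
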