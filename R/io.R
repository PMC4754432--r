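#' Read a substudy manifest
#'
#' Tab-separated file with a header and columns `study_id` plus either
#' `n_cases` and `n_controls` (case-control design) or `n_quant`
#' (quantitative trait); the effective sample size is derived per study
#' via [effective_n()].
#'
#' @param path Manifest path.
#' @return Data frame with `study_id` and `n_eff` (plus the input
#'   counts).
#' @export
read_studies <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!"study_id" %in% names(df))
    stop("manifest must have a 'study_id' column")
  has_cc <- all(c("n_cases", "n_controls") %in% names(df))
  cc <- if (has_cc) !is.na(df$n_cases) & !is.na(df$n_controls) else
    rep(FALSE, nrow(df))
  df$n_eff <- NA_real_
  if (any(cc)) df$n_eff[cc] <- effective_n(df$n_cases[cc],
                                           df$n_controls[cc])
  if ("n_quant" %in% names(df)) {
    q <- !cc & !is.na(df$n_quant)
    df$n_eff[q] <- effective_n(n_quant = df$n_quant[q])
  }
  if (anyNA(df$n_eff))
    stop("every study needs n_cases+n_controls or n_quant")
  df
}

.SUMSTAT_COLS <- c("SNP", "A1", "A2", "FREQ")

# Read one substudy file; returns data frame SNP, A1, A2, FREQ, Z.
.read_one_sumstats <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(.SUMSTAT_COLS, names(df))
  has_z <- "Z" %in% names(df)
  has_beta <- all(c("BETA", "SE") %in% names(df))
  if (length(missing_cols) || !(has_z || has_beta))
    stop(sprintf(
      "%s: missing mandatory column(s): %s", path,
      paste(c(missing_cols, if (!has_z && !has_beta) "Z or BETA+SE"),
            collapse = ", ")))
  if (!has_z) {
    bad_se <- !is.na(df$SE) & df$SE <= 0
    if (any(bad_se)) {
      message(sprintf("%s: dropping %d row(s) with SE <= 0", path,
                      sum(bad_se)))
      df <- df[!bad_se, , drop = FALSE]
    }
    df$Z <- df$BETA / df$SE
  }
  df[, c(.SUMSTAT_COLS, "Z")]
}

#' Read per-substudy summary statistics into a cohort
#'
#' Each file is tab-separated with a header and columns `SNP`, `A1`,
#' `A2`, `FREQ` and either `Z` or (`BETA`, `SE`) (converted as
#' `Z = BETA/SE`; rows with `SE <= 0` are dropped with a message).
#' Optional `CHR`/`POS` columns are carried from the first file listing a
#' SNP. Alleles are harmonised against the first study in which each SNP
#' appears: swapped `A1`/`A2` flips the z sign; any other allele
#' combination drops the row. SNPs absent from a substudy get `NA`.
#'
#' @param paths Character vector of per-study file paths, in manifest
#'   order.
#' @param studies Manifest data frame from [read_studies()] (or any
#'   frame with `study_id`, `n_eff`), one row per file.
#' @return A [gwas_cohort()].
#' @export
read_sumstats <- function(paths, studies) {
  stopifnot(length(paths) == nrow(studies))
  tabs <- lapply(paths, .read_one_sumstats)
  ref <- NULL
  for (t in tabs) {
    add <- t[!(t$SNP %in% ref$SNP), c("SNP", "A1", "A2", "FREQ")]
    ref <- rbind(ref, add)
  }
  m <- nrow(ref)
  z <- matrix(NA_real_, nrow = m, ncol = length(paths),
              dimnames = list(ref$SNP, as.character(studies$study_id)))
  dropped <- 0L
  for (j in seq_along(tabs)) {
    t <- tabs[[j]]
    i <- match(t$SNP, ref$SNP)
    same <- t$A1 == ref$A1[i] & t$A2 == ref$A2[i]
    flip <- t$A1 == ref$A2[i] & t$A2 == ref$A1[i]
    dropped <- dropped + sum(!same & !flip)
    z[i[same], j] <- t$Z[same]
    z[i[flip], j] <- -t$Z[flip]
  }
  if (dropped)
    message(sprintf("dropped %d row(s) with inconsistent allele labels",
                    dropped))
  snps <- data.frame(snp = ref$SNP, a1 = ref$A1, a2 = ref$A2,
                     allele_freq = ref$FREQ)
  gwas_cohort(snps, z, studies)
}

#' Write a cohort as per-substudy summary statistics files
#'
#' One tab-separated file per substudy (named `<study_id>.tsv`) with
#' columns `SNP`, `A1`, `A2`, `FREQ`, `Z`, plus a `studies.tsv`
#' manifest. Synthetic cohorts without allele labels get placeholder
#' `A`/`G` alleles.
#'
#' @param cohort A [gwas_cohort()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the written file paths.
#' @export
write_sumstats <- function(cohort, dir) {
  stopifnot(inherits(cohort, "gwas_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  a1 <- cohort$snps$a1 %||% rep("A", nrow(cohort$snps))
  a2 <- cohort$snps$a2 %||% rep("G", nrow(cohort$snps))
  ids <- as.character(cohort$studies$study_id)
  paths <- file.path(dir, paste0(ids, ".tsv"))
  for (j in seq_along(ids)) {
    keep <- !is.na(cohort$z[, j])
    utils::write.table(
      data.frame(SNP = cohort$snps$snp, A1 = a1, A2 = a2,
                 FREQ = cohort$snps$allele_freq,
                 Z = cohort$z[, j])[keep, ],
      paths[j], sep = "\t", quote = FALSE, row.names = FALSE)
  }
  manifest <- file.path(dir, "studies.tsv")
  man <- cohort$studies
  if (!"n_quant" %in% names(man) &&
      !all(c("n_cases", "n_controls") %in% names(man)))
    man$n_quant <- man$n_eff
  utils::write.table(man, manifest, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(paths, manifest))
}

#' Read a pairwise LD table
#'
#' Whitespace-delimited file with a header containing at least `SNP_A`,
#' `SNP_B` and `R2` (the PLINK `--r2` output dialect; extra columns such
#' as `CHR_A`/`BP_A` are ignored). Self-pairs and rows with `R2`
#' outside `[0, 1]` are rejected with a message; duplicated unordered
#' pairs keep the maximum `r^2`.
#'
#' @param path LD file path.
#' @return Data frame with columns `snp_a`, `snp_b`, `r_sq`.
#' @export
read_ld_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE)
  if (!nrow(df)) return(empty_ld_table())
  need <- c("SNP_A", "SNP_B", "R2")
  if (!all(need %in% names(df)))
    stop("LD table must have columns SNP_A, SNP_B, R2")
  bad <- !is.finite(df$R2) | df$R2 < 0 | df$R2 > 1 | df$SNP_A == df$SNP_B
  if (any(bad))
    message(sprintf("rejecting %d malformed LD row(s)", sum(bad)))
  df <- df[!bad, , drop = FALSE]
  a <- pmin(df$SNP_A, df$SNP_B)
  b <- pmax(df$SNP_A, df$SNP_B)
  key <- paste(a, b, sep = "\r")
  r <- tapply(df$R2, key, max)
  parts <- strsplit(names(r), "\r", fixed = TRUE)
  data.frame(snp_a = vapply(parts, `[`, "", 1),
             snp_b = vapply(parts, `[`, "", 2),
             r_sq = as.numeric(r))
}

#' Write an LD table in the PLINK-style dialect
#'
#' @param ld Data frame with `snp_a`, `snp_b`, `r_sq`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_ld_table <- function(ld, path) {
  utils::write.table(
    data.frame(SNP_A = ld$snp_a, SNP_B = ld$snp_b, R2 = ld$r_sq),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
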