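#' Multi-substudy summary statistics container
#'
#' Bundles per-SNP annotation, a z-score matrix (one row per SNP, one
#' column per substudy) and the substudy manifest with effective sample
#' sizes. Missing z-scores (SNPs absent from a substudy) are `NA`;
#' meta-analysis then uses the available studies only.
#'
#' @param snps Data frame with at least `snp` (unique id) and
#'   `allele_freq`; `het` is derived if absent. Optional columns `chrom`,
#'   `pos`, `a1`, `a2` are carried through untouched.
#' @param z Numeric matrix, `nrow(snps)` rows, one column per study,
#'   column names matching `studies$study_id`.
#' @param studies Data frame with `study_id` and `n_eff` (see
#'   [effective_n()]), one row per substudy.
#' @return An object of class `gwas_cohort`.
#' @export
gwas_cohort <- function(snps, z, studies) {
  stopifnot(is.data.frame(snps), is.data.frame(studies))
  if (!all(c("snp", "allele_freq") %in% names(snps)))
    stop("'snps' needs columns 'snp' and 'allele_freq'")
  if (anyDuplicated(snps$snp)) stop("duplicate SNP ids")
  if (!all(c("study_id", "n_eff") %in% names(studies)))
    stop("'studies' needs columns 'study_id' and 'n_eff'")
  if (any(studies$n_eff <= 0)) stop("'n_eff' must be > 0 for every study")
  z <- as.matrix(z)
  if (nrow(z) != nrow(snps))
    stop("z matrix must have one row per SNP")
  if (ncol(z) != nrow(studies))
    stop("z matrix must have one column per study")
  if (is.null(colnames(z))) colnames(z) <- studies$study_id
  if (!identical(colnames(z), as.character(studies$study_id)))
    stop("z column names must match the study manifest order")
  if (is.null(snps$het)) snps$het <- heterozygosity(snps$allele_freq)
  rownames(z) <- snps$snp
  structure(list(snps = snps, z = z, studies = studies),
            class = "gwas_cohort")
}

#' @export
print.gwas_cohort <- function(x, ...) {
  cat(sprintf("GWAS cohort: %d SNPs x %d substudies (total N_eff = %.0f)\n",
              nrow(x$snps), nrow(x$studies), sum(x$studies$n_eff)))
  invisible(x)
}

#' @export
`[.gwas_cohort` <- function(x, i, ...) {
  gwas_cohort(x$snps[i, , drop = FALSE], x$z[i, , drop = FALSE], x$studies)
}

#' A deterministic uneven substudy layout
#'
#' Consortium meta-analyses pool substudies of very different sizes. This
#' helper produces a fixed layout with geometrically graded effective
#' sizes (largest about `exp(2) ~ 7.4` times the smallest) scaled to a
#' requested total, mirroring that unevenness without any randomness.
#'
#' @param n_studies Number of substudies (`>= 2`).
#' @param total_n_eff Total effective sample size to distribute.
#' @return Study manifest data frame with `study_id` and `n_eff`.
#' @export
default_studies <- function(n_studies, total_n_eff) {
  if (n_studies < 2) stop("need at least 2 studies")
  w <- exp(seq(0, 2, length.out = n_studies))
  data.frame(study_id = sprintf("study%02d", seq_len(n_studies)),
             n_eff = total_n_eff * w / sum(w))
}
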