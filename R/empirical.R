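#' Allele-frequency and missingness QC
#'
#' Retains SNPs whose minor allele frequency exceeds `maf_min` and whose
#' z-score is finite in every substudy in which it is present (at least
#' one study). Removal counts are attached as attribute `"qc_counts"`.
#'
#' @param cohort A [gwas_cohort()].
#' @param maf_min Minor-allele-frequency floor, in `[0, 0.5)` (default
#'   `0.005`).
#' @param require_all_studies Require a finite z in all substudies
#'   (default `FALSE`: SNPs missing from some substudies are kept and
#'   meta-analysed over the available ones).
#' @return The filtered cohort.
#' @export
qc_filter <- function(cohort, maf_min = 0.005, require_all_studies = FALSE) {
  stopifnot(inherits(cohort, "gwas_cohort"))
  if (maf_min < 0 || maf_min >= 0.5) stop("'maf_min' must lie in [0, 0.5)")
  maf <- pmin(cohort$snps$allele_freq, 1 - cohort$snps$allele_freq)
  ok_maf <- maf > maf_min
  finite <- is.finite(cohort$z)
  bad <- !finite & !is.na(cohort$z)          # Inf/NaN, not just absent
  ok_z <- if (require_all_studies) rowSums(finite) == ncol(cohort$z)
  else rowSums(finite) >= 1L & rowSums(bad) == 0L
  keep <- ok_maf & ok_z
  if (!any(keep)) stop("QC removed every SNP")
  out <- cohort[keep]
  attr(out, "qc_counts") <- c(input = length(keep), kept = sum(keep),
                              removed_maf = sum(!ok_maf),
                              removed_z = sum(ok_maf & !ok_z))
  out
}

#' Random LD pruning
#'
#' Greedy maximal independent set on the graph whose edges are SNP pairs
#' with `r^2 >= r_sq_max`, visited in random order: a SNP is kept iff no
#' already-kept neighbour exists. The representative of each LD clique is
#' therefore chosen at random — never by z-score, which would re-introduce
#' the winner's curse — and the draw is repeated for every split
#' repetition. The kept set is maximal: every removed SNP has a kept
#' neighbour.
#'
#' @param snps Character vector of candidate SNP ids.
#' @param ld LD table (`snp_a`, `snp_b`, `r_sq`), e.g. [read_ld_table()].
#' @param r_sq_max Pruning threshold (default `0.8`).
#' @param seed Integer seed (optional).
#' @return Character vector of kept SNP ids (in input order).
#' @export
random_prune <- function(snps, ld, r_sq_max = 0.8, seed = NULL) {
  m <- length(snps)
  e <- ld[ld$r_sq >= r_sq_max, , drop = FALSE]
  ia <- match(e$snp_a, snps)
  ib <- match(e$snp_b, snps)
  ok <- !is.na(ia) & !is.na(ib) & ia != ib
  ia <- ia[ok]; ib <- ib[ok]
  if (!length(ia)) return(snps)
  adj <- vector("list", m)
  nb <- split(c(ib, ia), c(ia, ib))
  adj[as.integer(names(nb))] <- nb
  with_seed(seed, {
    ord <- sample.int(m)
    kept <- logical(m)
    blocked <- logical(m)
    for (v in ord) {
      if (!blocked[v]) {
        kept[v] <- TRUE
        blocked[adj[[v]]] <- TRUE
      }
    }
    snps[kept]
  })
}

#' Total linkage disequilibrium per SNP
#'
#' `TLD(snp) = sum of r^2` over all recorded pairs containing the SNP; a
#' SNP with no recorded pair has TLD 0.
#'
#' @inheritParams random_prune
#' @return Named numeric vector of TLD values, one per input SNP.
#' @export
tld <- function(snps, ld) {
  ia <- match(ld$snp_a, snps)
  ib <- match(ld$snp_b, snps)
  out <- numeric(length(snps))
  ok_a <- !is.na(ia); ok_b <- !is.na(ib)
  if (any(ok_a)) {
    s <- rowsum(ld$r_sq[ok_a], ia[ok_a])
    out[as.integer(rownames(s))] <- out[as.integer(rownames(s))] + s[, 1]
  }
  if (any(ok_b)) {
    s <- rowsum(ld$r_sq[ok_b], ib[ok_b])
    out[as.integer(rownames(s))] <- out[as.integer(rownames(s))] + s[, 1]
  }
  names(out) <- snps
  out
}

#' Filter SNPs by total linkage disequilibrium
#'
#' Keeps SNPs whose [tld()] is strictly below `tld_max`. Restricting to
#' low-TLD SNPs suppresses the apparent ubiquitous signal that arises from
#' tagging of large effects by extended LD blocks.
#'
#' @inheritParams random_prune
#' @param tld_max Threshold (default `15`), `> 0`.
#' @return Character vector of kept SNP ids.
#' @export
tld_filter <- function(snps, ld, tld_max = 15) {
  if (tld_max <= 0) stop("'tld_max' must be > 0")
  snps[tld(snps, ld) < tld_max]
}

#' Plan discovery/replication substudy splits
#'
#' For every discovery fraction and repetition, draws a random subset of
#' substudies whose effective-sample-size share approximates the target
#' fraction: studies are shuffled and added until the target share is
#' first met or exceeded; a draw is accepted when the achieved share is
#' within `tolerance` (relative) of the target and both sides are
#' non-empty, otherwise it is redrawn (the closest draw is kept as a
#' fallback). Deterministic given `seed`.
#'
#' @param studies Study manifest (`study_id`, `n_eff`), `>= 2` rows.
#' @param fractions Discovery-share targets (default the nine deciles
#'   `0.1 ... 0.9`).
#' @param n_reps Repetitions per fraction (default `100`).
#' @param seed Integer seed.
#' @param tolerance Relative acceptance tolerance on the achieved share
#'   (default `0.25`).
#' @param max_redraws Redraw budget per realization (default `200`).
#' @return List of realizations, each a list with `fraction_index`,
#'   `fraction`, `rep`, `discovery`, `replication` (study-id vectors),
#'   `n_d`, `n_r`, `achieved_fraction`, `seed`.
#' @export
plan_splits <- function(studies, fractions = seq(0.1, 0.9, by = 0.1),
                        n_reps = 100, seed = NULL, tolerance = 0.25,
                        max_redraws = 200) {
  if (nrow(studies) < 2)
    stop("cannot split fewer than 2 studies")
  if (any(fractions <= 0 | fractions >= 1))
    stop("'fractions' must lie strictly within (0, 1)")
  ids <- as.character(studies$study_id)
  n_eff <- studies$n_eff
  total <- sum(n_eff)
  out <- vector("list", length(fractions) * n_reps)
  k <- 0L
  for (i in seq_along(fractions)) {
    target <- fractions[i]
    for (j in seq_len(n_reps)) {
      sub_seed <- if (is.null(seed)) NULL else
        substream_seed(seed, "split", i, j)
      real <- with_seed(sub_seed, {
        best <- NULL
        for (try in seq_len(max_redraws)) {
          ord <- sample.int(length(ids))
          share <- cumsum(n_eff[ord]) / total
          n_take <- which(share >= target)[1]
          if (n_take >= length(ids)) n_take <- length(ids) - 1L
          achieved <- share[n_take]
          cand <- list(take = ord[seq_len(n_take)], achieved = achieved)
          if (is.null(best) ||
              abs(achieved - target) < abs(best$achieved - target))
            best <- cand
          if (abs(achieved - target) <= tolerance * target) break
        }
        best
      })
      disc <- ids[real$take]
      k <- k + 1L
      out[[k]] <- list(fraction_index = i, fraction = target, rep = j,
                       discovery = disc,
                       replication = setdiff(ids, disc),
                       n_d = sum(n_eff[real$take]),
                       n_r = total - sum(n_eff[real$take]),
                       achieved_fraction = real$achieved,
                       seed = sub_seed)
    }
  }
  out
}

#' Sample-size-weighted meta-analysis of substudy z-scores
#'
#' Combines per-substudy z-scores as
#' `z = sum(sqrt(n_i) z_i) / sqrt(sum(n_i))`, which preserves the
#' square-root-of-N scaling of effect sizes so that the combined score
#' follows the same mixture model at `N = sum(n_i)`. SNPs missing from a
#' substudy (`NA`) are combined over the available studies only, with the
#' effective size summed accordingly.
#'
#' @param z Numeric matrix (SNPs x studies) or vector (single study).
#' @param n_eff Per-study effective sample sizes.
#' @return Numeric vector of combined z-scores (`NaN` where no study has
#'   a finite z).
#' @export
meta_z <- function(z, n_eff) {
  if (is.null(dim(z))) z <- matrix(z, ncol = length(n_eff))
  stopifnot(ncol(z) == length(n_eff))
  w <- sqrt(n_eff)
  if (!anyNA(z)) return(drop(z %*% w) / sqrt(sum(n_eff)))
  obs <- !is.na(z)
  zz <- z
  zz[!obs] <- 0
  drop(zz %*% w) / sqrt(drop(obs %*% n_eff))
}

#' Binned conditional replication curves
#'
#' Bins discovery z-scores into `n_bins` equal-width half-open bins on
#' `[z_min, z_max)` (last bin closed; scores outside are excluded) and
#' returns per-bin replication summaries: SNP count, mean replication
#' z-score, mean squared replication z-score, the fraction replicating
#' (same sign as the bin centre and one-tailed `p < p_threshold`), and
#' the count-weighted mean heterozygosity when `het` is supplied.
#'
#' @param z_d,z_r Paired discovery/replication z-score vectors.
#' @param het Optional per-SNP heterozygosity (same length).
#' @param p_threshold One-tailed replication p-value threshold (default
#'   `0.05`).
#' @param n_bins Number of bins (default `200`; even, so no bin straddles
#'   zero).
#' @param z_min,z_max Bin range (default `[-6, 6]`).
#' @return Data frame with one row per bin: `bin`, `center`, `count`,
#'   `mean_zr`, `mean_zr_sq`, `repl_frac`, `mean_het` (`NA` where
#'   `count = 0`).
#' @export
bin_conditional <- function(z_d, z_r, het = NULL, p_threshold = 0.05,
                            n_bins = 200, z_min = -6, z_max = 6) {
  stopifnot(length(z_d) == length(z_r))
  breaks <- seq(z_min, z_max, length.out = n_bins + 1)
  centers <- (breaks[-1] + breaks[-(n_bins + 1)]) / 2
  idx <- findInterval(z_d, breaks, rightmost.closed = TRUE)
  keep <- idx >= 1L & idx <= n_bins
  idx <- idx[keep]
  zr <- z_r[keep]
  z_t <- p_to_z(p_threshold)
  success <- as.numeric(sign(zr) == sign(centers[idx]) & -abs(zr) < z_t)
  tab <- tabulate(idx, nbins = n_bins)
  sums <- function(v) {
    out <- numeric(n_bins)
    s <- rowsum(v, idx)
    out[as.integer(rownames(s))] <- s[, 1]
    out
  }
  mean_or_na <- function(total) ifelse(tab > 0, total / tab, NA_real_)
  out <- data.frame(bin = seq_len(n_bins), center = centers, count = tab,
                    mean_zr = mean_or_na(sums(zr)),
                    mean_zr_sq = mean_or_na(sums(zr^2)),
                    repl_frac = mean_or_na(sums(success)))
  out$mean_het <- if (is.null(het)) NA_real_ else
    mean_or_na(sums(het[keep]))
  out
}

#' Average binned curves over repetitions
#'
#' Count-weighted per-bin average of the conditional summaries across
#' repetitions; since each repetition is an unbiased estimate of the
#' conditional means, so is the average, with reduced variance.
#'
#' @param curves List of [bin_conditional()] data frames on identical
#'   bins.
#' @return A single averaged data frame in the same format (`count` is
#'   the summed count).
#' @export
aggregate_curves <- function(curves) {
  stopifnot(length(curves) >= 1)
  if (length(curves) == 1L) return(curves[[1]])
  base <- curves[[1]]
  w_tot <- Reduce(`+`, lapply(curves, `[[`, "count"))
  wavg <- function(col) {
    num <- Reduce(`+`, lapply(curves, function(cc) {
      v <- cc[[col]] * cc$count
      v[cc$count == 0] <- 0
      v
    }))
    ifelse(w_tot > 0, num / w_tot, NA_real_)
  }
  data.frame(bin = base$bin, center = base$center, count = w_tot,
             mean_zr = wavg("mean_zr"), mean_zr_sq = wavg("mean_zr_sq"),
             repl_frac = wavg("repl_frac"), mean_het = wavg("mean_het"))
}

#' Empirical and model QQ summaries
#'
#' `empirical_qq()` returns, for each threshold p-value on a log10 grid,
#' the proportion of SNPs whose two-tailed p-value is at least as
#' significant. `model_qq()` computes the corresponding model curve from
#' the mixture CDF, averaged over heterozygosity windows (equal-count by
#' default) so the H-dependence of the z-scale variances is respected.
#'
#' @param z Observed z-scores.
#' @param p_grid Threshold grid (default `10^seq(0, -10, length 101)`).
#' @return Data frame with columns `p_threshold` and `prop` (proportion
#'   of SNPs at least as significant).
#' @export
empirical_qq <- function(z, p_grid = 10^seq(0, -10, length.out = 101)) {
  stopifnot(length(z) >= 1)
  p <- 2 * stats::pnorm(-abs(z))
  p <- sort(p)
  prop <- findInterval(p_grid, p, rightmost.closed = FALSE) / length(p)
  # findInterval counts p <= threshold via sorted insertion position
  data.frame(p_threshold = p_grid, prop = prop)
}

#' @rdname empirical_qq
#' @param params,n_eff Model parameters and effective sample size.
#' @param het Per-SNP heterozygosity vector (defines the windows).
#' @param n_windows Number of heterozygosity windows (default `5`).
#' @export
model_qq <- function(params, n_eff, het,
                     p_grid = 10^seq(0, -10, length.out = 101),
                     n_windows = 5) {
  qs <- stats::quantile(het, probs = seq(0, 1, length.out = n_windows + 1))
  win <- cut(het, breaks = unique(qs), include.lowest = TRUE)
  h_bar <- tapply(het, win, mean)
  w <- tabulate(win, nbins = nlevels(win)) / length(het)
  z_thr <- stats::qnorm(p_grid / 2)            # negative
  prop <- rowSums(vapply(seq_along(h_bar), function(k) {
    w[k] * 2 * mixture_cdf(z_thr, params, n_eff, h_bar[k])
  }, numeric(length(z_thr))))
  data.frame(p_threshold = p_grid, prop = pmin(prop, 1))
}

#' Split, prune and bin a cohort into empirical replication curves
#'
#' The non-parametric estimation pipeline: for every split realization,
#' (optionally) re-prune the SNPs at random, meta-analyse the discovery
#' and replication substudies separately, and bin the replication
#' z-scores conditional on the discovery z-scores. The stacked result is
#' the empirical surface the mixture parameters are fitted to.
#'
#' @param cohort A [gwas_cohort()] (after [qc_filter()]).
#' @param splits Realizations from [plan_splits()].
#' @param ld Optional LD table; when non-empty, [random_prune()] is
#'   re-drawn per realization.
#' @param p_threshold One-tailed replication threshold (default `0.05`).
#' @param n_bins,z_min,z_max Binning layout (defaults `200` on
#'   `[-6, 6]`).
#' @param r_sq_max Pruning threshold (default `0.8`).
#' @param seed Integer seed for the per-realization pruning draws.
#' @return Data frame with one row per (realization, bin):
#'   `fraction_index`, `fraction`, `rep`, `n_d`, `n_r`, plus the
#'   [bin_conditional()] columns.
#' @export
split_curves <- function(cohort, splits, ld = NULL, p_threshold = 0.05,
                         n_bins = 200, z_min = -6, z_max = 6,
                         r_sq_max = 0.8, seed = NULL) {
  stopifnot(inherits(cohort, "gwas_cohort"))
  ids <- as.character(cohort$studies$study_id)
  n_eff <- cohort$studies$n_eff
  have_ld <- !is.null(ld) && nrow(ld) > 0
  pieces <- lapply(splits, function(sp) {
    rows <- seq_len(nrow(cohort$snps))
    if (have_ld) {
      kept <- random_prune(cohort$snps$snp, ld, r_sq_max = r_sq_max,
                           seed = if (is.null(seed)) NULL else
                             substream_seed(seed, "prune",
                                            sp$fraction_index, sp$rep))
      rows <- match(kept, cohort$snps$snp)
    }
    d_cols <- match(sp$discovery, ids)
    r_cols <- match(sp$replication, ids)
    zd <- meta_z(cohort$z[rows, d_cols, drop = FALSE], n_eff[d_cols])
    zr <- meta_z(cohort$z[rows, r_cols, drop = FALSE], n_eff[r_cols])
    bc <- bin_conditional(zd, zr, het = cohort$snps$het[rows],
                          p_threshold = p_threshold, n_bins = n_bins,
                          z_min = z_min, z_max = z_max)
    cbind(data.frame(fraction_index = sp$fraction_index,
                     fraction = sp$fraction, rep = sp$rep,
                     n_d = sp$n_d, n_r = sp$n_r), bc)
  })
  do.call(rbind, pieces)
}
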