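#' Simulated proportion of chip heritability explained by significant SNPs
#'
#' Monte-Carlo estimate of `S(N; z_t)`: the fraction of the additive
#' tagged (chip-heritability) variance carried by sparse-class SNPs that
#' is explained by those reaching the one-tailed significance threshold
#' at effective sample size `n_eff`. Each repetition assigns every
#' simulated SNP a noise component `eps ~ N(0, sigma0_sq)`; a proportion
#' `pi1` of SNPs additionally receive a causal-tag effect
#' `delta_c ~ N(0, (sigma_a_sq + sigma_b_sq) * n_eff * mean_het)`, with
#' observed `z = delta_c + eps`. `S` is the ratio of `sum(delta_c^2)`
#' over significant sparse SNPs to the sum over all sparse SNPs, with
#' numerator and denominator averaged over repetitions.
#'
#' @param params A [mixture_params()] object with `pi1 > 0`.
#' @param n_eff Effective sample size.
#' @param z_threshold One-tailed threshold, `<= 0` (default
#'   `p_to_z(5e-8)`).
#' @param mean_het Mean heterozygosity of the SNP panel.
#' @param m_snps Simulated SNP count per repetition (default `1e5`).
#' @param reps Repetitions to average over (default `20`).
#' @param seed Integer seed.
#' @param include_ubiquitous Also draw the `(1 - pi1)` ubiquitous-class
#'   z-scores (`delta_u ~ N(0, sigma_a_sq * n_eff * mean_het)` plus
#'   noise)? They never enter the `S` ratio — the flag exists to make
#'   that invariant checkable — but the draws are returned as `z_ubiq`.
#' @return List with `S`, `se` (Monte-Carlo standard error across
#'   repetitions), `n_sparse`, `reps` (and `z_ubiq` if requested).
#' @export
simulate_S <- function(params, n_eff, z_threshold = p_to_z(5e-8),
                       mean_het, m_snps = 1e5, reps = 20, seed = NULL,
                       include_ubiquitous = FALSE) {
  params <- as_mixture_params(params)
  if (any(z_threshold > 0)) stop("'z_threshold' must be <= 0")
  if (params$pi1 <= 0) stop("S is undefined when pi1 = 0")
  n_sparse <- max(1L, round(params$pi1 * m_snps))
  v_c <- (params$sigma_a_sq + params$sigma_b_sq) * n_eff * mean_het
  with_seed(seed, {
    num <- den <- ratio <- numeric(reps)
    for (r in seq_len(reps)) {
      delta_c <- stats::rnorm(n_sparse, 0, sqrt(v_c))
      eps <- stats::rnorm(n_sparse, 0, sqrt(params$sigma0_sq))
      z <- delta_c + eps
      sig <- -abs(z) < z_threshold
      num[r] <- sum(delta_c[sig]^2)
      den[r] <- sum(delta_c^2)
      ratio[r] <- num[r] / den[r]
    }
    out <- list(S = sum(num) / sum(den),
                se = stats::sd(ratio) / sqrt(reps),
                n_sparse = n_sparse, reps = reps)
    if (include_ubiquitous) {
      n_ubiq <- m_snps - n_sparse
      v_u <- params$sigma_a_sq * n_eff * mean_het
      out$z_ubiq <- stats::rnorm(n_ubiq, 0, sqrt(v_u)) +
        stats::rnorm(n_ubiq, 0, sqrt(params$sigma0_sq))
    }
    out
  })
}

#' Expectation-based proportion of explained heritability for observed z
#'
#' Given an observed set of z-scores, replaces the unobservable squared
#' effect `delta^2` by its posterior expectation [expected_delta_sq()]
#' and returns the ratio of the summed expectation over SNPs passing the
#' threshold to the sum over all SNPs.
#'
#' @param z Observed z-scores.
#' @inheritParams simulate_S
#' @param het Per-SNP heterozygosity (scalar mean or vector).
#' @return Proportion in `[0, 1]`.
#' @export
expected_S <- function(z, params, n_eff, het,
                       z_threshold = p_to_z(5e-8)) {
  if (any(z_threshold > 0)) stop("'z_threshold' must be <= 0")
  w <- expected_delta_sq(z, params, n_eff, het)
  sig <- -abs(z) < z_threshold
  if (!any(sig)) return(0)
  sum(w[sig]) / sum(w)
}

#' S(N) projection curve over a sample-size grid
#'
#' Evaluates [simulate_S()] on a log-spaced grid of effective sample
#' sizes (default 20 points per decade).
#'
#' @inheritParams simulate_S
#' @param n_range Two-element bracket of effective sample sizes.
#' @param points_per_decade Grid density (default `20`).
#' @return Data frame with columns `n_eff`, `S`, `se`.
#' @export
projection_curve <- function(params, n_range, z_threshold = p_to_z(5e-8),
                             mean_het, m_snps = 1e5, reps = 20,
                             seed = NULL, points_per_decade = 20) {
  stopifnot(length(n_range) == 2, n_range[1] > 0,
            n_range[2] > n_range[1])
  n_pts <- max(2L, ceiling(log10(n_range[2] / n_range[1]) *
                             points_per_decade) + 1L)
  n_grid <- 10^seq(log10(n_range[1]), log10(n_range[2]),
                   length.out = n_pts)
  rows <- lapply(seq_along(n_grid), function(i) {
    s <- simulate_S(params, n_grid[i], z_threshold, mean_het,
                    m_snps = m_snps, reps = reps,
                    seed = if (is.null(seed)) NULL else
                      substream_seed(seed, "proj", i))
    data.frame(n_eff = n_grid[i], S = s$S, se = s$se)
  })
  do.call(rbind, rows)
}

#' Effective sample size required to reach a target S
#'
#' Scans the [projection_curve()] over `n_bracket`, takes the monotone
#' (running-maximum) envelope to smooth Monte-Carlo jitter, and returns
#' the smallest grid sample size whose smoothed `S` meets `target_S`.
#'
#' @inheritParams projection_curve
#' @param target_S Target proportion in `(0, 1)` (e.g. `0.9` for
#'   "approaching fully explained").
#' @param n_bracket Sample-size bracket to scan.
#' @return List with `n_eff` (smallest grid value reaching the target)
#'   and `curve` (the scanned projection curve).
#' @export
n_for_target_S <- function(params, z_threshold = p_to_z(5e-8), mean_het,
                           target_S = 0.9, n_bracket = c(1e3, 1e7),
                           m_snps = 1e5, reps = 20, seed = NULL,
                           points_per_decade = 20) {
  if (target_S <= 0 || target_S >= 1)
    stop("'target_S' must lie strictly within (0, 1)")
  curve <- projection_curve(params, n_bracket, z_threshold, mean_het,
                            m_snps = m_snps, reps = reps, seed = seed,
                            points_per_decade = points_per_decade)
  smoothed <- cummax(curve$S)
  hit <- which(smoothed >= target_S)
  if (!length(hit))
    stop(sprintf("bracket does not span target S = %.3g (max S = %.3g)",
                 target_S, max(smoothed)))
  list(n_eff = curve$n_eff[hit[1]], curve = curve)
}
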