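#' Posterior of the replication z-score given a discovery z-score
#'
#' For a SNP observed at `z_d` in a discovery sample of effective size
#' `n_d`, the z-score `z_r` in an independent replication sample of
#' effective size `n_r` follows a two-arm normal mixture. Because effect
#' sizes scale as the square root of effective sample size, the discovery
#' posterior arms are rescaled by `sqrt(n_r/n_d)` and re-noised:
#' `m_u = sqrt(n_r/n_d) mu_u`, `s_u_sq = sigma0_sq + (n_r/n_d) var_u`
#' (and likewise for the sparse arm), with arm weight `tdr(z_d)`.
#'
#' @param z_d Discovery z-score(s).
#' @param n_d,n_r Discovery and replication effective sample sizes, `> 0`.
#' @param params A [mixture_params()] object.
#' @param het SNP heterozygosity (or per-bin mean heterozygosity).
#' @return A data frame with columns `tdr`, `m_u`, `m_s`, `s_u_sq`,
#'   `s_s_sq`, `e_delta_r` (expected replication effect size),
#'   `var_delta_r`, `var_z_r` and `e_z_r_sq` (`= var_z_r + e_delta_r^2`,
#'   the second-moment curve used by the fitting cost).
#' @seealso [expected_replication_z()], [replication_rate()],
#'   [combined_expectation()]
#' @export
replication_posterior <- function(z_d, n_d, n_r, params, het) {
  if (any(n_d <= 0) || any(n_r <= 0))
    stop("'n_d' and 'n_r' must be > 0")
  pm <- posterior_moments(z_d, params, n_d, het)
  ratio <- n_r / n_d
  sigma0_sq <- as_mixture_params(params)$sigma0_sq
  m_u <- sqrt(ratio) * pm$mu_u
  m_s <- sqrt(ratio) * pm$mu_s
  e_delta_r <- (1 - pm$tdr) * m_u + pm$tdr * m_s
  var_delta_r <- ratio * ((1 - pm$tdr) * pm$var_u + pm$tdr * pm$var_s +
                            pm$tdr * (1 - pm$tdr) * (pm$mu_s - pm$mu_u)^2)
  var_z_r <- var_delta_r + sigma0_sq
  data.frame(tdr = pm$tdr, m_u = m_u, m_s = m_s,
             s_u_sq = sigma0_sq + ratio * pm$var_u,
             s_s_sq = sigma0_sq + ratio * pm$var_s,
             e_delta_r = e_delta_r,
             var_delta_r = var_delta_r,
             var_z_r = var_z_r,
             e_z_r_sq = var_z_r + e_delta_r^2)
}

#' Expected replication z-score (adjusted effect size)
#'
#' `E(z_r | z_d) = E(delta_r | z_d) = sqrt(n_r/n_d) [(1 - tdr) mu_u +
#' tdr mu_s]`: the winner's-curse-corrected effect size expected in a
#' replication sample. Always shrunk towards zero relative to
#' `sqrt(n_r/n_d) z_d`.
#'
#' @inheritParams replication_posterior
#' @return Expected replication z-score(s).
#' @export
expected_replication_z <- function(z_d, n_d, n_r, params, het) {
  replication_posterior(z_d, n_d, n_r, params, het)$e_delta_r
}

#' Posterior variance of the replication effect size and z-score
#'
#' Returns both `var(delta_r | z_d)` (mixture variance of the rescaled
#' posterior arms) and `var(z_r | z_d) = var(delta_r | z_d) + sigma0_sq`
#' (law of total variance with the independent replication noise), plus the
#' second moment `E(z_r^2 | z_d)` used by the fitting cost.
#'
#' @inheritParams replication_posterior
#' @return Data frame with columns `var_delta_r`, `var_z_r`, `e_z_r_sq`.
#' @export
var_replication_z <- function(z_d, n_d, n_r, params, het) {
  replication_posterior(z_d, n_d, n_r, params, het)[
    , c("var_delta_r", "var_z_r", "e_z_r_sq")]
}

#' Replication probability
#'
#' Probability that the replication z-score is same-signed as `z_d` and
#' passes the one-tailed threshold `z_threshold`:
#' `R(z_d; z_t) = (1 - tdr) Phi(z_t; -|m_u|, s_u_sq) +
#'  tdr Phi(z_t; -|m_s|, s_s_sq)`.
#' At `z_d = 0` the two one-sided limits coincide, so the value is their
#' common limit.
#'
#' @inheritParams replication_posterior
#' @param z_threshold One-tailed threshold, `<= 0` (see [p_to_z()]).
#' @return Probabilities in `[0, 1]`.
#' @export
replication_rate <- function(z_d, n_d, n_r, params, het, z_threshold) {
  if (any(z_threshold > 0)) stop("'z_threshold' must be <= 0")
  rp <- replication_posterior(z_d, n_d, n_r, params, het)
  (1 - rp$tdr) * stats::pnorm(z_threshold, -abs(rp$m_u), sqrt(rp$s_u_sq)) +
    rp$tdr * stats::pnorm(z_threshold, -abs(rp$m_s), sqrt(rp$s_s_sq))
}

#' Combined (discovery + replication) dataset prediction
#'
#' In a multistage design the final z-score comes from the combined dataset
#' of effective size `n_dr = n_d + n_r`. With inverse-variance weights
#' `w_d = sqrt(n_d/n_dr)`, `w_r = sqrt(n_r/n_dr)` (so `w_d^2 + w_r^2 = 1`),
#' the combined z-score is `z_dr = w_d z_d + w_r z_r`, giving
#' `E(z_dr | z_d) = w_d z_d + w_r E(delta_r | z_d)` and
#' `var(z_dr | z_d) = w_r^2 var(z_r | z_d)`.
#'
#' @inheritParams replication_posterior
#' @param n_r Replication effective sample size, `>= 0` (`0` means the
#'   "combined" dataset is the discovery set itself).
#' @return Data frame with columns `w_d`, `w_r`, `e_z_dr`, `var_z_dr`.
#' @export
combined_expectation <- function(z_d, n_d, n_r, params, het) {
  if (any(n_d <= 0)) stop("'n_d' must be > 0")
  if (any(n_r < 0)) stop("'n_r' must be >= 0")
  n_dr <- n_d + n_r
  w_d <- sqrt(n_d / n_dr)
  w_r <- sqrt(n_r / n_dr)
  if (all(n_r == 0)) {
    k <- length(z_d)
    return(data.frame(w_d = rep(w_d, length.out = k),
                      w_r = rep(w_r, length.out = k),
                      e_z_dr = z_d, var_z_dr = rep(0, k)))
  }
  rp <- replication_posterior(z_d, n_d, pmax(n_r, .Machine$double.eps),
                              params, het)
  data.frame(w_d = w_d, w_r = w_r,
             e_z_dr = w_d * z_d + w_r * rp$e_delta_r,
             var_z_dr = w_r^2 * rp$var_z_r)
}

#' Probability of significance in the combined dataset
#'
#' Probability that a SNP at `z_d` in the discovery sample reaches the
#' one-tailed threshold `z_threshold` in the combined dataset, obtained
#' from [replication_rate()]'s mixture form evaluated at the transformed
#' threshold `z_t' = (z_t + w_d |z_d|) / w_r`. With `n_r = 0` the combined
#' dataset is the discovery set and the probability degenerates to the
#' indicator `-|z_d| < z_t`.
#'
#' @inheritParams combined_expectation
#' @param z_threshold One-tailed threshold, `<= 0`.
#' @return Probabilities in `[0, 1]`.
#' @export
combined_replication_rate <- function(z_d, n_d, n_r, params, het,
                                      z_threshold) {
  if (any(z_threshold > 0)) stop("'z_threshold' must be <= 0")
  if (any(n_d <= 0)) stop("'n_d' must be > 0")
  if (any(n_r < 0)) stop("'n_r' must be >= 0")
  n_dr <- n_d + n_r
  w_d <- sqrt(n_d / n_dr)
  w_r <- sqrt(n_r / n_dr)
  if (all(n_r == 0)) return(as.numeric(-abs(z_d) < z_threshold))
  rp <- replication_posterior(z_d, n_d, n_r, params, het)
  z_t_prime <- (z_threshold + w_d * abs(z_d)) / w_r
  (1 - rp$tdr) * stats::pnorm(z_t_prime, -abs(rp$m_u), sqrt(rp$s_u_sq)) +
    rp$tdr * stats::pnorm(z_t_prime, -abs(rp$m_s), sqrt(rp$s_s_sq))
}

#' Effective sample size of a study
#'
#' For case-control studies the z-score non-centrality grows with the
#' harmonic-mean-based effective size `n_eff = 2 / (1/n_cases +
#' 1/n_controls)`; a balanced study of `N` subjects therefore has
#' `n_eff = N / 2`. Quantitative-trait studies use the subject count
#' directly.
#'
#' @param n_cases,n_controls Case and control counts (case-control design).
#' @param n_quant Subject count (quantitative trait); used when both
#'   case/control counts are missing.
#' @return Effective sample size(s).
#' @export
effective_n <- function(n_cases = NULL, n_controls = NULL, n_quant = NULL) {
  if (!is.null(n_cases) && !is.null(n_controls)) {
    if (any(n_cases <= 0) || any(n_controls <= 0))
      stop("case/control counts must be > 0")
    return(2 / (1 / n_cases + 1 / n_controls))
  }
  if (!is.null(n_quant)) {
    if (any(n_quant <= 0)) stop("'n_quant' must be > 0")
    return(as.numeric(n_quant))
  }
  stop("supply either n_cases and n_controls, or n_quant")
}

#' Total subjects implied by an effective sample size
#'
#' Inverts the balanced case-control convention `n_eff = N / 2`: a
#' case-control effective size `n_eff` corresponds to `2 * n_eff` subjects
#' split equally between cases and controls. Quantitative-trait studies
#' are unchanged.
#'
#' @param n_eff Effective sample size(s).
#' @param design `"case-control"` (default) or `"quantitative"`.
#' @return Total subject count(s).
#' @export
total_n_from_eff <- function(n_eff, design = c("case-control",
                                               "quantitative")) {
  design <- match.arg(design)
  if (any(n_eff <= 0)) stop("'n_eff' must be > 0")
  if (design == "case-control") 2 * n_eff else n_eff
}
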