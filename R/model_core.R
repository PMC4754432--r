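#' SNP heterozygosity
#'
#' Allele-count variance `H = 2 p (1 - p)` for allele frequency `p`
#' (symmetric in `p` and `1 - p`), the quantity by which per-allele effect
#' variances are scaled, together with sample size, onto the z-score scale.
#'
#' @param allele_freq Allele frequency (or frequencies), each in `[0, 1]`.
#' @return Heterozygosity values in `[0, 0.5]`.
#' @examples
#' heterozygosity(c(0.5, 0.1))
#' @export
heterozygosity <- function(allele_freq) {
  if (any(!is.finite(allele_freq)) ||
      any(allele_freq < 0) || any(allele_freq > 1))
    stop("allele frequencies must lie in [0, 1]")
  2 * allele_freq * (1 - allele_freq)
}

# Clamp H away from 0 so no mixture arm is exactly zero-variance through a
# monomorphic SNP; truly monomorphic SNPs are removed by QC upstream.
.clamp_het <- function(het) pmin(pmax(het, 1e-12), 0.5)

#' Z-scale variances of the two effect classes
#'
#' The per-allele variances are mapped onto the z-score scale by the
#' effective sample size and heterozygosity:
#' `sigma1_sq = sigma_a_sq * n_eff * het` (ubiquitous effects) and
#' `sigma2_sq = sigma_b_sq * n_eff * het` (additional sparse effects).
#'
#' @param params A [mixture_params()] object.
#' @param n_eff Effective sample size(s), `> 0`.
#' @param het Heterozygosity value(s) in `[0, 0.5]`.
#' @return A list with vectors `sigma1_sq` and `sigma2_sq`.
#' @export
scaled_variances <- function(params, n_eff, het) {
  params <- as_mixture_params(params)
  if (any(n_eff <= 0)) stop("'n_eff' must be > 0")
  if (any(het < 0 | het > 0.5)) stop("'het' must lie in [0, 0.5]")
  nh <- n_eff * .clamp_het(het)
  list(sigma1_sq = params$sigma_a_sq * nh,
       sigma2_sq = params$sigma_b_sq * nh)
}

# log(exp(a) + exp(b)) robust to underflow; handles -Inf arms (pi1 = 0 or 1)
.logaddexp <- function(a, b) {
  m <- pmax(a, b)
  out <- m + log1p(exp(pmin(a, b) - m))
  out[!is.finite(m)] <- m[!is.finite(m)]
  out
}

# Per-arm log densities of the mixture; all downstream densities and tdr are
# assembled from these in log space, since the sparse-arm weight underflows
# naively for |z| > 8.
.mixture_logarms <- function(z, params, n_eff, het) {
  sv <- scaled_variances(params, n_eff, het)
  v_u <- params$sigma0_sq + sv$sigma1_sq
  v_s <- v_u + sv$sigma2_sq
  list(l0 = log1p(-params$pi1) + stats::dnorm(z, 0, sqrt(v_u), log = TRUE),
       l1 = log(params$pi1) + stats::dnorm(z, 0, sqrt(v_s), log = TRUE),
       v_u = v_u, v_s = v_s, sv = sv)
}

#' Mixture density and distribution of z-scores
#'
#' Marginal model for an observed z-score at a SNP with heterozygosity `het`
#' in a study of effective size `n_eff`: a weight-`(1 - pi1)` normal with
#' variance `sigma0_sq + sigma1_sq` (null noise plus ubiquitous effects) and
#' a weight-`pi1` normal with additional sparse variance `sigma2_sq`.
#'
#' @inheritParams scaled_variances
#' @param z Z-score(s).
#' @param log Return the log density?
#' @return `mixture_pdf()` the density, `mixture_cdf()` the cumulative
#'   probability `Pr(Z <= z)`.
#' @export
mixture_pdf <- function(z, params, n_eff, het, log = FALSE) {
  la <- .mixture_logarms(z, as_mixture_params(params), n_eff, het)
  lf <- .logaddexp(la$l0, la$l1)
  if (log) lf else exp(lf)
}

#' @rdname mixture_pdf
#' @export
mixture_cdf <- function(z, params, n_eff, het) {
  params <- as_mixture_params(params)
  sv <- scaled_variances(params, n_eff, het)
  v_u <- params$sigma0_sq + sv$sigma1_sq
  v_s <- v_u + sv$sigma2_sq
  (1 - params$pi1) * stats::pnorm(z, 0, sqrt(v_u)) +
    params$pi1 * stats::pnorm(z, 0, sqrt(v_s))
}

#' Local true discovery rate
#'
#' Posterior probability that a SNP with observed z-score `z` belongs to the
#' sparse (large-effect) class: `tdr(z) = pi1 * phi(z; 0, s0+s1+s2) / f(z)`.
#' Symmetric in `z`; identically `pi1` when `sigma_b_sq = 0` (the arms
#' coincide and the model is degenerate with respect to `pi1`).
#'
#' @inheritParams mixture_pdf
#' @return Probabilities in `[0, 1]`.
#' @export
tdr <- function(z, params, n_eff, het) {
  params <- as_mixture_params(params)
  la <- .mixture_logarms(z, params, n_eff, het)
  if (params$pi1 == 0) return(rep(0, length(la$l0)))
  if (params$pi1 == 1) return(rep(1, length(la$l1)))
  exp(la$l1 - .logaddexp(la$l0, la$l1))
}

#' Posterior moments of the true effect size given z
#'
#' The posterior of the true effect size `delta` given `z` is a two-arm
#' normal mixture with weight `tdr(z)` on the sparse arm. This returns the
#' arm means and variances together with `tdr`:
#' `mu_u = z s1/(s0+s1)`, `mu_s = z (s1+s2)/(s0+s1+s2)`,
#' `var_u = s0 s1/(s0+s1)`, `var_s = s0 (s1+s2)/(s0+s1+s2)`
#' (writing `s0, s1, s2` for `sigma0_sq` and the z-scale class variances).
#'
#' @inheritParams mixture_pdf
#' @return A data frame with columns `tdr`, `mu_u`, `mu_s`, `var_u`, `var_s`.
#' @export
posterior_moments <- function(z, params, n_eff, het) {
  params <- as_mixture_params(params)
  sv <- scaled_variances(params, n_eff, het)
  s0 <- params$sigma0_sq
  s1 <- sv$sigma1_sq
  s12 <- sv$sigma1_sq + sv$sigma2_sq
  data.frame(tdr = tdr(z, params, n_eff, het),
             mu_u = z * s1 / (s0 + s1),
             mu_s = z * s12 / (s0 + s12),
             var_u = s0 * s1 / (s0 + s1),
             var_s = s0 * s12 / (s0 + s12))
}

#' Posterior density of the true effect size
#'
#' `Pr(delta | z) = (1 - tdr) phi(delta; mu_u, var_u) +
#'  tdr phi(delta; mu_s, var_s)`.
#'
#' @inheritParams mixture_pdf
#' @param delta Effect-size value(s) at which to evaluate the density.
#' @return Density values.
#' @export
posterior_pdf <- function(delta, z, params, n_eff, het) {
  pm <- posterior_moments(z, params, n_eff, het)
  (1 - pm$tdr) * stats::dnorm(delta, pm$mu_u, sqrt(pm$var_u)) +
    pm$tdr * stats::dnorm(delta, pm$mu_s, sqrt(pm$var_s))
}

#' Expected effect-size components given z
#'
#' Two equivalent decompositions of the posterior mean effect size: into the
#' generative per-class parts (`e_delta_a` from ubiquitous effects carried by
#' every SNP, `e_delta_b` from the additional sparse effect) and into the
#' mixture-arm parts (`e_delta_u = (1 - tdr) mu_u`,
#' `e_delta_s = tdr mu_s`). The two decompositions sum to the same total
#' posterior mean.
#'
#' @inheritParams mixture_pdf
#' @return Data frame with columns `e_delta_a`, `e_delta_b`, `e_delta_u`,
#'   `e_delta_s`, `e_delta` (the common total).
#' @export
expected_components <- function(z, params, n_eff, het) {
  params <- as_mixture_params(params)
  sv <- scaled_variances(params, n_eff, het)
  s0 <- params$sigma0_sq
  s1 <- sv$sigma1_sq
  s12 <- sv$sigma1_sq + sv$sigma2_sq
  t <- tdr(z, params, n_eff, het)
  e_a <- z * (t * s1 / (s0 + s12) + (1 - t) * s1 / (s0 + s1))
  e_b <- z * t * sv$sigma2_sq / (s0 + s12)
  e_u <- (1 - t) * z * s1 / (s0 + s1)
  e_s <- t * z * s12 / (s0 + s12)
  data.frame(e_delta_a = e_a, e_delta_b = e_b,
             e_delta_u = e_u, e_delta_s = e_s,
             e_delta = e_u + e_s)
}

#' Posterior second moment of the true effect size
#'
#' `E(delta^2 | z)`, the quantity that replaces `z^2` in unbiased estimates
#' of the per-SNP contribution to phenotypic variance:
#' `(1-tdr) var_u + tdr var_s + tdr (1-tdr) (mu_s - mu_u)^2 +
#'  [(1-tdr) mu_u + tdr mu_s]^2`.
#'
#' @inheritParams mixture_pdf
#' @return Nonnegative values, each `>= E(delta|z)^2`.
#' @export
expected_delta_sq <- function(z, params, n_eff, het) {
  pm <- posterior_moments(z, params, n_eff, het)
  m <- (1 - pm$tdr) * pm$mu_u + pm$tdr * pm$mu_s
  (1 - pm$tdr) * pm$var_u + pm$tdr * pm$var_s +
    pm$tdr * (1 - pm$tdr) * (pm$mu_s - pm$mu_u)^2 + m^2
}

#' Winner's-curse overestimation factor
#'
#' Ratio `z^2 / E(delta^2 | z)`: the factor by which the per-SNP variance
#' contribution is over-estimated when the raw squared z-score (equivalently
#' the squared regression coefficient) is used in place of the posterior
#' second moment of the true effect.
#'
#' @inheritParams mixture_pdf
#' @return Ratios `>= 1` whenever noise is present (`sigma0_sq > 0`).
#' @export
overestimation_factor <- function(z, params, n_eff, het) {
  if (any(z == 0)) stop("overestimation factor is undefined at z = 0")
  z^2 / expected_delta_sq(z, params, n_eff, het)
}

#' Power to pass a one-tailed significance threshold given the effect size
#'
#' Probability that a SNP with true effect size `delta` yields a z-score
#' more extreme (same-signed) than the one-tailed threshold `z_threshold`:
#' `Phi(z_threshold; -|delta|, sigma0_sq)`.
#'
#' @param delta True effect size(s) on the z scale.
#' @param z_threshold One-tailed threshold, `<= 0` (see [p_to_z()]).
#' @param params A [mixture_params()] object (only `sigma0_sq` is used).
#' @return Probabilities in `[0, 1]`, increasing in `|delta|`.
#' @export
power_given_delta <- function(delta, z_threshold, params) {
  params <- as_mixture_params(params)
  if (any(z_threshold > 0)) stop("'z_threshold' must be <= 0")
  stats::pnorm(z_threshold, mean = -abs(delta), sd = sqrt(params$sigma0_sq))
}

#' One-tailed p-value threshold to z-score threshold
#'
#' The (negative) standard-normal quantile at `p_threshold`; e.g. `0.05`
#' maps to `-1.645` and genome-wide significance `5e-8` to `-5.33`.
#'
#' @param p_threshold Probability in `(0, 1)`.
#' @return Z-score threshold(s) (negative for `p < 0.5`).
#' @export
p_to_z <- function(p_threshold) {
  if (any(p_threshold <= 0 | p_threshold >= 1))
    stop("'p_threshold' must lie strictly within (0, 1)")
  stats::qnorm(p_threshold)
}
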