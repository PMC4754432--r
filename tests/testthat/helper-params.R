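# Reference parameter sets used across the suite.
# High-polygenicity set (schizophrenia-scale fit): pi1 ~ 4e-2.
scz_params <- function() {
  mixture_params(pi1 = 0.037, sigma0_sq = 1.014^2,
                 sigma_a_sq = 0.0057^2, sigma_b_sq = 0.020^2)
}

# Low-polygenicity set (putamen-volume-scale fit): pi1 ~ 1e-3.
putamen_params <- function() {
  mixture_params(pi1 = 0.0010, sigma0_sq = 1.002^2,
                 sigma_a_sq = 0.0033^2, sigma_b_sq = 0.034^2)
}

# Pure-noise model: no genetic signal of either class.
null_params <- function(sigma0_sq = 1) {
  mixture_params(pi1 = 0, sigma0_sq = sigma0_sq,
                 sigma_a_sq = 0, sigma_b_sq = 0)
}

# Random valid parameter draws for property-style loops.
random_params <- function() {
  mixture_params(pi1 = runif(1, 0.001, 0.2),
                 sigma0_sq = runif(1, 0.8, 1.3),
                 sigma_a_sq = 10^runif(1, -6, -4),
                 sigma_b_sq = 10^runif(1, -5, -3))
}
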