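# Independent Monte-Carlo oracle for the conditional (replication)
# quantities: simulates the generative story directly — shared class and
# per-allele effects, independent per-stage noise — without touching any
# of the package's closed-form code paths.
oracle_draws <- function(params, n_d, n_r, het, n_draws, seed) {
  set.seed(seed)
  cls <- rbinom(n_draws, 1L, params$pi1)
  a <- rnorm(n_draws, 0, sqrt(params$sigma_a_sq))
  b <- rnorm(n_draws, 0, sqrt(params$sigma_b_sq)) * cls
  g <- a + b
  delta_d <- sqrt(n_d * het) * g
  delta_r <- sqrt(n_r * het) * g
  s0 <- sqrt(params$sigma0_sq)
  data.frame(cls = cls,
             delta_d = delta_d,
             delta_r = delta_r,
             z_d = delta_d + rnorm(n_draws, 0, s0),
             z_r = delta_r + rnorm(n_draws, 0, s0))
}

# Select oracle draws whose discovery z-score falls in a narrow bin.
oracle_bin <- function(draws, z0, width = 0.2) {
  draws[abs(draws$z_d - z0) < width / 2, , drop = FALSE]
}

# Mean of x with its Monte-Carlo standard error.
mc_mean <- function(x) {
  list(mean = mean(x), se = stats::sd(x) / sqrt(length(x)))
}

# Sample variance of x with a (distribution-free) standard error.
mc_var <- function(x) {
  d2 <- (x - mean(x))^2
  list(var = stats::var(x), se = stats::sd(d2) / sqrt(length(x)))
}

expect_within_3se <- function(observed, mc, label = "") {
  expect_lt(abs(observed - mc[[1]]), 3 * mc$se + 1e-12, label = label)
}
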