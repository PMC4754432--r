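# Internal optimizer scale: variances on log scale, pi1 on logit scale,
# so Nelder-Mead works unconstrained while the public API stays natural.
.FIT_KEYS <- c("pi1", "sigma0_sq", "sigma_a_sq", "sigma_b_sq")

.to_internal <- function(params) {
  # clamp so degenerate starts (pi1 or a variance at 0) stay finite
  c(pi1 = stats::qlogis(min(max(params$pi1, 1e-8), 1 - 1e-8)),
    sigma0_sq = log(max(params$sigma0_sq, 1e-12)),
    sigma_a_sq = log(max(params$sigma_a_sq, 1e-12)),
    sigma_b_sq = log(max(params$sigma_b_sq, 1e-12)))
}

.from_internal <- function(theta, fixed = NULL) {
  full <- list(pi1 = NA_real_, sigma0_sq = NA_real_,
               sigma_a_sq = NA_real_, sigma_b_sq = NA_real_)
  for (k in names(fixed)) full[[k]] <- fixed[[k]]
  free <- setdiff(.FIT_KEYS, names(fixed))
  stopifnot(length(theta) == length(free))
  names(theta) <- free
  if ("pi1" %in% free) full$pi1 <- stats::plogis(theta[["pi1"]])
  for (k in intersect(free, .FIT_KEYS[-1])) full[[k]] <- exp(theta[[k]])
  mixture_params(full$pi1, full$sigma0_sq, full$sigma_a_sq,
                 full$sigma_b_sq)
}

#' Model replication curves at the empirical binning layout
#'
#' Evaluates the model's expected replication z-score (`delta`) and
#' expected squared replication z-score (`eta`) at each row of a stacked
#' empirical curve table — i.e. at the bin centre `center`, the
#' realization's `n_d`/`n_r`, and the bin's count-weighted mean
#' heterozygosity.
#'
#' @param params A [mixture_params()] object.
#' @param curves A [split_curves()] data frame (columns `center`, `n_d`,
#'   `n_r`, `mean_het`; rows with undefined `mean_het` get the global
#'   mean).
#' @return Data frame with columns `delta` and `eta` aligned with
#'   `curves` rows.
#' @export
model_curves <- function(params, curves) {
  het <- curves$mean_het
  if (anyNA(het)) het[is.na(het)] <- mean(het, na.rm = TRUE)
  rp <- replication_posterior(curves$center, curves$n_d, curves$n_r,
                              params, het)
  data.frame(delta = rp$e_delta_r, eta = rp$e_z_r_sq)
}

#' Weighted least-squares cost of a parameter set
#'
#' Sum over all (fraction, repetition, bin) cells of
#' `count * [(mean_zr - delta)^2 + (mean_zr_sq - eta)^2]`, where `delta`
#' and `eta` are the [model_curves()] predictions. Bins with zero count
#' contribute nothing. Both the first- and second-moment terms are
#' needed: the first moment alone does not pin down the parameters.
#'
#' @inheritParams model_curves
#' @return Nonnegative scalar.
#' @export
fit_cost <- function(params, curves) {
  use <- curves$count > 0
  cc <- curves[use, , drop = FALSE]
  mc <- model_curves(params, cc)
  sum(cc$count * ((cc$mean_zr - mc$delta)^2 +
                    (cc$mean_zr_sq - mc$eta)^2))
}

#' Fit the four mixture parameters to empirical replication curves
#'
#' Derivative-free Nelder-Mead minimization of [fit_cost()] over
#' (logit `pi1`, log variances), with multiple jittered starts and
#' best-of selection. Any parameter can be held fixed (e.g.
#' `fixed = list(sigma_a_sq = 0)` for the degenerate no-ubiquitous-effects
#' variant); fixed zero variances stay exactly zero.
#'
#' @param curves Stacked empirical curves from [split_curves()].
#' @param start Starting parameters (default `pi1 = 0.01`,
#'   `sigma0_sq = 1`, `sigma_a_sq = 1e-5`, `sigma_b_sq = 1e-4`, a neutral
#'   order-of-magnitude start).
#' @param n_starts Number of starts, the first unjittered (default `5`).
#' @param seed Integer seed for the start jitter.
#' @param fixed Named list of parameters to hold fixed (natural scale).
#' @param reltol Relative cost-change convergence tolerance (default
#'   `1e-6`).
#' @param maxit Maximum function evaluations per start (default `2000`).
#' @return An object of class `gwasmix_fit`: `params`, `cost`, `n_evals`,
#'   `converged`, `start_costs`, `fixed`, `model` (the fitted `delta`,
#'   `eta` curves aligned with `curves`), and `curves`.
#' @export
fit_mixture <- function(curves, start = NULL, n_starts = 5, seed = NULL,
                        fixed = NULL, reltol = 1e-6, maxit = 2000) {
  if (!nrow(curves) || !any(curves$count > 0))
    stop("empirical curves are empty")
  if (is.null(start))
    start <- mixture_params(0.01, 1, 1e-5, 1e-4)
  start <- as_mixture_params(start)
  if (!is.null(fixed)) {
    bad <- setdiff(names(fixed), .FIT_KEYS)
    if (length(bad)) stop("unknown fixed parameter(s): ",
                          paste(bad, collapse = ", "))
  }
  free <- setdiff(.FIT_KEYS, names(fixed))
  if (!length(free)) stop("all parameters fixed; nothing to fit")
  theta0 <- .to_internal(start)[free]
  use <- curves$count > 0
  cc <- curves[use, , drop = FALSE]
  het <- cc$mean_het
  if (anyNA(het)) het[is.na(het)] <- mean(het, na.rm = TRUE)
  objective <- function(theta) {
    p <- .from_internal(theta, fixed)
    rp <- replication_posterior(cc$center, cc$n_d, cc$n_r, p, het)
    val <- sum(cc$count * ((cc$mean_zr - rp$e_delta_r)^2 +
                             (cc$mean_zr_sq - rp$e_z_r_sq)^2))
    if (!is.finite(val)) .Machine$double.xmax else val
  }
  jitters <- with_seed(seed, {
    lapply(seq_len(n_starts), function(s) {
      if (s == 1L) rep(0, length(free)) else
        stats::rnorm(length(free), 0, 0.7)
    })
  })
  runs <- lapply(jitters, function(j) {
    stats::optim(theta0 + j, objective, method = "Nelder-Mead",
                 control = list(reltol = reltol, maxit = maxit))
  })
  costs <- vapply(runs, `[[`, numeric(1), "value")
  best <- runs[[which.min(costs)]]
  params <- .from_internal(best$par, fixed)
  structure(list(params = params,
                 cost = best$value,
                 n_evals = sum(vapply(runs, function(r)
                   r$counts[["function"]], numeric(1))),
                 converged = best$convergence == 0,
                 start_costs = costs,
                 fixed = fixed,
                 model = model_curves(params, curves),
                 curves = curves),
            class = "gwasmix_fit")
}

#' @export
print.gwasmix_fit <- function(x, ...) {
  cat("GWAS z-score mixture fit",
      if (!x$converged) "(optimizer did not report convergence)", "\n")
  print(x$params)
  cat(sprintf("  cost = %.6g over %d populated cells; %d evaluations\n",
              x$cost, sum(x$curves$count > 0), x$n_evals))
  if (!is.null(x$ci95)) {
    cat("  95% bootstrap intervals (natural scale):\n")
    for (k in rownames(x$ci95))
      cat(sprintf("    %-10s [%.4g; %.4g]\n", k, x$ci95[k, 1],
                  x$ci95[k, 2]))
  }
  invisible(x)
}

#' Parametric-bootstrap confidence intervals for a fit
#'
#' Regenerates `B` synthetic cohorts from the fitted parameters using a
#' template study layout, reruns the split/bin pipeline and refit on
#' each, and takes the 2.5/97.5 percentiles of the refitted parameters
#' on the internal (log / logit) scale, mapped back to the natural
#' scale — intervals are therefore asymmetric, as sampling distributions
#' of variance parameters are. With `B < 20` a warning is issued and the
#' full range of the refits is reported instead of percentiles.
#'
#' @param fit A [fit_mixture()] result.
#' @param template List with `studies`, `m_snps`, and optionally
#'   `maf_range`, `fractions`, `n_reps`, `p_threshold`, `n_bins`.
#' @param B Bootstrap replicate count (default `50`).
#' @param seed Integer seed.
#' @return The fit object with a `ci95` matrix (rows = parameters,
#'   columns `lower`, `upper`) and `boot` (the refit draws) attached.
#' @export
confidence_intervals <- function(fit, template, B = 50, seed = NULL) {
  stopifnot(inherits(fit, "gwasmix_fit"))
  widen <- B < 20
  if (widen)
    warning("B < 20 bootstrap replicates: reporting the full refit range")
  fractions <- template$fractions %||% seq(0.1, 0.9, by = 0.1)
  n_reps <- template$n_reps %||% 10
  draws <- matrix(NA_real_, nrow = B, ncol = 4,
                  dimnames = list(NULL, .FIT_KEYS))
  for (b in seq_len(B)) {
    sub <- if (is.null(seed)) NULL else substream_seed(seed, "boot", b)
    sim <- generate_from_fitted(fit, template, seed = sub)
    splits <- plan_splits(sim$cohort$studies, fractions = fractions,
                          n_reps = n_reps, seed = sub)
    curves <- split_curves(sim$cohort, splits,
                           p_threshold = template$p_threshold %||% 0.05,
                           n_bins = template$n_bins %||% 200)
    refit <- fit_mixture(curves, start = fit$params, n_starts = 1,
                         fixed = fit$fixed)
    draws[b, ] <- unlist(refit$params)
  }
  internal <- draws
  internal[, "pi1"] <- stats::qlogis(pmin(pmax(draws[, "pi1"], 1e-12),
                                          1 - 1e-12))
  internal[, -1] <- log(pmax(draws[, -1], 1e-300))
  probs <- if (widen) c(0, 1) else c(0.025, 0.975)
  qs <- apply(internal, 2, stats::quantile, probs = probs, names = FALSE)
  ci <- cbind(lower = c(stats::plogis(qs[1, 1]), exp(qs[1, -1])),
              upper = c(stats::plogis(qs[2, 1]), exp(qs[2, -1])))
  rownames(ci) <- .FIT_KEYS
  fit$ci95 <- ci
  fit$boot <- draws
  fit
}
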