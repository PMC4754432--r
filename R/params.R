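#' Model parameters for the two-component z-score mixture
#'
#' Container for the four parameters of the Gaussian mixture model of GWAS
#' z-scores: the polygenicity index `pi1` (prior probability that a SNP
#' carries a sparse, large effect), the null/noise variance `sigma0_sq`
#' (variance of the non-replicating component, close to 1 but possibly
#' inflated by population substructure), and the per-allele effect variances
#' `sigma_a_sq` (ubiquitous small effects) and `sigma_b_sq` (additional
#' sparse effects). The ubiquitous-class prior `pi0 = 1 - pi1` is always
#' derived, never stored.
#'
#' On the z-score scale the per-allele variances enter multiplied by
#' `N * H`, where `N` is the effective sample size and `H = 2p(1-p)` the SNP
#' heterozygosity; see [scaled_variances()].
#'
#' @param pi1 Prior probability of the sparse class, in `[0, 1]`.
#' @param sigma0_sq Variance of the null (noise) component, `> 0`.
#' @param sigma_a_sq Per-allele variance of ubiquitous effects, `>= 0`.
#' @param sigma_b_sq Per-allele additional variance of sparse effects, `>= 0`.
#'
#' @return An object of class `mixture_params` (a named list of the four
#'   natural-scale parameters).
#' @examples
#' p <- mixture_params(pi1 = 0.037, sigma0_sq = 1.014^2,
#'                     sigma_a_sq = 0.0057^2, sigma_b_sq = 0.020^2)
#' p
#' @export
mixture_params <- function(pi1, sigma0_sq, sigma_a_sq, sigma_b_sq) {
  stopifnot(is.numeric(pi1), length(pi1) == 1L,
            is.numeric(sigma0_sq), length(sigma0_sq) == 1L,
            is.numeric(sigma_a_sq), length(sigma_a_sq) == 1L,
            is.numeric(sigma_b_sq), length(sigma_b_sq) == 1L)
  if (is.na(pi1) || pi1 < 0 || pi1 > 1)
    stop("'pi1' must be a probability in [0, 1]")
  if (is.na(sigma0_sq) || sigma0_sq <= 0)
    stop("'sigma0_sq' must be > 0")
  if (is.na(sigma_a_sq) || sigma_a_sq < 0)
    stop("'sigma_a_sq' must be >= 0")
  if (is.na(sigma_b_sq) || sigma_b_sq < 0)
    stop("'sigma_b_sq' must be >= 0")
  structure(list(pi1 = pi1, sigma0_sq = sigma0_sq,
                 sigma_a_sq = sigma_a_sq, sigma_b_sq = sigma_b_sq),
            class = "mixture_params")
}

#' @export
print.mixture_params <- function(x, digits = 4, ...) {
  cat("Two-component GWAS z-score mixture parameters\n")
  cat(sprintf("  pi1     (polygenicity index) : %s\n",
              format(x$pi1, digits = digits)))
  cat(sprintf("  sigma0  (null/noise sd)      : %s   [sigma0^2 = %s]\n",
              format(sqrt(x$sigma0_sq), digits = digits),
              format(x$sigma0_sq, digits = digits)))
  cat(sprintf("  sigma_a (ubiquitous, per allele): %s\n",
              format(sqrt(x$sigma_a_sq), digits = digits)))
  cat(sprintf("  sigma_b (sparse, per allele)    : %s\n",
              format(sqrt(x$sigma_b_sq), digits = digits)))
  invisible(x)
}

as_mixture_params <- function(x) {
  if (inherits(x, "mixture_params")) return(x)
  if (is.list(x) || is.numeric(x)) {
    x <- as.list(x)
    need <- c("pi1", "sigma0_sq", "sigma_a_sq", "sigma_b_sq")
    if (!all(need %in% names(x)))
      stop("parameter list must have fields: ", paste(need, collapse = ", "))
    return(mixture_params(x$pi1, x$sigma0_sq, x$sigma_a_sq, x$sigma_b_sq))
  }
  stop("cannot interpret 'params' as mixture parameters")
}

#' Read and write mixture parameters as a flat key-value config
#'
#' The on-disk format is a minimal TOML-style block of `key = value` lines
#' with the natural-scale keys `pi1`, `sigma0_sq`, `sigma_a_sq`,
#' `sigma_b_sq`. Comment lines (`#`) and a `[model]` section header are
#' tolerated on read.
#'
#' @param path File path.
#' @param params A [mixture_params()] object.
#' @return `read_params()` returns a `mixture_params` object;
#'   `write_params()` returns `path` invisibly.
#' @export
read_params <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#") &
                   !grepl("^\\[", lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- lengths(kv) != 2L
  if (any(bad)) stop("malformed config line(s): ",
                     paste(lines[bad], collapse = "; "))
  vals <- vapply(kv, function(p) suppressWarnings(as.numeric(trimws(p[2]))),
                 numeric(1))
  names(vals) <- vapply(kv, function(p) trimws(p[1]), character(1))
  if (anyNA(vals)) stop("non-numeric value in config: ", path)
  as_mixture_params(as.list(vals))
}

#' @rdname read_params
#' @export
write_params <- function(params, path) {
  params <- as_mixture_params(params)
  writeLines(c("[model]",
               sprintf("pi1 = %.17g", params$pi1),
               sprintf("sigma0_sq = %.17g", params$sigma0_sq),
               sprintf("sigma_a_sq = %.17g", params$sigma_a_sq),
               sprintf("sigma_b_sq = %.17g", params$sigma_b_sq)),
             path)
  invisible(path)
}
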