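# Deterministic sub-seed derivation so that every stochastic stage of a
# pipeline (generation, per-repetition pruning, splits, bootstrap) draws
# from its own reproducible stream under one master seed.
substream_seed <- function(seed, ...) {
  labels <- paste(c(seed, ...), collapse = "/")
  h <- 0
  for (cp in utf8ToInt(labels)) h <- (h * 31 + cp) %% 2147483647
  as.integer(h)
}

with_seed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

#' Generate synthetic multi-substudy GWAS summary statistics
#'
#' Draws per-SNP allele frequencies, class labels and per-allele effects
#' from the generative model behind the z-score mixture, then per-study
#' z-scores `z = delta + eps` where `delta = sqrt(n_eff * het) * (a + b)`
#' is shared across substudies (with `b = 0` outside the sparse class) and
#' `eps ~ N(0, sigma0_sq)` is drawn independently per substudy. The
#' returned truth table makes the unobservable decomposition available for
#' validation.
#'
#' Optional LD blocks emulate tagging: each block has a causal member
#' whose effect the remaining members receive attenuated by a per-member
#' signed correlation `r` (drawn uniformly from `ld_blocks$r_range`), with
#' the within-block noise correlated accordingly; the implied pairwise
#' `r^2` table is emitted alongside.
#'
#' @param params A [mixture_params()] object.
#' @param studies Study manifest (`study_id`, `n_eff`), e.g.
#'   [default_studies()].
#' @param m_snps Number of SNPs to simulate.
#' @param maf_range Lower/upper bounds of the uniform minor-allele
#'   frequency law (defaults to the post-QC range `(0.005, 0.5)`).
#' @param seed Integer seed (optional; the current RNG state is used when
#'   `NULL`).
#' @param ld_blocks Optional list with `n_blocks`, `block_size` and
#'   `r_range` describing the tagging structure.
#' @return A list with elements `cohort` (a [gwas_cohort()]), `truth`
#'   (data frame `snp`, `class` (1 = sparse), `a`, `b`) and `ld` (pairwise
#'   `snp_a`, `snp_b`, `r_sq` data frame; empty without `ld_blocks`).
#' @export
generate_cohort <- function(params, studies, m_snps,
                            maf_range = c(0.005, 0.5), seed = NULL,
                            ld_blocks = NULL) {
  params <- as_mixture_params(params)
  if (m_snps < 1) stop("'m_snps' must be >= 1")
  if (length(maf_range) != 2 || maf_range[1] <= 0 || maf_range[2] > 0.5 ||
      maf_range[1] >= maf_range[2])
    stop("'maf_range' must be increasing within (0, 0.5]")
  with_seed(seed, {
    m <- as.integer(m_snps)
    freq <- stats::runif(m, maf_range[1], maf_range[2])
    het <- heterozygosity(freq)
    cls <- stats::rbinom(m, 1L, params$pi1)
    a <- stats::rnorm(m, 0, sqrt(params$sigma_a_sq))
    b <- ifelse(cls == 1L, stats::rnorm(m, 0, sqrt(params$sigma_b_sq)), 0)
    ld <- empty_ld_table()
    if (!is.null(ld_blocks)) {
      blk <- .assign_ld_blocks(m, ld_blocks)
      # tags inherit the causal member's (attenuated) effect and class
      a <- blk$r * a[blk$causal]
      b <- blk$r * b[blk$causal]
      cls <- cls[blk$causal]
      ld <- blk$ld
    }
    n_eff <- studies$n_eff
    s_ids <- as.character(studies$study_id)
    delta <- outer(sqrt(het) * (a + b), sqrt(n_eff))
    eps <- matrix(stats::rnorm(m * length(n_eff), 0,
                               sqrt(params$sigma0_sq)),
                  nrow = m)
    if (!is.null(ld_blocks)) eps <- .correlate_block_noise(eps, blk)
    z <- delta + eps
    colnames(z) <- s_ids
    snp_ids <- sprintf("snp%07d", seq_len(m))
    snps <- data.frame(snp = snp_ids, allele_freq = freq, het = het)
    if (nrow(ld)) {
      ld$snp_a <- snp_ids[ld$snp_a]
      ld$snp_b <- snp_ids[ld$snp_b]
    }
    list(cohort = gwas_cohort(snps, z, studies),
         truth = data.frame(snp = snp_ids, class = cls, a = a, b = b),
         ld = ld)
  })
}

empty_ld_table <- function() {
  data.frame(snp_a = character(), snp_b = character(), r_sq = numeric())
}

# Partition the first n_blocks * block_size SNPs into blocks; member 1 of
# each block is causal (r = 1), the rest get r ~ U(r_range). Remaining
# SNPs are isolated (their own block of one).
.assign_ld_blocks <- function(m, ld_blocks) {
  n_blocks <- ld_blocks$n_blocks
  size <- ld_blocks$block_size
  r_range <- if (is.null(ld_blocks$r_range)) c(0.6, 0.95) else
    ld_blocks$r_range
  if (n_blocks * size > m)
    stop("LD blocks require more SNPs than simulated")
  idx <- seq_len(n_blocks * size)
  block <- rep(seq_len(n_blocks), each = size)
  pos_in_block <- rep(seq_len(size), times = n_blocks)
  causal_of_block <- idx[pos_in_block == 1L]
  causal <- seq_len(m)                 # isolated SNPs are their own causal
  causal[idx] <- causal_of_block[block]
  r <- rep(1, m)
  tags <- idx[pos_in_block != 1L]
  r[tags] <- stats::runif(length(tags), r_range[1], r_range[2])
  pairs <- do.call(rbind, lapply(seq_len(n_blocks), function(bk) {
    members <- idx[block == bk]
    cmb <- utils::combn(members, 2)
    data.frame(snp_a = cmb[1, ], snp_b = cmb[2, ],
               r_sq = (r[cmb[1, ]] * r[cmb[2, ]])^2)
  }))
  list(causal = causal, r = r, block = block, idx = idx,
       tags = tags, ld = pairs)
}

# Within a block, tag noise = r * causal noise + sqrt(1 - r^2) * own noise,
# giving corr(eps_tag, eps_causal) = r consistently with the emitted r^2.
.correlate_block_noise <- function(eps, blk) {
  tags <- blk$tags
  if (!length(tags)) return(eps)
  r_t <- blk$r[tags]
  eps[tags, ] <- r_t * eps[blk$causal[tags], , drop = FALSE] +
    sqrt(1 - r_t^2) * eps[tags, , drop = FALSE]
  eps
}

#' Regenerate a synthetic cohort from a fitted model
#'
#' Parametric-bootstrap engine: delegates to [generate_cohort()] with the
#' fitted parameters and a template describing the study layout and SNP
#' count, so refits of the regenerated data estimate the sampling
#' distribution of the parameters.
#'
#' @param fit A [fit_mixture()] result (or a `mixture_params` object).
#' @param template List with `studies`, `m_snps` and optionally
#'   `maf_range`, `ld_blocks`.
#' @param seed Integer seed.
#' @return As [generate_cohort()].
#' @export
generate_from_fitted <- function(fit, template, seed = NULL) {
  params <- if (inherits(fit, "gwasmix_fit")) fit$params else
    as_mixture_params(fit)
  generate_cohort(params, template$studies, template$m_snps,
                  maf_range = template$maf_range %||% c(0.005, 0.5),
                  seed = seed, ld_blocks = template$ld_blocks)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
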