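make_cohort <- function(freq, z, n_eff = rep(1e4, ncol(z))) {
  gwas_cohort(data.frame(snp = sprintf("rs%d", seq_along(freq)),
                         allele_freq = freq),
              z, data.frame(study_id = paste0("s", seq_len(ncol(z))),
                            n_eff = n_eff))
}

test_that("QC keeps polymorphic SNPs above the MAF floor with usable
          z-scores", {
  z <- matrix(rnorm(6), ncol = 2)
  co <- make_cohort(c(0.001, 0.01, 0.3), z)
  kept <- qc_filter(co, maf_min = 0.005)
  expect_equal(nrow(kept$snps), 2L)
  expect_equal(attr(kept, "qc_counts")[["removed_maf"]], 1)
  # maf_min = 0 keeps every polymorphic SNP
  expect_equal(nrow(qc_filter(co, maf_min = 0)$snps), 3L)
  # brute-force agreement on a larger random table
  set.seed(91)
  freq <- runif(1e4, 0, 0.5)
  co2 <- make_cohort(freq, matrix(rnorm(2e4), ncol = 2))
  expect_equal(nrow(qc_filter(co2)$snps), sum(pmin(freq, 1 - freq) > 0.005))
  # non-finite z is rejected, NA (absent) tolerated
  z3 <- matrix(c(1, Inf, 0.5, NA, 2, 1), ncol = 2)
  co3 <- make_cohort(rep(0.2, 3), z3)
  expect_equal(qc_filter(co3)$snps$snp, c("rs1", "rs3"))
  expect_error(qc_filter(make_cohort(0.001, matrix(1))), "every SNP")
})

test_that("random pruning returns a maximal independent set at the r2
          threshold", {
  chain <- data.frame(snp_a = c("A", "B", "A"), snp_b = c("B", "C", "C"),
                      r_sq = c(0.9, 0.9, 0.5))
  snps <- c("A", "B", "C")
  for (s in 1:20) {
    kept <- random_prune(snps, chain, r_sq_max = 0.8, seed = s)
    expect_true(identical(sort(kept), c("A", "C")) ||
                  identical(kept, "B"))
  }
  # no LD: everything kept
  expect_equal(random_prune(snps, chain[0, ]), snps)
  # random graphs: kept set is always independent and maximal
  set.seed(92)
  for (rep in 1:5) {
    m <- 100
    ids <- sprintf("v%03d", 1:m)
    pairs <- t(combn(m, 2))
    pick <- runif(nrow(pairs)) < 0.03
    ld <- data.frame(snp_a = ids[pairs[pick, 1]],
                     snp_b = ids[pairs[pick, 2]],
                     r_sq = runif(sum(pick), 0.5, 1))
    kept <- random_prune(ids, ld, seed = rep)
    high <- ld[ld$r_sq >= 0.8, ]
    in_kept <- function(x) x %in% kept
    expect_false(any(in_kept(high$snp_a) & in_kept(high$snp_b)))
    # maximality: every dropped SNP has a kept high-LD neighbour
    dropped <- setdiff(ids, kept)
    nb_kept <- vapply(dropped, function(v) {
      nb <- c(high$snp_b[high$snp_a == v], high$snp_a[high$snp_b == v])
      any(nb %in% kept)
    }, logical(1))
    expect_true(all(nb_kept))
  }
})

test_that("TLD sums recorded r2 per SNP and the filter thresholds it", {
  ld <- data.frame(snp_a = c("A", "A", "A"), snp_b = c("B", "C", "D"),
                   r_sq = c(0.9, 0.9, 0.5))
  v <- tld(c("A", "B", "E"), ld)
  expect_equal(unname(v), c(2.3, 0.9, 0))
  expect_equal(tld_filter(c("A", "B", "E"), ld, tld_max = 15),
               c("A", "B", "E"))
  expect_equal(tld_filter(c("A", "B", "E"), ld, tld_max = 1),
               c("B", "E"))
  expect_equal(tld_filter(c("A", "B", "E"), ld, tld_max = 0.5), "E")
  expect_error(tld_filter("A", ld, tld_max = 0), "> 0")
  # brute force on synthetic blocks
  set.seed(93)
  sim <- generate_cohort(scz_params(), default_studies(2, 1e4), 500,
                         seed = 7,
                         ld_blocks = list(n_blocks = 10, block_size = 8))
  ids <- sim$cohort$snps$snp
  brute <- vapply(ids, function(s)
    sum(sim$ld$r_sq[sim$ld$snp_a == s | sim$ld$snp_b == s]), numeric(1))
  expect_equal(unname(tld(ids, sim$ld)), unname(brute))
  expect_equal(tld_filter(ids, sim$ld, 3), ids[brute < 3])
})

test_that("split planning hits target effective-sample fractions with
          disjoint study sets", {
  two <- data.frame(study_id = c("a", "b"), n_eff = c(100, 100))
  sp <- plan_splits(two, fractions = 0.5, n_reps = 5, seed = 1)
  for (s in sp) {
    expect_equal(length(s$discovery), 1L)
    expect_equal(s$achieved_fraction, 0.5)
  }
  studies <- default_studies(20, 38163)
  sp <- plan_splits(studies, n_reps = 4, seed = 2)
  expect_length(sp, 9 * 4)
  for (s in sp) {
    expect_length(intersect(s$discovery, s$replication), 0)
    expect_setequal(c(s$discovery, s$replication), studies$study_id)
    expect_lt(abs(s$achieved_fraction - s$fraction), 0.25 * s$fraction + 1e-9)
    expect_equal(s$n_d + s$n_r, sum(studies$n_eff))
  }
  # deterministic given seed
  expect_identical(plan_splits(studies, n_reps = 2, seed = 5),
                   plan_splits(studies, n_reps = 2, seed = 5))
  expect_error(plan_splits(studies[1, , drop = FALSE]), "2 studies")
})

test_that("meta-analysis weights z-scores by the square root of study
          size and handles missingness", {
  expect_equal(meta_z(3, 1e4), 3)
  expect_equal(meta_z(c(1, 1), c(500, 500)), sqrt(2))
  z <- matrix(c(1, NA, 2, 3), ncol = 2)
  out <- meta_z(z, c(100, 300))
  expect_equal(out[1], (sqrt(100) * 1 + sqrt(300) * 2) / sqrt(400))
  expect_equal(out[2], 3)   # only study 2 observed
})

test_that("meta-analyzed substudy z-scores are distributed as one cohort
          at the summed effective size", {
  p <- scz_params()
  studies <- default_studies(5, 30000)
  multi <- generate_cohort(p, studies, 1e5, seed = 94)
  single <- generate_cohort(p, data.frame(study_id = "all", n_eff = 30000),
                            1e5, seed = 95)
  zm <- meta_z(multi$cohort$z, studies$n_eff)
  ks <- suppressWarnings(ks.test(zm, single$cohort$z[, 1]))
  expect_gt(ks$p.value, 0.01)
})

test_that("conditional binning uses 200 half-open bins on [-6,6] and
          masks empty bins", {
  bc <- bin_conditional(numeric(0), numeric(0))
  expect_equal(nrow(bc), 200L)
  expect_equal(bc$center[2] - bc$center[1], 12 / 200)
  expect_true(all(is.na(bc$mean_zr[bc$count == 0])))
  # all z_d in one bin: that bin holds the plain sample means
  z_r <- c(0.5, 1.5, -1)
  bc <- bin_conditional(rep(2.01, 3), z_r, het = c(0.1, 0.2, 0.3))
  k <- which(bc$count > 0)
  expect_length(k, 1L)
  expect_equal(bc$mean_zr[k], mean(z_r))
  expect_equal(bc$mean_zr_sq[k], mean(z_r^2))
  expect_equal(bc$mean_het[k], 0.2)
  expect_equal(bc$repl_frac[k], 0)   # none pass one-tailed 0.05
  # out-of-range discovery scores are excluded
  bc <- bin_conditional(c(-7, 6.5, 0), c(1, 1, 1))
  expect_equal(sum(bc$count), 1)
  # null data: replication fraction calibrates to the threshold
  set.seed(96)
  zd <- rnorm(2e5); zr <- rnorm(2e5)
  bc <- bin_conditional(zd, zr, p_threshold = 0.05)
  busy <- bc$count > 500
  expect_lt(max(abs(bc$repl_frac[busy] - 0.05)), 0.02)
})

test_that("aggregation is a count-weighted average that reduces noise", {
  set.seed(97)
  mk <- function() bin_conditional(rnorm(2000), rnorm(2000))
  one <- mk()
  expect_identical(aggregate_curves(list(one)), one)
  two <- list(mk(), mk())
  agg <- aggregate_curves(two)
  k <- which(two[[1]]$count > 0 & two[[2]]$count > 0)[1]
  w <- c(two[[1]]$count[k], two[[2]]$count[k])
  expect_equal(agg$mean_zr[k],
               sum(w * c(two[[1]]$mean_zr[k], two[[2]]$mean_zr[k])) / sum(w))
  # equal counts reduce to the arithmetic mean
  eq <- lapply(1:2, function(i) {
    bc <- two[[i]]
    bc$count <- rep(1L, nrow(bc))
    bc$mean_zr <- i * 1.0
    bc
  })
  expect_equal(aggregate_curves(eq)$mean_zr, rep(1.5, 200))
  # aggregated curves drift less from truth than single repetitions
  p <- scz_params()
  studies <- default_studies(6, 20000)
  sim <- generate_cohort(p, studies, 4e4, seed = 98)
  splits <- plan_splits(studies, fractions = 0.5, n_reps = 10, seed = 99)
  curves <- lapply(splits, function(sp) {
    d <- match(sp$discovery, studies$study_id)
    r <- match(sp$replication, studies$study_id)
    bc <- bin_conditional(meta_z(sim$cohort$z[, d, drop = FALSE],
                                 studies$n_eff[d]),
                          meta_z(sim$cohort$z[, r, drop = FALSE],
                                 studies$n_eff[r]),
                          het = sim$cohort$snps$het)
    attr(bc, "n_d") <- sp$n_d; attr(bc, "n_r") <- sp$n_r
    bc
  })
  rms <- function(bc, n_d, n_r) {
    k <- bc$count > 30
    truth <- expected_replication_z(bc$center[k], n_d, n_r, p,
                                    bc$mean_het[k])
    sqrt(sum(bc$count[k] * (bc$mean_zr[k] - truth)^2) / sum(bc$count[k]))
  }
  agg <- aggregate_curves(curves)
  rms_singles <- vapply(curves, function(bc)
    rms(bc, attr(bc, "n_d"), attr(bc, "n_r")), numeric(1))
  n_d_bar <- mean(vapply(splits, `[[`, numeric(1), "n_d"))
  expect_lt(rms(agg, n_d_bar, sum(studies$n_eff) - n_d_bar),
            mean(rms_singles))
})

test_that("QQ summaries: null data on the diagonal, model curve tracks
          simulated mixture data", {
  set.seed(100)
  z <- rnorm(5e4)
  qq <- empirical_qq(z)
  expect_equal(qq$prop[qq$p_threshold == 1], 1)
  busy <- qq$p_threshold > 1e-3
  expect_lt(max(abs(qq$prop[busy] - qq$p_threshold[busy])), 0.01)
  # mixture data: empirical curve matches the H-window model curve
  p <- scz_params()
  sim <- generate_cohort(p, data.frame(study_id = "all", n_eff = 34000),
                         1e5, seed = 101)
  z <- sim$cohort$z[, 1]
  grid <- 10^seq(0, -6, length.out = 25)
  emp <- empirical_qq(z, p_grid = grid)
  mod <- model_qq(p, 34000, sim$cohort$snps$het, p_grid = grid)
  n <- length(z)
  se <- sqrt(pmax(mod$prop * (1 - mod$prop), 1e-12) / n)
  expect_true(all(abs(emp$prop - mod$prop) < 4 * se + 3 / n))
})

test_that("the split pipeline stacks per-realization binned curves", {
  p <- putamen_params()
  studies <- default_studies(4, 12596)
  sim <- generate_cohort(p, studies, 2e4, seed = 102)
  splits <- plan_splits(studies, fractions = c(0.3, 0.5), n_reps = 2,
                        seed = 103)
  curves <- split_curves(sim$cohort, splits, seed = 104)
  expect_equal(nrow(curves), 4 * 200)
  expect_setequal(unique(curves$fraction), c(0.3, 0.5))
  expect_equal(sum(curves$count),
               sum(vapply(splits, function(sp) {
                 d <- match(sp$discovery, studies$study_id)
                 zd <- meta_z(sim$cohort$z[, d, drop = FALSE],
                              studies$n_eff[d])
                 sum(zd >= -6 & zd <= 6)
               }, numeric(1))))
})
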