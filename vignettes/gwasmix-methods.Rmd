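---
title: "Modelling GWAS z-scores as a two-component Gaussian mixture"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling GWAS z-scores as a two-component Gaussian mixture}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gwasmix)
```

## The model

A genome-wide association study reduces, per SNP, to a Wald statistic
$z = \hat\beta / \mathrm{se}(\hat\beta)$. gwasmix models each z-score as
$z = \delta + \epsilon$: a *true effect* $\delta$ that replicates in an
independent sample, plus noise $\epsilon \sim N(0, \sigma_0^2)$ that does
not ($\sigma_0^2$ is near 1 but may be inflated by population
substructure; genomic-control correction of the input is deliberately not
performed, because $\sigma_0^2$ absorbs the inflation).

SNPs fall into two classes. All SNPs carry a *ubiquitous* small effect —
interpreted as weak LD with causal variants — with per-allele variance
$\sigma_a^2$. A fraction $\pi_1$ (the **polygenicity index**)
additionally carries a *sparse* large effect, per-allele variance
$\sigma_b^2$, interpreted as strong LD with causal variants. Under
Hardy–Weinberg equilibrium the per-allele variances reach the z scale
multiplied by $N H$, where $N$ is the effective sample size and
$H = 2p(1-p)$ the SNP heterozygosity:
$\sigma_1^2 = \sigma_a^2 N H$, $\sigma_2^2 = \sigma_b^2 N H$. The
marginal density of a z-score is then the two-arm mixture

$$ f(z) = (1-\pi_1)\,\phi(z; 0, \sigma_0^2 + \sigma_1^2)
        + \pi_1\,\phi(z; 0, \sigma_0^2 + \sigma_1^2 + \sigma_2^2), $$

with exactly four parameters
$(\pi_1, \sigma_0^2, \sigma_a^2, \sigma_b^2)$. The posterior probability
that a SNP with score $z$ belongs to the sparse arm is the local true
discovery rate `tdr(z)`; the posterior of $\delta$ given $z$ is itself a
two-arm normal mixture whose arm means are the familiar shrinkage
estimators $z\,\sigma_1^2/(\sigma_0^2+\sigma_1^2)$ (ubiquitous) and
$z\,(\sigma_1^2+\sigma_2^2)/(\sigma_0^2+\sigma_1^2+\sigma_2^2)$
(sparse). Everything downstream — winner's-curse-corrected effect sizes,
replication probabilities, multistage power, heritability projections —
is a closed-form functional of these arms.

Two degenerate variants are worth naming because they motivate the full
model. With $\sigma_a^2 = 0$ the model is the classical two-groups
null/non-null mixture; it cannot reproduce the non-zero slope of the
empirical replication curve near $z_d = 0$. With $\sigma_b^2 = 0$ the
arms coincide, `tdr` is identically $\pi_1$, the model becomes degenerate
with respect to $\pi_1$, and it cannot follow the empirical curves at
$|z_d| > 4$. Both failure modes are asserted in the test suite on
synthetic data.

## Replication and multistage predictions

Effect sizes scale as $\sqrt{N}$, so for a discovery sample $N_d$ and
replication sample $N_r$, the posterior arms of the replication score
$z_r$ given $z_d$ are the discovery arms rescaled by $\sqrt{N_r/N_d}$
and re-noised by $\sigma_0^2$ (`replication_posterior()`). The expected
replication z — the *adjusted* effect size — shrinks $z_d$ towards zero,
which is the model's correction for the winner's curse. The replication
probability at a one-tailed threshold $z_t \le 0$ (same sign as $z_d$,
$p_r < p_t$) is the mixture CDF at $z_t$ with arm means $-|m|$. One-tailed
conventions are used throughout: $z_t = -1.645$ at $p_t = 0.05$ and
$z_t = -5.33$ at genome-wide $p_t = 5\times10^{-8}$.

For a multistage design the final assessment uses the combined dataset
$N_{dr} = N_d + N_r$; with inverse-variance weights
$w_d = \sqrt{N_d/N_{dr}}$, $w_r = \sqrt{N_r/N_{dr}}$ the combined score
is $w_d z_d + w_r z_r$, and the probability of combined significance is
the replication-rate form evaluated at the transformed threshold
$z_t' = (z_t + w_d |z_d|)/w_r$ (`combined_replication_rate()`). At
$N_r = 0$ this collapses, by construction, to the indicator
$-|z_d| < z_t$.

Case-control studies enter through the effective sample size
$N_\mathrm{eff} = 2/(1/N_\mathrm{cases} + 1/N_\mathrm{controls})$, so a
balanced study of $N$ subjects has $N_\mathrm{eff} = N/2$; quantitative
traits use the subject count directly. Sample sizes supplied to the
prediction layer are always effective sizes; conversion from raw totals
is left to the caller (`effective_n()`, `total_n_from_eff()`).

## The empirical estimation scheme

The parameters are deliberately *not* fitted by likelihood on the
marginal z distribution: $\sigma_1^2, \sigma_2^2 \propto N$, so a single
marginal cannot separate the roles of the parameters. Instead the
substudies of a meta-analysed GWAS are repeatedly split into
complementary discovery and replication sets at nine target
effective-sample fractions (0.1–0.9), re-drawn `n_reps` times per
fraction. Within each realization:

1. SNPs are randomly pruned on the $r^2 \ge 0.8$ LD graph
   (`random_prune()`): a random-order greedy maximal independent set, so
   every LD block contributes one representative chosen *at random* —
   never by z-score, which would re-introduce the winner's curse. The
   draw is repeated per realization.
2. Discovery and replication z-scores are meta-analysed separately with
   $\sqrt{N}$ weights (`meta_z()`), which preserves the model's scaling
   so each side follows the mixture at its summed effective size.
3. Replication scores are binned on the discovery score: 200 equal-width
   bins on $[-6, 6]$ (an even count, so no bin straddles zero; scores
   outside the range are excluded). Per bin the SNP count, mean $z_r$,
   mean $z_r^2$, replication fraction and mean heterozygosity are
   recorded (`bin_conditional()`).

Because each realization is an unbiased estimate of the conditional
curves, so is their count-weighted average (`aggregate_curves()`).

Fitting minimizes the weighted squared discrepancy between the empirical
and model curves of both the first moment ($\bar z_{ijk}$ vs.
$\delta_{ijk} = E(z_r|z_d)$) and the second moment ($\overline{z^2}_{ijk}$
vs. $\eta_{ijk} = E(z_r^2|z_d) = \mathrm{var}(\delta_r|z_d) + \sigma_0^2
+ \delta_{ijk}^2$), summed over fractions, repetitions and bins with the
bin count as weight. The first moment alone does not pin the parameters
down; the second moment is what separates a few large effects from many
small ones. Optimization is derivative-free Nelder–Mead on
$(\mathrm{logit}\,\pi_1, \log\sigma_0^2, \log\sigma_a^2,
\log\sigma_b^2)$ — positivity and bounds without constrained
optimizers — with five starts (the first at the neutral default
$\pi_1 = 0.01$, $\sigma_0^2 = 1$, $\sigma_a^2 = 10^{-5}$,
$\sigma_b^2 = 10^{-4}$, the rest jittered), relative tolerance $10^{-6}$
and at most 2000 evaluations per start.

Model curves are evaluated at the bin centre with the count-weighted
mean heterozygosity of the SNPs in that bin for that repetition. The
per-bin mean H (rather than a per-SNP evaluation) is the cheapest choice
consistent with the weak dependence of the curves on H within a bin, and
it keeps a cost evaluation at one closed-form call per populated cell.

Confidence intervals come from a parametric bootstrap: regenerate
synthetic cohorts from the fitted parameters at the template's study
layout, rerun the split/bin/fit pipeline on each, and take 2.5/97.5
percentiles on the internal log/logit scale — hence asymmetric intervals
on the natural scale, as variance parameters demand. This bootstrap is
the package's own procedure, reported as such in its output.

## Projections of explained chip heritability

`simulate_S()` estimates $S(N; z_t)$, the proportion of the additive
tagged (chip-heritability) variance carried by sparse-class SNPs that is
explained by those reaching significance at effective size $N$: draw
$\epsilon \sim N(0, \sigma_0^2)$ and, for the $\pi_1$ fraction,
$\delta_c \sim N(0, (\sigma_a^2+\sigma_b^2) N \bar H)$; with
$z = \delta_c + \epsilon$, $S$ is the ratio of $\sum \delta_c^2$ over
significant sparse SNPs to the sum over all of them, numerator and
denominator averaged over repetitions. Only the sparse class enters the
ratio; ubiquitous draws are available behind a flag purely so the test
suite can assert they change nothing. $\bar H$ is never guessed
internally: it is computed from the input panel or supplied explicitly.
For an observed z set, `expected_S()` replaces $\delta_c^2$ with the
posterior expectation $E(\delta^2|z)$. "Approaching fully explained
heritability" is operationalized as $S \ge 0.90$ by default in
`n_for_target_S()` (configurable; the grid is 20 log-spaced points per
decade, smoothed by a running maximum before thresholding).

Note one subtlety the tests respect: a panel with heterogeneous per-SNP
$H$ has larger $S$ than a fixed-$\bar H$ simulation at the same mean,
because $\delta^2 \propto H$ correlates with significance. Cross-method
checks therefore match configurations (near-constant allele frequency)
before comparing.

## The synthetic-data generator

`generate_cohort()` draws the generative story directly: allele
frequencies uniform on (0.005, 0.5) — the post-QC MAF floor; the real
MAF spectrum is not part of the model, and the uniform law is a declared
default, not a reproduction of any dataset; class labels Bernoulli
$(\pi_1)$; per-allele effects $a \sim N(0, \sigma_a^2)$ shared by all
substudies, $b \sim N(0, \sigma_b^2)$ added for the sparse class; and
per-substudy noise drawn independently, so that study $i$ reports
$z = \sqrt{N_i H}(a + b\,\mathbf{1}[\mathrm{sparse}]) + \epsilon_i$. A
truth table (class, $a$, $b$) accompanies every cohort so tests can
condition on the unobservable decomposition. The default substudy
layout is deterministic and uneven (geometrically graded sizes spanning
a factor $e^2 \approx 7.4$), mirroring the size imbalance of consortium
meta-analyses.

Optional LD blocks emulate tagging only at the level the TLD experiment
needs: each block's causal member passes its effect to the other members
attenuated by a signed $r$ drawn per member, with within-block noise
correlated at the same $r$ and the implied pairwise $r^2$ table emitted.
There is no haplotype or population-structure simulation; passing tests
on these cohorts therefore demonstrates correctness of the estimation
machinery under the model's own assumptions — independent SNPs, Gaussian
effects, exact $\sqrt{NH}$ scaling — not robustness to real LD spectra,
allele-frequency-dependent architectures, or uncorrected stratification.

All randomness descends from one integer seed through a deterministic
per-(stage, fraction, repetition) substream hash, so the 9-fraction
split machinery is reproducible stage by stage.

## Numerical choices

* Mixture densities and `tdr` are assembled in log space; the sparse-arm
  weight underflows naively beyond $|z| \approx 8$.
* $H$ is clamped to $[10^{-12}, 0.5]$; monomorphic SNPs are a QC
  matter, not a model case.
* The overestimation factor $z^2 / E(\delta^2|z)$ is a domain error at
  $z = 0$ rather than a silent infinity.
* Bins are half-open $[lo, hi)$ with the last bin closed; the
  replication sign convention uses the bin centre.
* Split draws accept an achieved discovery share within ±25% relative
  of the target (the paper-scale layouts hit far tighter in practice);
  the best draw is kept as a fallback after 200 redraws.
* Zero-count bins are masked `NA` and contribute nothing to the cost.
* Fixed-at-zero variances in `fit_mixture(fixed = ...)` stay exactly
  zero; free parameters never touch zero thanks to the log/logit scale.

## Scale of the validation experiments

The test suite validates parameter recovery at $3\times10^5$ SNPs per
cohort with 9 fractions × 10 repetitions and ten independent seeded
runs per parameter regime — about fifteen seconds per pipeline run.
Monte-Carlo oracle comparisons use $10^6$ draws per sample-size
configuration. These sizes give the recovery distributions and oracle
standard errors quoted in the tests; running at consortium scale
(millions of SNPs, 100 repetitions) only narrows them.

## Known limitations

* LD enters only through pruning, TLD filtering and the attenuation toy
  model; the fitted $\sigma_a^2$ partly absorbs residual LD structure,
  exactly as the interpretation of "ubiquitous effects as weak LD"
  suggests.
* Per-allele variances are assumed independent of allele frequency;
  heterozygosity-dependent coefficients are out of scope.
* The liability-scale conversion of $S$ and case-control ascertainment
  corrections are external to the package.
* With $\sigma_b^2$ near zero the fit is degenerate in $\pi_1$; the fit
  object reports the cost, and the flatness of the cost in $\pi_1$ is
  the caller's diagnostic for that regime.
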