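---
title: "Two-stage screening-testing for interaction detection: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-stage screening-testing for interaction detection: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(episcreen)
```

## The multiple-testing problem and the two-stage remedy

A genome-wide scan for pairwise gene-gene (GxG) or gene-environment (GxE)
interactions tests on the order of $p(p-1)/2$ feature pairs. At modern panel
sizes the Bonferroni (or any family-wise) penalty for that family is
crushing, while true interaction signals are few and weak.

The two-stage procedure implemented by `episcreen` reduces the family before
any phenotype model is fit:

1. **Screening.** Every pair is screened with a statistic that is *strictly
   a function of the feature values* — it never reads disease status or the
   trait. Here the statistic is composite linkage disequilibrium,
   operationalized as Pearson's product-moment correlation $r$ between the
   additively coded features, referred to the $t$ distribution,
   $t = r\sqrt{(n-2)/(1-r^2)}$, two-sided.
2. **Testing.** Only pairs surviving the screen are fit in a regression
   model with an interaction term, and the multiplicity correction counts
   *only the tests actually conducted*.

Validity rests on a simple property of independence: under the global null
(features jointly independent of the phenotype), *any* function of the
features is also independent of the phenotype. The screen is such a
function, so conditioning the testing family on its outcome does not
disturb the null distribution of the testing statistics. Crucially this
argument does not use the assumption that feature pairs are independent in
the population — that assumption affects the screen's power and
interpretation, not type I error — and `calibration_study()` verifies
empirical family-wise error control both with independent and with
correlated SNP pairs.

## Why the pooled case-control screen gains power from main effects

The classic case-only argument says dependence among cases signals an
interaction on the relative-risk scale (when the features are independent
in the population), while controls of a rare disease resemble the
population and contribute only noise. That account misses an effect of
ascertainment: a case-control sample *pools* two differently conditioned
strata, and conditioning on disease status induces dependence between
independently segregating risk loci whenever they carry main effects. The
induced pooled-sample correlation grows with the main-effect relative risk
even when the interaction is weak, so the pooled screen can be powerful
where the cases-only screen is not.

`screening_power_study()` demonstrates this with the generative model below;
the exact induced correlations can also be computed by enumerating the nine
two-locus genotype cells (see `expected_prevalence()` for the analogous
prevalence enumeration).

## The generative model

`simulate_population()` draws two independent biallelic SNPs under
Hardy-Weinberg equilibrium (minor-allele-count probabilities $(1-q)^2,\,
2q(1-q),\, q^2$) and a binary disease with log-linear relative-risk
penetrance

$$\log P[D] \;=\; \lambda + \beta_1 g_1 + \beta_2 g_2 + \beta_3 g_1 g_2 .$$

Defaults mirror the headline simulation configuration: baseline risk
$\exp(\lambda) = 0.05$, MAF $0.2$ for both SNPs, equal main effects
$\beta_1 = \beta_2$, weak interaction $\exp(\beta_3) = 1.1$, populations of
40000 individuals, and samples of 1000 cases and 1000 controls screened at
$\alpha = 0.05$.

```{r}
m <- population_model(beta1 = log(1.5), beta2 = log(1.5), beta3 = log(1.1))
expected_prevalence(m)
pop <- simulate_population(m, n_pop = 40000, seed = 1)
samp <- sample_case_control(pop, 1000, 1000, seed = 2)
screen_all_pairs(samp$genotypes, "pooled", samp$disease)
```

### Risk clamping and the valid parameter regime

The log-linear model is not bounded above: for the default parameters the
implied risk of the $(g_1, g_2) = (2, 2)$ cell exceeds 1 once the
main-effect RR passes $\;(0.05 \cdot 1.1^4)^{-1/4} \approx 1.92$. The
simulator clamps per-individual risk at 1 and warns with the clamped
fraction, which keeps it total, but in the clamped regime the generative
law is no longer the stated model and its qualitative behaviour changes:
exact enumeration shows the pooled-sample correlation peaks near RR 2.5 and
then falls, while the controls-only dependence keeps growing (the disease
is no longer rare, so controls no longer resemble the population). The
default grid of `screening_power_study()` is therefore `seq(1, 2, by =
0.25)` — the regime in which the model is exactly the log-linear law and
the disease stays moderately rare. Users can extend the grid, but power
curves beyond RR $\approx 2$ characterize the clamped model, not the
log-linear one.

### Other generator properties

* One master seed is split into genotype and disease streams, so genotypes
  are bit-identical across effect-size grids with the same seed.
* Sampling of cases and controls is without replacement within strata; a
  population with too few cases raises an error rather than resampling.
* No LD blocks, covariates, or population stratification are simulated, and
  genotypes are never missing. Simulated power and calibration results
  therefore say nothing about confounding by ancestry, about LD-induced
  redundancy between screened pairs, or about missingness mechanisms in
  real genotype data.

## Testing-stage models

`fit_logistic_interaction()` fits the four-parameter logistic model
$\operatorname{logit} P[D] = \alpha^* + \beta^*_1 g_1 + \beta^*_2 g_2 +
\beta^*_3 g_1 g_2$ by maximum likelihood and compares it to a nested null
by a likelihood-ratio chi-square: dropping the interaction (1 df), one main
effect together with the interaction (2 df; which main effect is
configurable), or all three effect terms (3 df). Note the deliberate scale
mismatch that mirrors practice: the case-control data are generated on the
relative-risk scale but analyzed on the odds scale; the two interaction
parameters coincide only for a rare disease, and no correction is
attempted.

Numerical choices:

* IRLS convergence: relative deviance change $< 10^{-8}$, at most 100
  iterations; non-convergence is an error, never a silent `NA`.
* Complete or quasi-complete separation (fitted probabilities pinned at 0
  or 1) raises an error naming the offending genotype cell(s).
* Rank-deficient designs and single-class outcomes are errors.
* Likelihood-ratio tests are the canonical statistic — they behave better
  than Wald in sparse genotype cells; `method = "wald"` is available for
  cross-checking.

`fit_linear_joint()` is the continuous-trait analogue (the
within-diseased-population design, e.g. screening obese patients for
feature dependencies and testing survivors for joint effects on BMI): OLS
fit of `trait ~ 1 + g1 + g2 + g1:g2` with an F test of the same three null
patterns. A perfect fit with a non-constant trait (zero residual sum of
squares) reports `statistic = Inf`, `p = 0`; a constant trait is an error.

## The two-stage orchestrator

`run_two_stage()` chains screen → select → test → adjust. Selection is
either by screening p-value threshold (`alpha_screen`) or by rank
(`top_m`), with boundary ties broken deterministically by pair index
order. Pairs that are unscreenable (monomorphic within the screening
stratum) are excluded both from selection and from the Bonferroni
denominator. The Bonferroni adjustment is `min(1, p * n_tested)` over the
tests conducted; Bonferroni is the only built-in correction, with the
permutation FDR estimator as the alternative error metric. Screening level
and family level are independent knobs — no alpha is split between stages,
because the screen costs no testing-stage alpha. An empty selection is a
valid empty result.

The default testing-stage family level is 0.05 family-wise; nothing in the
design forces that choice and it is exposed as `family_alpha`.

## Permutation FDR with few permutations

`permutation_fdr()` estimates, for each p-value threshold $t$, the plug-in
false discovery rate of the testing stage,

$$\widehat{\mathrm{FDR}}(t) = \frac{\bar N_0(t)}{N(t)} \wedge 1,$$

with $N(t)$ the observed count of testing-stage p-values $\le t$ and $\bar
N_0(t)$ the average count under random permutation of the phenotype.
Permuting labels rather than genotype rows is equivalent under row
exchangeability and cheaper. No null-proportion ($\pi_0$) correction is
applied, so the estimate is conservative; no confidence interval is
provided. The default of 10 permutations is deliberately small — the
estimator is usable at that budget, and the test suite compares 10 against
1000 permutations on a spiked scan.

When the screening stage never reads the permuted phenotype (pooled
scheme, any single-stratum sample, and all continuous-trait designs),
screening and selection are computed once and only the testing stage is
recomputed per permutation. This is an exact shortcut — verified
bit-identical to naive recomputation — not an approximation. With
cases-only or controls-only screening of a binary outcome the stratum
itself changes under permutation, and the full scan is re-run.

When `n_observed = 0` at a threshold the estimate is reported as 0 with a
flag rather than as a division failure.

## Simulation studies and problem sizes

The packaged studies use desk-scale defaults chosen once: the power study
runs 1000 replicates per grid point at the headline configuration
(populations of 40000; 1000 cases + 1000 controls; grid RR 1.0-2.0 by
0.25), and the calibration study runs 2000 global-null replicates of a
400-individual, 4-SNP scan at MAF 0.3, reporting empirical FWER and
screening size with binomial standard errors. Every study result carries
its seed, replicate count and configuration, and regenerates
bit-identically from them. Two further properties the suite checks:
screening p-values are uniform under feature independence, and
the 1-df likelihood-ratio statistic has mean 1 under the global null.

## Known limitations

* The screen operates on additive codings only; allele-level
  (haplotype) composite-LD decompositions are out of scope, and dominance
  or recessive interaction patterns will register only through their
  additive projections.
* Continuous exposures are screened by the same linear correlation, so
  purely non-monotone dependencies are invisible to the screen.
* The testing stage fits no covariates and makes no retrospective-likelihood
  correction for case-control sampling.
* The pair enumeration is dense ($O(p^2)$ records); the package targets
  candidate panels, not genome-scale chunked scans.
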