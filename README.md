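# episcreen

Two-stage screening-testing for gene-gene (GxG) and gene-environment (GxE)
interaction detection in case-control studies.

## The problem and the method

Scanning all pairs of *p* genetic/environmental features for interaction
effects means testing *p(p−1)/2* hypotheses, and the family-wise penalty for
that family drowns weak interaction signals. The two-stage remedy: first
**screen** every pair with a statistic that is strictly a function of the
feature values — composite linkage disequilibrium, measured as Pearson's
product-moment correlation *r* of the additive 0/1/2 codings referred to
the *t* distribution, *t = r√((n−2)/(1−r²))* — computed in the pooled
case-control sample (or in cases or controls alone); then **test** only the
survivors in a logistic model with an interaction term,

    logit P[D] = α* + β*₁·g₁ + β*₂·g₂ + β*₃·g₁g₂,

by a likelihood-ratio test of the interaction alone (1 df), a main effect
plus the interaction (2 df), or all three effect terms (3 df). Because the
screen never reads the phenotype, the Bonferroni correction legitimately
counts **only the tests actually conducted**, and type I error is controlled
even when the feature-independence assumption behind the screen fails.

A counterintuitive consequence of case-control ascertainment motivates the
pooled screen: pooling cases and controls induces dependence between
independently segregating loci whenever they carry *main* effects, so the
pooled screen gains power from main effects, not just from interactions.
The package ships the simulation machinery that demonstrates this — a
log-linear relative-risk simulator
(`log P[D] = λ + β₁g₁ + β₂g₂ + β₃g₁g₂` with Hardy-Weinberg genotypes), a
power study across a grid of main-effect relative risks, global-null
calibration studies, and a plug-in permutation FDR estimator usable with as
few as 10 permutations. A continuous-trait testing stage
(`trait ~ 1 + g1 + g2 + g1:g2`, F tests) supports the
within-diseased-population design.

Intended users: statistical geneticists and epidemiologists running
candidate-panel interaction scans, and methodologists studying two-stage
designs.

## Worked example

Simulate the headline configuration — baseline risk 5%, MAF 0.2, equal
main-effect relative risks of 2, weak interaction RR 1.1 — draw 1000 cases
and 1000 controls, and run the two-stage scan:

```r
library(episcreen)
model <- population_model(beta1 = log(2), beta2 = log(2), beta3 = log(1.1))
pop   <- simulate_population(model, n_pop = 40000, seed = 11)
samp  <- sample_case_control(pop, 1000, 1000, seed = 12)
res   <- run_two_stage(samp$genotypes, samp$disease,
                       config = two_stage_config(screen_scheme = "pooled",
                                                 alpha_screen = 0.05,
                                                 test_kind = "interaction_1df"))
summary(res)
#> Two-stage screening-testing scan
#> Two-stage config: pooled screen, screen p <= 0.05; test interaction_1df; bonferroni at family alpha 0.05
#>   pairs screened:   1 (1 screenable)
#>   pairs tested:     1
#>   discoveries:      1 at family alpha 0.05
#>   tested pairs:
#>  feature1 feature2        b3 statistic df           p  adjusted_p
#>      SNP1     SNP2 0.4164712  8.233129  1 0.004113254 0.004113254
```

The two SNPs are independent in the population, yet the pooled sample shows
composite LD (`res$screened`: r = 0.090, p = 5.1e-05) — dependence induced
by ascertainment plus main effects — so the pair survives the screen, and
the testing stage finds an interaction on the logit scale
(β̂₃ = 0.42, LR χ²₁ = 8.23, p = 0.0041, Bonferroni over the 1 test
conducted). The screening power study across a grid of main-effect relative
risks:

```r
pt <- screening_power_study(rr_grid = c(1, 1.5, 2), n_reps = 200, seed = 14)
print(pt)
#> Screening power study: 200 replicates per grid point, seed 14, alpha 0.05
#>   1000 cases / 1000 controls from populations of 40000; MAF 0.2; interaction RR 1.1
#>                 RR1 RR1.5   RR2
#> main_effect_RR 1.00 1.500 2.000
#> cases_only     0.13 0.215 0.240
#> controls_only  0.03 0.040 0.260
#> pooled         0.09 0.425 0.905
```

At RR 1 all three schemes sit near the nominal 5% (the weak interaction adds
a little cases-only power); as the main effects strengthen, pooled-sample
power climbs to 0.9 while cases-only and controls-only lag — the main-effect
boost in action. `plot(pt)` draws the three-series power curve.

A command-line wrapper over the same functions is installed at
`inst/cli/twostage.R` (subcommands `simulate`, `screen`, `run`, `fdr`,
`experiment`, with shared `--seed`/`--out`/`--config` flags); every run
writes a JSON manifest sufficient to reproduce it.

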