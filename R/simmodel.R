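#' Specify the generative relative-risk interaction model
#'
#' Defines the penetrance model used throughout the simulation studies:
#' \deqn{\log P[D] = \lambda + \beta_1 g_1 + \beta_2 g_2 + \beta_3 g_1 g_2}
#' where \eqn{g_1, g_2 \in \{0,1,2\}} are additively coded minor-allele
#' counts at two biallelic SNPs, \eqn{\exp(\lambda)} is the baseline disease
#' risk, \eqn{\exp(\beta_1), \exp(\beta_2)} are per-allele relative risks and
#' \eqn{\exp(\beta_3)} is the multiplicative interaction relative risk.
#'
#' @param baseline_log_risk Baseline log risk \eqn{\lambda}; `exp(baseline_log_risk)`
#'   must lie in (0, 1). Default `log(0.05)`, a moderately rare disease.
#' @param beta1,beta2 Per-allele log relative risks of SNP1 and SNP2.
#' @param beta3 Interaction log relative risk.
#' @param maf1,maf2 Minor allele frequencies, in (0, 1); values above 0.5
#'   trigger a warning (the coded allele is then not the minor allele).
#'
#' @return An object of class `population_model`.
#' @seealso [simulate_population()], [expected_prevalence()]
#' @examples
#' m <- population_model(beta1 = log(2), beta2 = log(2), beta3 = log(1.1))
#' expected_prevalence(m)
#' @export
population_model <- function(baseline_log_risk = log(0.05),
                             beta1 = 0, beta2 = 0, beta3 = 0,
                             maf1 = 0.2, maf2 = 0.2) {
  coefs <- c(baseline_log_risk = baseline_log_risk,
             beta1 = beta1, beta2 = beta2, beta3 = beta3)
  if (!all(is.finite(coefs)))
    stop("all model coefficients must be finite, got: ",
         paste(names(coefs)[!is.finite(coefs)], collapse = ", "))
  if (!(exp(baseline_log_risk) > 0 && exp(baseline_log_risk) < 1))
    stop("exp(baseline_log_risk) must lie in (0, 1); got ",
         format(exp(baseline_log_risk)))
  for (q in c(maf1 = maf1, maf2 = maf2)) {
    if (!is.finite(q) || q <= 0 || q >= 1)
      stop("minor allele frequencies must lie in (0, 1); got ", format(q))
  }
  if (maf1 > 0.5 || maf2 > 0.5)
    warning("MAF > 0.5: the coded allele is not the minor allele")
  structure(list(baseline_log_risk = baseline_log_risk,
                 beta1 = beta1, beta2 = beta2, beta3 = beta3,
                 maf1 = maf1, maf2 = maf2),
            class = "population_model")
}

#' @export
print.population_model <- function(x, ...) {
  cat("Relative-risk interaction model: log P[D] = lambda + b1*g1 + b2*g2 + b3*g1*g2\n")
  cat(sprintf("  baseline risk exp(lambda) = %.4g\n", exp(x$baseline_log_risk)))
  cat(sprintf("  RR per allele: SNP1 %.4g, SNP2 %.4g; interaction RR %.4g\n",
              exp(x$beta1), exp(x$beta2), exp(x$beta3)))
  cat(sprintf("  MAF: %.3g / %.3g\n", x$maf1, x$maf2))
  invisible(x)
}

# Per-individual disease risk, clamped at 1 (the log-linear model is not
# bounded above; clamping keeps the simulator total).
risk_from_genotypes <- function(model, g1, g2) {
  pmin(1, exp(model$baseline_log_risk + model$beta1 * g1 +
                model$beta2 * g2 + model$beta3 * g1 * g2))
}

# Hardy-Weinberg genotype probabilities for minor-allele count 0/1/2.
hwe_probs <- function(q) c((1 - q)^2, 2 * q * (1 - q), q^2)

#' Exact expected disease prevalence under the model
#'
#' Enumerates the nine two-locus genotype combinations under Hardy-Weinberg
#' equilibrium and independence of the two SNPs, weighting each clamped risk
#' by its genotype probability.
#'
#' @param model A [population_model()].
#' @return Expected population prevalence (scalar in (0, 1]).
#' @export
expected_prevalence <- function(model) {
  p1 <- hwe_probs(model$maf1)
  p2 <- hwe_probs(model$maf2)
  g <- expand.grid(g1 = 0:2, g2 = 0:2)
  sum(p1[g$g1 + 1] * p2[g$g2 + 1] * risk_from_genotypes(model, g$g1, g$g2))
}

# Split a master seed into independent stream seeds so that, e.g., genotypes
# are reusable across effect-size grids (genotype stream does not depend on
# the betas).
derive_seeds <- function(seed, n) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  old <- get0(".Random.seed", globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  sample.int(.Machine$integer.max - 1L, n)
}

#' Simulate a population under the relative-risk interaction model
#'
#' Draws `n_pop` individuals with two independent biallelic SNPs under
#' Hardy-Weinberg equilibrium (genotype probabilities \eqn{(1-q)^2, 2q(1-q),
#' q^2} for minor-allele counts 0/1/2) and a binary disease status drawn
#' Bernoulli with per-individual risk
#' \eqn{\min(1, \exp(\lambda + \beta_1 g_1 + \beta_2 g_2 + \beta_3 g_1 g_2))}.
#' If any individual's nominal risk exceeds 1 the risk is clamped and a
#' warning reports the clamped fraction.
#'
#' The master seed is split deterministically into a genotype stream and a
#' disease stream, so the same seed yields identical genotypes across
#' different effect-size settings.
#'
#' @param model A [population_model()].
#' @param n_pop Population size (>= 1).
#' @param seed Integer master seed; the simulation is bit-reproducible given
#'   `(model, n_pop, seed)`.
#' @return An object of class `population`: list with `genotypes`
#'   (`n_pop` x 2 integer matrix, columns `SNP1`, `SNP2`), `disease`
#'   (binary vector), `model`, `seed`.
#' @examples
#' pop <- simulate_population(population_model(), n_pop = 5000, seed = 1)
#' mean(pop$disease)  # close to 0.05
#' @export
simulate_population <- function(model, n_pop, seed) {
  stopifnot(inherits(model, "population_model"))
  if (!is.numeric(n_pop) || length(n_pop) != 1 || n_pop < 1)
    stop("n_pop must be a positive integer")
  n_pop <- as.integer(n_pop)
  seeds <- derive_seeds(seed, 2)

  set.seed(seeds[1])
  g1 <- stats::rbinom(n_pop, 2L, model$maf1)
  g2 <- stats::rbinom(n_pop, 2L, model$maf2)

  risk_raw <- exp(model$baseline_log_risk + model$beta1 * g1 +
                    model$beta2 * g2 + model$beta3 * g1 * g2)
  clamped <- risk_raw > 1
  if (any(clamped))
    warning(sprintf("risk clamped at 1 for %.3g%% of individuals",
                    100 * mean(clamped)))
  risk <- pmin(1, risk_raw)

  set.seed(seeds[2])
  disease <- stats::rbinom(n_pop, 1L, risk)

  genotypes <- cbind(SNP1 = as.integer(g1), SNP2 = as.integer(g2))
  structure(list(genotypes = genotypes, disease = disease,
                 model = model, seed = as.integer(seed)),
            class = "population")
}

#' @export
print.population <- function(x, ...) {
  cat(sprintf("Simulated population: %d individuals, %d SNPs\n",
              nrow(x$genotypes), ncol(x$genotypes)))
  cat(sprintf("  prevalence %.4g (%d cases), seed %d\n",
              mean(x$disease), sum(x$disease), x$seed))
  invisible(x)
}

#' Draw a case-control sample from a simulated population
#'
#' Simple random sampling without replacement within each disease stratum.
#' The sampling scheme is inferred from the requested counts: cases only,
#' controls only, or pooled.
#'
#' @param pop A [simulate_population()] result.
#' @param n_cases,n_controls Numbers of cases and controls to draw
#'   (non-negative; at least one must be positive).
#' @param seed Integer seed for the sampling step.
#' @return An object of class `case_control_sample`: list with `genotypes`
#'   (n x p matrix), `disease` (binary vector) and `scheme` (one of
#'   `"cases_only"`, `"controls_only"`, `"pooled"`).
#' @export
sample_case_control <- function(pop, n_cases, n_controls, seed) {
  stopifnot(inherits(pop, "population"))
  n_cases <- as.integer(n_cases); n_controls <- as.integer(n_controls)
  if (n_cases < 0 || n_controls < 0) stop("sample sizes must be non-negative")
  if (n_cases + n_controls == 0) stop("at least one of n_cases, n_controls must be positive")
  cases <- which(pop$disease == 1L)
  controls <- which(pop$disease == 0L)
  if (length(cases) < n_cases)
    stop(sprintf("requested %d cases but only %d available in the population",
                 n_cases, length(cases)))
  if (length(controls) < n_controls)
    stop(sprintf("requested %d controls but only %d available in the population",
                 n_controls, length(controls)))
  set.seed(as.integer(seed))
  idx <- c(if (n_cases > 0) sample(cases, n_cases),
           if (n_controls > 0) sample(controls, n_controls))
  scheme <- if (n_cases > 0 && n_controls > 0) "pooled"
            else if (n_cases > 0) "cases_only" else "controls_only"
  structure(list(genotypes = pop$genotypes[idx, , drop = FALSE],
                 disease = pop$disease[idx], scheme = scheme),
            class = "case_control_sample")
}

#' @export
print.case_control_sample <- function(x, ...) {
  cat(sprintf("Case-control sample (%s): %d cases, %d controls, %d SNPs\n",
              x$scheme, sum(x$disease == 1), sum(x$disease == 0),
              ncol(x$genotypes)))
  invisible(x)
}
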