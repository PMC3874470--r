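# Scripted simulation studies: the headline power study (screening power in
# cases, controls, and the pooled case-control sample over a grid of main
# effect relative risks) and calibration studies for the two-stage pipeline.

SCHEMES <- c("cases_only", "controls_only", "pooled")

#' Screening power in cases, controls, and the pooled sample
#'
#' Empirical power of the composite-LD screen to detect a disease-related
#' SNP pair, as a function of the main-effect relative risk. Per replicate:
#' a population of `n_pop` individuals is simulated under the relative-risk
#' model with equal main effects `beta1 = beta2 = log(RR)`, a weak
#' interaction (`rr_interaction`, default 1.1), baseline risk
#' `baseline_risk` (default 5\%) and MAFs 0.2; `n_cases` cases and
#' `n_controls` controls are drawn; and the screen is run at level `alpha`
#' on the cases alone, the controls alone, and the pooled sample. Power is
#' the rejection fraction per scheme.
#'
#' The point of the study: pooling cases and controls conditions on disease
#' status in a way that induces dependence between independently segregating
#' SNPs when main effects are present, so pooled-sample screening power
#' grows with the main-effect relative risk even though the interaction is
#' weak and the SNPs are independent in the population.
#'
#' @param rr_grid Main-effect relative risks (>= 1). Default 1.0 to 2.0 in
#'   steps of 0.25, spanning the regime in which the log-linear risk stays
#'   below 1 for every genotype class (beyond RR ~1.92 at the default
#'   parameters the top genotype cell must be clamped and the generative law
#'   is no longer the stated model; see the package vignette).
#' @param n_reps Replicates per grid point (>= 100 recommended). Default 1000.
#' @param seed Integer master seed.
#' @param n_pop Population size per replicate (default 40000).
#' @param n_cases,n_controls Sample sizes (default 1000 each).
#' @param maf Minor allele frequency of both SNPs (default 0.2).
#' @param baseline_risk Baseline disease risk (default 0.05).
#' @param rr_interaction Interaction relative risk (default 1.1).
#' @param alpha Screening level (default 0.05).
#' @return An object of class `power_table`: `power` and `mc_se` (scheme x
#'   grid matrices; `mc_se = sqrt(p(1-p)/n_reps)`), `rr_grid`, `n_reps`,
#'   `seed`, the full configuration, and the overall fraction of
#'   risk-clamped individuals.
#' @seealso [plot.power_table()]
#' @export
screening_power_study <- function(rr_grid = seq(1, 2, by = 0.25),
                                n_reps = 1000, seed = 1,
                                n_pop = 40000, n_cases = 1000,
                                n_controls = 1000, maf = 0.2,
                                baseline_risk = 0.05, rr_interaction = 1.1,
                                alpha = 0.05) {
  if (any(rr_grid < 1)) stop("rr_grid values must be >= 1")
  if (n_reps < 1) stop("n_reps must be positive")
  rej <- array(0L, dim = c(3, length(rr_grid)),
               dimnames = list(SCHEMES, paste0("RR", rr_grid)))
  clamped_total <- 0; n_total <- 0
  seeds <- derive_seeds(seed, length(rr_grid) * n_reps * 2)
  s <- 0L
  for (gi in seq_along(rr_grid)) {
    model <- population_model(baseline_log_risk = log(baseline_risk),
                              beta1 = log(rr_grid[gi]), beta2 = log(rr_grid[gi]),
                              beta3 = log(rr_interaction),
                              maf1 = maf, maf2 = maf)
    for (rep in seq_len(n_reps)) {
      s <- s + 1L
      pop <- withCallingHandlers(
        simulate_population(model, n_pop, seed = seeds[s]),
        warning = function(w) {
          if (grepl("risk clamped", conditionMessage(w)))
            invokeRestart("muffleWarning")
        })
      clamped_total <- clamped_total +
        sum(risk_raw_fraction_clamped(model, pop$genotypes)) * n_pop
      n_total <- n_total + n_pop
      if (sum(pop$disease) < n_cases || sum(1 - pop$disease) < n_controls)
        stop(sprintf(paste0("replicate yielded %d cases / %d controls; fewer than",
                            " requested -- increase n_pop"),
                     sum(pop$disease), sum(1 - pop$disease)))
      s <- s + 1L
      samp <- sample_case_control(pop, n_cases, n_controls, seed = seeds[s])
      is_case <- samp$disease == 1
      for (sc in seq_along(SCHEMES)) {
        rows <- switch(SCHEMES[sc], cases_only = is_case,
                       controls_only = !is_case,
                       pooled = rep(TRUE, length(is_case)))
        p <- tryCatch(
          composite_ld_screen(samp$genotypes[rows, 1],
                              samp$genotypes[rows, 2])$p_value,
          error = function(e) NA_real_)
        if (!is.na(p) && p <= alpha) rej[sc, gi] <- rej[sc, gi] + 1L
      }
    }
  }
  power <- rej / n_reps
  structure(list(power = power,
                 mc_se = sqrt(power * (1 - power) / n_reps),
                 rr_grid = rr_grid, n_reps = n_reps, seed = seed,
                 alpha = alpha,
                 config = list(n_pop = n_pop, n_cases = n_cases,
                               n_controls = n_controls, maf = maf,
                               baseline_risk = baseline_risk,
                               rr_interaction = rr_interaction),
                 clamped_fraction = clamped_total / n_total),
            class = "power_table")
}

risk_raw_fraction_clamped <- function(model, genotypes) {
  mean(exp(model$baseline_log_risk + model$beta1 * genotypes[, 1] +
             model$beta2 * genotypes[, 2] +
             model$beta3 * genotypes[, 1] * genotypes[, 2]) > 1)
}

#' @export
print.power_table <- function(x, ...) {
  cat(sprintf("Screening power study: %d replicates per grid point, seed %d, alpha %.3g\n",
              x$n_reps, x$seed, x$alpha))
  cat(sprintf("  %d cases / %d controls from populations of %d; MAF %.3g; interaction RR %.3g\n",
              x$config$n_cases, x$config$n_controls, x$config$n_pop,
              x$config$maf, x$config$rr_interaction))
  tab <- rbind(main_effect_RR = x$rr_grid, round(x$power, 3))
  print(tab)
  invisible(x)
}

#' Plot a screening power study
#'
#' Line chart with one series per sampling scheme, mirroring the
#' three-series layout of the power study: cases only, controls only, and
#' the pooled case-control sample.
#'
#' @param x A `power_table` from [screening_power_study()].
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.power_table <- function(x, ...) {
  graphics::matplot(x$rr_grid, t(x$power), type = "b", pch = 1:3, lty = 1:3,
                    col = c("firebrick", "steelblue", "black"),
                    xlab = "Main effect relative risk, exp(b1) = exp(b2)",
                    ylab = "Screening power", ylim = c(0, 1), ...)
  graphics::legend("topleft", legend = rownames(x$power), pch = 1:3,
                   lty = 1:3, col = c("firebrick", "steelblue", "black"),
                   bty = "n")
  graphics::abline(h = x$alpha, lty = 3, col = "grey")
  invisible(x)
}

#' Type I error calibration of the two-stage pipeline
#'
#' Simulates data under the global null (disease independent of all
#' genotypes), runs the full two-stage procedure per replicate, and reports
#' the empirical family-wise error rate (fraction of replicates with at
#' least one discovery) and the screening-stage rejection rate, with
#' binomial standard errors. Optionally the first two SNPs are made
#' correlated in the population (SNP2 copies SNP1 with probability 1/2) to
#' verify that validity does not rest on the feature-independence
#' assumption behind the screen.
#'
#' @param config A [two_stage_config()].
#' @param n_reps Number of simulation replicates.
#' @param seed Integer master seed.
#' @param n Sample size per replicate (half cases, half controls).
#' @param p Number of SNPs.
#' @param maf Minor allele frequency.
#' @param correlated_pair If `TRUE`, SNP2 duplicates SNP1 with probability
#'   1/2 per individual.
#' @return A list of class `calibration_report`: `fwer`, `fwer_se`,
#'   `screen_rejection_rate`, `screen_se`, plus the replication settings.
#' @export
calibration_study <- function(config = two_stage_config(), n_reps = 2000,
                              seed = 1, n = 400, p = 4, maf = 0.3,
                              correlated_pair = FALSE) {
  seeds <- derive_seeds(seed, n_reps)
  any_disc <- logical(n_reps)
  screen_rej <- 0; screen_pairs <- 0
  for (rep in seq_len(n_reps)) {
    set.seed(seeds[rep])
    G <- matrix(stats::rbinom(n * p, 2L, maf), n, p,
                dimnames = list(NULL, paste0("SNP", seq_len(p))))
    if (correlated_pair) {
      copy <- stats::runif(n) < 0.5
      G[copy, 2] <- G[copy, 1]
    }
    disease <- rep(c(1L, 0L), length.out = n)  # labels independent of G
    res <- run_two_stage(G, disease, config = config)
    any_disc[rep] <- nrow(res$discoveries) > 0
    ok <- res$screened$screenable
    screen_rej <- screen_rej + sum(res$screened$p[ok] <= config$alpha_screen)
    screen_pairs <- screen_pairs + sum(ok)
  }
  fwer <- mean(any_disc)
  srate <- screen_rej / screen_pairs
  structure(list(fwer = fwer,
                 fwer_se = sqrt(fwer * (1 - fwer) / n_reps),
                 screen_rejection_rate = srate,
                 screen_se = sqrt(srate * (1 - srate) / screen_pairs),
                 n_reps = n_reps, seed = seed, n = n, p = p, maf = maf,
                 correlated_pair = correlated_pair, config = config),
            class = "calibration_report")
}

#' @export
print.calibration_report <- function(x, ...) {
  cat(sprintf("Global-null calibration: %d replicates (n = %d, %d SNPs%s)\n",
              x$n_reps, x$n, x$p,
              if (x$correlated_pair) ", SNP1-SNP2 correlated" else ""))
  cat(sprintf("  empirical FWER:            %.4g (SE %.4g) at family alpha %.3g\n",
              x$fwer, x$fwer_se, x$config$family_alpha))
  cat(sprintf("  screening rejection rate:  %.4g (SE %.4g) at screen alpha %.3g\n",
              x$screen_rejection_rate, x$screen_se, x$config$alpha_screen))
  invisible(x)
}
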