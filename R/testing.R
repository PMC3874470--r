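# Testing-stage models: four-parameter interaction regressions with 1-, 2-
# and 3-df hypothesis tests. The likelihood-ratio statistic is the canonical
# choice (better behaved than Wald in sparse genotype cells); Wald is kept as
# a cross-check option for the logistic model.

TEST_KINDS <- c("interaction_1df", "main_plus_interaction_2df", "joint_3df")

# Columns of the design (1, g1, g2, g1*g2) dropped under each null.
null_drop_cols <- function(test_kind, main_effect) {
  switch(test_kind,
         interaction_1df = 4L,
         main_plus_interaction_2df = c(1L + main_effect, 4L),
         joint_3df = 2:4)
}

interaction_design <- function(g1, g2) {
  X <- cbind("(Intercept)" = 1, g1 = as.numeric(g1), g2 = as.numeric(g2),
             "g1:g2" = as.numeric(g1) * as.numeric(g2))
  if (qr(X)$rank < ncol(X))
    stop("design matrix (1, g1, g2, g1*g2) is rank deficient")
  X
}

glm_binomial_fit <- function(X, y) {
  fit <- suppressWarnings(
    stats::glm.fit(X, y, family = stats::binomial(),
                   control = stats::glm.control(epsilon = 1e-8, maxit = 100))
  )
  if (!fit$converged)
    stop("logistic fit did not converge within 100 iterations")
  fit
}

# Quasi-complete separation shows up as fitted probabilities pinned at 0/1.
check_separation <- function(fit, g1, g2) {
  eps <- 1e-8
  pinned <- fit$fitted.values < eps | fit$fitted.values > 1 - eps
  if (any(pinned)) {
    cells <- unique(paste0("(g1=", g1[pinned], ", g2=", g2[pinned], ")"))
    stop("complete or quasi-complete separation detected; offending cell(s): ",
         paste(cells, collapse = ", "))
  }
}

#' Testing-stage logistic interaction model
#'
#' Maximum-likelihood fit of the four-parameter logistic model
#' \deqn{\mathrm{logit}\, P[D] = \alpha + \beta_1 g_1 + \beta_2 g_2 + \beta_3 g_1 g_2}
#' with a likelihood-ratio chi-square test of one of three null patterns:
#' the interaction alone (1 df), one main effect together with the
#' interaction (2 df), or all three effect terms jointly (3 df).
#'
#' Note the deliberate scale mismatch in the simulation studies: data are
#' generated on the relative-risk scale but analyzed, as in practice for
#' case-control samples, on the odds scale; no correction is attempted.
#'
#' @param g1,g2 Numeric feature vectors (genotype dosages or exposures).
#' @param disease Binary 0/1 outcome; both classes must be present.
#' @param test_kind One of `"interaction_1df"`,
#'   `"main_plus_interaction_2df"`, `"joint_3df"`.
#' @param main_effect For the 2-df test, which main effect (1 or 2) is
#'   tested together with the interaction. Default 1.
#' @param method `"lrt"` (likelihood ratio, default) or `"wald"`.
#' @return An object of class `interaction_test`: coefficients (logit
#'   scale), `statistic` (chi-square), `df`, `p_value`, `test_kind`,
#'   `method`, `model = "logistic"`.
#' @examples
#' set.seed(1)
#' g1 <- rbinom(400, 2, 0.3); g2 <- rbinom(400, 2, 0.3)
#' d <- rbinom(400, 1, plogis(-1 + 0.5 * g1 * g2))
#' fit_logistic_interaction(g1, g2, d, "interaction_1df")
#' @export
fit_logistic_interaction <- function(g1, g2, disease,
                                     test_kind = TEST_KINDS,
                                     main_effect = 1L,
                                     method = c("lrt", "wald")) {
  test_kind <- match.arg(test_kind)
  method <- match.arg(method)
  if (length(g1) != length(g2) || length(g1) != length(disease))
    stop("g1, g2 and disease must have equal length")
  disease <- as.integer(disease)
  if (!all(disease %in% 0:1)) stop("disease must be binary 0/1")
  if (length(unique(disease)) < 2)
    stop("only one disease class present; both cases and controls are required")

  X <- interaction_design(g1, g2)
  full <- glm_binomial_fit(X, disease)
  check_separation(full, g1, g2)

  drop <- null_drop_cols(test_kind, as.integer(main_effect))
  df <- length(drop)
  if (method == "lrt") {
    null <- glm_binomial_fit(X[, -drop, drop = FALSE], disease)
    statistic <- null$deviance - full$deviance
  } else {
    w <- full$weights
    V <- solve(crossprod(X * sqrt(w)))
    b <- full$coefficients[drop]
    statistic <- drop(t(b) %*% solve(V[drop, drop, drop = FALSE]) %*% b)
  }
  new_interaction_test(full$coefficients, test_kind, statistic, df,
                       p_value = stats::pchisq(statistic, df, lower.tail = FALSE),
                       method = method, model = "logistic")
}

#' Testing-stage linear model for a continuous trait
#'
#' Ordinary least-squares fit of
#' `trait ~ 1 + g1 + g2 + g1:g2` with an F test of the same three null
#' patterns as [fit_logistic_interaction()]. This is the testing stage of
#' the within-diseased-population design: screen for feature dependencies in
#' the affected sample, then test the survivors for joint effects on a
#' quantitative trait (e.g. BMI among obese study participants).
#'
#' @inheritParams fit_logistic_interaction
#' @param trait Continuous outcome vector; must not be constant.
#' @return An object of class `interaction_test` with `statistic` the F
#'   statistic, `df` the numerator degrees of freedom, `df_resid` the
#'   residual degrees of freedom, and `p_value` from the F distribution.
#'   A perfect fit (zero residual sum of squares with a non-constant trait)
#'   reports `statistic = Inf`, `p_value = 0`.
#' @export
fit_linear_joint <- function(g1, g2, trait,
                             test_kind = TEST_KINDS,
                             main_effect = 1L) {
  test_kind <- match.arg(test_kind)
  if (length(g1) != length(g2) || length(g1) != length(trait))
    stop("g1, g2 and trait must have equal length")
  trait <- as.numeric(trait)
  if (stats::var(trait) == 0) stop("trait is constant (zero variance)")

  X <- interaction_design(g1, g2)
  n <- nrow(X)
  df_resid <- n - ncol(X)
  if (df_resid < 1) stop("residual degrees of freedom < 1")

  full <- stats::lm.fit(X, trait)
  drop <- null_drop_cols(test_kind, as.integer(main_effect))
  df <- length(drop)
  null <- stats::lm.fit(X[, -drop, drop = FALSE], trait)
  rss1 <- sum(full$residuals^2)
  rss0 <- sum(null$residuals^2)
  if (rss1 <= .Machine$double.eps * sum(trait^2)) {
    statistic <- Inf
    p <- 0
  } else {
    statistic <- ((rss0 - rss1) / df) / (rss1 / df_resid)
    p <- stats::pf(statistic, df, df_resid, lower.tail = FALSE)
  }
  out <- new_interaction_test(full$coefficients, test_kind, statistic, df,
                              p_value = p, method = "f", model = "linear")
  out$df_resid <- df_resid
  out
}

new_interaction_test <- function(coefficients, test_kind, statistic, df,
                                 p_value, method, model) {
  structure(list(coefficients = coefficients, test_kind = test_kind,
                 statistic = statistic, df = df, p_value = p_value,
                 method = method, model = model),
            class = "interaction_test")
}

#' @export
print.interaction_test <- function(x, ...) {
  cat(sprintf("%s interaction model, %s (%s)\n", x$model, x$test_kind, x$method))
  cat("  coefficients:\n")
  print(round(x$coefficients, 5))
  cat(sprintf("  statistic = %.5g on %d df, p = %.4g\n",
              x$statistic, x$df, x$p_value))
  invisible(x)
}

#' @export
coef.interaction_test <- function(object, ...) object$coefficients
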