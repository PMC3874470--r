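test_that("symmetric 2x2x2 table gives zero interaction on the logit scale", {
  tab <- make_table(rep(10, 8))
  dat <- expand_table(tab)
  fit <- fit_logistic_interaction(dat$g1, dat$g2, dat$d, "interaction_1df")
  expect_equal(unname(coef(fit)["g1:g2"]), 0, tolerance = 1e-8)
  expect_equal(fit$statistic, 0, tolerance = 1e-8)
})

test_that("saturated logistic recovers the closed-form log-odds-ratio-ratio", {
  set.seed(21)
  for (rep in 1:8) {
    counts <- sample(5:40, 8, replace = TRUE)
    tab <- make_table(counts)
    dat <- expand_table(tab)
    fit <- fit_logistic_interaction(dat$g1, dat$g2, dat$d, "interaction_1df")
    expect_equal(unname(coef(fit)["g1:g2"]), oracle_lorr(tab),
                 tolerance = 1e-6)
  }
})

test_that("test kinds carry the matching degrees of freedom", {
  set.seed(22)
  g1 <- rgeno(300, 0.3); g2 <- rgeno(300, 0.3)
  d <- rbinom(300, 1, 0.4)
  expect_equal(fit_logistic_interaction(g1, g2, d, "interaction_1df")$df, 1)
  expect_equal(fit_logistic_interaction(g1, g2, d, "main_plus_interaction_2df")$df, 2)
  expect_equal(fit_logistic_interaction(g1, g2, d, "joint_3df")$df, 3)
  expect_equal(fit_linear_joint(g1, g2, rnorm(300), "joint_3df")$df, 3)
})

test_that("swapping g1 and g2 leaves the interaction and statistics unchanged", {
  set.seed(23)
  g1 <- rgeno(250, 0.2); g2 <- rgeno(250, 0.35)
  d <- rbinom(250, 1, plogis(-1 + 0.3 * g1 + 0.2 * g1 * g2))
  for (kind in c("interaction_1df", "joint_3df")) {
    a <- fit_logistic_interaction(g1, g2, d, kind)
    b <- fit_logistic_interaction(g2, g1, d, kind)
    expect_equal(unname(coef(a)["g1:g2"]), unname(coef(b)["g1:g2"]),
                 tolerance = 1e-8)
    expect_equal(a$statistic, b$statistic, tolerance = 1e-7)
  }
  y <- rnorm(250, g1 * g2)
  a <- fit_linear_joint(g1, g2, y, "joint_3df")
  b <- fit_linear_joint(g2, g1, y, "joint_3df")
  expect_equal(a$statistic, b$statistic, tolerance = 1e-9)
})

test_that("joint 3-df LR test is invariant to allele relabeling", {
  set.seed(24)
  g1 <- rgeno(300, 0.3); g2 <- rgeno(300, 0.25)
  d <- rbinom(300, 1, plogis(-0.5 + 0.25 * g1 - 0.2 * g2 + 0.15 * g1 * g2))
  a <- fit_logistic_interaction(g1, g2, d, "joint_3df")
  b <- fit_logistic_interaction(2 - g1, g2, d, "joint_3df")
  c3 <- fit_logistic_interaction(2 - g1, 2 - g2, d, "joint_3df")
  expect_equal(a$statistic, b$statistic, tolerance = 1e-6)
  expect_equal(a$statistic, c3$statistic, tolerance = 1e-6)
})

test_that("degenerate inputs raise informative errors", {
  set.seed(25)
  g1 <- rgeno(100, 0.3); g2 <- rgeno(100, 0.3)
  expect_error(fit_logistic_interaction(g1, g2, rep(1, 100)), "one disease class")
  expect_error(fit_logistic_interaction(g1, 2 * g1, rbinom(100, 1, 0.5)),
               "rank deficient")
  # perfectly separating predictor
  d <- as.integer(g1 >= 1)
  expect_error(fit_logistic_interaction(g1, g2, d), "separation")
  expect_error(fit_linear_joint(g1, g2, rep(3, 100)), "constant")
})

test_that("1-df LR statistic is calibrated chi-square(1) under the null", {
  set.seed(26)
  reps <- 5000; n <- 300
  stats <- numeric(reps)
  for (k in seq_len(reps)) {
    g1 <- rgeno(n, 0.3); g2 <- rgeno(n, 0.3)
    d <- rbinom(n, 1, 0.4)
    stats[k] <- fit_logistic_interaction(g1, g2, d, "interaction_1df")$statistic
  }
  se <- sd(stats) / sqrt(reps)
  expect_lt(abs(mean(stats) - 1), 3 * se)
  # p-values approximately uniform as well
  p <- pchisq(stats, 1, lower.tail = FALSE)
  expect_lt(abs(mean(p <= 0.05) - 0.05), 3 * sqrt(0.05 * 0.95 / reps))
})

test_that("linear model recovers an exact interaction and matches normal equations", {
  g1 <- c(0, 0, 1, 1, 2, 2, 0, 1)
  g2 <- c(0, 1, 0, 1, 0, 2, 2, 2)
  y_exact <- 1 + g1 * g2
  fit <- fit_linear_joint(g1, g2, y_exact, "joint_3df")
  expect_equal(unname(coef(fit)), c(1, 0, 0, 1), tolerance = 1e-10)
  expect_identical(fit$p_value, 0)

  y <- c(2.1, 1.4, 3.3, 2.2, 0.9, 5.0, 1.1, 4.2)
  fit <- fit_linear_joint(g1, g2, y, "joint_3df")
  X <- cbind(1, g1, g2, g1 * g2)
  beta_ref <- solve(t(X) %*% X, t(X) %*% y)  # normal equations
  expect_equal(unname(coef(fit)), unname(drop(beta_ref)), tolerance = 1e-10)
  # F statistic against the lm/anova reference
  ref <- anova(lm(y ~ 1), lm(y ~ g1 * g2))
  expect_equal(fit$statistic, ref$F[2], tolerance = 1e-10)
  expect_equal(fit$p_value, ref$`Pr(>F)`[2], tolerance = 1e-10)
})

test_that("linear 3-df p-values are calibrated under a pure-noise trait", {
  set.seed(27)
  reps <- 2000; n <- 120
  p <- numeric(reps)
  for (k in seq_len(reps)) {
    g1 <- rgeno(n, 0.3); g2 <- rgeno(n, 0.3)
    p[k] <- fit_linear_joint(g1, g2, 2 + rnorm(n), "joint_3df")$p_value
  }
  expect_lt(abs(mean(p <= 0.05) - 0.05), 3 * sqrt(0.05 * 0.95 / reps))
  ks <- suppressWarnings(ks.test(p, "punif"))$statistic
  expect_lt(unname(ks), 0.035)
})

test_that("Wald and LR statistics agree to first order at large n", {
  set.seed(28)
  g1 <- rgeno(4000, 0.3); g2 <- rgeno(4000, 0.3)
  d <- rbinom(4000, 1, plogis(-0.8 + 0.15 * g1 * g2))
  lr <- fit_logistic_interaction(g1, g2, d, "interaction_1df", method = "lrt")
  wd <- fit_logistic_interaction(g1, g2, d, "interaction_1df", method = "wald")
  expect_equal(lr$statistic, wd$statistic, tolerance = 0.05)
})
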