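make_scan_data <- function(n = 400, p = 4, maf = 0.3, seed = 31) {
  set.seed(seed)
  G <- matrix(rgeno(n * p, maf), n, p,
              dimnames = list(NULL, paste0("SNP", seq_len(p))))
  d <- rbinom(n, 1, plogis(-0.5 + 0.4 * G[, 1] * G[, 2]))
  list(G = G, d = d)
}

test_that("config validates its knobs and ties selection to one of them", {
  expect_error(two_stage_config(alpha_screen = 0), "\\(0, 1\\]")
  expect_error(two_stage_config(alpha_screen = 1.2), "\\(0, 1\\]")
  expect_error(two_stage_config(selection = "top_m"), "requires m")
  expect_error(two_stage_config(family_alpha = 0), "\\(0, 1\\)")
  cfg <- two_stage_config(selection = "top_m", m = 3)
  expect_identical(cfg$m, 3L)
  cfg <- two_stage_config(alpha_screen = 0.1)
  expect_null(cfg$m)
})

test_that("a vacuous screen reduces to single-stage Bonferroni over all pairs", {
  dat <- make_scan_data()
  res <- run_two_stage(dat$G, dat$d, config = two_stage_config(alpha_screen = 1))
  n_pairs <- choose(ncol(dat$G), 2)
  expect_equal(res$n_tested, n_pairs)
  # reference: test every pair directly and Bonferroni-correct
  raw <- numeric(0)
  for (i in 1:(ncol(dat$G) - 1)) for (j in (i + 1):ncol(dat$G))
    raw <- c(raw, fit_logistic_interaction(dat$G[, i], dat$G[, j], dat$d,
                                           "interaction_1df")$p_value)
  expect_equal(res$tested$p, raw, tolerance = 1e-12)
  expect_equal(res$tested$adjusted_p, pmin(1, raw * n_pairs), tolerance = 1e-12)
})

test_that("empty selection is a valid empty result, not an error", {
  dat <- make_scan_data()
  res <- run_two_stage(dat$G, dat$d,
                       config = two_stage_config(selection = "top_m", m = 0))
  expect_equal(res$n_tested, 0)
  expect_equal(nrow(res$tested), 0)
  expect_equal(nrow(res$discoveries), 0)
  res2 <- run_two_stage(dat$G, dat$d,
                        config = two_stage_config(alpha_screen = 1e-12))
  expect_equal(res2$n_tested, 0)
})

test_that("shrinking alpha_screen never increases the number of tests", {
  dat <- make_scan_data(p = 6, seed = 33)
  alphas <- c(1, 0.5, 0.2, 0.05, 0.01, 0.001)
  n_tested <- vapply(alphas, function(a)
    run_two_stage(dat$G, dat$d,
                  config = two_stage_config(alpha_screen = a))$n_tested,
    integer(1))
  expect_true(all(diff(n_tested) <= 0))
})

test_that("top-m selection takes the m smallest screen p-values, ties by index", {
  dat <- make_scan_data(p = 5, seed = 34)
  full <- screen_all_pairs(dat$G, "pooled", dat$d)
  for (m in c(1, 3, 6)) {
    res <- run_two_stage(dat$G, dat$d,
                         config = two_stage_config(selection = "top_m", m = m))
    expect_equal(res$n_tested, m)
    want <- order(full$p)[seq_len(m)]
    expect_setequal(paste(res$tested$i, res$tested$j),
                    paste(full$i[want], full$j[want]))
  }
  # m larger than the number of pairs tests everything
  res <- run_two_stage(dat$G, dat$d,
                       config = two_stage_config(selection = "top_m", m = 99))
  expect_equal(res$n_tested, nrow(full))
})

test_that("permuting disease labels leaves the pooled screening stage fixed", {
  dat <- make_scan_data(seed = 35)
  set.seed(1)
  perm <- sample(dat$d)
  a <- run_two_stage(dat$G, dat$d, config = two_stage_config(alpha_screen = 0.5))
  b <- run_two_stage(dat$G, perm, config = two_stage_config(alpha_screen = 0.5))
  expect_identical(a$screened, b$screened)
  expect_equal(a$n_tested, b$n_tested)
  expect_false(isTRUE(all.equal(a$tested$p, b$tested$p)))
})

test_that("unscreenable pairs are excluded from selection and the denominator", {
  set.seed(36)
  G <- cbind(A = rgeno(200, 0.3), B = rep(1, 200), C = rgeno(200, 0.3))
  d <- rbinom(200, 1, 0.5)
  res <- run_two_stage(G, d, config = two_stage_config(alpha_screen = 1))
  expect_equal(sum(res$screened$screenable), 1)  # only (A, C)
  expect_equal(res$n_tested, 1)
  expect_equal(res$tested$feature1, "A")
  expect_equal(res$tested$feature2, "C")
  expect_equal(res$tested$adjusted_p, res$tested$p)  # Bonferroni over 1 test
})

test_that("a continuous trait routes the testing stage through the linear model", {
  set.seed(37)
  n <- 300
  G <- cbind(A = rgeno(n, 0.3), B = rgeno(n, 0.3), C = rgeno(n, 0.3))
  y <- 1 + 0.8 * G[, 1] * G[, 2] + rnorm(n)
  res <- run_two_stage(G, disease = NULL, trait = y,
                       config = two_stage_config(screen_scheme = "cases_only",
                                                 alpha_screen = 1,
                                                 test_kind = "joint_3df"))
  expect_equal(res$n_tested, 3)
  ref <- fit_linear_joint(G[, 1], G[, 2], y, "joint_3df")
  row <- res$tested[res$tested$feature1 == "A" & res$tested$feature2 == "B", ]
  expect_equal(row$p, ref$p_value, tolerance = 1e-12)
  expect_equal(row$b3, unname(coef(ref)["g1:g2"]), tolerance = 1e-12)
})

test_that("global-null FWER stays at or below the family level", {
  cal <- calibration_study(two_stage_config(), n_reps = 500, seed = 41)
  expect_lte(cal$fwer, 0.05 + 3 * sqrt(0.05 * 0.95 / 500))
  expect_lt(abs(cal$screen_rejection_rate - 0.05), 4 * cal$screen_se + 0.01)
})
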