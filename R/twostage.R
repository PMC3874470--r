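#' Configure a two-stage screening-testing scan
#'
#' Bundles the knobs of the two-stage procedure. Screening level and
#' testing-stage family level are independent: screening costs no
#' testing-stage alpha because the screen never looks at the phenotype.
#'
#' @param screen_scheme Stratum used by the screening stage: `"pooled"`
#'   (default), `"cases_only"` or `"controls_only"`.
#' @param selection `"p_threshold"` (screen p <= `alpha_screen`) or
#'   `"top_m"` (the `m` smallest screening p-values; boundary ties broken by
#'   pair index order).
#' @param alpha_screen Screening-stage level in (0, 1]; active when
#'   `selection = "p_threshold"`. Default 0.05.
#' @param m Number of pairs to carry forward; active when
#'   `selection = "top_m"`.
#' @param test_kind Testing-stage hypothesis: `"interaction_1df"`,
#'   `"main_plus_interaction_2df"` or `"joint_3df"`.
#' @param family_alpha Family-wise level for the testing stage (default
#'   0.05).
#' @param correction Multiplicity correction; `"bonferroni"` is the only
#'   built-in (see [permutation_fdr()] for the FDR alternative).
#' @return An object of class `two_stage_config`.
#' @export
two_stage_config <- function(screen_scheme = c("pooled", "cases_only", "controls_only"),
                             selection = c("p_threshold", "top_m"),
                             alpha_screen = 0.05, m = NULL,
                             test_kind = TEST_KINDS,
                             family_alpha = 0.05,
                             correction = "bonferroni") {
  screen_scheme <- match.arg(screen_scheme)
  selection <- match.arg(selection)
  test_kind <- match.arg(test_kind)
  correction <- match.arg(correction, "bonferroni")
  if (selection == "p_threshold") {
    if (!is.numeric(alpha_screen) || alpha_screen <= 0 || alpha_screen > 1)
      stop("alpha_screen must lie in (0, 1]")
    m <- NULL
  } else {
    if (is.null(m) || m < 0) stop("selection = 'top_m' requires m >= 0")
    m <- as.integer(m)
  }
  if (!is.numeric(family_alpha) || family_alpha <= 0 || family_alpha >= 1)
    stop("family_alpha must lie in (0, 1)")
  structure(list(screen_scheme = screen_scheme, selection = selection,
                 alpha_screen = alpha_screen, m = m, test_kind = test_kind,
                 family_alpha = family_alpha, correction = correction),
            class = "two_stage_config")
}

#' @export
print.two_stage_config <- function(x, ...) {
  sel <- if (x$selection == "p_threshold")
    sprintf("screen p <= %.4g", x$alpha_screen) else sprintf("top %d pairs", x$m)
  cat(sprintf("Two-stage config: %s screen, %s; test %s; %s at family alpha %.4g\n",
              x$screen_scheme, sel, x$test_kind, x$correction, x$family_alpha))
  invisible(x)
}

select_pairs <- function(screened, config) {
  ok <- which(screened$screenable)
  if (config$selection == "p_threshold") {
    ok[screened$p[ok] <= config$alpha_screen]
  } else {
    # ties at the top-m boundary broken by pair index order: rows are already
    # in (i, j) order, and order() is stable
    ok[order(screened$p[ok])[seq_len(min(config$m, length(ok)))]]
  }
}

#' Run the two-stage screening-testing procedure
#'
#' Screens every feature pair with the composite-LD statistic on the
#' configured stratum, selects the survivors, fits the testing-stage model
#' to each selected pair on the full supplied sample, and applies the
#' Bonferroni correction over only the tests actually conducted. This is the
#' central validity contract: because the screening statistic is strictly a
#' function of the feature values (never the phenotype), the testing-stage
#' family is legitimately reduced to the selected pairs, and type I error is
#' controlled even when the feature-independence assumption behind the
#' screen is violated.
#'
#' If a continuous `trait` is supplied the testing stage uses
#' [fit_linear_joint()] (the within-diseased design); otherwise
#' [fit_logistic_interaction()] on `disease`.
#'
#' @param G Numeric matrix, individuals x features.
#' @param disease Binary outcome vector, or `NULL` for a single-stratum
#'   sample analyzed with a continuous trait.
#' @param trait Optional continuous outcome; when present the testing stage
#'   is linear.
#' @param config A [two_stage_config()].
#' @return An object of class `two_stage_result`: `screened` (the
#'   [screen_all_pairs()] table), `tested` (data frame of testing-stage
#'   records with `adjusted_p = min(1, p * n_tested)`), `n_tested`,
#'   `discoveries` (tested rows with `adjusted_p <= family_alpha`), and the
#'   `config`. No pair passing the screen is a valid empty result, not an
#'   error.
#' @examples
#' set.seed(2)
#' G <- matrix(rbinom(400 * 4, 2, 0.3), ncol = 4,
#'             dimnames = list(NULL, paste0("SNP", 1:4)))
#' d <- rbinom(400, 1, 0.3)
#' run_two_stage(G, d, config = two_stage_config(alpha_screen = 0.5))
#' @export
run_two_stage <- function(G, disease = NULL, trait = NULL,
                          config = two_stage_config()) {
  stopifnot(inherits(config, "two_stage_config"))
  G <- as.matrix(G)
  if (is.null(disease) && is.null(trait))
    stop("at least one of disease or trait must be supplied")
  if (!is.null(trait) && length(trait) != nrow(G))
    stop("trait length does not match genotype rows")
  screened <- screen_all_pairs(G, scheme = config$screen_scheme,
                               disease = disease)
  sel <- select_pairs(screened, config)
  n_tested <- length(sel)

  tested <- data.frame(i = integer(), j = integer(),
                       feature1 = character(), feature2 = character(),
                       test_kind = character(),
                       b0 = numeric(), b1 = numeric(), b2 = numeric(),
                       b3 = numeric(), statistic = numeric(), df = integer(),
                       p = numeric(), adjusted_p = numeric(),
                       stringsAsFactors = FALSE)
  for (k in sel) {
    i <- screened$i[k]; j <- screened$j[k]
    rec <- if (!is.null(trait))
      fit_linear_joint(G[, i], G[, j], trait, test_kind = config$test_kind)
    else
      fit_logistic_interaction(G[, i], G[, j], disease,
                               test_kind = config$test_kind)
    tested[nrow(tested) + 1L, ] <-
      list(i, j, screened$feature1[k], screened$feature2[k], config$test_kind,
           rec$coefficients[1], rec$coefficients[2], rec$coefficients[3],
           rec$coefficients[4], rec$statistic, rec$df, rec$p_value, NA_real_)
  }
  tested$adjusted_p <- pmin(1, tested$p * n_tested)
  discoveries <- tested[tested$adjusted_p <= config$family_alpha, , drop = FALSE]

  structure(list(screened = screened, tested = tested, n_tested = n_tested,
                 discoveries = discoveries, config = config),
            class = "two_stage_result")
}

#' @export
print.two_stage_result <- function(x, ...) {
  cat(sprintf("Two-stage scan: %d pairs screened (%d screenable), %d tested, %d discoveries\n",
              nrow(x$screened), sum(x$screened$screenable), x$n_tested,
              nrow(x$discoveries)))
  if (nrow(x$discoveries) > 0) {
    cat("Discoveries (Bonferroni over tests conducted):\n")
    print(x$discoveries[, c("feature1", "feature2", "b3", "statistic", "df",
                            "p", "adjusted_p")], row.names = FALSE)
  }
  invisible(x)
}

#' @export
summary.two_stage_result <- function(object, ...) {
  cat("Two-stage screening-testing scan\n")
  print(object$config)
  cat(sprintf("  pairs screened:   %d (%d screenable)\n",
              nrow(object$screened), sum(object$screened$screenable)))
  cat(sprintf("  pairs tested:     %d\n", object$n_tested))
  cat(sprintf("  discoveries:      %d at family alpha %.4g\n",
              nrow(object$discoveries), object$config$family_alpha))
  if (object$n_tested > 0) {
    cat("  tested pairs:\n")
    print(object$tested[, c("feature1", "feature2", "b3", "statistic", "df",
                            "p", "adjusted_p")], row.names = FALSE)
  }
  invisible(object)
}
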