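# Plug-in permutation estimator of the false discovery rate for
# screening-testing scans. Valid under exchangeability of observations under
# the null of feature-phenotype independence; labels (not genotype rows) are
# permuted, which is equivalent under row exchangeability and cheaper.

test_pair_p <- function(G, i, j, disease, trait, config) {
  rec <- if (!is.null(trait))
    fit_linear_joint(G[, i], G[, j], trait, test_kind = config$test_kind)
  else
    fit_logistic_interaction(G[, i], G[, j], disease,
                             test_kind = config$test_kind)
  rec$p_value
}

#' Permutation-based plug-in FDR for a two-stage scan
#'
#' Estimates, for each p-value threshold t, the false discovery rate of the
#' testing stage as
#' \deqn{\widehat{FDR}(t) = \frac{\bar N_0(t)}{N(t)}}
#' where N(t) is the number of observed testing-stage p-values <= t and
#' \eqn{\bar N_0(t)} the average count under phenotype permutation, capped
#' at 1. The estimator is usable with very few permutations (default 10);
#' no null-proportion correction is applied, so it is conservative.
#'
#' For configurations whose screening stage never reads the permuted
#' phenotype (the pooled scheme, any single-stratum sample, and all
#' continuous-trait designs), screening and selection are computed once and
#' only the testing stage is recomputed per permutation. This is an exact
#' optimization, bit-identical to naive full recomputation. When the screen
#' itself depends on the permuted labels (cases-only or controls-only
#' screening of a binary outcome), the full scan is re-run per permutation.
#'
#' @inheritParams run_two_stage
#' @param n_perm Number of permutations (>= 1). Default 10.
#' @param thresholds Vector of testing-stage p-value cutoffs.
#' @param seed Integer seed for the permutation stream.
#' @param recompute `"auto"` (default; use the exact once-screened shortcut
#'   when valid) or `"always"` (force naive full recomputation, mainly for
#'   verification).
#' @return A data frame of class `fdr_estimates` with one row per
#'   threshold: `threshold`, `n_observed`, `mean_null`, `fdr_hat`, `mc_se`
#'   (Monte-Carlo standard error of `fdr_hat` over permutations), `flagged`
#'   (`TRUE` when `n_observed = 0`, where `fdr_hat` is reported as 0 by
#'   convention), `n_perm`. The per-permutation null counts are attached as
#'   `attr(, "perm_counts")`.
#' @export
permutation_fdr <- function(G, disease = NULL, trait = NULL,
                            config = two_stage_config(),
                            n_perm = 10, thresholds = c(0.05, 0.01, 0.001),
                            seed = 1, recompute = c("auto", "always")) {
  recompute <- match.arg(recompute)
  if (n_perm < 1) stop("n_perm must be >= 1")
  G <- as.matrix(G)
  thresholds <- sort(as.numeric(thresholds))

  observed <- run_two_stage(G, disease = disease, trait = trait, config = config)
  obs_p <- observed$tested$p
  n_observed <- vapply(thresholds, function(t) sum(obs_p <= t), integer(1))

  permute_trait <- !is.null(trait)
  screen_label_free <- permute_trait || is.null(disease) ||
    config$screen_scheme == "pooled"
  use_shortcut <- screen_label_free && recompute == "auto"

  set.seed(as.integer(seed))
  counts <- matrix(0L, n_perm, length(thresholds))
  for (b in seq_len(n_perm)) {
    perm <- sample.int(nrow(G))
    d_b <- if (permute_trait) disease else disease[perm]
    y_b <- if (permute_trait) trait[perm] else NULL
    if (use_shortcut) {
      sel <- select_pairs(observed$screened, config)
      p_b <- vapply(sel, function(k)
        test_pair_p(G, observed$screened$i[k], observed$screened$j[k],
                    d_b, y_b, config), numeric(1))
    } else {
      p_b <- run_two_stage(G, disease = d_b, trait = y_b, config = config)$tested$p
    }
    counts[b, ] <- vapply(thresholds, function(t) sum(p_b <= t), integer(1))
  }

  mean_null <- colMeans(counts)
  flagged <- n_observed == 0
  fdr_hat <- ifelse(flagged, 0, pmin(1, mean_null / pmax(n_observed, 1L)))
  mc_se <- ifelse(flagged, NA_real_,
                  apply(counts, 2, stats::sd) / sqrt(n_perm) / pmax(n_observed, 1L))

  out <- data.frame(threshold = thresholds, n_observed = n_observed,
                    mean_null = mean_null, fdr_hat = fdr_hat, mc_se = mc_se,
                    flagged = flagged, n_perm = n_perm)
  attr(out, "perm_counts") <- counts
  class(out) <- c("fdr_estimates", "data.frame")
  out
}

#' @export
print.fdr_estimates <- function(x, ...) {
  cat(sprintf("Plug-in permutation FDR (%d permutations)\n", x$n_perm[1]))
  print.data.frame(round_df(x[, c("threshold", "n_observed", "mean_null",
                                  "fdr_hat", "mc_se")], 4), row.names = FALSE)
  if (any(x$flagged))
    cat("note: thresholds with no observed discoveries report fdr_hat = 0 by convention\n")
  invisible(x)
}

round_df <- function(df, digits) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], round, digits = digits)
  df
}
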