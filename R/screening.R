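#' Screen one feature pair for composite linkage disequilibrium
#'
#' The screening-stage statistic: Pearson's product-moment correlation
#' between two additively coded features, referred to the t distribution
#' with n - 2 degrees of freedom,
#' \eqn{t = r \sqrt{(n-2)/(1-r^2)}}, two-sided. For genotype pairs this is
#' the composite-LD screen; continuous environmental exposures are accepted
#' by the same operation unchanged.
#'
#' Missing values are handled pairwise complete-case, with the effective n
#' (and degrees of freedom) recomputed. A perfectly correlated pair
#' (|r| = 1) is reported with `t = +/-Inf` and p-value 0.
#'
#' @param g1,g2 Numeric vectors of equal length (>= 3 complete pairs), each
#'   with nonzero variance on the complete cases.
#' @return An object of class `screen_record`: list with `r`, `t_stat`,
#'   `df`, `p_value`, `n`.
#' @examples
#' composite_ld_screen(c(0, 0, 1, 2, 1), c(0, 1, 1, 2, 0))
#' @export
composite_ld_screen <- function(g1, g2) {
  if (length(g1) != length(g2)) stop("g1 and g2 must have equal length")
  ok <- stats::complete.cases(g1, g2)
  x <- as.numeric(g1[ok]); y <- as.numeric(g2[ok])
  n <- length(x)
  if (n < 3) stop("need at least 3 complete observation pairs, got ", n)
  if (stats::var(x) == 0 || stats::var(y) == 0)
    stop("constant feature vector: pair is unscreenable")
  r <- stats::cor(x, y)
  df <- n - 2L
  if (abs(r) >= 1) {
    r <- sign(r)
    t_stat <- sign(r) * Inf
    p <- 0
  } else {
    t_stat <- r * sqrt(df / (1 - r^2))
    p <- 2 * stats::pt(-abs(t_stat), df)
  }
  structure(list(r = r, t_stat = t_stat, df = df, p_value = p, n = n),
            class = "screen_record")
}

#' @export
print.screen_record <- function(x, ...) {
  cat(sprintf("Composite-LD screen: r = %.4g, t = %.4g on %d df, p = %.4g (n = %d)\n",
              x$r, x$t_stat, x$df, x$p_value, x$n))
  invisible(x)
}

select_scheme_rows <- function(n, scheme, disease) {
  if (is.null(disease)) return(seq_len(n))  # sample is already one stratum
  if (length(disease) != n) stop("disease vector length does not match genotype rows")
  switch(scheme,
         pooled = seq_len(n),
         cases_only = which(disease == 1),
         controls_only = which(disease == 0),
         stop("unknown scheme: ", scheme))
}

#' Screen every unordered feature pair
#'
#' Runs [composite_ld_screen()] on each unordered column pair (j < k) of the
#' feature matrix, restricted to the rows selected by the sampling scheme.
#' The screen is strictly a function of the feature values on those rows: the
#' disease vector is used only to pick the stratum, never in the statistic,
#' which is what makes downstream testing-stage multiplicity correction
#' valid.
#'
#' A column that is monomorphic (zero variance) within the selected stratum
#' makes its pairs unscreenable: the record is kept, flagged with
#' `screenable = FALSE` and `NA` statistics, and such pairs are excluded from
#' selection by [run_two_stage()].
#'
#' @param G Numeric matrix, individuals x features (genotypes coded 0/1/2
#'   and/or continuous exposures). Column names are used as feature names.
#' @param scheme One of `"pooled"`, `"cases_only"`, `"controls_only"`.
#' @param disease Binary vector used to select the stratum; may be `NULL`
#'   when the matrix is already a single-stratum sample.
#' @return A data frame of class `screen_table`, one row per pair in
#'   lexicographic (j, k) order: columns `i`, `j`, `feature1`, `feature2`,
#'   `scheme`, `n`, `r`, `t`, `df`, `p`, `screenable`.
#' @export
screen_all_pairs <- function(G, scheme = c("pooled", "cases_only", "controls_only"),
                             disease = NULL) {
  scheme <- match.arg(scheme)
  G <- as.matrix(G)
  if (ncol(G) < 2) stop("need at least two feature columns")
  rows <- select_scheme_rows(nrow(G), scheme, disease)
  if (length(rows) < 3) stop("selected stratum has fewer than 3 individuals")
  S <- G[rows, , drop = FALSE]
  p <- ncol(S)
  nms <- colnames(S)
  if (is.null(nms)) nms <- paste0("F", seq_len(p))

  pairs <- which(upper.tri(matrix(0, p, p)), arr.ind = TRUE)
  pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]

  out <- data.frame(i = pairs[, 1], j = pairs[, 2],
                    feature1 = nms[pairs[, 1]], feature2 = nms[pairs[, 2]],
                    scheme = scheme, n = NA_integer_, r = NA_real_,
                    t = NA_real_, df = NA_integer_, p = NA_real_,
                    screenable = TRUE, stringsAsFactors = FALSE)
  for (k in seq_len(nrow(out))) {
    rec <- tryCatch(composite_ld_screen(S[, out$i[k]], S[, out$j[k]]),
                    error = function(e) NULL)
    if (is.null(rec)) {
      out$screenable[k] <- FALSE
    } else {
      out$n[k] <- rec$n; out$r[k] <- rec$r; out$t[k] <- rec$t_stat
      out$df[k] <- rec$df; out$p[k] <- rec$p_value
    }
  }
  rownames(out) <- NULL
  class(out) <- c("screen_table", "data.frame")
  out
}
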