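# Independent oracles, written against the definitions rather than the
# package internals, plus small data builders shared across test files.

# Exact expected prevalence by enumerating the 9 two-locus genotype cells
# under HWE and SNP independence (does not call package code).
oracle_prevalence <- function(lambda, b1, b2, b3, q1, q2) {
  hwe <- function(q) c((1 - q)^2, 2 * q * (1 - q), q^2)
  total <- 0
  for (g1 in 0:2) for (g2 in 0:2) {
    risk <- min(1, exp(lambda + b1 * g1 + b2 * g2 + b3 * g1 * g2))
    total <- total + hwe(q1)[g1 + 1] * hwe(q2)[g2 + 1] * risk
  }
  total
}

# P(g1, g2 | D = 1) by Bayes' rule over the same 9 cells.
oracle_case_genotype_freq <- function(lambda, b1, b2, b3, q1, q2) {
  hwe <- function(q) c((1 - q)^2, 2 * q * (1 - q), q^2)
  joint <- matrix(0, 3, 3, dimnames = list(g1 = 0:2, g2 = 0:2))
  for (g1 in 0:2) for (g2 in 0:2) {
    risk <- min(1, exp(lambda + b1 * g1 + b2 * g2 + b3 * g1 * g2))
    joint[g1 + 1, g2 + 1] <- hwe(q1)[g1 + 1] * hwe(q2)[g2 + 1] * risk
  }
  joint / sum(joint)
}

# Pearson r, t and two-sided p from the raw product-moment formula.
oracle_pearson <- function(x, y) {
  n <- length(x)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  sxx <- sum((x - mean(x))^2)
  syy <- sum((y - mean(y))^2)
  r <- sxy / sqrt(sxx * syy)
  t <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, t = t, df = n - 2, p = 2 * pt(-abs(t), n - 2))
}

# Saturated-model interaction log-odds-ratio-ratio from a 2x2x2 table of
# counts n[d, g1, g2] with d, g1, g2 in {0, 1} (1-based indices offset).
oracle_lorr <- function(n) {
  or1 <- (n["1", "1", "1"] * n["1", "0", "0"]) / (n["1", "1", "0"] * n["1", "0", "1"])
  or0 <- (n["0", "1", "1"] * n["0", "0", "0"]) / (n["0", "1", "0"] * n["0", "0", "1"])
  log(or1 / or0)
}

# Expand a 2x2x2 count table into individual-level vectors.
expand_table <- function(n) {
  d <- g1 <- g2 <- integer(0)
  for (dd in 0:1) for (a in 0:1) for (b in 0:1) {
    k <- n[as.character(dd), as.character(a), as.character(b)]
    d <- c(d, rep(dd, k)); g1 <- c(g1, rep(a, k)); g2 <- c(g2, rep(b, k))
  }
  list(d = d, g1 = g1, g2 = g2)
}

make_table <- function(counts) {
  array(counts, dim = c(2, 2, 2),
        dimnames = list(d = c("0", "1"), g1 = c("0", "1"), g2 = c("0", "1")))
}

# HWE genotype vector.
rgeno <- function(n, maf) rbinom(n, 2L, maf)

# Multi-SNP spiked cohort: pairs (1,2), (3,4), ... of the first
# 2 * n_true_pairs SNPs carry a pure interaction effect on disease risk;
# remaining SNPs are null. Case-control ascertained.
make_spiked_sample <- function(n_pop = 20000, p = 15, n_true_pairs = 5,
                               maf = 0.3, base_risk = 0.05,
                               rr_interaction = 2, n_cases = 750,
                               n_controls = 750) {
  G <- matrix(rbinom(n_pop * p, 2L, maf), n_pop, p,
              dimnames = list(NULL, paste0("SNP", seq_len(p))))
  logrisk <- rep(log(base_risk), n_pop)
  true_pairs <- lapply(seq_len(n_true_pairs), function(k) c(2 * k - 1, 2 * k))
  for (pr in true_pairs)
    logrisk <- logrisk + log(rr_interaction) * G[, pr[1]] * G[, pr[2]]
  d <- rbinom(n_pop, 1L, pmin(1, exp(logrisk)))
  idx <- c(sample(which(d == 1), n_cases), sample(which(d == 0), n_controls))
  list(G = G[idx, , drop = FALSE], disease = d[idx], true_pairs = true_pairs)
}
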