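#' Generate the seeded fixture datasets used by the test suite
#'
#' Writes four small deterministic two-SNP case-control datasets as paired
#' tab-delimited feature/phenotype tables under `dir`:
#' \describe{
#'   \item{null_pair}{no genetic effects at all (global null).}
#'   \item{main_effects}{strong equal main effects (RR 2 per allele), no
#'     interaction.}
#'   \item{interaction_only}{no main effects, strong interaction (RR 3),
#'     the classic case-only signal.}
#'   \item{headline_sample}{the headline simulation configuration: baseline
#'     risk 5\%, MAF 0.2, main-effect RR 2, interaction RR 1.1, 1000 cases
#'     + 1000 controls.}
#' }
#' Files are regenerable bit-identically from the seed.
#'
#' @param dir Output directory (created if needed).
#' @param seed Integer master seed. Default 1.
#' @param n_cases,n_controls Sample sizes per dataset (default 250 each,
#'   except `headline_sample` which uses 1000 + 1000).
#' @return Invisibly, a named list of the file paths written.
#' @export
generate_fixtures <- function(dir, seed = 1, n_cases = 250, n_controls = 250) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  specs <- list(
    null_pair = list(model = population_model(), nca = n_cases, nco = n_controls,
                     n_pop = 20000),
    main_effects = list(model = population_model(beta1 = log(2), beta2 = log(2)),
                        nca = n_cases, nco = n_controls, n_pop = 20000),
    interaction_only = list(model = population_model(beta3 = log(3)),
                            nca = n_cases, nco = n_controls, n_pop = 20000),
    headline_sample = list(model = population_model(beta1 = log(2), beta2 = log(2),
                                                   beta3 = log(1.1)),
                          nca = 1000, nco = 1000, n_pop = 40000)
  )
  seeds <- derive_seeds(seed, 2 * length(specs))
  paths <- list()
  for (k in seq_along(specs)) {
    nm <- names(specs)[k]; sp <- specs[[k]]
    pop <- suppressWarnings(simulate_population(sp$model, sp$n_pop,
                                                seed = seeds[2 * k - 1]))
    samp <- sample_case_control(pop, sp$nca, sp$nco, seed = seeds[2 * k])
    ids <- sprintf("%s_%04d", nm, seq_len(nrow(samp$genotypes)))
    fpath <- file.path(dir, paste0(nm, "_features.tsv"))
    ppath <- file.path(dir, paste0(nm, "_phenotypes.tsv"))
    M <- samp$genotypes; rownames(M) <- ids
    write_feature_table(M, fpath)
    write_phenotype_table(ids, disease = samp$disease, path = ppath)
    paths[[nm]] <- c(features = fpath, phenotypes = ppath)
  }
  invisible(paths)
}
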