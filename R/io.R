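# Data ingestion and result serialization. Feature tables are tab-delimited
# (first column `id`, then one numeric column per feature); VCF ingestion
# converts biallelic sites to additive minor-allele dosages. All writers
# produce stable column orders and headers.

#' Read a feature table
#'
#' Loads an individuals x features matrix from tab-delimited text or from a
#' VCF. Delimited input must have an `id` column followed by numeric feature
#' columns (genotypes coded 0/1/2 and/or continuous exposures). VCF input
#' (requires the `vcfR` package) keeps biallelic sites only — multiallelic
#' sites are skipped with a message — and converts genotypes to additive
#' dosage of the minor allele; when the ALT allele frequency in the sample
#' exceeds 0.5 the dosage is flipped so the counted allele is the minor one,
#' and each flip is reported. VCF positions are 1-based per the standard;
#' internal feature indices are the 1-based column positions in file order.
#'
#' @param path Path to the file.
#' @param format `"delimited"` (default) or `"vcf"`.
#' @return An object of class `feature_table`: list with `ids` (character),
#'   `features` (numeric matrix with column names), `feature_kinds`
#'   (`"genotype"` or `"exposure"` per column, inferred for delimited input
#'   from whether all non-missing values are in \{0, 1, 2\}).
#' @export
read_feature_table <- function(path, format = c("delimited", "vcf")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "vcf") return(read_feature_table_vcf(path))
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2 || names(df)[1] != "id")
    stop("delimited feature table must have an 'id' column followed by feature columns")
  ids <- as.character(df$id)
  if (anyDuplicated(ids)) stop("duplicate individual ids in ", path)
  feats <- df[, -1, drop = FALSE]
  bad <- !vapply(feats, is.numeric, logical(1))
  if (any(bad)) {
    lines <- which(!vapply(feats[[which(bad)[1]]], function(v)
      !is.na(suppressWarnings(as.numeric(v))), logical(1)))
    stop(sprintf("malformed non-numeric values in column '%s' (e.g. data row %d)",
                 names(feats)[which(bad)[1]], lines[1]))
  }
  M <- as.matrix(feats)
  all_missing <- colSums(!is.na(M)) == 0
  if (any(all_missing)) {
    warning("dropping all-missing feature column(s): ",
            paste(colnames(M)[all_missing], collapse = ", "))
    M <- M[, !all_missing, drop = FALSE]
  }
  if (anyDuplicated(colnames(M))) stop("duplicate feature names in ", path)
  new_feature_table(ids, M)
}

new_feature_table <- function(ids, M) {
  kinds <- apply(M, 2, function(v) {
    v <- v[!is.na(v)]
    if (length(v) > 0 && all(v %in% 0:2)) "genotype" else "exposure"
  })
  structure(list(ids = ids, features = M, feature_kinds = kinds),
            class = "feature_table")
}

read_feature_table_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("VCF input requires the 'vcfR' package")
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  alt <- vcfR::getALT(vcf)
  biallelic <- !is.na(alt) & !grepl(",", alt)
  if (any(!biallelic))
    message(sum(!biallelic), " multiallelic site(s) skipped")
  vcf <- vcf[biallelic, ]
  gt <- vcfR::extract.gt(vcf, element = "GT")
  dose <- apply(gt, c(1, 2), function(g) {
    if (is.na(g)) return(NA_real_)
    alleles <- strsplit(g, "[/|]")[[1]]
    if (any(alleles == ".")) return(NA_real_)
    sum(alleles != "0")
  })
  site_ids <- paste0(vcfR::getCHROM(vcf), ":", vcfR::getPOS(vcf))
  M <- t(dose)  # individuals x sites
  colnames(M) <- site_ids
  # minor-allele orientation from the sample when the ALT allele is major
  for (k in seq_len(ncol(M))) {
    af <- mean(M[, k], na.rm = TRUE) / 2
    if (!is.nan(af) && af > 0.5) {
      M[, k] <- 2 - M[, k]
      message("site ", colnames(M)[k],
              ": ALT allele is major (freq ", round(af, 3),
              "); dosage flipped to minor-allele count")
    }
  }
  new_feature_table(rownames(M), M)
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("Feature table: %d individuals x %d features (%d genotype, %d exposure)\n",
              length(x$ids), ncol(x$features),
              sum(x$feature_kinds == "genotype"),
              sum(x$feature_kinds == "exposure")))
  invisible(x)
}

#' Write a feature table as tab-delimited text
#'
#' Inverse of [read_feature_table()] for the delimited format.
#'
#' @param x A `feature_table`, or a numeric matrix (row names used as ids).
#' @param path Output path.
#' @export
write_feature_table <- function(x, path) {
  if (inherits(x, "feature_table")) {
    ids <- x$ids; M <- x$features
  } else {
    M <- as.matrix(x)
    ids <- if (!is.null(rownames(M))) rownames(M) else as.character(seq_len(nrow(M)))
  }
  df <- data.frame(id = ids, M, check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a phenotype table
#'
#' Tab-delimited with columns `id`, then `disease` (0/1) and/or `trait`
#' (continuous). Rows with all phenotypes missing are dropped with a
#' message.
#'
#' @param path Path to the file.
#' @return List of class `phenotype_table`: `ids`, `disease` (integer or
#'   `NULL`), `trait` (numeric or `NULL`).
#' @export
read_phenotype_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!"id" %in% names(df)) stop("phenotype table must have an 'id' column")
  has_d <- "disease" %in% names(df); has_t <- "trait" %in% names(df)
  if (!has_d && !has_t)
    stop("phenotype table must have a 'disease' and/or 'trait' column")
  keep <- rep(FALSE, nrow(df))
  if (has_d) keep <- keep | !is.na(df$disease)
  if (has_t) keep <- keep | !is.na(df$trait)
  if (any(!keep)) {
    message(sum(!keep), " individual(s) with all phenotypes missing dropped")
    df <- df[keep, , drop = FALSE]
  }
  if (has_d && !all(df$disease %in% c(0, 1, NA)))
    stop("disease column must be binary 0/1")
  structure(list(ids = as.character(df$id),
                 disease = if (has_d) as.integer(df$disease) else NULL,
                 trait = if (has_t) as.numeric(df$trait) else NULL),
            class = "phenotype_table")
}

#' Write a phenotype table
#'
#' @param ids Individual identifiers.
#' @param disease Optional binary vector.
#' @param trait Optional continuous vector.
#' @param path Output path.
#' @export
write_phenotype_table <- function(ids, disease = NULL, trait = NULL, path) {
  df <- data.frame(id = ids, stringsAsFactors = FALSE)
  if (!is.null(disease)) df$disease <- as.integer(disease)
  if (!is.null(trait)) df$trait <- trait
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Align a feature table with a phenotype table by id
#'
#' Inner join on individual id; errors if no individuals are shared.
#'
#' @param features A `feature_table`.
#' @param phenotypes A `phenotype_table`.
#' @return List with `G` (feature matrix), `disease`, `trait`, `ids`.
#' @export
align_tables <- function(features, phenotypes) {
  common <- intersect(features$ids, phenotypes$ids)
  if (length(common) == 0) stop("no shared individual ids between tables")
  fi <- match(common, features$ids); pi <- match(common, phenotypes$ids)
  list(G = features$features[fi, , drop = FALSE],
       disease = if (!is.null(phenotypes$disease)) phenotypes$disease[pi] else NULL,
       trait = if (!is.null(phenotypes$trait)) phenotypes$trait[pi] else NULL,
       ids = common)
}

#' Write screening results as tab-delimited text
#'
#' Stable column order: `i`, `j`, `feature1`, `feature2`, `scheme`, `n`,
#' `r`, `t`, `df`, `p`, `screenable`.
#'
#' @param screened A `screen_table` from [screen_all_pairs()].
#' @param path Output path.
#' @export
write_screen_table <- function(screened, path) {
  utils::write.table(as.data.frame(screened), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write testing-stage results as tab-delimited text
#'
#' @param tested The `tested` data frame of a [run_two_stage()] result.
#' @param path Output path.
#' @export
write_test_table <- function(tested, path) {
  utils::write.table(tested, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a two-stage configuration from YAML
#'
#' Keys mirror the arguments of [two_stage_config()]; missing keys take the
#' defaults.
#'
#' @param path Path to a YAML file.
#' @return A [two_stage_config()].
#' @export
read_two_stage_config <- function(path) {
  y <- yaml::read_yaml(path)
  allowed <- names(formals(two_stage_config))
  unknown <- setdiff(names(y), allowed)
  if (length(unknown) > 0)
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  do.call(two_stage_config, y)
}

#' Write a machine-readable run manifest
#'
#' Records the configuration, seed and package version of an analysis run
#' as JSON, sufficient to reproduce its outputs exactly.
#'
#' @param path Output path.
#' @param seed Seed used.
#' @param config Configuration object or list.
#' @param extra Optional named list of additional fields.
#' @export
write_run_manifest <- function(path, seed, config, extra = list()) {
  manifest <- c(list(package = "episcreen",
                     version = as.character(utils::packageVersion("episcreen")),
                     timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                     seed = seed,
                     config = unclass(config)),
                extra)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, null = "null",
                       pretty = TRUE)
  invisible(path)
}
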