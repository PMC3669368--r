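## Tabular I/O for genotypes, phenotypes, power tables and run configs.

#' Write / read a genotype matrix as TSV
#'
#' Individuals x SNPs table of 0/1/2 codes with a header of SNP ids.
#'
#' @param genotypes a [genotype_matrix].
#' @param path file path.
#' @return `read_genotype_tsv` returns a [genotype_matrix].
#' @export
write_genotype_tsv <- function(genotypes, path) {
  X <- .as_genotype_values(genotypes)
  ids <- if (inherits(genotypes, "genotype_matrix") &&
             !is.null(genotypes$snp_ids)) genotypes$snp_ids
         else paste0("snp", seq_len(ncol(X)))
  colnames(X) <- ids
  write.table(X, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_genotype_tsv
#' @export
read_genotype_tsv <- function(path) {
  X <- as.matrix(read.table(path, header = TRUE, sep = "\t",
                            check.names = FALSE))
  if (!all(X %in% 0:2))
    stop("genotype TSV contains entries outside {0, 1, 2}: ", path)
  genotype_matrix(X, snp_ids = colnames(X))
}

#' Write / read a case-control phenotype vector as TSV
#'
#' Two columns: individual id and 0/1 status, aligned with the genotype
#' file's row order.
#'
#' @param status 0/1 vector.
#' @param path file path.
#' @return `read_phenotype_tsv` returns the integer status vector.
#' @export
write_phenotype_tsv <- function(status, path) {
  write.table(data.frame(individual = seq_along(status),
                         status = as.integer(status)),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_phenotype_tsv
#' @export
read_phenotype_tsv <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t")
  if (!all(df$status %in% 0:1)) stop("status entries must be 0/1: ", path)
  as.integer(df$status)
}

#' Read genotypes from a VCF file
#'
#' Converts GT fields to additive minor-allele counts. Multi-allelic sites
#' and missing genotypes are rejected.
#'
#' @param path VCF file path (uncompressed or gzipped).
#' @return A [genotype_matrix] (individuals x SNPs) with positions and ids.
#' @export
read_genotype_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("the vcfR package is required to read VCF input")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  alt <- vcfR::getALT(v)
  if (any(grepl(",", alt, fixed = TRUE)))
    stop("multi-allelic sites are not supported")
  gt <- vcfR::extract.gt(v, element = "GT")
  if (anyNA(gt)) stop("missing genotypes are not supported")
  gt <- gsub("|", "/", gt, fixed = TRUE)
  a1 <- substr(gt, 1, 1)
  a2 <- substr(gt, 3, 3)
  if (!all(c(a1, a2) %in% c("0", "1")) || !all(nchar(gt) == 3))
    stop("only diploid biallelic GT fields (0/0, 0/1, 1/1) are supported")
  G <- t(matrix((a1 == "1") + (a2 == "1"), nrow(gt), ncol(gt)))
  genotype_matrix(G, positions = as.numeric(vcfR::getPOS(v)),
                  snp_ids = vcfR::getID(v))
}

## ---- power-table round trip ----------------------------------------------

.power_numeric_cols <- c("n_causal", "n_noncausal", "rr", "n_total",
                         "maf_causal", "maf_noncausal", "ld_high",
                         "n_blocks", "alpha", "replicates", "n_failed",
                         "power", "se")

#' Write / read a power table as TSV
#'
#' Numeric columns are rendered with 17 significant digits so estimates
#' re-parse bit-identically.
#'
#' @param power_table power table from [run_grid()].
#' @param path file path.
#' @return `read_power_table` returns the power-table data.frame.
#' @export
write_power_table <- function(power_table, path) {
  out <- power_table
  for (cl in intersect(.power_numeric_cols, names(out)))
    out[[cl]] <- ifelse(is.na(out[[cl]]), "NA",
                        sprintf("%.17g", out[[cl]]))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_power_table
#' @export
read_power_table <- function(path) {
  df <- tryCatch(read.table(path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE,
                            colClasses = "character"),
                 error = function(e)
                   stop("malformed power table ", path, ": ",
                        conditionMessage(e)))
  for (cl in intersect(.power_numeric_cols, names(df))) {
    parsed <- suppressWarnings(as.numeric(df[[cl]]))
    bad <- which(is.na(parsed) & df[[cl]] != "NA")
    if (length(bad))
      stop(sprintf("malformed numeric value in column %s, line %d of %s",
                   cl, bad[1] + 1, path))
    df[[cl]] <- parsed
  }
  df
}

## ---- run configuration ----------------------------------------------------

.config_defaults <- list(grid = "no_ld", methods = SET_TEST_METHODS,
                         alpha = 0.05, replicates = 500, vegas_sims = 1000,
                         base_seed = 1L, workers = 1L)

#' Load and validate a run configuration
#'
#' Reads a YAML file naming a grid (`no_ld`, `causal_ld`, `causal_ld_tag`
#' or `noncausal_ld`) and optional overrides of `methods`, `alpha`,
#' `replicates`, `vegas_sims`, `base_seed` and `workers`. Unknown keys and
#' out-of-range values are rejected with all offending keys listed; defaults
#' fill everything else. The returned object carries the fully built list
#' of settings.
#'
#' @param path YAML file path.
#' @return An object of class `run_config` with the effective scalar fields
#'   plus `settings`.
#' @export
load_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  unknown <- setdiff(names(raw), names(.config_defaults))
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(.config_defaults, raw)
  problems <- character(0)
  if (!cfg$grid %in% c("no_ld", "causal_ld", "causal_ld_tag",
                       "noncausal_ld"))
    problems <- c(problems, "grid")
  if (!all(cfg$methods %in% SET_TEST_METHODS))
    problems <- c(problems, "methods")
  if (!is.numeric(cfg$alpha) || cfg$alpha <= 0 || cfg$alpha >= 1)
    problems <- c(problems, "alpha")
  if (!is.numeric(cfg$replicates) || cfg$replicates < 1)
    problems <- c(problems, "replicates")
  if (!is.numeric(cfg$vegas_sims) || cfg$vegas_sims < 100)
    problems <- c(problems, "vegas_sims")
  if (!is.numeric(cfg$base_seed)) problems <- c(problems, "base_seed")
  if (!is.numeric(cfg$workers) || cfg$workers < 1)
    problems <- c(problems, "workers")
  if (length(problems))
    stop("invalid config values for: ", paste(problems, collapse = ", "))
  cfg$settings <- switch(cfg$grid,
    no_ld = build_nold_grid(cfg$replicates, cfg$alpha),
    causal_ld = build_causal_ld_grid(FALSE, cfg$replicates, cfg$alpha),
    causal_ld_tag = build_causal_ld_grid(TRUE, cfg$replicates, cfg$alpha),
    noncausal_ld = build_noncausal_ld_grid(cfg$replicates, cfg$alpha))
  structure(cfg, class = "run_config")
}

#' Write the effective scalar fields of a config back to YAML
#'
#' Round-trips with [load_config()]: reloading the emitted file reproduces
#' the same effective configuration.
#'
#' @param config a `run_config`.
#' @param path output YAML path.
#' @export
save_config <- function(config, path) {
  yaml::write_yaml(config[setdiff(names(.config_defaults), NULL)], path)
  invisible(path)
}

## ---- published VSTM4 region summary --------------------------------------

#' Published LD summary of the six top SNPs around VSTM4
#'
#' Loads the published pairwise r-squared matrix of the six most associated
#' SNPs in and downstream of the VSTM4 gene (chromosome 10), shipped as a
#' plain-text fixture, together with positions reconstructed from the
#' published downstream offsets and a nominal 13 kb gene interval. Only this
#' LD summary is packaged; the underlying cohort genotype and phenotype data
#' are access-controlled and are not part of the package.
#'
#' @return List with `snp_id`, `position`, `intragenic`, `gene`
#'   (start/stop) and the 6 x 6 `r2` matrix.
#' @export
vstm4_region <- function() {
  dir <- system.file("extdata", package = "snpsetpower")
  snps <- read.table(file.path(dir, "vstm4_snps.tsv"), header = TRUE,
                     sep = "\t", stringsAsFactors = FALSE)
  r2 <- as.matrix(read.table(file.path(dir, "vstm4_ld_r2.tsv"),
                             header = TRUE, sep = "\t", row.names = 1,
                             check.names = FALSE))
  gene_start <- 49887000
  gene_stop <- 49900000
  position <- ifelse(snps$bp_downstream == 0,
                     (gene_start + gene_stop) / 2,
                     gene_stop + snps$bp_downstream)
  list(snp_id = snps$snp_id, position = position,
       intragenic = snps$bp_downstream == 0,
       gene = c(gene_start, gene_stop), r2 = r2)
}
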