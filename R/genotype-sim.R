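#' Genotype matrix container
#'
#' A light S3 container for an `n` individuals by `M` SNPs matrix of additive
#' genotype codes (0/1/2 copies of the minor/risk allele), together with the
#' per-SNP minor allele frequencies used (or implied) by the generating model
#' and optional base-pair positions and SNP labels.
#'
#' @param values integer matrix with entries in `{0, 1, 2}`.
#' @param mafs numeric vector of length `ncol(values)` with entries in
#'   `(0, 0.5]`, or `NULL` when unknown (e.g. data read from disk).
#' @param positions optional numeric vector of base-pair coordinates.
#' @param snp_ids optional character vector of SNP labels.
#' @return An object of class `genotype_matrix` with fields `values`, `mafs`,
#'   `positions`, `snp_ids`.
#' @export
genotype_matrix <- function(values, mafs = NULL, positions = NULL,
                            snp_ids = NULL) {
  values <- as.matrix(values)
  if (!all(values %in% 0:2))
    stop("genotype values must all be 0, 1 or 2")
  storage.mode(values) <- "integer"
  m <- ncol(values)
  if (!is.null(mafs)) {
    if (length(mafs) != m) stop("length(mafs) must equal ncol(values)")
    if (any(mafs <= 0 | mafs > 0.5))
      stop("mafs must lie in (0, 0.5]")
  }
  if (!is.null(positions) && length(positions) != m)
    stop("length(positions) must equal ncol(values)")
  if (!is.null(snp_ids) && length(snp_ids) != m)
    stop("length(snp_ids) must equal ncol(values)")
  if (is.null(snp_ids) && !is.null(colnames(values)))
    snp_ids <- colnames(values)
  structure(list(values = values, mafs = mafs, positions = positions,
                 snp_ids = snp_ids),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d individuals x %d SNPs\n",
              nrow(x$values), ncol(x$values)))
  if (!is.null(x$mafs))
    cat(sprintf("  target MAFs in [%.3g, %.3g]\n",
                min(x$mafs), max(x$mafs)))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$values)

.as_genotype_values <- function(genotypes) {
  if (inherits(genotypes, "genotype_matrix")) genotypes$values
  else as.matrix(genotypes)
}

#' Simulate independent SNP genotypes under HWE
#'
#' Every SNP is drawn independently as Binomial(2, maf), i.e. a site in
#' Hardy-Weinberg equilibrium with no LD between sites.
#'
#' @param n number of individuals (>= 1).
#' @param mafs vector of minor allele frequencies in `(0, 0.5]`.
#' @param seed integer seed; `NULL` continues the current RNG stream.
#' @return A [genotype_matrix].
#' @export
simulate_independent <- function(n, mafs, seed = NULL) {
  if (length(n) != 1 || is.na(n) || n < 1)
    stop("n must be a positive integer")
  if (any(mafs <= 0 | mafs > 0.5))
    stop("all mafs must lie in (0, 0.5]")
  if (!is.null(seed)) set.seed(seed)
  genotype_matrix(cpp_hwe_genotypes(as.integer(n), as.numeric(mafs)),
                  mafs = mafs)
}

#' Feasibility of a correlation between two Bernoulli variables
#'
#' Checks the Frechet bounds for a Pearson correlation `r` between Bernoulli
#' variables with success probabilities `p1` and `p2`: the upper bound is
#' `min(sqrt(p1*q2/(p2*q1)), sqrt(p2*q1/(p1*q2)))` and the lower bound is
#' `-min(sqrt(p1*p2/(q1*q2)), sqrt(q1*q2/(p1*p2)))` with `q = 1 - p`.
#'
#' @param p1,p2 marginal probabilities in `(0, 1)`.
#' @param r target correlation.
#' @return `TRUE` iff `(p1, p2, r)` is jointly feasible.
#' @export
check_correlation_feasibility <- function(p1, p2, r) {
  stopifnot(p1 > 0, p1 < 1, p2 > 0, p2 < 1)
  q1 <- 1 - p1
  q2 <- 1 - p2
  upper <- min(sqrt(p1 * q2 / (p2 * q1)), sqrt(p2 * q1 / (p1 * q2)))
  lower <- -min(sqrt(p1 * p2 / (q1 * q2)), sqrt(q1 * q2 / (p1 * p2)))
  r >= lower && r <= upper
}

.stop_infeasible <- function(p1, p2, r) {
  q1 <- 1 - p1; q2 <- 1 - p2
  upper <- min(sqrt(p1 * q2 / (p2 * q1)), sqrt(p2 * q1 / (p1 * q2)))
  stop(sprintf(paste0("correlation r = %.3g infeasible for Bernoulli ",
                      "marginals (%.3g, %.3g): Frechet upper bound is %.3g"),
               r, p1, p2, upper))
}

## One haplotype layer of an exchangeable correlated-Bernoulli block via the
## conditional linear family: allele j has conditional mean
##   p + r / (1 + (j - 2) r) * sum_{i<j} (y_i - p),
## which yields exact marginals Bernoulli(p) and exchangeable correlation r.
## Vectorised over individuals (rows).
.exchangeable_allele_layer <- function(n, p, m, r) {
  L <- matrix(0L, n, m)
  L[, 1] <- as.integer(runif(n) < p)
  if (m > 1) {
    s <- L[, 1] - p
    for (j in 2:m) {
      lambda <- p + r / (1 + (j - 2) * r) * s
      L[, j] <- as.integer(runif(n) < lambda)
      s <- s + (L[, j] - p)
    }
  }
  L
}

#' Simulate an exchangeable-correlation LD block
#'
#' All SNPs in the block share MAF `maf` and pairwise genotype correlation
#' `r`. Correlation is imposed at the allele (haplotype-layer) level with the
#' conditional-linear-family construction for correlated binary variables;
#' genotypes are the sum of two independent layers, which preserves HWE at
#' every site and makes the genotype-level correlation equal the allele-level
#' correlation.
#'
#' @param n number of individuals.
#' @param maf shared minor allele frequency in `(0, 0.5]`.
#' @param m_snps number of SNPs in the block (>= 1).
#' @param r target pairwise correlation in `[0, 1)`. Equal marginals make any
#'   such `r` feasible.
#' @param seed integer seed; `NULL` continues the current RNG stream.
#' @return A [genotype_matrix].
#' @export
simulate_exchangeable_block <- function(n, maf, m_snps, r, seed = NULL) {
  if (n < 1) stop("n must be a positive integer")
  if (maf <= 0 || maf > 0.5) stop("maf must lie in (0, 0.5]")
  if (m_snps < 1) stop("m_snps must be >= 1")
  if (r < 0 || r >= 1) stop("r must lie in [0, 1)")
  if (!check_correlation_feasibility(maf, maf, r))
    .stop_infeasible(maf, maf, r)
  if (!is.null(seed)) set.seed(seed)
  G <- .exchangeable_allele_layer(n, maf, m_snps, r) +
       .exchangeable_allele_layer(n, maf, m_snps, r)
  genotype_matrix(G, mafs = rep(maf, m_snps))
}

## Tag-SNP allele layers conditional on an anchor allele layer: each tag
## allele has conditional mean p + r * (anchor - p), i.e. a one-factor
## construction with anchor-tag correlation r and tag-tag correlation r^2.
.anchored_tag_layer <- function(anchor_layer, p, n_tags, r) {
  n <- length(anchor_layer)
  lambda <- p + r * (anchor_layer - p)
  L <- matrix(0L, n, n_tags)
  for (k in seq_len(n_tags))
    L[, k] <- as.integer(runif(n) < lambda)
  L
}

#' Simulate a causal-anchored LD block
#'
#' One causal "anchor" SNP plus `n_noncausal` tag SNPs, all at MAF `maf`.
#' Every tag is correlated `r` with the anchor; the one-factor construction
#' gives the tags the minimum achievable mutual correlation, `r^2` (0.25 at
#' r = 0.5, 0.81 at r = 0.9). The anchor is the first returned column.
#'
#' @inheritParams simulate_exchangeable_block
#' @param n_noncausal number of tag SNPs in the block.
#' @return A [genotype_matrix] with the anchor in column 1.
#' @export
simulate_causal_anchored_block <- function(n, maf, n_noncausal, r,
                                           seed = NULL) {
  if (n < 1) stop("n must be a positive integer")
  if (maf <= 0 || maf > 0.5) stop("maf must lie in (0, 0.5]")
  if (n_noncausal < 0) stop("n_noncausal must be >= 0")
  if (r < 0 || r >= 1) stop("r must lie in [0, 1)")
  if (!check_correlation_feasibility(maf, maf, r))
    .stop_infeasible(maf, maf, r)
  if (!is.null(seed)) set.seed(seed)
  a1 <- as.integer(runif(n) < maf)
  a2 <- as.integer(runif(n) < maf)
  G <- cbind(a1 + a2,
             .anchored_tag_layer(a1, maf, n_noncausal, r) +
             .anchored_tag_layer(a2, maf, n_noncausal, r))
  genotype_matrix(G, mafs = rep(maf, n_noncausal + 1),
                  snp_ids = c("anchor", paste0("tag", seq_len(n_noncausal))))
}
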