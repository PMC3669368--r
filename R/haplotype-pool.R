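#' Haplotype pool container
#'
#' A population of phased haplotypes with sampling frequencies, used to
#' simulate genotypes with realistic, locally-blocked LD: each individual is
#' the sum of two haplotypes drawn i.i.d. from the pool.
#'
#' @param haplotypes H x M binary matrix (one row per haplotype, allele per
#'   SNP).
#' @param frequencies H sampling probabilities summing to 1.
#' @param positions M base-pair coordinates.
#' @param gene_interval length-2 vector `(start, stop)` in bp, 1-based
#'   inclusive.
#' @param causal_indices indices (into SNP columns) of the causal SNPs.
#' @return An object of class `haplotype_pool`.
#' @export
haplotype_pool <- function(haplotypes, frequencies, positions, gene_interval,
                           causal_indices) {
  haplotypes <- as.matrix(haplotypes)
  if (!all(haplotypes %in% 0:1)) stop("haplotypes must be binary")
  storage.mode(haplotypes) <- "integer"
  if (nrow(haplotypes) < 1) stop("pool must contain at least one haplotype")
  if (length(frequencies) != nrow(haplotypes))
    stop("one frequency per haplotype required")
  if (any(frequencies < 0) || abs(sum(frequencies) - 1) > 1e-9)
    stop("frequencies must be non-negative and sum to 1")
  if (length(positions) != ncol(haplotypes))
    stop("one position per SNP required")
  if (length(gene_interval) != 2 || gene_interval[1] > gene_interval[2])
    stop("gene_interval must be (start, stop) with start <= stop")
  if (length(causal_indices) &&
      (any(causal_indices < 1) || any(causal_indices > ncol(haplotypes))))
    stop("causal_indices out of range")
  structure(list(haplotypes = haplotypes,
                 frequencies = as.numeric(frequencies),
                 positions = as.numeric(positions),
                 gene_interval = as.numeric(gene_interval),
                 causal_indices = as.integer(causal_indices)),
            class = "haplotype_pool")
}

#' @export
print.haplotype_pool <- function(x, ...) {
  cat(sprintf(paste0("haplotype_pool: %d haplotypes x %d SNPs, gene ",
                     "[%d, %d], %d causal SNPs\n"),
              nrow(x$haplotypes), ncol(x$haplotypes),
              x$gene_interval[1], x$gene_interval[2],
              length(x$causal_indices)))
  invisible(x)
}

#' Pool-implied allele frequencies
#'
#' Frequency-weighted mean allele per SNP: `sum_h freq_h * allele_h`.
#'
#' @param pool a [haplotype_pool].
#' @return numeric vector of implied allele frequencies.
#' @export
pool_implied_mafs <- function(pool) {
  as.numeric(crossprod(pool$haplotypes, pool$frequencies))
}

#' Population LD of a haplotype pool
#'
#' Exact Pearson correlation of genotype codes implied by the pool. Because a
#' genotype is the sum of two i.i.d. haplotypes, genotype-level correlation
#' equals the allele-level correlation computed from the haplotype
#' frequencies. Monomorphic SNPs get correlation 0 with all others.
#'
#' @param pool a [haplotype_pool].
#' @return M x M correlation matrix.
#' @export
pool_ld <- function(pool) {
  f <- pool_implied_mafs(pool)
  H <- pool$haplotypes
  ex <- crossprod(H * pool$frequencies, H)   # E[X_j X_k]
  cov <- ex - tcrossprod(f)
  sd <- sqrt(pmax(f * (1 - f), 0))
  denom <- tcrossprod(sd)
  r <- ifelse(denom > 0, cov / denom, 0)
  diag(r) <- 1
  r
}

#' Sample genotypes from a haplotype pool
#'
#' Each individual is the sum of two haplotypes drawn i.i.d. from the pool's
#' frequency distribution.
#'
#' @param pool a [haplotype_pool].
#' @param n number of individuals.
#' @param seed integer seed; `NULL` continues the current RNG stream.
#' @return A [genotype_matrix] whose `mafs` are the pool-implied frequencies
#'   (capped at 0.5 for the container's minor-allele convention).
#' @export
sample_from_pool <- function(pool, n, seed = NULL) {
  if (!inherits(pool, "haplotype_pool")) stop("pool must be a haplotype_pool")
  if (n < 1) stop("n must be a positive integer")
  if (!is.null(seed)) set.seed(seed)
  H <- nrow(pool$haplotypes)
  i1 <- sample.int(H, n, replace = TRUE, prob = pool$frequencies)
  i2 <- sample.int(H, n, replace = TRUE, prob = pool$frequencies)
  G <- pool$haplotypes[i1, , drop = FALSE] +
       pool$haplotypes[i2, , drop = FALSE]
  f <- pool_implied_mafs(pool)
  genotype_matrix(G, mafs = pmin(pmax(f, 1e-12), 0.5),
                  positions = pool$positions)
}

## ---- synthetic realistic region ------------------------------------------

## Fixed SNP layout of the synthetic ~900 kb region: a central 400 kb gene
## with 33 intragenic SNPs, 23 intergenic SNPs to the left and 24 to the
## right; 6 causal SNPs (4 intragenic, 2 intergenic, both of the latter
## within 25 kb of a gene boundary so that small windows capture them).
.realistic_layout <- function() {
  left <- c(seq(10000, 220000, by = 10000), 228000)           # 23 SNPs
  intra <- round(seq(252000, 648000, length.out = 33))        # 33 SNPs
  right <- c(655000, 659000, 663000, 668000,
             seq(680000, 870000, by = 10000))                 # 24 SNPs
  positions <- c(left, intra, right)
  list(positions = positions,
       gene = c(250001, 650000),
       # global indices: left 1..23, intragenic 24..56, right 57..80
       causal = c(23L, 27L, 35L, 43L, 55L, 59L),
       # adjacent-pair LD blocks (index ranges into the sorted positions)
       blocks = list(c(5, 7), c(21, 23), c(30, 35), c(40, 43),
                     c(53, 60), c(62, 65)),
       block_r = c(0.80, 0.85, 0.90, 0.85, 0.95, 0.80))
}

#' Synthetic haplotype pool with realistic blocked LD
#'
#' Builds a synthetic stand-in for a phased ~900 kb region: 80 common SNPs, a
#' central ~400 kb gene containing 33 SNPs (4 of them causal), 23 + 24
#' intergenic SNPs flanking it (2 of them causal, one per side, within 25 kb
#' of the gene), and several multi-SNP LD blocks including one
#' moderate-strong block crossing the upper gene boundary. Haplotypes are
#' generated by a first-order Markov chain along the SNPs with high
#' adjacent-allele correlation inside the designated blocks and weak
#' background correlation elsewhere; block members share a target frequency
#' so the chain's correlation caps never bind. Implied allele frequencies
#' are clamped into [0.06, 0.50] by flipping alleles in individual
#' haplotypes where needed.
#'
#' @param seed integer seed; two calls with the same seed return identical
#'   pools.
#' @param n_haplotypes pool size (default 400).
#' @return A [haplotype_pool] of 80 SNPs.
#' @export
make_realistic_fixture <- function(seed = 1L, n_haplotypes = 400L) {
  set.seed(seed)
  lay <- .realistic_layout()
  M <- length(lay$positions)
  H <- as.integer(n_haplotypes)

  f <- runif(M, 0.10, 0.48)
  rho <- rep(0.08, M - 1)                 # background adjacent correlation
  for (b in seq_along(lay$blocks)) {
    rng <- lay$blocks[[b]]
    idx <- rng[1]:rng[2]
    f[idx] <- pmin(pmax(f[rng[1]] + runif(length(idx), -0.01, 0.01),
                        0.10), 0.48)
    rho[rng[1]:(rng[2] - 1)] <- lay$block_r[b]
  }

  hap <- matrix(0L, H, M)
  hap[, 1] <- as.integer(runif(H) < f[1])
  for (j in 2:M) {
    b <- rho[j - 1] * sqrt(f[j] * (1 - f[j]) / (f[j - 1] * (1 - f[j - 1])))
    # cap so the conditional probability stays in [0, 1]
    b <- min(b, (1 - f[j]) / (1 - f[j - 1]), f[j] / f[j - 1])
    lambda <- f[j] + b * (hap[, j - 1] - f[j - 1])
    hap[, j] <- as.integer(runif(H) < lambda)
  }

  # clamp implied frequencies into [0.06, 0.50]
  for (j in seq_len(M)) {
    fj <- mean(hap[, j])
    if (fj > 0.50) {
      ones <- which(hap[, j] == 1L)
      hap[sample(ones, ceiling((fj - 0.50) * H)), j] <- 0L
    } else if (fj < 0.06) {
      zeros <- which(hap[, j] == 0L)
      hap[sample(zeros, ceiling((0.06 - fj) * H)), j] <- 1L
    }
  }

  haplotype_pool(hap, rep(1 / H, H), lay$positions, lay$gene, lay$causal)
}

## ---- plain-text pool format ----------------------------------------------

#' Write / read a haplotype pool as delimited text
#'
#' Header lines give positions, gene start/stop and causal indices; each
#' following row is `frequency<TAB>allele string` (0/1 characters).
#'
#' @param pool a [haplotype_pool].
#' @param path file path.
#' @return `read_haplotype_pool` returns a [haplotype_pool];
#'   `write_haplotype_pool` returns `path` invisibly.
#' @export
write_haplotype_pool <- function(pool, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste("positions:", paste(format(pool$positions,
                                                scientific = FALSE,
                                                trim = TRUE),
                                         collapse = " ")),
               paste("gene:", pool$gene_interval[1], pool$gene_interval[2]),
               paste("causal:", paste(pool$causal_indices, collapse = " "))),
             con)
  alleles <- apply(pool$haplotypes, 1, paste, collapse = "")
  writeLines(paste(sprintf("%.17g", pool$frequencies), alleles, sep = "\t"),
             con)
  invisible(path)
}

#' @rdname write_haplotype_pool
#' @export
read_haplotype_pool <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 4) stop("malformed haplotype pool file: ", path)
  grab <- function(prefix, i) {
    if (!startsWith(lines[i], prefix))
      stop("expected '", prefix, "' on line ", i, " of ", path)
    as.numeric(strsplit(trimws(sub(prefix, "", lines[i], fixed = TRUE)),
                        "\\s+")[[1]])
  }
  positions <- grab("positions:", 1)
  gene <- grab("gene:", 2)
  causal <- grab("causal:", 3)
  body <- strsplit(lines[-(1:3)], "\t", fixed = TRUE)
  freqs <- vapply(body, function(x) as.numeric(x[1]), 0)
  hap <- do.call(rbind, lapply(body, function(x)
    as.integer(strsplit(x[2], "")[[1]])))
  haplotype_pool(hap, freqs, positions, gene, causal)
}
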