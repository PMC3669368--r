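## ---- single-marker trend test --------------------------------------------

## Vectorised Cochran-Armitage trend statistics (additive scores 0/1/2,
## score-test / null-variance form) for every column of X at once.
## For binary y the statistic equals n * cor(G, y)^2; monomorphic columns
## get statistic 0 and p = 1.
.trend_stats <- function(X, y) {
  n <- length(y)
  py <- mean(y)
  u <- as.numeric(crossprod(X, y - py))
  cs <- colSums(X)
  sgg <- colSums(X * X) - cs^2 / n
  v <- py * (1 - py) * sgg
  stat <- ifelse(sgg > 0, u^2 / v, 0)
  p <- ifelse(sgg > 0, pchisq(stat, df = 1, lower.tail = FALSE), 1)
  list(statistic = stat, p_value = p)
}

#' Cochran-Armitage trend test for one SNP
#'
#' Additive-score (0/1/2) linear trend test of association between genotype
#' and binary phenotype, in the score-test (null-variance) form: the
#' statistic is `n * cor(G, D)^2`, referred to a 1-df chi-square (two-sided).
#' A monomorphic column returns statistic 0 and p = 1.
#'
#' @param genotype_column vector of 0/1/2 genotype codes.
#' @param status 0/1 phenotype vector (both groups must be non-empty).
#' @return List with `statistic` and `p_value`.
#' @export
trend_test <- function(genotype_column, status) {
  if (length(genotype_column) != length(status))
    stop("genotype and status lengths differ")
  if (all(status == status[1]))
    stop("invalid design: need both cases and controls")
  res <- .trend_stats(cbind(as.numeric(genotype_column)), status)
  list(statistic = unname(res$statistic), p_value = unname(res$p_value))
}

#' Pairwise LD (genotype correlation) matrix
#'
#' Pearson correlation of additive genotype codes, computed from the sample.
#' Monomorphic columns get correlation 0 with all others (diagonal 1).
#'
#' @param genotypes a [genotype_matrix] or plain 0/1/2 matrix with >= 2 rows.
#' @return M x M correlation matrix.
#' @export
pairwise_ld <- function(genotypes) {
  X <- .as_genotype_values(genotypes)
  if (nrow(X) < 2) stop("need at least two individuals")
  .fast_cor(X)
}

.fast_cor <- function(X) {
  n <- nrow(X)
  X <- X * 1.0
  mu <- colMeans(X)
  Xc <- X - rep(mu, each = n)
  ss <- sqrt(colSums(Xc * Xc))
  ss[ss == 0] <- Inf                       # monomorphic -> correlation 0
  C <- crossprod(Xc) / tcrossprod(ss)
  diag(C) <- 1
  C
}

## ---- GATES ----------------------------------------------------------------

## Effective number of independent tests among correlated markers:
## M - sum over eigenvalues > 1 of (eigenvalue - 1).
.effective_n_tests <- function(C) {
  if (ncol(C) == 1) return(1)
  ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
  ncol(C) - sum(pmax(ev - 1, 0))
}

## Approximate correlation between two trend-test p-values from the genotype
## correlation r: sixth-order polynomial fit (default) or the plain r^2
## fallback.
.pvalue_correlation <- function(r, transform = c("polynomial", "r2")) {
  transform <- match.arg(transform)
  if (transform == "polynomial") {
    0.2982 * r^6 - 0.0127 * r^5 + 0.0588 * r^4 + 0.0099 * r^3 +
      0.6281 * r^2 - 0.0009 * r
  } else {
    r^2
  }
}

.gates_p <- function(p_values, ld, transform = "polynomial") {
  m <- length(p_values)
  if (m == 1) return(min(p_values, 1))
  rho <- .pvalue_correlation(ld, transform)
  diag(rho) <- 1
  ord <- order(p_values)
  ps <- p_values[ord]
  rho <- rho[ord, ord, drop = FALSE]
  me_all <- .effective_n_tests(rho)
  me_j <- vapply(seq_len(m), function(j)
    .effective_n_tests(rho[seq_len(j), seq_len(j), drop = FALSE]), 0)
  min(min(me_all * ps / me_j), 1)
}

#' GATES gene-based test
#'
#' Extended Simes combination of single-SNP trend-test p-values: with
#' p-values sorted ascending, the gene p-value is
#' `min_j { Me * p_(j) / Me(j) }`, where `Me` is the effective number of
#' independent tests among all M SNPs (`M - sum_{lambda > 1}(lambda - 1)`
#' over eigenvalues of the p-value correlation matrix) and `Me(j)` the same
#' quantity for the j SNPs with smallest p-values. Highly correlated SNPs
#' therefore count less than independent ones. The p-value correlation is
#' approximated from the sample genotype correlation, by default with a
#' sixth-order polynomial (`r^2` available as a fallback transform).
#'
#' @param p_values per-SNP trend-test p-values.
#' @param ld genotype correlation matrix aligned with `p_values`.
#' @param transform `"polynomial"` (default) or `"r2"`.
#' @return An object of class `set_test_result` with fields `method`,
#'   `p_value` and `details` (`me`, per-rank `me_j`).
#' @export
gates <- function(p_values, ld, transform = c("polynomial", "r2")) {
  transform <- match.arg(transform)
  ld <- as.matrix(ld)
  if (length(p_values) != ncol(ld) || nrow(ld) != ncol(ld))
    stop("p_values and ld dimensions do not match")
  m <- length(p_values)
  rho <- .pvalue_correlation(ld, transform)
  diag(rho) <- 1
  ord <- order(p_values)
  rho_o <- rho[ord, ord, drop = FALSE]
  me_j <- vapply(seq_len(m), function(j)
    .effective_n_tests(rho_o[seq_len(j), seq_len(j), drop = FALSE]), 0)
  set_test_result("GATES", .gates_p(p_values, ld, transform),
                  details = list(me = me_j[m], me_j = me_j))
}

## ---- VEGAS ----------------------------------------------------------------

## Cholesky with escalating diagonal jitter (1e-8 up to 1e-4) for sample LD
## matrices that are numerically rank deficient (e.g. duplicated SNPs).
.safe_chol <- function(C) {
  fit <- tryCatch(chol(C), error = function(e) NULL)
  jitter <- 1e-8
  while (is.null(fit) && jitter <= 1e-4) {
    fit <- tryCatch(chol(C + diag(jitter, ncol(C))), error = function(e) NULL)
    jitter <- jitter * 10
  }
  if (is.null(fit))
    stop("Cholesky factorisation of the LD matrix failed even after ",
         "diagonal jitter up to 1e-4; the matrix is too ill-conditioned")
  fit
}

## Monte Carlo null for both VEGAS statistics from one set of draws:
## rows of Z ~ N(0, Sigma) via the Cholesky factor, squared elementwise,
## then summed (SUM) and maximised (MAX) per replicate.
.vegas_both <- function(statistics, ld, n_sim) {
  m <- length(statistics)
  U <- .safe_chol(ld)
  Z <- matrix(rnorm(n_sim * m), n_sim, m) %*% U
  Z2 <- Z * Z
  sums <- rowSums(Z2)
  maxs <- Z2[, 1]
  if (m > 1) for (j in 2:m) maxs <- pmax.int(maxs, Z2[, j])
  c(sum = (1 + sum(sums >= sum(statistics))) / (1 + n_sim),
    max = (1 + sum(maxs >= max(statistics))) / (1 + n_sim))
}

#' VEGAS gene-based test (SUM and MAX variants)
#'
#' The observed gene statistic is the sum (VEGAS-SUM) or maximum (VEGAS-MAX)
#' of the per-SNP 1-df trend chi-squares. Its null distribution under the
#' sample LD is estimated by Monte Carlo: a vector of independent standard
#' normals is multiplied by the Cholesky factor of the LD matrix and squared
#' elementwise, and the gene statistic of each simulated vector forms the
#' null sample. The p-value is `(1 + #exceedances) / (1 + n_sim)` with
#' non-strict exceedance, so it is always positive.
#'
#' @param statistics per-SNP trend chi-square statistics.
#' @param ld genotype correlation matrix aligned with `statistics`.
#' @param mode `"sum"` or `"max"`.
#' @param n_sim number of Monte Carlo replicates (>= 100; default 1000).
#' @param seed integer seed; `NULL` continues the current RNG stream.
#' @return An object of class `set_test_result` with `details` holding
#'   `n_sim` and the exceedance count.
#' @export
vegas <- function(statistics, ld, mode = c("sum", "max"), n_sim = 1000,
                  seed = NULL) {
  mode <- match.arg(mode)
  ld <- as.matrix(ld)
  if (length(statistics) != ncol(ld) || nrow(ld) != ncol(ld))
    stop("statistics and ld dimensions do not match")
  if (n_sim < 100) stop("n_sim must be >= 100")
  if (!is.null(seed)) set.seed(seed)
  p <- .vegas_both(statistics, ld, n_sim)[[mode]]
  set_test_result(if (mode == "sum") "VEGAS-SUM" else "VEGAS-MAX", p,
                  details = list(n_sim = n_sim,
                                 exceedances = round(p * (1 + n_sim) - 1)))
}

## ---- logistic-regression tests -------------------------------------------

## Null (intercept-only) binomial deviance in closed form.
.null_deviance <- function(y) {
  n <- length(y)
  n1 <- sum(y)
  n0 <- n - n1
  -2 * (n1 * log(n1 / n) + n0 * log(n0 / n))
}

## Likelihood-ratio test of a binary outcome on a covariate matrix.
## Fast IRLS first; falls back to glm.fit for rank-deficient designs
## (aliased columns are dropped by pivoting and df adjusts accordingly).
## Returns p = NA when the fit fails to converge (a failed replicate).
.lr_pvalue <- function(X, y) {
  X <- X * 1.0
  fit <- cpp_logistic_deviance(cbind(1, X), y)
  if (fit$ok && fit$converged) {
    df <- ncol(X)
    dev <- fit$deviance
  } else {
    gf <- suppressWarnings(stats::glm.fit(cbind(1, X), y,
                                          family = stats::binomial()))
    if (!gf$converged)
      return(list(p_value = NA_real_, df = NA_integer_, converged = FALSE))
    df <- sum(!is.na(gf$coefficients)) - 1
    dev <- gf$deviance
  }
  lrt <- max(.null_deviance(y) - dev, 0)
  list(p_value = pchisq(lrt, df = df, lower.tail = FALSE),
       df = df, converged = TRUE)
}

## Principal-component reduction of a genotype matrix: correlation-matrix
## PCA of the polymorphic columns, keeping the minimal number of leading
## components whose cumulative explained variance reaches the threshold.
.pc_scores <- function(X, variance_threshold = 0.80) {
  X <- X * 1.0
  n <- nrow(X)
  Xc <- X - rep(colMeans(X), each = n)
  ss <- sqrt(colSums(Xc * Xc))
  keep <- which(ss > 0)
  Xc <- Xc[, keep, drop = FALSE]
  ss <- ss[keep]
  Xs <- Xc / rep(ss / sqrt(n - 1), each = n)       # unit-variance columns
  C <- crossprod(Xs) / (n - 1)
  e <- eigen(C, symmetric = TRUE)
  cumvar <- cumsum(pmax(e$values, 0)) / ncol(Xs)
  k <- which(cumvar >= variance_threshold)[1]
  if (is.na(k)) k <- ncol(Xs)
  list(scores = Xs %*% e$vectors[, seq_len(k), drop = FALSE],
       n_components = k, explained = cumvar[k])
}

#' Logistic-regression gene-based test (LR)
#'
#' Every SNP enters an additive logistic regression of disease status on the
#' genotype matrix; the gene p-value is the likelihood-ratio test against
#' the intercept-only model, with df equal to the number of retained
#' (polymorphic, non-aliased) columns.
#'
#' @param genotypes a [genotype_matrix] or plain 0/1/2 matrix.
#' @param status 0/1 phenotype vector.
#' @return An object of class `set_test_result`; `details` holds `df` and
#'   `converged`. A non-convergent fit yields `p_value = NA`.
#' @export
lr_test <- function(genotypes, status) {
  X <- .prune_monomorphic(.as_genotype_values(genotypes))
  if (ncol(X) == 0)
    return(set_test_result("LR", 1, details = list(df = 0L,
                                                   converged = TRUE)))
  res <- .lr_pvalue(X, status)
  set_test_result("LR", res$p_value,
                  details = list(df = res$df, converged = res$converged))
}

#' Logistic regression on principal components (LR-PC)
#'
#' Principal components of the standardised (correlation-matrix) genotype
#' matrix are computed and the smallest set of leading components explaining
#' at least `variance_threshold` of the genotype variability is retained;
#' disease status is then regressed on those components and the gene
#' p-value is the likelihood-ratio test against the intercept-only model
#' with df equal to the number of retained components.
#'
#' @inheritParams lr_test
#' @param variance_threshold cumulative explained-variance target (default
#'   0.80).
#' @return An object of class `set_test_result`; `details` holds the number
#'   of retained components `n_components`, the explained fraction, `df` and
#'   `converged`.
#' @export
lr_pc_test <- function(genotypes, status, variance_threshold = 0.80) {
  X <- .prune_monomorphic(.as_genotype_values(genotypes))
  if (ncol(X) == 0)
    return(set_test_result("LR-PC", 1,
                           details = list(df = 0L, n_components = 0L,
                                          converged = TRUE)))
  pc <- .pc_scores(X, variance_threshold)
  res <- .lr_pvalue(pc$scores, status)
  set_test_result("LR-PC", res$p_value,
                  details = list(df = res$df,
                                 n_components = pc$n_components,
                                 explained = pc$explained,
                                 converged = res$converged))
}

## ---- shared plumbing ------------------------------------------------------

#' Set-test result container
#'
#' @param method method label.
#' @param p_value set-level p-value in `(0, 1]` (or `NA` for a failed fit).
#' @param details method-specific diagnostics.
#' @return An object of class `set_test_result`.
#' @export
set_test_result <- function(method, p_value, details = list()) {
  structure(list(method = method, p_value = p_value, details = details),
            class = "set_test_result")
}

#' @export
print.set_test_result <- function(x, ...) {
  cat(sprintf("%s set test: p = %.4g\n", x$method, x$p_value))
  invisible(x)
}

.prune_monomorphic <- function(X) {
  keep <- colSums(X != rep(X[1, ], each = nrow(X))) > 0
  X[, keep, drop = FALSE]
}

## Core engine: all requested set-test p-values for one analysis matrix.
## VEGAS-SUM and VEGAS-MAX share one set of null draws (seeded separately
## from the data-generating streams so dropping a method never perturbs the
## others). Returns a named vector with NA marking failed replicates.
.set_test_pvalues <- function(X, y, methods = SET_TEST_METHODS,
                              vegas_sims = 1000, vegas_seed = NULL,
                              alpha = NULL) {
  out <- setNames(rep(NA_real_, length(methods)), methods)
  X <- .prune_monomorphic(X * 1.0)
  if (ncol(X) == 0) {
    out[] <- 1
    return(out)
  }
  need_marginal <- any(c("gates", "vegas_sum", "vegas_max") %in% methods)
  if (need_marginal) {
    tr <- .trend_stats(X, y)
    C <- .fast_cor(X)
  }
  if ("gates" %in% methods)
    out["gates"] <- .gates_p(tr$p_value, C)
  if (any(c("vegas_sum", "vegas_max") %in% methods)) {
    if (!is.null(vegas_seed)) set.seed(vegas_seed)
    vg <- .vegas_both(tr$statistic, C, vegas_sims)
    if ("vegas_sum" %in% methods) out["vegas_sum"] <- vg[["sum"]]
    if ("vegas_max" %in% methods) out["vegas_max"] <- vg[["max"]]
  }
  if ("lr" %in% methods)
    out["lr"] <- .lr_pvalue(X, y)$p_value
  if ("lr_pc" %in% methods) {
    pc <- .pc_scores(X)
    out["lr_pc"] <- .lr_pvalue(pc$scores, y)$p_value
  }
  out
}

#' Run the five gene-based tests on one data set
#'
#' Convenience wrapper applying any subset of the five set tests (plus the
#' per-SNP trend tests) to a genotype matrix and case-control status.
#' Monomorphic SNPs are dropped from the set tests; if nothing remains the
#' set p-value is 1.
#'
#' @param genotypes a [genotype_matrix] or plain 0/1/2 matrix.
#' @param status 0/1 phenotype vector.
#' @param methods subset of [SET_TEST_METHODS].
#' @param vegas_sims Monte Carlo replicates for VEGAS (default 1000).
#' @param seed seed for the VEGAS null draws; `NULL` continues the current
#'   RNG stream.
#' @return List with `set_tests` (data.frame of method label and p-value)
#'   and `snp_tests` (data.frame of per-SNP trend statistics and p-values).
#' @export
run_set_tests <- function(genotypes, status, methods = SET_TEST_METHODS,
                          vegas_sims = 1000, seed = NULL) {
  methods <- match.arg(methods, SET_TEST_METHODS, several.ok = TRUE)
  X <- .as_genotype_values(genotypes)
  ids <- if (inherits(genotypes, "genotype_matrix") &&
             !is.null(genotypes$snp_ids)) genotypes$snp_ids
         else paste0("snp", seq_len(ncol(X)))
  tr <- .trend_stats(X * 1.0, status)
  p <- .set_test_pvalues(X, status, methods, vegas_sims, vegas_seed = seed)
  list(set_tests = data.frame(method = SET_TEST_LABELS[methods],
                              p_value = unname(p[methods]),
                              row.names = NULL),
       snp_tests = data.frame(snp_id = ids, statistic = tr$statistic,
                              p_value = tr$p_value, row.names = NULL))
}
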