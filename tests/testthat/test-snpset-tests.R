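test_that("trend test matches the Cochran-Armitage oracle", {
  # cases (30,20,10) vs controls (10,20,30) over codes 0/1/2
  g <- rep(c(0, 1, 2, 0, 1, 2), c(30, 20, 10, 10, 20, 30))
  status <- rep(c(1, 0), each = 60)
  res <- trend_test(g, status)
  oracle <- suppressWarnings(
    stats::prop.trend.test(c(30, 20, 10), rep(40, 3), score = 0:2))
  expect_equal(res$statistic, unname(oracle$statistic), tolerance = 1e-12)
  expect_equal(res$statistic, 20)          # frozen hand-checked value
  expect_equal(res$p_value, unname(oracle$p.value), tolerance = 1e-12)
  # monomorphic column
  flat <- trend_test(rep(1, 120), status)
  expect_equal(flat$statistic, 0)
  expect_equal(flat$p_value, 1)
  expect_error(trend_test(g, rep(1, 120)), "cases and controls")
})

test_that("trend-test p-values are null-calibrated", {
  set.seed(10)
  g <- rbinom(300, 2, 0.3)
  ps <- replicate(400, trend_test(sample(g), rbinom(300, 1, 0.5))$p_value)
  # discreteness of the permutation distribution produces ties; the KS
  # check is only a coarse uniformity screen
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif"))$p.value, 0.001)
})

test_that("pairwise LD handles duplicates, independence and monomorphs", {
  g <- simulate_independent(10000, rep(0.3, 3), seed = 8)
  X <- cbind(g$values, g$values[, 1], 1L)
  C <- pairwise_ld(X)
  expect_equal(C[1, 4], 1)                       # duplicated column
  expect_lt(max(abs(C[1:3, 1:3][upper.tri(diag(3))])), 4 / sqrt(10000))
  expect_equal(C[5, 1:4], rep(0, 4))             # monomorphic column
  expect_equal(diag(C), rep(1, 5))
})

test_that("GATES reduces to Simes under identity LD and handles redundancy", {
  # singleton identity
  expect_equal(gates(0.2, matrix(1, 1, 1))$p_value, 0.2)
  # Simes: min(3*.01/1, 3*.20/2, 3*.90/3) = 0.03
  expect_equal(gates(c(0.01, 0.20, 0.90), diag(3))$p_value, 0.03,
               tolerance = 1e-12)
  # two perfectly correlated SNPs with equal p-values collapse to p0
  r <- gates(c(0.04, 0.04), matrix(1, 2, 2))
  expect_equal(r$p_value, 0.04, tolerance = 1e-6)
  # the polynomial p-value-correlation transform maps r = 1 to ~0.98, so
  # the effective test count collapses to ~1
  expect_equal(r$details$me, 1, tolerance = 0.05)
  expect_equal(gates(c(0.04, 0.04), matrix(1, 2, 2),
                     transform = "r2")$details$me, 1, tolerance = 1e-9)
  expect_error(gates(c(0.1, 0.2), diag(3)), "dimensions")
})

test_that("GATES never exceeds Bonferroni and ignores column order", {
  set.seed(21)
  for (k in 1:20) {
    m <- sample(2:8, 1)
    g <- simulate_exchangeable_block(600, 0.3, m, runif(1, 0, 0.8))
    C <- pairwise_ld(g)
    p <- runif(m)^2
    res <- gates(p, C)$p_value
    expect_lte(res, min(1, m * min(p)) + 1e-12)
    expect_gt(res, 0)
    perm <- sample(m)
    expect_equal(gates(p[perm], C[perm, perm])$p_value, res,
                 tolerance = 1e-9)
  }
})

test_that("VEGAS matches chi-square closed forms under identity LD", {
  mc_tol <- function(p, n_sim = 20000) 4 * sqrt(p * (1 - p) / n_sim)
  stats4 <- c(1.2, 3.4, 0.3, 2.2)
  p_sum <- vegas(stats4, diag(4), "sum", n_sim = 20000, seed = 1)$p_value
  closed_sum <- pchisq(sum(stats4), df = 4, lower.tail = FALSE)
  expect_lt(abs(p_sum - closed_sum), mc_tol(closed_sum))
  p_max <- vegas(stats4[1:2], diag(2), "max", n_sim = 20000,
                 seed = 2)$p_value
  closed_max <- 1 - pchisq(max(stats4[1:2]), df = 1)^2
  expect_lt(abs(p_max - closed_max), mc_tol(closed_max))
  # singleton reduces to the single-marker p-value
  p_one <- vegas(3.0, matrix(1, 1, 1), "sum", n_sim = 20000, seed = 3)$p_value
  closed_one <- pchisq(3.0, df = 1, lower.tail = FALSE)
  expect_lt(abs(p_one - closed_one), mc_tol(closed_one))
  expect_error(vegas(stats4, diag(4), "sum", n_sim = 50), "100")
})

test_that("VEGAS tolerates rank-deficient LD via diagonal jitter", {
  C <- matrix(1, 3, 3)                            # three identical SNPs
  res <- vegas(c(2, 2, 2), C, "max", n_sim = 1000, seed = 4)
  expect_gt(res$p_value, 0)
  expect_lte(res$p_value, 1)
})

test_that("LR likelihood-ratio test agrees with glm and handles aliasing", {
  cc <- make_cc_data(n_total = 800, seed = 17)
  X <- cc$genotypes$values
  y <- cc$status
  res <- lr_test(X, y)
  fit <- stats::glm(y ~ X, family = stats::binomial())
  p_glm <- pchisq(fit$null.deviance - fit$deviance, df = ncol(X),
                  lower.tail = FALSE)
  expect_equal(res$p_value, p_glm, tolerance = 1e-6)
  expect_equal(res$details$df, ncol(X))
  # duplicated column: aliased column dropped, df unchanged
  res_dup <- lr_test(cbind(X, X[, 1]), y)
  expect_equal(res_dup$details$df, ncol(X))
  expect_equal(res_dup$p_value, res$p_value, tolerance = 1e-6)
})

test_that("LR and trend test agree asymptotically for one SNP", {
  cc <- make_cc_data(n_total = 2000, n_noncausal = 0, rr = 1.5, seed = 23)
  g <- cc$genotypes$values[, 1, drop = FALSE]
  p_lr <- lr_test(g, cc$status)$p_value
  p_tr <- trend_test(g[, 1], cc$status)$p_value
  expect_equal(p_lr, p_tr, tolerance = 0.01)
})

test_that("LR-PC retains the minimal component set explaining 80%", {
  cc <- make_cc_data(n_total = 800, seed = 29)
  X <- cc$genotypes$values
  y <- cc$status
  # singleton: one component, identical to LR
  expect_equal(lr_pc_test(X[, 1, drop = FALSE], y)$p_value,
               lr_test(X[, 1, drop = FALSE], y)$p_value, tolerance = 1e-9)
  expect_equal(lr_pc_test(X[, 1, drop = FALSE], y)$details$n_components, 1)
  # two independent SNPs: each component explains ~50% < 80%, so X = 2
  expect_equal(lr_pc_test(X[, 1:2], y)$details$n_components, 2)
  # a tight high-LD block is summarised by far fewer components
  blk <- simulate_exchangeable_block(800, 0.3, 8, 0.9, seed = 31)
  expect_lt(lr_pc_test(blk$values, y)$details$n_components, 4)
})

test_that("high-LD non-causal block starves LR-PC of the causal signal", {
  # 32 exchangeable r=0.9 non-causal SNPs + 4 independent causal SNPs:
  # the first PC (the block average) already explains >= 80% of the
  # genotype correlation, so the retained set excludes the causal SNPs
  set.seed(33)
  blk <- simulate_exchangeable_block(2000, 0.3, 32, 0.9)$values
  caus <- simulate_independent(2000, rep(0.3, 4))$values
  y <- rbinom(2000, 1, 0.5)
  det <- lr_pc_test(cbind(caus, blk), y)$details
  expect_lte(det$n_components, 2)
  expect_gte(det$explained, 0.80)
})

test_that("set tests are invariant to SNP ordering", {
  cc <- make_cc_data(n_total = 600, n_noncausal = 5, seed = 37)
  X <- cc$genotypes$values
  y <- cc$status
  perm <- c(4, 1, 6, 2, 5, 3)
  for (fn in list(lr_test, lr_pc_test)) {
    expect_equal(fn(X[, perm], y)$p_value, fn(X, y)$p_value,
                 tolerance = 1e-6)
  }
  tr <- snpsetpower:::.trend_stats(X * 1.0, y)
  C <- pairwise_ld(X)
  expect_equal(gates(tr$p_value[perm], C[perm, perm])$p_value,
               gates(tr$p_value, C)$p_value, tolerance = 1e-9)
})

test_that("all five tests hold their type-I error under the null", {
  n_rep <- 2000
  n <- 400
  m <- 6
  alpha <- 0.05
  set.seed(101)
  rej <- matrix(0, n_rep, 5,
                dimnames = list(NULL, snpsetpower::SET_TEST_METHODS))
  for (k in seq_len(n_rep)) {
    X <- matrix(rbinom(n * m, 2, 0.3), n, m)
    y <- rep(c(1L, 0L), n / 2)[sample.int(n)]
    p <- snpsetpower:::.set_test_pvalues(X, y, vegas_sims = 400)
    rej[k, ] <- p <= alpha
  }
  rates <- colMeans(rej)
  band <- 3 * binom_se(alpha, n_rep)
  for (m_id in colnames(rej))
    expect_lt(abs(rates[[m_id]] - alpha), band)
})

test_that("run_set_tests returns tidy per-method and per-SNP results", {
  cc <- make_cc_data(n_total = 400, seed = 41)
  out <- run_set_tests(cc$genotypes, cc$status, vegas_sims = 200, seed = 1)
  expect_setequal(out$set_tests$method,
                  unname(snpsetpower::SET_TEST_LABELS))
  expect_true(all(out$set_tests$p_value > 0 & out$set_tests$p_value <= 1))
  expect_equal(nrow(out$snp_tests), ncol(cc$genotypes$values))
  # empty set after monomorphic pruning: p = 1 everywhere
  flat <- matrix(1L, 100, 2)
  p_flat <- snpsetpower:::.set_test_pvalues(flat, rep(0:1, 50))
  expect_true(all(p_flat == 1))
})
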