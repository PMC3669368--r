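test_that("independent simulation hits target MAFs and HWE frequencies", {
  n <- 50000
  g <- simulate_independent(n, c(0.05, 0.30), seed = 11)
  freq <- colMeans(g$values) / 2
  expect_lt(abs(freq[1] - 0.05), 4 * binom_se(0.05, 2 * n))
  expect_lt(abs(freq[2] - 0.30), 4 * binom_se(0.30, 2 * n))
  # HWE expansion (1-m)^2, 2m(1-m), m^2 at m = 0.30
  counts <- tabulate(g$values[, 2] + 1, 3) / n
  expect_equal(counts, c(0.49, 0.42, 0.09), tolerance = 0.01)
  # independence: off-diagonal genotype correlation near 0
  expect_lt(abs(pairwise_ld(g)[1, 2]), 4 / sqrt(n))
})

test_that("independent simulation is reproducible and validates input", {
  expect_identical(simulate_independent(50, c(0.2, 0.4), seed = 5)$values,
                   simulate_independent(50, c(0.2, 0.4), seed = 5)$values)
  expect_error(simulate_independent(0, 0.3), "positive")
  expect_error(simulate_independent(10, 0.7), "0, 0.5")
  expect_error(simulate_independent(10, 0), "0, 0.5")
  # degenerate frequency: an (almost) all-zero column
  expect_true(all(simulate_independent(100, 1e-9, seed = 1)$values == 0))
})

test_that("exchangeable blocks target the requested correlation and HWE", {
  n <- 50000
  for (cfg in list(list(maf = 0.30, m = 8, r = 0.9),
                   list(maf = 0.05, m = 4, r = 0.5))) {
    g <- simulate_exchangeable_block(n, cfg$maf, cfg$m, cfg$r, seed = 7)
    C <- pairwise_ld(g)
    expect_lt(abs(mean_offdiag(C) - cfg$r), 0.03)
    freq <- mean(g$values) / 2
    expect_lt(abs(freq - cfg$maf), 4 * binom_se(cfg$maf, 2 * n * cfg$m))
    # HWE per site
    counts <- tabulate(g$values[, 1] + 1, 3) / n
    m <- cfg$maf
    expect_equal(counts, c((1 - m)^2, 2 * m * (1 - m), m^2),
                 tolerance = 0.01)
  }
})

test_that("zero-correlation exchangeable block behaves like independence", {
  g <- simulate_exchangeable_block(20000, 0.3, 4, 0, seed = 3)
  expect_lt(max(abs(pairwise_ld(g)[upper.tri(diag(4))])), 0.03)
})

test_that("causal-anchored blocks give r to the anchor and r^2 among tags", {
  n <- 50000
  g <- simulate_causal_anchored_block(n, 0.30, 4, 0.9, seed = 13)
  C <- pairwise_ld(g)
  expect_lt(max(abs(C[1, -1] - 0.9)), 0.03)
  tags <- C[-1, -1]
  expect_lt(abs(mean_offdiag(tags) - 0.81), 0.05)
  g2 <- simulate_causal_anchored_block(n, 0.05, 4, 0.5, seed = 14)
  C2 <- pairwise_ld(g2)
  expect_lt(max(abs(C2[1, -1] - 0.5)), 0.03)
  expect_lt(abs(mean_offdiag(C2[-1, -1]) - 0.25), 0.05)
  # r = 0: anchor and tags mutually independent
  g0 <- simulate_causal_anchored_block(20000, 0.3, 3, 0, seed = 15)
  expect_lt(max(abs(pairwise_ld(g0)[upper.tri(diag(4))])), 0.03)
})

test_that("Frechet feasibility bounds are enforced", {
  expect_true(check_correlation_feasibility(0.3, 0.3, 0.9))
  expect_true(check_correlation_feasibility(0.11, 0.47, 0))
  # upper bound sqrt(0.05*0.70 / (0.30*0.95)) ~ 0.35 < 0.9
  expect_false(check_correlation_feasibility(0.05, 0.30, 0.9))
  expect_true(check_correlation_feasibility(0.05, 0.30, 0.3))
})

test_that("pool sampling reproduces pool-implied frequencies and LD", {
  # degenerate pool: one haplotype of all minor alleles
  p1 <- haplotype_pool(matrix(1L, 1, 5), 1, 1:5, c(2, 4), 1)
  expect_true(all(sample_from_pool(p1, 50, seed = 1)$values == 2))
  # two equiprobable complementary haplotypes: MAF 1/2, |r| = 1 at the
  # haplotype level
  p2 <- haplotype_pool(rbind(c(1L, 0L, 1L), c(0L, 1L, 0L)), c(0.5, 0.5),
                       1:3, c(1, 3), 1)
  g2 <- sample_from_pool(p2, 4000, seed = 2)
  expect_equal(unname(colMeans(g2$values) / 2), rep(0.5, 3),
               tolerance = 0.05)
  expect_equal(abs(pool_ld(p2)[1, 2]), 1)
  # realistic fixture: empirical MAFs track implied frequencies
  pool <- make_realistic_fixture(seed = 2)
  g <- sample_from_pool(pool, 2000, seed = 3)
  f <- pool_implied_mafs(pool)
  dev <- abs(colMeans(g$values) / 2 - f)
  expect_true(all(dev < 4 * binom_se(pmax(f, 0.05), 2 * 2000)))
})

test_that("realistic fixture has the documented region composition", {
  pool <- make_realistic_fixture(seed = 1)
  pos <- pool$positions
  gene <- pool$gene_interval
  intra <- pos >= gene[1] & pos <= gene[2]
  expect_length(pos, 80)
  expect_equal(sum(intra), 33)
  expect_equal(sum(pos < gene[1]), 23)
  expect_equal(sum(pos > gene[2]), 24)
  expect_length(pool$causal_indices, 6)
  expect_equal(sum(intra[pool$causal_indices]), 4)
  f <- pool_implied_mafs(pool)
  expect_true(all(f >= 0.06 & f <= 0.50))
  expect_equal(sum(pool$frequencies), 1, tolerance = 1e-9)
  # a multi-SNP LD block (r^2 > 0.5) crosses the upper gene boundary
  ld2 <- pool_ld(pool)^2
  last_in <- max(which(intra))
  expect_gt(max(ld2[(last_in - 2):last_in,
                    (last_in + 1):(last_in + 3)]), 0.5)
  # determinism
  pool_b <- make_realistic_fixture(seed = 1)
  expect_identical(pool$haplotypes, pool_b$haplotypes)
  expect_false(identical(make_realistic_fixture(seed = 9)$haplotypes,
                         pool$haplotypes))
})

test_that("haplotype pools round-trip through the text format", {
  pool <- make_realistic_fixture(seed = 4, n_haplotypes = 40)
  path <- withr::local_tempfile(fileext = ".txt")
  write_haplotype_pool(pool, path)
  back <- read_haplotype_pool(path)
  expect_identical(back$haplotypes, pool$haplotypes)
  expect_equal(back$frequencies, pool$frequencies)
  expect_equal(back$positions, pool$positions)
  expect_equal(back$gene_interval, pool$gene_interval)
  expect_identical(back$causal_indices, pool$causal_indices)
})
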