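test_that("grid constructors enumerate the documented setting counts", {
  nold <- build_nold_grid(replicates = 10)
  expect_length(nold, 288)
  # the zero-non-causal option appears once per causal combination
  expect_equal(sum(vapply(nold, function(s) s$n_noncausal == 0,
                          logical(1))), 32)
  expect_true(all(vapply(nold, function(s) s$kind == "independent",
                         logical(1))))

  cld <- build_causal_ld_grid(replicates = 10)
  expect_length(cld, 96)
  expect_true(all(vapply(cld, function(s)
    s$n_noncausal %in% c(4, 8) && s$n_causal %in% c(1, 2, 4) &&
      s$ld_r %in% c(0.5, 0.9) &&
      s$n_noncausal %% s$n_causal == 0, logical(1))))
  cld2 <- build_causal_ld_grid(include_tag_only = TRUE, replicates = 10)
  expect_length(cld2, 192)
  expect_equal(sum(vapply(cld2, function(s)
    s$analyze_mask == "noncausal_only", logical(1))), 96)

  ncld <- build_noncausal_ld_grid(replicates = 10)
  expect_length(ncld, 1088)
  for (s in ncld) {
    expect_true(nrow(s$blocks) %in% 1:2)
    expect_true(all(s$blocks$r %in% c(0.5, 0.9)))
    expect_equal(sum(s$blocks$size), s$n_noncausal)
    if (nrow(s$blocks) == 2)
      expect_equal(s$blocks$size[1], s$blocks$size[2])
  }
})

test_that("setting constructor validates its arguments", {
  expect_error(simulation_setting("x", "independent", n_causal = 1, rr = 2,
                                  n_total = 2001, maf_causal = 0.3),
               "even")
  expect_error(simulation_setting("x", "independent", n_causal = 1, rr = 2,
                                  n_total = 2000, maf_causal = 0.3,
                                  alpha = 1.5), "alpha")
  expect_error(simulation_setting("x", "independent", n_causal = 1, rr = 2,
                                  n_total = 2000, maf_causal = 0.3,
                                  replicates = 0), "replicates")
  expect_error(simulation_setting("x", "exchangeable", n_causal = 1,
                                  n_noncausal = 4, rr = 2, n_total = 2000,
                                  maf_causal = 0.3, maf_noncausal = 0.3,
                                  blocks = data.frame(size = 3, r = 0.5)),
               "summing")
})

test_that("derived seeds are valid integers and purpose-separated", {
  s1 <- snpsetpower:::derive_seed(1, "nold_001", 3, "genotypes")
  s2 <- snpsetpower:::derive_seed(1, "nold_001", 3, "disease")
  s3 <- snpsetpower:::derive_seed(2, "nold_001", 3, "genotypes")
  expect_true(is.integer(c(s1, s2, s3)))
  expect_true(all(c(s1, s2, s3) >= 0 & c(s1, s2, s3) < 2^31))
  expect_false(s1 == s2)
  expect_false(s1 == s3)
  expect_identical(s1, snpsetpower:::derive_seed(1, "nold_001", 3,
                                                 "genotypes"))
})

test_that("run_setting is deterministic and has the right shape", {
  s <- simulation_setting("det", "independent", n_causal = 2,
                          n_noncausal = 2, rr = 2, n_total = 400,
                          maf_causal = 0.3, maf_noncausal = 0.3,
                          replicates = 8)
  a <- run_setting(s, seed = 7)
  b <- run_setting(s, seed = 7)
  expect_identical(a, b)
  expect_equal(nrow(a), 5)
  expect_true(all(a$power >= 0 & a$power <= 1))
  expect_equal(a$se, sqrt(a$power * (1 - a$power) / a$replicates))
  c_ <- run_setting(s, seed = 8)
  expect_false(identical(a$power, c_$power))
})

test_that("dropping a method does not perturb the others", {
  s <- simulation_setting("strm", "independent", n_causal = 1,
                          n_noncausal = 4, rr = 2, n_total = 400,
                          maf_causal = 0.3, maf_noncausal = 0.3,
                          replicates = 10)
  all5 <- run_setting(s, seed = 3)
  no_vegas <- run_setting(s, methods = c("gates", "lr"), seed = 3)
  expect_equal(no_vegas$power[no_vegas$method == "gates"],
               all5$power[all5$method == "gates"])
  expect_equal(no_vegas$power[no_vegas$method == "lr"],
               all5$power[all5$method == "lr"])
})

test_that("null settings reject at about the nominal level", {
  s <- simulation_setting("null", "independent", n_causal = 1,
                          n_noncausal = 3, rr = 1, n_total = 400,
                          maf_causal = 0.3, maf_noncausal = 0.3,
                          replicates = 150)
  pt <- run_setting(s, seed = 11)
  for (k in seq_len(nrow(pt)))
    expect_lt(abs(pt$power[k] - 0.05), 3 * binom_se(0.05, 150) + 0.01)
})

test_that("a strong lone causal SNP gives near-certain detection", {
  s <- simulation_setting("strong", "independent", n_causal = 1,
                          n_noncausal = 0, rr = 2, n_total = 4000,
                          maf_causal = 0.3, replicates = 30)
  pt <- run_setting(s, seed = 13)
  expect_true(all(pt$power > 0.9))
})

test_that("power rises with relative risk and sample size", {
  base <- list(n_causal = 2, n_noncausal = 4, maf = 0.3, reps = 100)
  mk <- function(id, rr, n_total)
    simulation_setting(id, "independent", n_causal = base$n_causal,
                       n_noncausal = base$n_noncausal, rr = rr,
                       n_total = n_total, maf_causal = base$maf,
                       maf_noncausal = base$maf, replicates = base$reps)
  pt <- run_grid(list(mk("lo_rr", 1.25, 2000), mk("hi_rr", 2, 2000),
                      mk("hi_n", 1.25, 4000)), methods = "gates",
                 base_seed = 5)
  p <- setNames(pt$power, pt$setting_id)
  expect_gt(p[["hi_rr"]], p[["lo_rr"]] - 0.05)
  expect_gt(p[["hi_n"]], p[["lo_rr"]] - 0.05)
})

test_that("masking all analysed SNPs yields zero power", {
  s <- simulation_setting("mask0", "independent", n_causal = 1,
                          n_noncausal = 0, rr = 2, n_total = 400,
                          maf_causal = 0.3, analyze_mask = "noncausal_only",
                          replicates = 5)
  pt <- run_setting(s, seed = 1)
  expect_true(all(pt$power == 0))
})

test_that("run_grid validates, parallelises deterministically and skips
           failing settings", {
  grid <- build_nold_grid(replicates = 4)[c(1, 50, 200)]
  expect_error(run_grid(grid, replicates = 0), ">= 1")
  a <- run_grid(grid, methods = c("gates", "lr"), base_seed = 2)
  expect_equal(nrow(a), 3 * 2)
  b <- run_grid(grid, methods = c("gates", "lr"), base_seed = 2,
                workers = 2)
  expect_equal(a, b)
  # an unfeasible setting is recorded as a warning, not an error
  bad <- simulation_setting("bad", "independent", n_causal = 1,
                            n_noncausal = 0, rr = 30, n_total = 400,
                            maf_causal = 0.05, replicates = 2)
  expect_warning(res <- run_grid(c(grid[1], list(bad)), methods = "gates",
                                 base_seed = 1), "bad")
  expect_equal(nrow(res), 1)
})

test_that("tag-only analysis of anchored blocks still carries signal", {
  s_all <- simulation_setting("anch_a", "causal_anchored", n_causal = 1,
                              n_noncausal = 4, rr = 2, n_total = 2000,
                              maf_causal = 0.3, maf_noncausal = 0.3,
                              ld_r = 0.9, replicates = 40)
  s_tag <- simulation_setting("anch_t", "causal_anchored", n_causal = 1,
                              n_noncausal = 4, rr = 2, n_total = 2000,
                              maf_causal = 0.3, maf_noncausal = 0.3,
                              ld_r = 0.9, analyze_mask = "noncausal_only",
                              replicates = 40)
  pt <- run_grid(list(s_all, s_tag), methods = "gates", base_seed = 9)
  p <- setNames(pt$power, pt$setting_id)
  expect_gt(p[["anch_t"]], 0.3)          # tags proxy the causal signal
  expect_gte(p[["anch_a"]], p[["anch_t"]] - 0.1)
})
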