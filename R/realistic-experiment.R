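#' Power across window sizes and LD-threshold selection on a realistic
#' region
#'
#' For each window size, selects the SNPs of the haplotype pool assigned to
#' the gene by the plain window rule (and optionally by the window + LD
#' threshold rule, using the pool's exact population LD) and estimates
#' power of the set tests on the selected SNP set.
#'
#' @param pool a [haplotype_pool], e.g. [make_realistic_fixture()].
#' @param window_kb vector of window sizes in kb.
#' @param rr heterozygote relative risk per causal SNP.
#' @param n_total total sample size (cases + controls).
#' @param replicates Monte Carlo replicates per point.
#' @param methods subset of [SET_TEST_METHODS].
#' @param base_seed base seed.
#' @param ld_rule optional [selection_rule] of kind `"ld_window"`; when
#'   given, each window is also run with the LD-threshold selection.
#' @param alpha per-gene significance level.
#' @return Power-table data.frame with extra columns `rule`, `window_kb`,
#'   `n_snps`, `n_causal_selected`.
#' @export
realistic_power_experiment <- function(pool, window_kb = c(0, 25, 50, 100,
                                                           150, 250),
                                       rr = 2, n_total = 1000,
                                       replicates = 100,
                                       methods = SET_TEST_METHODS,
                                       base_seed = 1L, ld_rule = NULL,
                                       alpha = 0.05) {
  ld <- pool_ld(pool)
  run_point <- function(rule_name, w, idx) {
    s <- simulation_setting(id = sprintf("real_%s_w%g", rule_name, w),
                            kind = "pool", pool = pool, rr = rr,
                            n_total = n_total, analyze_indices = idx,
                            alpha = alpha, replicates = replicates)
    pt <- run_setting(s, methods, seed = base_seed)
    pt$rule <- rule_name
    pt$window_kb <- w
    pt$n_snps <- length(idx)
    pt$n_causal_selected <- length(intersect(idx, pool$causal_indices))
    pt
  }
  rows <- lapply(window_kb, function(w)
    run_point("window", w,
              select_by_window(pool$positions, pool$gene_interval, w)))
  if (!is.null(ld_rule)) {
    rows <- c(rows, lapply(window_kb, function(w) {
      rule <- selection_rule("ld_window", w, ld_rule$r2_threshold)
      run_point("ld_window", w,
                select_by_ld(pool$positions, ld, pool$gene_interval, rule))
    }))
  }
  do.call(rbind, rows)
}
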