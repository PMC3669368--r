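#' Simulation setting for a power estimate
#'
#' Bundles the disease architecture, LD regime and analysis options of one
#' cell of a simulation grid.
#'
#' @param id short unique label used for reproducible per-setting seeding.
#' @param kind LD regime: `"independent"`, `"exchangeable"`,
#'   `"causal_anchored"` or `"pool"`.
#' @param n_causal,n_noncausal causal / non-causal SNP counts (non-pool
#'   kinds).
#' @param rr heterozygote relative risk applied per causal SNP.
#' @param n_total total sample size, split evenly between cases and
#'   controls.
#' @param maf_causal,maf_noncausal minor allele frequencies; `maf_noncausal`
#'   may be `NA` when `n_noncausal = 0`.
#' @param ld_r anchor-tag correlation (`causal_anchored` kind).
#' @param blocks data.frame with columns `size` and `r`, one row per
#'   exchangeable non-causal block (`exchangeable` kind); sizes must sum to
#'   `n_noncausal`.
#' @param pool a [haplotype_pool] (`pool` kind).
#' @param analyze_indices SNP columns entering the tests (`pool` kind);
#'   defaults to all pool SNPs.
#' @param analyze_mask `"all"` or `"noncausal_only"` (the tag-SNP-only
#'   scenario in which causal SNPs are not genotyped).
#' @param alpha per-gene significance level (default 0.05).
#' @param replicates Monte Carlo case-control samples per setting.
#' @return An object of class `simulation_setting`.
#' @export
simulation_setting <- function(id, kind = c("independent", "exchangeable",
                                            "causal_anchored", "pool"),
                               n_causal = NULL, n_noncausal = 0, rr = NULL,
                               n_total = NULL, maf_causal = NULL,
                               maf_noncausal = NA, ld_r = NA, blocks = NULL,
                               pool = NULL, analyze_indices = NULL,
                               analyze_mask = c("all", "noncausal_only"),
                               alpha = 0.05, replicates = 500) {
  kind <- match.arg(kind)
  analyze_mask <- match.arg(analyze_mask)
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  if (replicates < 1) stop("replicates must be >= 1")
  if (n_total %% 2 != 0) stop("n_total must be even (equal cases/controls)")
  if (kind == "pool") {
    if (is.null(pool)) stop("pool kind requires a haplotype_pool")
    n_causal <- length(pool$causal_indices)
    if (is.null(analyze_indices))
      analyze_indices <- seq_len(ncol(pool$haplotypes))
  } else {
    if (is.null(n_causal) || n_causal < 1) stop("n_causal must be >= 1")
    if (n_noncausal > 0 && (is.na(maf_noncausal) ||
                            maf_noncausal <= 0 || maf_noncausal > 0.5))
      stop("maf_noncausal must lie in (0, 0.5] when n_noncausal > 0")
    if (kind == "exchangeable") {
      if (is.null(blocks) || sum(blocks$size) != n_noncausal)
        stop("exchangeable kind requires blocks with sizes summing to ",
             "n_noncausal")
      if (any(blocks$size < 2))
        stop("exchangeable blocks need >= 2 members")
    }
    if (kind == "causal_anchored") {
      if (is.na(ld_r)) stop("causal_anchored kind requires ld_r")
      if (n_noncausal %% n_causal != 0)
        stop("n_noncausal must split evenly across the causal anchors")
    }
  }
  structure(list(id = id, kind = kind, n_causal = n_causal,
                 n_noncausal = n_noncausal, rr = rr, n_total = n_total,
                 maf_causal = maf_causal, maf_noncausal = maf_noncausal,
                 ld_r = ld_r, blocks = blocks, pool = pool,
                 analyze_indices = analyze_indices,
                 analyze_mask = analyze_mask, alpha = alpha,
                 replicates = as.integer(replicates)),
            class = "simulation_setting")
}

## ---- grid constructors ----------------------------------------------------

.causal_combos <- function() {
  expand.grid(n_causal = c(1, 2, 4, 8), rr = c(1.25, 2),
              n_total = c(2000, 4000), maf_causal = c(0.05, 0.30),
              KEEP.OUT.ATTRS = FALSE)
}

.noncausal_options <- function() {
  rbind(data.frame(n_noncausal = 0, maf_noncausal = NA_real_),
        expand.grid(n_noncausal = c(2, 4, 8, 32),
                    maf_noncausal = c(0.05, 0.30),
                    KEEP.OUT.ATTRS = FALSE))
}

#' Factorial grid with no LD (288 settings)
#'
#' Crosses 32 causal combinations (1/2/4/8 causal SNPs x relative risk
#' 1.25/2 x total n 2000/4000 x causal MAF 5%/30%) with 9 non-causal options
#' (none, or 2/4/8/32 non-causal SNPs at 5% or 30% MAF), all SNPs
#' independent: 32 x 9 = 288 settings.
#'
#' @param replicates,alpha defaults for every setting.
#' @return List of [simulation_setting] objects.
#' @export
build_nold_grid <- function(replicates = 500, alpha = 0.05) {
  cells <- merge(.causal_combos(), .noncausal_options(), by = NULL)
  lapply(seq_len(nrow(cells)), function(k) {
    cl <- cells[k, ]
    simulation_setting(id = sprintf("nold_%03d", k), kind = "independent",
                       n_causal = cl$n_causal, n_noncausal = cl$n_noncausal,
                       rr = cl$rr, n_total = cl$n_total,
                       maf_causal = cl$maf_causal,
                       maf_noncausal = cl$maf_noncausal,
                       alpha = alpha, replicates = replicates)
  })
}

#' Factorial grid with causal-anchored LD (96 or 192 settings)
#'
#' 3 causal counts (1/2/4) x 2 non-causal counts (4/8) x 2 relative risks x
#' 2 sample sizes x 2 shared MAFs x 2 LD levels (r = 0.5 or 0.9) = 96
#' settings. Each causal SNP anchors its own block and the non-causal SNPs
#' split evenly across anchors, each correlated `r` with its anchor and
#' `r^2` with each other. With `include_tag_only = TRUE`, every setting is
#' duplicated with `analyze_mask = "noncausal_only"` (tag SNPs measured,
#' causal SNPs not), for 192 settings.
#'
#' @param include_tag_only duplicate settings with the causal SNPs masked.
#' @param replicates,alpha defaults for every setting.
#' @return List of [simulation_setting] objects.
#' @export
build_causal_ld_grid <- function(include_tag_only = FALSE, replicates = 500,
                                 alpha = 0.05) {
  cells <- expand.grid(n_causal = c(1, 2, 4), n_noncausal = c(4, 8),
                       rr = c(1.25, 2), n_total = c(2000, 4000),
                       maf = c(0.05, 0.30), ld_r = c(0.5, 0.9),
                       KEEP.OUT.ATTRS = FALSE)
  build <- function(k, mask, tag) {
    cl <- cells[k, ]
    simulation_setting(id = sprintf("cld_%03d%s", k, tag),
                       kind = "causal_anchored",
                       n_causal = cl$n_causal, n_noncausal = cl$n_noncausal,
                       rr = cl$rr, n_total = cl$n_total,
                       maf_causal = cl$maf, maf_noncausal = cl$maf,
                       ld_r = cl$ld_r, analyze_mask = mask,
                       alpha = alpha, replicates = replicates)
  }
  grid <- lapply(seq_len(nrow(cells)), build, mask = "all", tag = "")
  if (include_tag_only)
    grid <- c(grid, lapply(seq_len(nrow(cells)), build,
                           mask = "noncausal_only", tag = "t"))
  grid
}

#' Factorial grid with LD between non-causal SNPs (1088 settings)
#'
#' The 32 causal combinations are crossed with non-causal arrangements in
#' which all non-causal SNPs (2/4/8/32 at 5% or 30% MAF) sit in exchangeable
#' LD blocks: a single block at low (r = 0.5) or high (r = 0.9) LD, or --
#' for counts >= 4 -- an even split into two blocks at high/high, low/low or
#' high/low LD (a 2-SNP count cannot split into two blocks of at least two
#' members). This enumeration gives 32 x 2 x (2 + 5 + 5 + 5) = 1088
#' settings; the constructor asserts that count.
#'
#' @param replicates,alpha defaults for every setting.
#' @return List of [simulation_setting] objects.
#' @export
build_noncausal_ld_grid <- function(replicates = 500, alpha = 0.05) {
  configs <- function(count) {
    one <- list(data.frame(size = count, r = 0.5),
                data.frame(size = count, r = 0.9))
    if (count < 4) return(one)
    half <- count / 2
    c(one, list(data.frame(size = c(half, half), r = c(0.9, 0.9)),
                data.frame(size = c(half, half), r = c(0.5, 0.5)),
                data.frame(size = c(half, half), r = c(0.9, 0.5))))
  }
  causal <- .causal_combos()
  grid <- list()
  k <- 0
  for (i in seq_len(nrow(causal))) {
    cc <- causal[i, ]
    for (count in c(2, 4, 8, 32)) for (maf_nc in c(0.05, 0.30)) {
      for (blocks in configs(count)) {
        k <- k + 1
        grid[[k]] <- simulation_setting(
          id = sprintf("ncld_%04d", k), kind = "exchangeable",
          n_causal = cc$n_causal, n_noncausal = count, rr = cc$rr,
          n_total = cc$n_total, maf_causal = cc$maf_causal,
          maf_noncausal = maf_nc, blocks = blocks,
          alpha = alpha, replicates = replicates)
      }
    }
  }
  stopifnot(length(grid) == 1088)
  grid
}

## ---- one-setting power estimate ------------------------------------------

## Simulate one case-control replicate of a setting. Disease depends only on
## the causal genotypes, so the population is simulated at the causal SNPs
## (as two allele layers when tags must later be anchored to them) and
## non-causal genotypes are generated just for the sampled individuals --
## exactly distribution-preserving and far cheaper. Separate derived seeds
## per purpose keep every stream independent.
.simulate_replicate <- function(s, base_seed, rep_i, pop_multiplier = 10) {
  sd_geno <- derive_seed(base_seed, s$id, rep_i, "genotypes")
  sd_dis <- derive_seed(base_seed, s$id, rep_i, "disease")
  sd_samp <- derive_seed(base_seed, s$id, rep_i, "sampling")
  sd_nc <- derive_seed(base_seed, s$id, rep_i, "noncausal")

  n_cases <- n_controls <- s$n_total / 2
  p_du <- 0.10 / s$n_causal
  prev <- 1 - (1 - p_du)^s$n_causal
  mult <- pop_multiplier
  for (attempt in 1:6) {
    n_pop <- max(mult * s$n_total, ceiling(1.5 * n_cases / prev))
    set.seed(sd_geno)
    layers <- NULL
    if (s$kind == "pool") {
      pop <- sample_from_pool(s$pool, n_pop)
      causal_idx <- s$pool$causal_indices
      mafs_causal <- pop$mafs[causal_idx]
      Gc <- pop$values[, causal_idx, drop = FALSE]
    } else if (s$kind == "causal_anchored") {
      L1 <- cpp_bernoulli_matrix(n_pop, s$n_causal, s$maf_causal)
      L2 <- cpp_bernoulli_matrix(n_pop, s$n_causal, s$maf_causal)
      layers <- list(L1, L2)
      Gc <- L1 + L2
      mafs_causal <- rep(s$maf_causal, s$n_causal)
    } else {
      Gc <- cpp_hwe_genotypes(n_pop, rep(s$maf_causal, s$n_causal))
      mafs_causal <- rep(s$maf_causal, s$n_causal)
    }
    model <- disease_model(s$n_causal, s$rr, mafs_causal, p_du = p_du)
    set.seed(sd_dis)
    status <- cpp_disease_status(Gc, model$probs)
    cases <- which(status == 1L)
    controls <- which(status == 0L)
    if (length(cases) >= n_cases && length(controls) >= n_controls) break
    mult <- mult * 2
    if (attempt == 6)
      stop("population repeatedly short of cases; increase pop_multiplier")
  }
  set.seed(sd_samp)
  idx <- c(cases[sample.int(length(cases), n_cases)],
           controls[sample.int(length(controls), n_controls)])
  y <- rep(c(1L, 0L), c(n_cases, n_controls))

  set.seed(sd_nc)
  Xnc <- NULL
  if (s$kind == "independent" && s$n_noncausal > 0) {
    Xnc <- cpp_hwe_genotypes(s$n_total, rep(s$maf_noncausal, s$n_noncausal))
  } else if (s$kind == "exchangeable" && s$n_noncausal > 0) {
    Xnc <- do.call(cbind, lapply(seq_len(nrow(s$blocks)), function(b)
      simulate_exchangeable_block(s$n_total, s$maf_noncausal,
                                  s$blocks$size[b], s$blocks$r[b])$values))
  } else if (s$kind == "causal_anchored" && s$n_noncausal > 0) {
    per_anchor <- s$n_noncausal / s$n_causal
    Xnc <- do.call(cbind, lapply(seq_len(s$n_causal), function(j)
      .anchored_tag_layer(layers[[1]][idx, j], s$maf_causal, per_anchor,
                          s$ld_r) +
      .anchored_tag_layer(layers[[2]][idx, j], s$maf_causal, per_anchor,
                          s$ld_r)))
  }

  if (s$kind == "pool") {
    cols <- s$analyze_indices
    if (s$analyze_mask == "noncausal_only")
      cols <- setdiff(cols, s$pool$causal_indices)
    X <- pop$values[idx, cols, drop = FALSE]
  } else if (s$analyze_mask == "noncausal_only") {
    X <- if (is.null(Xnc)) matrix(0L, s$n_total, 0) else Xnc
  } else {
    X <- cbind(Gc[idx, , drop = FALSE], Xnc)
  }
  list(X = X, y = y,
       vegas_seed = derive_seed(base_seed, s$id, rep_i, "vegas"))
}

#' Estimate power of the set tests for one simulation setting
#'
#' Repeats `setting$replicates` times: simulate a population under the
#' setting's LD regime, assign disease via the Bernoulli-per-causal-SNP
#' model, sample the case-control panel, and apply the requested set tests
#' at level `alpha` to the masked SNP set. Power is the rejection fraction;
#' replicates whose logistic fit fails to converge are excluded from that
#' method's denominator and counted.
#'
#' @param setting a [simulation_setting].
#' @param methods subset of [SET_TEST_METHODS].
#' @param seed base seed; all per-replicate streams derive from it and the
#'   setting id.
#' @param vegas_sims Monte Carlo replicates for VEGAS (default 1000).
#' @param pop_multiplier population size as a multiple of `n_total`
#'   (default 10, which at ~10% prevalence yields about twice the cases
#'   needed; doubled automatically on a shortfall).
#' @return A power-table data.frame, one row per method.
#' @export
run_setting <- function(setting, methods = SET_TEST_METHODS, seed = 1L,
                        vegas_sims = 1000, pop_multiplier = 10) {
  s <- setting
  methods <- match.arg(methods, SET_TEST_METHODS, several.ok = TRUE)
  reject <- failed <- setNames(numeric(length(methods)), methods)
  for (rep_i in seq_len(s$replicates)) {
    dat <- .simulate_replicate(s, seed, rep_i, pop_multiplier)
    p <- .set_test_pvalues(dat$X, dat$y, methods, vegas_sims,
                           vegas_seed = dat$vegas_seed)
    ok <- !is.na(p)
    failed[!ok] <- failed[!ok] + 1
    reject[ok] <- reject[ok] + (p[ok] <= s$alpha)
  }
  denom <- s$replicates - failed
  power <- ifelse(denom > 0, reject / denom, NA_real_)
  blocks_high <- switch(s$kind,
    exchangeable = mean(s$blocks$r == 0.9),
    causal_anchored = as.numeric(s$ld_r == 0.9),
    NA_real_)
  data.frame(setting_id = s$id, kind = s$kind,
             n_causal = s$n_causal, n_noncausal = s$n_noncausal,
             rr = s$rr %||% NA_real_, n_total = s$n_total,
             maf_causal = s$maf_causal %||% NA_real_,
             maf_noncausal = s$maf_noncausal,
             ld_high = blocks_high,
             n_blocks = if (s$kind == "exchangeable") nrow(s$blocks)
                        else NA_real_,
             analyze_mask = s$analyze_mask, alpha = s$alpha,
             method = methods, replicates = s$replicates,
             n_failed = as.numeric(failed), power = as.numeric(power),
             se = sqrt(pmax(power * (1 - power), 0) / pmax(denom, 1)),
             row.names = NULL)
}

#' Run a grid of simulation settings
#'
#' Per-setting seeds derive deterministically from `base_seed` and the
#' setting id, so results are identical regardless of worker count or
#' execution order. A setting that errors is recorded (with a warning) and
#' skipped rather than aborting the grid.
#'
#' @param grid list of [simulation_setting] objects.
#' @param methods subset of [SET_TEST_METHODS].
#' @param replicates optional global override of each setting's replicate
#'   count (must be >= 1).
#' @param base_seed base seed for all settings.
#' @param workers number of parallel workers (forked; 1 = serial).
#' @param vegas_sims Monte Carlo replicates for VEGAS.
#' @return A power-table data.frame, one row per (setting, method).
#' @export
run_grid <- function(grid, methods = SET_TEST_METHODS, replicates = NULL,
                     base_seed = 1L, workers = 1L, vegas_sims = 1000) {
  if (!is.null(replicates) && replicates < 1)
    stop("replicates override must be >= 1")
  run_one <- function(s) {
    if (!is.null(replicates)) s$replicates <- as.integer(replicates)
    tryCatch(run_setting(s, methods, seed = base_seed,
                         vegas_sims = vegas_sims),
             error = function(e) {
               warning(sprintf("setting %s failed: %s", s$id,
                               conditionMessage(e)), call. = FALSE)
               NULL
             })
  }
  rows <- if (workers > 1)
    parallel::mclapply(grid, run_one, mc.cores = workers)
  else lapply(grid, run_one)
  do.call(rbind, rows)
}
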