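## Shared small fixtures, built in code at test time.

## A small case-control data set with one moderately strong causal SNP and a
## few independent non-causal SNPs.
make_cc_data <- function(n_total = 1000, n_noncausal = 4, rr = 2,
                         maf = 0.3, seed = 42) {
  pop <- simulate_independent(max(20000, 15 * n_total),
                              rep(maf, 1 + n_noncausal), seed = seed)
  model <- disease_model(1, rr, maf)
  status <- simulate_disease_status(pop, model, seed = seed + 1)
  sample_case_control(pop, status, n_total / 2, n_total / 2,
                      seed = seed + 2)
}

## Empirical binomial SE helper for frequency checks.
binom_se <- function(p, n) sqrt(p * (1 - p) / n)

mean_offdiag <- function(C) mean(C[upper.tri(C)])
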