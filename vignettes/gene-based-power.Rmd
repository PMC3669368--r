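---
title: "Power of gene-based SNP-set tests with non-causal SNPs and LD"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Power of gene-based SNP-set tests with non-causal SNPs and LD}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`snpsetpower` is a simulation laboratory for a question that matters to
anyone running gene-based tests of association on common variants: *how
much power is lost when non-causal SNPs are swept into the tested set, and
how does linkage disequilibrium (LD) between the set members change the
answer?* The package simulates case-control genotype/phenotype data under
controlled LD architectures, applies five popular SNP-set tests, estimates
power over factorial grids, and summarises the cost of non-causal SNPs by
regressing power on the design parameters.

This vignette documents the models, the tunable parameters, the numerical
choices, and the limits of what the simulations can show.

## The disease model

Disease status is generated from the causal SNPs only, through a
"unique-contribution" architecture. With $i$ causal SNPs, each causal SNP
is assigned a unique disease prevalence

$$P(D_U) = 0.10 / i,$$

so overall prevalence $1 - (1 - 0.10/i)^i \approx 10\%$ for every $i$. At
a causal SNP with minor (risk) allele frequency $m$ and additive relative
risk $\gamma$, the genotype-conditional risks are

$$P(D \mid G=0) = \frac{P(D_U)}{(1-m)^2 + 2\gamma m(1-m) + (2\gamma-1)m^2},$$

with $P(D\mid G=1) = \gamma\,P(D\mid G=0)$ and
$P(D\mid G=2) = (2\gamma - 1)\,P(D\mid G=0)$; the denominator makes the
HWE-weighted mean risk equal $P(D_U)$ exactly (an identity the test suite
asserts to $10^{-12}$). Each individual draws one Bernoulli per causal SNP
with probability $P(D_U \mid G)$ and is diseased if any draw fires; draws
are consumed individual-major, SNP-minor from a dedicated seeded stream.

### A structural consequence worth knowing

Because a fixed ~10% prevalence is split across $i$ independent causes,
the per-SNP case-control signal *dilutes* as $i$ grows:

$$P(\text{case} \mid G_j = g) - P(\text{case}) =
  (1 - P(D_U))^{i-1}\,\bigl(P(D_U \mid g) - P(D_U)\bigr) \propto 1/i,$$

so the per-SNP trend noncentrality scales as $1/i^2$ and even the *summed*
noncentrality over all causal SNPs scales as $1/i$. Under this model,
estimated power therefore **decreases** in the number of generative causal
SNPs: the regression of power on design parameters yields a *negative*
per-causal-SNP coefficient, and the cancellation ratio
(gain per causal SNP / loss per non-causal SNP) is negative. This is a
mathematical property of any "OR of unique causes with fixed total
prevalence" architecture, not a Monte Carlo artefact; the package's
analysis scripts print it as such. Power *does* increase when causal SNPs
are added to the *analysed set* while the generating architecture is held
fixed — the realistic-region experiment below shows exactly that bump.
Reported cancellation ratios elsewhere in the literature that are positive
arise from architectures in which each causal SNP retains its full
marginal effect regardless of how many causal SNPs exist (e.g. a joint
liability or logistic risk model); with this package's generator those two
readings can be compared simply by varying which SNPs enter the analysis.

## Genotype generators

All generators work at the allele (haplotype-layer) level and return
genotypes as the sum of two independent layers, which preserves
Hardy-Weinberg equilibrium at every site and makes genotype-level
correlation equal allele-level correlation:

* **independent** — every SNP is Binomial(2, MAF);
* **exchangeable block** — a conditional-linear-family construction for
  correlated Bernoulli vectors gives every pair in the block correlation
  $r$ exactly (feasible for any $r \in [0,1)$ at equal marginals);
* **causal-anchored block** — a one-factor construction correlates each
  tag SNP $r$ with its causal anchor, which gives tags the minimum
  achievable mutual correlation $r^2$ (0.25 at $r=0.5$, 0.81 at $r=0.9$);
* **haplotype pool** — individuals are sums of two haplotypes drawn
  i.i.d. from a frequency-weighted pool, reproducing arbitrary local LD.

Correlation targets $(p_1, p_2, r)$ are screened against the Fréchet
bounds before simulation and infeasible requests are rejected, never
clipped.

### The synthetic realistic region

`make_realistic_fixture()` builds a synthetic stand-in for a phased ~900 kb
region: 80 common SNPs, a central ~400 kb gene with 33 intragenic SNPs, 23
and 24 intergenic SNPs on the flanks, and 6 causal SNPs (4 intragenic, 2
intergenic — one per side, within 25 kb of a gene boundary so that small
windows capture them). Haplotypes follow a first-order Markov chain along
the SNPs with high adjacent-allele correlation inside designated blocks —
including one moderate-strong block that crosses the upper gene boundary —
and weak background correlation elsewhere. Implied allele frequencies are
clamped into [0.06, 0.50]. The fixture reproduces the *composition* of a
real region (intragenic/intergenic/causal counts, a boundary-crossing
block, common-variant MAF spectrum), not any particular region's
per-window SNP counts, and its block layout is a design choice frozen in
the package: conclusions about specific real genes require a pool built
from real phased data, which `read_haplotype_pool()` accepts in a plain
text format.

## The five set tests

For each case-control sample the package computes per-SNP Cochran-Armitage
trend tests (score form, so the statistic is $n\,\mathrm{cor}(G,D)^2$) and
the sample LD matrix, then:

* **GATES** — extended Simes: $P = \min_j M_e\,p_{(j)}/M_e(j)$ with the
  effective number of tests $M_e = M - \sum_{\lambda_k > 1}(\lambda_k - 1)$
  from the eigenvalues of the p-value correlation matrix. The p-value
  correlation is approximated from genotype correlation by a sixth-order
  polynomial (an $r^2$ fallback is available).
* **VEGAS-SUM / VEGAS-MAX** — the sum or max of the per-SNP trend
  chi-squares, referred to a Monte Carlo null: standard normal vectors are
  rotated by the Cholesky factor of the LD matrix and squared. The
  p-value is $(1 + \#\{\text{null} \ge \text{obs}\})/(1 + n_{sim})$
  (non-strict exceedance, never zero); default $n_{sim} = 1000$.
* **LR** — additive logistic regression on all SNPs, likelihood-ratio
  test against the intercept-only model.
* **LR-PC** — logistic regression on the minimal set of leading principal
  components of the *standardised* genotype matrix explaining at least 80%
  of the variability (correlation-matrix PCA, matching the "fraction of
  genotype correlation" reading of the threshold).

Monomorphic SNPs are dropped from every set test; an empty set yields
p = 1. Rank-deficient logistic designs fall back from the fast IRLS path
to `glm.fit`, which drops aliased columns; non-convergent fits are counted
as failed replicates and excluded from the power denominator.

## Power engine and grids

One replicate of a setting: simulate a population at the causal SNPs,
assign disease, sample `n_total/2` cases and controls, generate the
non-causal SNPs for the sampled individuals (exactly
distribution-preserving, because non-causal genotypes are conditionally
independent of disease given the causal genotypes — for anchored blocks
the tag layers are drawn conditional on the sampled causal allele layers),
and apply each test at level $\alpha$. Defaults:

* $\alpha = 0.05$ per gene (exposed everywhere; the choice matters only as
  a monotone rescaling of the power surface);
* 500 replicates per setting for a full study; the analysis scripts and
  acceptance checks run 100 to keep a desk-scale run in minutes
  (Monte Carlo SE at power 0.5 is then 0.05);
* population size $\max(10 \times n_{total},\ $ enough to expect
  $1.5\times$ the cases needed$)$, regenerated with a doubled multiplier
  on a shortfall. At ~10% prevalence a 10-fold population yields about
  twice the cases needed while keeping the population draw from dominating
  the runtime; a fresh population is drawn every replicate.

Every random draw derives from a base seed via a 31-bit hash of
(setting id, replicate, purpose), with separate streams for genotypes,
disease, sampling, non-causal generation and the VEGAS null — so disabling
one method never perturbs another's results, and grids parallelise
deterministically.

Three grid constructors reproduce the factorial designs: `build_nold_grid`
(32 causal combinations × 9 non-causal options = 288 settings, no LD),
`build_causal_ld_grid` (96 settings of causal-anchored blocks; 192 with
tag-SNP-only duplicates), and `build_noncausal_ld_grid` (non-causal SNPs
in one exchangeable block at $r$ = 0.5 or 0.9, or — for counts ≥ 4 —
split evenly into two blocks at high/high, low/low or high/low LD; the
two-block configurations are undefined for a 2-SNP count, and the
constructor documents and asserts its enumeration of 1088 settings).

## Summarising power

`fit_power_regression` fits main-effects OLS of estimated power on the
numerically-coded design parameters (relative risk 1.25/2, counts as
integers, MAFs 0.05/0.30, $n$ 2000/4000; LD level and block count where
present). Settings with no non-causal SNPs have an undefined non-causal
MAF; they are midpoint-coded at the mean of the observed levels (0.175),
which keeps that column orthogonal to the non-causal count. Power is
modelled untransformed, cancellation ratios are computed from unrounded
coefficients, and a non-positive loss (possible under Monte Carlo noise)
makes the ratio `NA` with a message instead of an error.

## SNP-to-gene assignment

`select_by_window` takes SNPs within $w$ kb of the gene boundaries
(1-based inclusive coordinates, inclusive boundaries);
`select_by_ld` additionally requires an intergenic SNP to have $r^2$
*strictly* above the threshold (default 0.7) with at least one intragenic
SNP. LD chaining through already-selected intergenic SNPs is deliberately
not implemented: the rule compares each candidate directly against the
intragenic set, the reading that keeps the selection independent of
iteration order. Single-gene context only — windows are never truncated by
neighbouring genes.

## Numerical choices

* Trend test in the score (null-variance) form; two-sided via the 1-df
  chi-square tail; monomorphic columns score 0 with p = 1.
* VEGAS Cholesky failures (e.g. duplicated SNPs) escalate diagonal jitter
  from $10^{-8}$ to $10^{-4}$ before giving up.
* The IRLS logistic solver matches `glm` deviances to ~$10^{-6}$ (asserted
  in tests) and defers to `glm.fit` whenever its normal equations are
  singular.
* Power tables render numeric columns with 17 significant digits so disk
  round-trips are bit-identical.

## What the simulations do and do not show

The generators emulate HWE genotypes with block-structured LD and a
case-control phenotype with per-SNP additive relative risks. They do not
model covariates, population stratification, genotyping error, missing
data, quantitative traits, rare variants, or selection of SNP panels by
array design. Passing tests therefore support conclusions about the
*relative* behaviour of the five set tests under controlled LD and
signal-to-noise compositions — not calibrated absolute power for any real
study, and not the behaviour of the tests under model misspecifications
the generator cannot produce. The problem sizes used by the packaged
analyses (100 replicates per setting, populations of $10\times$ the panel)
are the package's own desk-scale choices; rerunning with 500 replicates
reproduces the full-study precision at proportional cost.
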