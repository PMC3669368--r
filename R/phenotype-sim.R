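#' Conditional disease probabilities at one causal SNP
#'
#' Under an additive relative-risk model with heterozygote relative risk
#' `gamma` (and `2*gamma - 1` for the risk homozygote), the baseline risk is
#' chosen so that the HWE-weighted mean risk equals the SNP's unique disease
#' prevalence `p_du`:
#' `P(D|G=0) = p_du / ((1-m)^2 + 2*gamma*m*(1-m) + (2*gamma-1)*m^2)`,
#' `P(D|G=1) = gamma * P(D|G=0)`, `P(D|G=2) = (2*gamma-1) * P(D|G=0)`.
#'
#' @param p_du per-SNP unique disease prevalence in `(0, 1)`.
#' @param m minor (risk) allele frequency in `(0, 0.5]`.
#' @param gamma heterozygote relative risk, `>= 1`.
#' @return Named numeric vector `c(g0, g1, g2)` of `P(D | G = 0, 1, 2)`.
#' @export
conditional_disease_probs <- function(p_du, m, gamma) {
  if (p_du <= 0 || p_du >= 1) stop("p_du must lie in (0, 1)")
  if (m <= 0 || m > 0.5) stop("m must lie in (0, 0.5]")
  if (gamma < 1) stop("gamma must be >= 1")
  denom <- (1 - m)^2 + 2 * gamma * m * (1 - m) + (2 * gamma - 1) * m^2
  p0 <- p_du / denom
  probs <- c(g0 = p0, g1 = gamma * p0, g2 = (2 * gamma - 1) * p0)
  if (any(probs > 1))
    stop(sprintf(paste0("infeasible disease model: p_du = %.4g, m = %.4g, ",
                        "gamma = %.4g gives P(D|G=2) = %.4g > 1"),
                 p_du, m, gamma, probs["g2"]))
  probs
}

#' Disease model for a set of causal SNPs
#'
#' Each of the `n_causal` causal SNPs carries a unique disease prevalence
#' `p_du = 0.10 / n_causal` (so overall prevalence
#' `1 - (1 - p_du)^n_causal` is approximately 10%) and the same heterozygote
#' relative risk `gamma`.
#'
#' @param n_causal number of causal SNPs.
#' @param gamma heterozygote relative risk (applied per causal SNP).
#' @param causal_mafs MAFs of the causal SNPs (recycled to length
#'   `n_causal`).
#' @param causal_indices columns of the genotype matrix holding the causal
#'   SNPs; defaults to the first `n_causal`.
#' @param p_du per-SNP unique prevalence; defaults to `0.10 / n_causal`.
#' @return An object of class `disease_model`.
#' @export
disease_model <- function(n_causal, gamma, causal_mafs,
                          causal_indices = seq_len(n_causal),
                          p_du = 0.10 / n_causal) {
  if (n_causal < 1) stop("n_causal must be >= 1")
  if (length(causal_indices) != n_causal)
    stop("causal_indices must have length n_causal")
  causal_mafs <- rep_len(causal_mafs, n_causal)
  probs <- vapply(causal_mafs,
                  function(m) conditional_disease_probs(p_du, m, gamma),
                  numeric(3))
  structure(list(n_causal = as.integer(n_causal), gamma = gamma,
                 p_du = p_du, causal_indices = as.integer(causal_indices),
                 causal_mafs = causal_mafs, probs = probs),
            class = "disease_model")
}

#' Simulate disease status from causal genotypes
#'
#' For each individual, one Bernoulli draw per causal SNP with probability
#' `P(D_U | G)` at that SNP; the individual is diseased if any draw comes up
#' positive. Draws are consumed individual-major, causal-SNP-minor so the
#' output is reproducible under `seed`.
#'
#' @param genotypes a [genotype_matrix] (or plain 0/1/2 matrix).
#' @param model a [disease_model].
#' @param seed integer seed; `NULL` continues the current RNG stream.
#' @return Integer vector of 0/1 disease status, one per individual.
#' @export
simulate_disease_status <- function(genotypes, model, seed = NULL) {
  G <- .as_genotype_values(genotypes)
  if (any(model$causal_indices > ncol(G)))
    stop("causal_indices outside the genotype matrix columns")
  if (!is.null(seed)) set.seed(seed)
  cpp_disease_status(G[, model$causal_indices, drop = FALSE], model$probs)
}

#' Sample a case-control panel from a simulated population
#'
#' Uniform sampling without replacement within each status stratum; the
#' output is ordered cases first, then controls.
#'
#' @param genotypes a [genotype_matrix] for the population.
#' @param status 0/1 disease status vector for the population.
#' @param n_cases,n_controls panel sizes.
#' @param seed integer seed; `NULL` continues the current RNG stream.
#' @return List with the sampled `genotypes` ([genotype_matrix]) and aligned
#'   `status` vector.
#' @export
sample_case_control <- function(genotypes, status, n_cases, n_controls,
                                seed = NULL) {
  G <- .as_genotype_values(genotypes)
  if (length(status) != nrow(G))
    stop("status must have one entry per individual")
  cases <- which(status == 1L)
  controls <- which(status == 0L)
  if (length(cases) < n_cases || length(controls) < n_controls)
    stop(sprintf(paste0("population has %d cases / %d controls but %d / %d ",
                        "were requested; simulate a larger population ",
                        "(increase the population multiplier)"),
                 length(cases), length(controls), n_cases, n_controls))
  if (!is.null(seed)) set.seed(seed)
  idx <- c(cases[sample.int(length(cases), n_cases)],
           controls[sample.int(length(controls), n_controls)])
  g <- genotype_matrix(G[idx, , drop = FALSE],
                       mafs = if (inherits(genotypes, "genotype_matrix"))
                         genotypes$mafs else NULL)
  list(genotypes = g,
       status = rep(c(1L, 0L), c(n_cases, n_controls)))
}
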