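#' Regress estimated power on simulation design parameters
#'
#' Ordinary least squares of estimated power on the design parameters as
#' numeric main effects (relative risk as 1.25/2, SNP counts as integers,
#' MAFs as 0.05/0.30, total n as 2000/4000; in LD grids `ld_high` is the
#' fraction of high-LD blocks and `n_blocks` the block count), one row per
#' setting for the chosen method. Settings with no non-causal SNPs have an
#' undefined non-causal MAF; these are midpoint-coded at the mean of the
#' observed MAF levels, which keeps the column orthogonal to the non-causal
#' count.
#'
#' @param power_table power table from [run_grid()] / [run_setting()].
#' @param method one of [SET_TEST_METHODS].
#' @param parameters design columns to include as main effects.
#' @return An object of class `power_regression`: `method`, `coefficients`
#'   (term/estimate/std_error), `r_squared`, `loss_per_noncausal` (negated
#'   `n_noncausal` slope), `gain_per_causal` (`n_causal` slope) and
#'   `cancellation_ratio`.
#' @export
fit_power_regression <- function(power_table, method,
                                 parameters = c("rr", "n_causal",
                                                "n_noncausal", "maf_causal",
                                                "maf_noncausal", "n_total")) {
  method <- match.arg(method, SET_TEST_METHODS)
  df <- power_table[power_table$method == method, , drop = FALSE]
  if (nrow(df) == 0) stop("no rows for method ", method)
  missing_cols <- setdiff(parameters, names(df))
  if (length(missing_cols))
    stop("power table lacks parameter columns: ",
         paste(missing_cols, collapse = ", "))
  if ("maf_noncausal" %in% parameters &&
      anyNA(df$maf_noncausal)) {
    observed <- unique(df$maf_noncausal[!is.na(df$maf_noncausal)])
    df$maf_noncausal[is.na(df$maf_noncausal)] <- mean(observed)
  }
  for (p in parameters)
    if (length(unique(df[[p]])) < 2)
      stop("parameter ", p, " has fewer than 2 distinct values")
  fml <- stats::reformulate(parameters, response = "power")
  fit <- lm(fml, data = df)
  cf <- coef(fit)
  if (anyNA(cf))
    stop("rank-deficient design; collinear columns: ",
         paste(names(cf)[is.na(cf)], collapse = ", "))
  sm <- suppressWarnings(summary(fit))
  tss <- sum((df$power - mean(df$power))^2)
  r2 <- if (tss < 1e-24) 0 else 1 - sum(stats::residuals(fit)^2) / tss
  loss <- unname(-cf["n_noncausal"])
  gain <- unname(cf["n_causal"])
  structure(list(method = method,
                 coefficients = data.frame(
                   term = names(cf), estimate = unname(cf),
                   std_error = unname(sm$coefficients[, "Std. Error"]),
                   row.names = NULL),
                 r_squared = r2,
                 loss_per_noncausal = if ("n_noncausal" %in% parameters)
                   loss else NA_real_,
                 gain_per_causal = if ("n_causal" %in% parameters)
                   gain else NA_real_),
            class = "power_regression")
}

#' @export
print.power_regression <- function(x, ...) {
  cat(sprintf("power regression for %s: r^2 = %.3f\n",
              SET_TEST_LABELS[x$method], x$r_squared))
  print(x$coefficients)
  invisible(x)
}

#' Non-causal SNPs cancelling one causal SNP
#'
#' Ratio of the per-causal-SNP power gain to the per-non-causal-SNP power
#' loss: a rough estimate of how many non-causal SNPs cancel out the power
#' contributed by a single causal variant. Computed from the unrounded
#' regression coefficients. A non-positive loss (possible under Monte Carlo
#' noise on small grids) yields `NA` with a message rather than an error.
#'
#' @param summary a `power_regression` from [fit_power_regression()].
#' @return Numeric ratio, or `NA` when the loss is non-positive.
#' @export
cancellation_ratio <- function(summary) {
  loss <- summary$loss_per_noncausal
  gain <- summary$gain_per_causal
  if (is.na(loss) || loss <= 0) {
    message("non-positive estimated loss per non-causal SNP; ",
            "cancellation ratio undefined")
    return(NA_real_)
  }
  gain / loss
}

#' Mean per-non-causal-SNP power loss across methods
#'
#' @param summaries list of `power_regression` objects.
#' @return Mean of `loss_per_noncausal` across the summaries.
#' @export
average_noncausal_loss <- function(summaries) {
  if (length(summaries) < 1) stop("need at least one summary")
  mean(vapply(summaries, function(s) s$loss_per_noncausal, 0))
}

#' Per-method loss / gain / cancellation summary of a power table
#'
#' Fits [fit_power_regression()] for each method present and tabulates the
#' per-non-causal-SNP loss, per-causal-SNP gain, cancellation ratio and
#' regression r-squared.
#'
#' @param power_table power table from [run_grid()].
#' @param parameters design columns passed to [fit_power_regression()].
#' @return data.frame with one row per method.
#' @export
summarize_power_table <- function(power_table,
                                  parameters = c("rr", "n_causal",
                                                 "n_noncausal", "maf_causal",
                                                 "maf_noncausal",
                                                 "n_total")) {
  methods <- intersect(SET_TEST_METHODS, unique(power_table$method))
  rows <- lapply(methods, function(m) {
    reg <- fit_power_regression(power_table, m, parameters)
    data.frame(method = SET_TEST_LABELS[m],
               loss_per_noncausal = reg$loss_per_noncausal,
               gain_per_causal = reg$gain_per_causal,
               cancellation_ratio = suppressMessages(cancellation_ratio(reg)),
               r_squared = reg$r_squared, row.names = NULL)
  })
  do.call(rbind, rows)
}
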