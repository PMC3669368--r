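#' Names of the five gene-based set tests
#'
#' Internal method identifiers, in the order used throughout the package:
#' `gates`, `vegas_sum`, `vegas_max`, `lr`, `lr_pc`.
#' @export
SET_TEST_METHODS <- c("gates", "vegas_sum", "vegas_max", "lr", "lr_pc")

#' Display labels for the five set tests
#' @export
SET_TEST_LABELS <- c(gates = "GATES", vegas_sum = "VEGAS-SUM",
                     vegas_max = "VEGAS-MAX", lr = "LR", lr_pc = "LR-PC")

## Deterministic 31-bit string hash used to split one base seed into
## independent per-(setting, replicate, purpose) streams.  Keeping every
## derived seed below 2^31 means it is always a valid R integer seed.
derive_seed <- function(...) {
  key <- paste(unlist(list(...)), collapse = "/")
  h <- 17
  for (b in utf8ToInt(key)) h <- (h * 31 + b) %% 2147483647
  as.integer(h)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
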