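#' Selection rule for assigning intergenic SNPs to a gene
#'
#' @param kind `"window"` (plain symmetric window) or `"ld_window"` (window
#'   plus an LD threshold against intragenic SNPs).
#' @param window_kb window size in kb (>= 0), applied to both ends.
#' @param r2_threshold squared-correlation cutoff in `(0, 1)`; SNP inclusion
#'   requires `r^2` strictly greater than the threshold (`ld_window` only).
#' @return An object of class `selection_rule`.
#' @export
selection_rule <- function(kind = c("window", "ld_window"), window_kb,
                           r2_threshold = 0.7) {
  kind <- match.arg(kind)
  if (window_kb < 0) stop("window_kb must be >= 0")
  if (kind == "ld_window" && (r2_threshold <= 0 || r2_threshold >= 1))
    stop("r2_threshold must lie in (0, 1)")
  structure(list(kind = kind, window_kb = window_kb,
                 r2_threshold = r2_threshold),
            class = "selection_rule")
}

.gene_interval <- function(gene) {
  gene <- unlist(gene, use.names = FALSE)
  if (length(gene) != 2 || gene[1] > gene[2])
    stop("gene must be (start, stop) with start <= stop")
  gene
}

#' Window-based SNP selection
#'
#' Selects SNPs with position in `[start - 1000 * window_kb,
#' stop + 1000 * window_kb]` (1-based inclusive coordinates, inclusive
#' boundaries). A window of 0 selects exactly the intragenic SNPs.
#'
#' @param positions base-pair positions of the SNPs.
#' @param gene length-2 `(start, stop)` interval in bp.
#' @param window_kb window size in kb.
#' @return Sorted integer vector of selected SNP indices.
#' @export
select_by_window <- function(positions, gene, window_kb) {
  gene <- .gene_interval(gene)
  if (window_kb < 0) stop("window_kb must be >= 0")
  which(positions >= gene[1] - 1000 * window_kb &
        positions <= gene[2] + 1000 * window_kb)
}

#' Window-plus-LD-threshold SNP selection
#'
#' Selects all intragenic SNPs, plus intergenic SNPs inside the window whose
#' maximum squared correlation against any intragenic SNP strictly exceeds
#' the rule's threshold.
#'
#' @param positions base-pair positions of the SNPs.
#' @param ld LD matrix aligned with `positions`; Pearson correlation `r` by
#'   default, or squared correlation when `ld_type = "r2"`.
#' @param gene length-2 `(start, stop)` interval in bp.
#' @param rule a [selection_rule] (its `window_kb` and `r2_threshold` are
#'   used).
#' @param ld_type `"r"` (default) or `"r2"`.
#' @return Sorted integer vector of selected SNP indices.
#' @export
select_by_ld <- function(positions, ld, gene, rule, ld_type = c("r", "r2")) {
  ld_type <- match.arg(ld_type)
  gene <- .gene_interval(gene)
  ld <- as.matrix(ld)
  if (nrow(ld) != length(positions) || ncol(ld) != length(positions))
    stop("ld dimensions do not match positions")
  r2 <- if (ld_type == "r") ld^2 else ld
  intra <- which(positions >= gene[1] & positions <= gene[2])
  windowed <- select_by_window(positions, gene, rule$window_kb)
  candidates <- setdiff(windowed, intra)
  if (length(intra) == 0) return(integer(0))
  hit <- candidates[vapply(candidates, function(j)
    max(r2[j, intra]) > rule$r2_threshold, logical(1))]
  sort(c(intra, hit))
}
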