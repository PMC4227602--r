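TRANSITIONS <- c("A>G", "G>A", "C>T", "T>C")

#' Variant-call QC summary: Ti/Tv ratio and heterozygosity
#'
#' The transition/transversion ratio over SNVs is a standard sanity check on
#' a call set (genome-wide values near 2 are expected for human whole-genome
#' data). When per-sample genotypes are supplied, the fraction of
#' heterozygous calls among called genotypes is reported too.
#'
#' @param variants Tibble with `ref` and `alt` columns; non-SNV rows are
#'   ignored for Ti/Tv.
#' @param genotypes Optional long tibble with a `dosage` column (0/1/2/NA).
#' @return One-row tibble: `n_snv`, `n_transitions`, `n_transversions`,
#'   `titv_ratio` (`NA` when there are no transversions), `het_fraction`
#'   (`NA` without genotypes).
#' @export
#' @examples
#' qc_summary(tibble::tibble(ref = c("A", "C", "A", "G"),
#'                           alt = c("G", "T", "C", "T")))
qc_summary <- function(variants, genotypes = NULL) {
  variants <- as_tibble(variants)
  snv <- filter(variants, nchar(.data$ref) == 1, nchar(.data$alt) == 1,
                .data$ref != .data$alt)
  if (nrow(snv) == 0) abort("no SNVs in input")
  change <- paste0(toupper(snv$ref), ">", toupper(snv$alt))
  n_ti <- sum(change %in% TRANSITIONS)
  n_tv <- nrow(snv) - n_ti
  het <- NA_real_
  if (!is.null(genotypes)) {
    called <- genotypes$dosage[!is.na(genotypes$dosage)]
    het <- mean(called == 1)
  }
  tibble(n_snv = nrow(snv), n_transitions = n_ti, n_transversions = n_tv,
         titv_ratio = if (n_tv > 0) n_ti / n_tv else NA_real_,
         het_fraction = het)
}
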