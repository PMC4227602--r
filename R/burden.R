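#' Per-sample carrier status across a gene's variant set
#'
#' A sample is a carrier when it carries at least one alternate allele at at
#' least one called locus; a non-carrier must be homozygous reference at
#' every called locus. Samples with no called genotype at any locus are
#' excluded (missingness alone can never create a carrier).
#'
#' @param genotypes Tibble with one row per (sample, variant): `sample_id`,
#'   `id` (variant), `gene`, and `dosage` in `{0, 1, 2, NA}` (alternate
#'   allele count; `NA` = missing call).
#' @return Tibble with one row per (sample, gene): `sample_id`, `gene`,
#'   `carrier` (logical), `n_called`.
#' @export
carrier_status <- function(genotypes) {
  genotypes |>
    group_by(.data$sample_id, .data$gene) |>
    summarise(
      carrier = any(.data$dosage > 0, na.rm = TRUE),
      n_called = sum(!is.na(.data$dosage)),
      .groups = "drop"
    ) |>
    filter(.data$n_called > 0)
}

#' Gene-level carrier burden test
#'
#' Pearson chi-square (1 df, no continuity correction by default) comparing
#' the numbers of case and control individuals carrying one or more variant
#' alleles against those homozygous reference at all tested loci.
#'
#' @param case_carriers,case_noncarriers,control_carriers,control_noncarriers
#'   Counts of the 2x2 carrier table.
#' @param correction `"none"` (default) or `"yates"`.
#' @return Tibble with `statistic`, `df`, `p`.
#' @export
#' @examples
#' burden_chi2(30, 70, 15, 85)
burden_chi2 <- function(case_carriers, case_noncarriers,
                        control_carriers, control_noncarriers,
                        correction = c("none", "yates")) {
  correction <- match.arg(correction)
  tab <- matrix(c(case_carriers, case_noncarriers,
                  control_carriers, control_noncarriers),
                nrow = 2, byrow = TRUE)
  if (any(tab < 0)) abort("negative count")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    abort("zero margin: the chi-square test is undefined; use an exact test")
  }
  ct <- suppressWarnings(chisq.test(tab, correct = correction == "yates"))
  tibble(statistic = unname(ct$statistic), df = 1, p = unname(ct$p.value))
}

#' Carrier burden test per gene from per-sample genotypes
#'
#' Classifies each sample's carrier status per gene with [carrier_status()],
#' tabulates carriers vs non-carriers in cases and controls, and applies
#' [burden_chi2()] gene by gene.
#'
#' @param genotypes As in [carrier_status()].
#' @param phenotypes Tibble with `sample_id` and `stratum` (`"case"` or
#'   `"control"`).
#' @param correction Passed to [burden_chi2()].
#' @return One row per gene: the four carrier-table counts, `statistic`,
#'   `df`, `p`.
#' @export
burden_test <- function(genotypes, phenotypes,
                        correction = c("none", "yates")) {
  correction <- match.arg(correction)
  status <- carrier_status(genotypes) |>
    left_join(phenotypes, by = "sample_id")
  if (any(is.na(status$stratum))) abort("sample missing from phenotype table")
  status |>
    group_by(.data$gene) |>
    summarise(
      case_carriers = sum(.data$carrier & .data$stratum == "case"),
      case_noncarriers = sum(!.data$carrier & .data$stratum == "case"),
      control_carriers = sum(.data$carrier & .data$stratum == "control"),
      control_noncarriers = sum(!.data$carrier & .data$stratum == "control"),
      .groups = "drop"
    ) |>
    mutate(test = pmap(list(.data$case_carriers, .data$case_noncarriers,
                            .data$control_carriers, .data$control_noncarriers),
                       burden_chi2, correction = correction)) |>
    tidyr::unnest("test")
}
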