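#' Minor-allele frequency from genotype counts
#'
#' Computed from the genotype-count sums themselves, `(2 hom_alt + het) /
#' (2 n)`; when the alternate allele is the major one the frequency is
#' folded to the minor allele and flagged.
#'
#' @param hom_alt,het,hom_ref Genotype counts (vectorised).
#' @return Tibble with `maf`, `alt_freq` and `folded` (TRUE when the
#'   alternate allele was the major allele).
#' @export
#' @examples
#' maf(3, 88, 1380)   # 94/2942 = 0.032
maf <- function(hom_alt, het, hom_ref) {
  n <- hom_alt + het + hom_ref
  if (any(n <= 0)) abort("genotype counts sum to zero")
  if (any(c(hom_alt, het, hom_ref) < 0)) abort("negative genotype count")
  alt_freq <- (2 * hom_alt + het) / (2 * n)
  tibble(maf = pmin(alt_freq, 1 - alt_freq), alt_freq = alt_freq,
         folded = alt_freq > 0.5)
}

# Levene conditional distribution of heterozygote counts given n genotypes
# and n_minor minor alleles; log-scale for stability. Returns the
# probability of every feasible het count (same parity as n_minor).
levene_het_probs <- function(n, n_minor) {
  n_major <- 2 * n - n_minor
  hets <- seq(n_minor %% 2, min(n_minor, n_major), by = 2)
  logp <- lfactorial(n) -
    lfactorial((n_minor - hets) / 2) - lfactorial(hets) -
    lfactorial((n_major - hets) / 2) +
    hets * log(2) +
    lfactorial(n_minor) + lfactorial(n_major) - lfactorial(2 * n)
  p <- exp(logp - max(logp))
  tibble(het = hets, prob = p / sum(p))
}

#' Exact test of Hardy-Weinberg equilibrium
#'
#' Conditional exact test on the Levene distribution: given the sample size
#' and the minor-allele count, the p-value is the summed probability of all
#' heterozygote counts whose point probability does not exceed that of the
#' observed count. No mid-p or continuity adjustments.
#'
#' @param hom_alt,het,hom_ref Genotype counts (vectorised).
#' @return Numeric vector of p-values; monomorphic samples give 1.
#' @export
#' @examples
#' hwe_exact(3, 88, 1380)
hwe_exact <- function(hom_alt, het, hom_ref) {
  pmap_dbl(list(hom_alt, het, hom_ref), function(aa, ab, bb) {
    n <- aa + ab + bb
    if (n <= 0) abort("genotype counts sum to zero")
    n_alt <- 2 * aa + ab
    n_minor <- min(n_alt, 2 * n - n_alt)
    if (n_minor == 0) return(1)
    dist <- levene_het_probs(n, n_minor)
    p_obs <- dist$prob[dist$het == ab]
    if (length(p_obs) == 0) abort("heterozygote count incompatible with allele count")
    # 1 + 1e-9 guard against ties lost to floating point
    min(1, sum(dist$prob[dist$prob <= p_obs * (1 + 1e-9)]))
  })
}

#' Allelic Fisher exact test for case-control association
#'
#' Exact hypergeometric test on the 2x2 table of alternate vs reference
#' allele counts in cases vs controls. The default tail is one-sided in the
#' direction of case enrichment, the configuration under which the published
#' headline p-values of this workflow's study design are reproduced from
#' genotype counts.
#'
#' @param case,control One-row data frames (or lists) with `hom_alt`, `het`,
#'   `hom_ref`.
#' @param alternative `"enrichment"` (one-sided toward higher case alternate
#'   frequency) or `"two.sided"`.
#' @return The p-value.
#' @export
#' @examples
#' allelic_fisher(list(hom_alt = 3, het = 88, hom_ref = 1380),
#'                list(hom_alt = 0, het = 44, hom_ref = 985))
allelic_fisher <- function(case, control,
                           alternative = c("enrichment", "two.sided")) {
  alternative <- match.arg(alternative)
  ca <- 2 * case$hom_alt + case$het
  cn <- 2 * (case$hom_alt + case$het + case$hom_ref)
  ka <- 2 * control$hom_alt + control$het
  kn <- 2 * (control$hom_alt + control$het + control$hom_ref)
  if (cn <= 0 || kn <= 0) abort("empty stratum")
  tab <- matrix(c(ca, cn - ca, ka, kn - ka), nrow = 2, byrow = TRUE)
  fisher.test(tab, alternative =
                if (alternative == "enrichment") "greater" else "two.sided"
              )$p.value
}

#' Expected homozygote count under Hardy-Weinberg equilibrium
#'
#' `n q^2` with `q` the alternate-allele frequency estimated from the
#' counts; used to judge whether an observed excess of rare-allele
#' homozygotes is remarkable.
#'
#' @inheritParams maf
#' @return Numeric vector of expected alternate-homozygote counts.
#' @export
expected_homozygotes <- function(hom_alt, het, hom_ref) {
  n <- hom_alt + het + hom_ref
  q <- maf(hom_alt, het, hom_ref)$alt_freq
  n * q^2
}

#' Case-control association table
#'
#' Builds the per-variant results table of the workflow: genotype counts,
#' minor-allele frequencies, exact Hardy-Weinberg p-values in each stratum,
#' and the allelic Fisher exact p-value. One row per variant, ordered as
#' given; variants missing a stratum are returned flagged incomplete with
#' `NA` statistics.
#'
#' @param counts Tibble with one row per (variant, stratum): columns `id`,
#'   `stratum` (`"case"` or `"control"`), `hom_alt`, `het`, `hom_ref`.
#' @param alternative Passed to [allelic_fisher()].
#'
#' @return Tibble with one row per variant: counts per stratum, `case_maf`,
#'   `control_maf`, `hwe_p_cases`, `hwe_p_controls`, `allelic_p`,
#'   `complete`.
#' @export
associate <- function(counts, alternative = c("enrichment", "two.sided")) {
  alternative <- match.arg(alternative)
  counts <- as_tibble(counts)
  stopifnot(all(counts$stratum %in% c("case", "control")))
  ids <- unique(counts$id)
  map(ids, function(v) {
    ca <- filter(counts, .data$id == v, .data$stratum == "case")
    co <- filter(counts, .data$id == v, .data$stratum == "control")
    complete <- nrow(ca) == 1 && nrow(co) == 1
    if (!complete) {
      return(tibble(id = v, case_hom_alt = NA_real_, case_het = NA_real_,
                    case_hom_ref = NA_real_, control_hom_alt = NA_real_,
                    control_het = NA_real_, control_hom_ref = NA_real_,
                    case_n = NA_real_, control_n = NA_real_,
                    case_maf = NA_real_, control_maf = NA_real_,
                    hwe_p_cases = NA_real_, hwe_p_controls = NA_real_,
                    allelic_p = NA_real_, complete = FALSE))
    }
    tibble(
      id = v,
      case_hom_alt = ca$hom_alt, case_het = ca$het, case_hom_ref = ca$hom_ref,
      control_hom_alt = co$hom_alt, control_het = co$het,
      control_hom_ref = co$hom_ref,
      case_n = ca$hom_alt + ca$het + ca$hom_ref,
      control_n = co$hom_alt + co$het + co$hom_ref,
      case_maf = maf(ca$hom_alt, ca$het, ca$hom_ref)$maf,
      control_maf = maf(co$hom_alt, co$het, co$hom_ref)$maf,
      hwe_p_cases = hwe_exact(ca$hom_alt, ca$het, ca$hom_ref),
      hwe_p_controls = hwe_exact(co$hom_alt, co$het, co$hom_ref),
      allelic_p = allelic_fisher(ca, co, alternative = alternative),
      complete = TRUE
    )
  }) |> list_rbind()
}
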