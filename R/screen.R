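#' Reference-panel enrichment test
#'
#' Fisher's exact test on the 2x2 allele table (cohort alt/ref vs panel
#' alt/ref). The screening rule of the workflow looks for variants whose
#' alternate allele is *more* common in the discovery cohort than in the
#' reference panel, so the default tail is one-sided toward cohort
#' enrichment; a two-sided test is available.
#'
#' @param cohort_alt,cohort_total Alternate-allele count and total allele
#'   count in the discovery cohort.
#' @param panel_alt,panel_total Alternate-allele count and total allele count
#'   in the reference panel.
#' @param alternative `"enrichment"` (one-sided, default) or `"two.sided"`.
#'
#' @return A tibble with `p` and `mlp` (`-log10(p)`), one row per input
#'   element (the counts are vectorised).
#' @export
#' @examples
#' enrichment_test(2, 198, 0, 744)
enrichment_test <- function(cohort_alt, cohort_total, panel_alt, panel_total,
                            alternative = c("enrichment", "two.sided")) {
  alternative <- match.arg(alternative)
  if (any(cohort_total <= 0) || any(panel_total <= 0)) {
    abort("allele totals must be positive")
  }
  if (any(cohort_alt > cohort_total) || any(panel_alt > panel_total)) {
    abort("alt count exceeds total alleles")
  }
  p <- pmap_dbl(list(cohort_alt, cohort_total, panel_alt, panel_total),
                function(a, ta, b, tb) {
    tab <- matrix(c(a, ta - a, b, tb - b), nrow = 2, byrow = TRUE)
    fisher.test(tab, alternative =
                  if (alternative == "enrichment") "greater" else "two.sided"
                )$p.value
  })
  p <- pmin(p, 1)
  tibble(p = p, mlp = -log10(p))
}

#' Poly-base (homopolymer) context flag
#'
#' True when the variant's anchor base sits inside a homopolymer run of at
#' least `min_run` identical bases in the reference. The flanking sequence
#' must be centred on the anchor base with at least `min_run` bases to each
#' side.
#'
#' @param flank Reference sequence centred on the variant's anchor base (odd
#'   length).
#' @param min_run Minimum run length to flag (default 5).
#' @return Logical flag.
#' @export
polybase_flag <- function(flank, min_run = 5) {
  flank <- toupper(flank)
  n <- nchar(flank)
  if (n %% 2 == 0) abort("flank must be centred: odd length required")
  centre <- (n + 1) %/% 2
  if (centre - 1 < min_run || n - centre < min_run) {
    abort("flank shorter than min_run on one side")
  }
  bases <- strsplit(flank, "")[[1]]
  r <- rle(bases)
  idx <- rep(seq_along(r$lengths), r$lengths)
  r$lengths[idx[centre]] >= min_run
}

#' Repeat-region insertion flag
#'
#' The exclusion rule applies to insertions only: an insertion whose anchor
#' span overlaps a repeat interval is flagged; SNVs and deletions are never
#' flagged by this rule.
#'
#' @param variants Tibble with `chrom`, `pos`, `ref`, `alt`.
#' @param repeats Tibble of repeat intervals (`chrom`, `start`, `end`).
#' @return Logical vector, one element per variant.
#' @export
repeat_insertion_flag <- function(variants, repeats) {
  variants <- variant_span(as_tibble(variants))
  is_ins <- nchar(variants$alt) > nchar(variants$ref)
  pmap_lgl(variants, function(chrom, span_start, span_end, ...) {
    any(in_span(chrom, span_start, span_end,
                repeats$chrom, repeats$start, repeats$end))
  }) & is_ins
}

#' Target-intron regulatory criteria
#'
#' A variant passes when it (1) lies inside the target interval, (2) overlaps
#' a regulatory (ENCODE-marked) element, (3) overlaps a conserved element or
#' has an evolutionary-constraint (GERP) score at or above the threshold, and
#' (4) does not overlap a repeat.
#'
#' @param variants Tibble with `chrom`, `pos`, `ref`, `alt`.
#' @param target One-row data frame (`chrom`, `start`, `end`).
#' @param encode_elements,conserved_elements,repeats Interval tibbles
#'   (`chrom`, `start`, `end`).
#' @param gerp Optional numeric vector of per-variant constraint scores
#'   (aligned with `variants`); `NA` means no score.
#' @param gerp_threshold Score at or above which a site counts as conserved
#'   (default 2).
#' @return Logical vector, one element per variant.
#' @export
intron3_criteria <- function(variants, target, encode_elements,
                             conserved_elements, repeats,
                             gerp = NULL, gerp_threshold = 2) {
  variants <- variant_span(as_tibble(variants))
  if (is.null(gerp)) gerp <- rep(NA_real_, nrow(variants))
  overlaps_track <- function(track) {
    pmap_lgl(variants[, c("chrom", "span_start", "span_end")],
             function(chrom, span_start, span_end) {
      nrow(track) > 0 && any(in_span(chrom, span_start, span_end,
                                     track$chrom, track$start, track$end))
    })
  }
  in_target <- in_span(variants$chrom, variants$span_start, variants$span_end,
                       target$chrom, target$start, target$end)
  conserved <- overlaps_track(conserved_elements) |
    (!is.na(gerp) & gerp >= gerp_threshold)
  in_target & overlaps_track(encode_elements) & conserved &
    !overlaps_track(repeats)
}

#' Screen variants against a reference panel
#'
#' Runs the full prioritisation rule: a variant passes when its alternate
#' allele is more frequent in the discovery cohort than in the reference
#' panel, the enrichment Fisher test is significant at `alpha` (strict
#' inequality), and neither exclusion flag (poly-base context,
#' repeat-region insertion) applies.
#'
#' @param variants Tibble with `id`, `chrom`, `pos`, `ref`, `alt`, and
#'   allele-count columns `cohort_alt`, `cohort_total`. Panel counts come
#'   from `panel`, matched by (`chrom`, `pos`, `ref`, `alt`); a variant
#'   missing from the panel is treated as unseen there (`panel_alt = 0` out
#'   of `2 * panel_size` alleles) and reported via a message.
#' @param panel Tibble with `chrom`, `pos`, `ref`, `alt`, `panel_alt`,
#'   `panel_total`.
#' @param repeats Repeat intervals for the insertion exclusion (may be
#'   empty).
#' @param flanks Optional named character vector of reference flanks keyed by
#'   variant `id`, for the poly-base exclusion; variants without a flank are
#'   not flagged.
#' @param panel_size Diploid panel size used for missing panel records
#'   (default 372, a European reference panel).
#' @param alpha Significance threshold (default 0.05, strict).
#' @param min_run Homopolymer run length for [polybase_flag()].
#' @param alternative Sidedness of [enrichment_test()].
#'
#' @return A tibble ordered by (`chrom`, `pos`): `id`, `chrom`, `pos`,
#'   `ref`, `alt`, `cohort_freq`, `panel_freq`, `p`, `mlp`, `enriched`,
#'   `excluded_polybase`, `excluded_repeat_insertion`, `passes`.
#' @export
run_screen <- function(variants, panel, repeats = NULL, flanks = NULL,
                       panel_size = 372, alpha = 0.05, min_run = 5,
                       alternative = c("enrichment", "two.sided")) {
  alternative <- match.arg(alternative)
  variants <- as_tibble(variants)
  res <- left_join(variants, panel,
                   by = c("chrom", "pos", "ref", "alt"))
  missing_panel <- is.na(res$panel_total)
  if (any(missing_panel)) {
    inform(paste0(sum(missing_panel), " variant(s) missing from the panel; ",
                  "treated as 0/", 2 * panel_size, " alt alleles"))
    res$panel_alt[missing_panel] <- 0
    res$panel_total[missing_panel] <- 2 * panel_size
  }
  test <- enrichment_test(res$cohort_alt, res$cohort_total,
                          res$panel_alt, res$panel_total,
                          alternative = alternative)
  res$cohort_freq <- res$cohort_alt / res$cohort_total
  res$panel_freq <- res$panel_alt / res$panel_total
  res$p <- test$p
  res$mlp <- test$mlp
  res$enriched <- res$cohort_freq > res$panel_freq
  res$excluded_polybase <- if (is.null(flanks)) {
    rep(FALSE, nrow(res))
  } else {
    map_lgl(res$id, function(id) {
      fl <- if (id %in% names(flanks)) flanks[[id]] else NA_character_
      !is.null(fl) && !is.na(fl) && polybase_flag(fl, min_run = min_run)
    })
  }
  res$excluded_repeat_insertion <- if (is.null(repeats) || nrow(repeats) == 0) {
    rep(FALSE, nrow(res))
  } else {
    repeat_insertion_flag(res, repeats)
  }
  res$passes <- res$enriched & res$p < alpha &
    !res$excluded_polybase & res$excluded_repeat_insertion == FALSE
  res |>
    select("id", "chrom", "pos", "ref", "alt", "cohort_freq", "panel_freq",
           "p", "mlp", "enriched", "excluded_polybase",
           "excluded_repeat_insertion", "passes") |>
    arrange(.data$chrom, .data$pos)
}
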