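# Seeded synthetic-data generators. One global seed expands into
# per-component substreams so adding a generator never perturbs the output
# of an existing one.

substream_seed <- function(seed, component) {
  h <- sum(utf8ToInt(component) * seq_along(utf8ToInt(component)) * 131)
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}

with_substream <- function(seed, component, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(substream_seed(seed, component))
  force(code)
}

#' Case allele frequency implied by an odds ratio
#'
#' Allele-scale odds ratio: `q_case = OR q / (1 - q + OR q)` for control
#' frequency `q`, matching the 2x2 allelic test the cohorts feed.
#'
#' @param control_maf Control minor-allele frequency.
#' @param odds_ratio Allelic odds ratio (> 0).
#' @return Case allele frequency.
#' @export
case_freq_from_or <- function(control_maf, odds_ratio) {
  stopifnot(all(odds_ratio > 0), all(control_maf >= 0), all(control_maf <= 1))
  odds_ratio * control_maf / (1 - control_maf + odds_ratio * control_maf)
}

#' Simulate a case-control cohort under Hardy-Weinberg equilibrium
#'
#' Draws per-sample genotypes for each variant independently, under HWE
#' within each stratum: controls at `control_maf`, cases at the frequency
#' implied by the allelic odds ratio (see [case_freq_from_or()]).
#' Default cohort sizes follow a large candidate-gene case-control design
#' (1,510 cases, 1,095 controls).
#'
#' @param variants Tibble with `id`, `control_maf` and either `odds_ratio`
#'   or `case_maf`.
#' @param n_cases,n_controls Cohort sizes.
#' @param seed Integer seed; identical seed gives identical output.
#' @return Long tibble: `sample_id`, `stratum`, `id`, `dosage` (0/1/2).
#' @export
simulate_cohort <- function(variants, n_cases = 1510, n_controls = 1095,
                            seed = 1) {
  variants <- as_tibble(variants)
  if (!"case_maf" %in% names(variants)) {
    variants$case_maf <- case_freq_from_or(variants$control_maf,
                                           variants$odds_ratio)
  }
  with_substream(seed, "cohort", {
    strata <- tibble(
      stratum = rep(c("case", "control"), c(n_cases, n_controls)),
      sample_id = c(sprintf("case_%04d", seq_len(n_cases)),
                    sprintf("ctrl_%04d", seq_len(n_controls)))
    )
    map(seq_len(nrow(variants)), function(i) {
      q <- ifelse(strata$stratum == "case",
                  variants$case_maf[i], variants$control_maf[i])
      tibble(sample_id = strata$sample_id, stratum = strata$stratum,
             id = variants$id[i],
             dosage = rbinom(nrow(strata), 2, q))
    }) |> list_rbind()
  })
}

#' Tabulate per-sample genotypes into genotype counts
#'
#' @param genotypes Long tibble with `id`, `stratum`, `dosage`.
#' @return Tibble with `id`, `stratum`, `hom_alt`, `het`, `hom_ref`, ready
#'   for [associate()].
#' @export
tabulate_genotypes <- function(genotypes) {
  genotypes |>
    filter(!is.na(.data$dosage)) |>
    group_by(.data$id, .data$stratum) |>
    summarise(hom_alt = sum(.data$dosage == 2),
              het = sum(.data$dosage == 1),
              hom_ref = sum(.data$dosage == 0), .groups = "drop")
}

#' Simulate a reference allele-frequency panel
#'
#' Binomial draws of alternate-allele counts out of `2 * panel_size`
#' chromosomes per variant, emulating a sites-only population panel
#' (default 372 diploid samples, the size of a European reference panel).
#'
#' @param variants Tibble with `id`, `chrom`, `pos`, `ref`, `alt` and
#'   `panel_freq` (true alternate-allele frequency in the panel population).
#' @param panel_size Diploid sample count (default 372).
#' @param seed Integer seed.
#' @return `variants` with `panel_alt` and `panel_total` columns appended.
#' @export
simulate_reference_panel <- function(variants, panel_size = 372, seed = 1) {
  variants <- as_tibble(variants)
  with_substream(seed, "panel", {
    mutate(variants,
           panel_alt = rbinom(n(), 2 * panel_size, .data$panel_freq),
           panel_total = 2 * panel_size)
  })
}

#' Simulate unphased two-locus genotypes from haplotype frequencies
#'
#' Forms `n` diploid samples from `2n` haplotypes drawn i.i.d. from the
#' given frequencies and returns the unphased 3x3 genotype table (rows:
#' alternate dosage at locus 1; columns: locus 2).
#'
#' @param freqs Named numeric (`AB`, `Ab`, `aB`, `ab`) summing to 1.
#' @param n Number of diploid samples.
#' @param seed Integer seed.
#' @return 3x3 genotype-count matrix.
#' @export
simulate_haplotype_pairs <- function(freqs, n, seed = 1) {
  p <- freqs[HAP_NAMES]
  stopifnot(abs(sum(p) - 1) < 1e-8, all(p >= 0))
  dose <- rbind(AB = c(0, 0), Ab = c(0, 1), aB = c(1, 0), ab = c(1, 1))
  with_substream(seed, "haplotypes", {
    h1 <- sample.int(4, n, replace = TRUE, prob = p)
    h2 <- sample.int(4, n, replace = TRUE, prob = p)
    g1 <- dose[h1, 1] + dose[h2, 1]
    g2 <- dose[h1, 2] + dose[h2, 2]
    tab <- matrix(0, 3, 3)
    for (s in seq_len(n)) tab[g1[s] + 1, g2[s] + 1] <-
        tab[g1[s] + 1, g2[s] + 1] + 1
    tab
  })
}

#' Published genotype counts of the twelve genotyped candidate variants
#'
#' The deterministic fixture behind the association stage: the case and
#' control genotype counts, reference-panel frequencies and printed
#' statistics for the twelve rare candidate variants genotyped in the
#' bipolar-disorder case-control study of the ANK3 and CACNA1C genes.
#' `printed_maf` and `printed_p` are kept as printed (strings preserve the
#' printed precision).
#'
#' @return Tibble with one row per (variant, stratum): `gene`, `id`,
#'   `chrom`, `pos`, `region`, `ref`, `alt`, `panel_maf`, `printed_mlp`,
#'   `stratum`, `n_samples`, `hom_alt`, `het`, `hom_ref`, `printed_maf`,
#'   `printed_p`.
#' @export
#' @examples
#' counts <- table1_fixture()
#' associate(counts)
table1_fixture <- function() {
  row <- function(gene, id, chrom, pos, region, ref, alt, panel_maf, mlp,
                  ca, cb, cc, maf_ca, p, ka, kb, kc, maf_k, n_ca, n_k) {
    tibble(gene = gene, id = id, chrom = chrom, pos = pos, region = region,
           ref = ref, alt = alt, panel_maf = panel_maf, printed_mlp = mlp,
           stratum = c("case", "control"), n_samples = c(n_ca, n_k),
           hom_alt = c(ca, ka), het = c(cb, kb), hom_ref = c(cc, kc),
           printed_maf = c(maf_ca, maf_k),
           printed_p = c(p, NA_character_))
  }
  bind_rows(
    row("ANK3", "rs184389434", "10", 62493837, "promoter", "A", "T", 0,
        1.39, 0, 15, 1454, "0.0051", "0.41", 0, 12, 1019, "0.0058",
        1469, 1031),
    row("ANK3", "ss825679002", "10", 61788626, "utr3", "C", "A", 0,
        1.39, 0, 36, 1431, "0.012", "0.35", 0, 28, 998, "0.014",
        1467, 1026),
    row("ANK3", "rs139972937", "10", 61832711, "coding_nonsynonymous",
        "A", "G", 0, 1.39, 0, 9, 1465, "0.0031", "0.042", 0, 1, 1029,
        "0.0005", 1474, 1030),
    row("CACNA1C", "ss825679004", "12", 2161934, "promoter", "G", "A", 0,
        1.39, 0, 5, 1462, "0.0017", "0.57", 0, 4, 1027, "0.0019",
        1467, 1031),
    row("CACNA1C", "ss825679005", "12", 2694668, "splice_donor", "G", "A",
        0, 1.39, 0, 3, 1470, "0.0010", "0.7", 0, 2, 1030, "0.0010",
        1473, 1032),
    row("CACNA1C", "rs146482058", "12", 2403077, "intron_target", "T", "TT",
        0, 10.9, 3, 134, 1322, "0.048", "0.31", 4, 96, 922, "0.051",
        1486, 1022),
    row("CACNA1C", "rs79398153", "12", 2295156, "intron_target", "C", "T",
        0.01, 1.57, 3, 88, 1380, "0.032", "0.015", 0, 44, 985, "0.021",
        1498, 1029),
    row("CACNA1C", "rs191953785", "12", 2425097, "intron_target", "C", "T",
        0, 2.29, 0, 25, 1450, "0.0085", "0.34", 0, 20, 1005, "0.0098",
        1475, 1020),
    row("CACNA1C", "rs112312080", "12", 2354510, "intron_target", "C", "T",
        0.001, 2.02, 0, 35, 1439, "0.012", "0.30", 0, 20, 1008, "0.0097",
        1501, 1028),
    row("CACNA1C", "rs113414207", "12", 2292742, "intron_target", "A", "AC",
        0, 2.15, 0, 76, 1394, "0.026", "0.19", 0, 44, 982, "0.021",
        1497, 1026),
    row("CACNA1C", "ss825679006", "12", 2329069, "intron_target", "G", "T",
        0, 2.15, 0, 14, 1457, "0.0048", "0.43", 0, 8, 1024, "0.0039",
        1498, 1033),
    row("CACNA1C", "ss825679007", "12", 2423175, "intron_target", "G", "C",
        0, 2.15, 0, 4, 1471, "0.0014", "0.34", 0, 1, 1025, "0.0010",
        1502, 1026)
  )
}

#' Expand genotype counts to individual-level records
#'
#' Inverse of [tabulate_genotypes()]: deterministic expansion of genotype
#' counts into one row per (sample, variant).
#'
#' @param counts Tibble with `id`, `stratum`, `hom_alt`, `het`, `hom_ref`.
#' @return Long tibble: `sample_id`, `stratum`, `id`, `dosage`.
#' @export
expand_counts <- function(counts) {
  pmap(as_tibble(counts)[, c("id", "stratum", "hom_alt", "het", "hom_ref")],
       function(id, stratum, hom_alt, het, hom_ref) {
    n <- hom_alt + het + hom_ref
    tibble(sample_id = sprintf("%s_%s_%04d", stratum, id, seq_len(n)),
           stratum = stratum, id = id,
           dosage = rep(c(2, 1, 0), c(hom_alt, het, hom_ref)))
  }) |> list_rbind()
}

#' Synthetic genome context for end-to-end testing
#'
#' Builds a miniature genomic neighbourhood with every feature the
#' annotation and screening stages look at: two multi-isoform coding genes
#' (one per strand), a non-coding transcript, regulatory (ENCODE-like),
#' conserved and repeat interval tracks, a target intron interval between
#' them, reference flanks containing homopolymer runs, and a set of planted
#' variants whose true labels and filter outcomes are recorded alongside.
#'
#' @param seed Integer seed (geometry is fixed; the seed feeds the CDS base
#'   composition).
#' @return List with `models`, `cds_sequences`, `target`, `tracks`
#'   (`encode`, `conserved`, `repeats`), `flanks` (named by variant id) and
#'   `variants` (tibble with planted-truth columns `truth_labels`,
#'   `truth_polybase`, `truth_repeat_insertion`, `truth_intron3`).
#' @export
synth_genome_context <- function(seed = 1) {
  # gene A: + strand, 3 exons; CDS within exons 1-3
  gene_a <- bind_rows(
    transcript_model("txA1", "GENEA", "chr1", "+",
                     exons = tibble(start = c(10001, 10501, 11001),
                                    end = c(10100, 10600, 11200)),
                     cds_start = 10051, cds_end = 11102),
    transcript_model("txA2", "GENEA", "chr1", "+",
                     exons = tibble(start = c(10001, 11001),
                                    end = c(10100, 11200)),
                     cds_start = 10051, cds_end = 11103)
  )
  # gene B: - strand, 2 exons (transcription right to left)
  gene_b <- transcript_model("txB1", "GENEB", "chr1", "-",
                             exons = tibble(start = c(20001, 20501),
                                            end = c(20200, 20700)),
                             cds_start = 20103, cds_end = 20600)
  nc <- transcript_model("txN1", "GENEN", "chr1", "+",
                         exons = tibble(start = 30001, end = 30500))
  models <- bind_rows(gene_a, gene_b, nc)

  cds_sequences <- with_substream(seed, "cds", {
    out <- list()
    for (k in which(models$is_coding)) {
      m <- models[k, ]
      len <- length(cds_positions(m))
      stopifnot(len %% 3 == 0)
      out[[m$transcript_id]] <- paste(
        c("ATG", sample(c("A", "C", "G", "T"), len - 3, replace = TRUE)),
        collapse = "")
    }
    out
  })

  target <- tibble(chrom = "chr1", start = 40001, end = 45000)
  tracks <- list(
    encode = tibble(chrom = "chr1", start = c(40501, 42001, 44001),
                    end = c(40600, 42100, 44100)),
    conserved = tibble(chrom = "chr1", start = c(40551, 44001),
                       end = c(40650, 44100)),
    repeats = tibble(chrom = "chr1", start = c(42001, 50001),
                     end = c(42200, 50200))
  )

  variants <- tibble::tribble(
    ~id, ~pos, ~ref, ~alt, ~truth_labels, ~truth_polybase,
    ~truth_repeat_insertion, ~truth_intron3,
    # promoter of gene A (both isoforms share exon 1)
    "v_prom",    9500,  "G", "A", "promoter",        FALSE, FALSE, FALSE,
    # 5'UTR: exon 1 before the CDS start
    "v_utr5",    10020, "C", "T", "utr5",            FALSE, FALSE, FALSE,
    # 3'UTR: exon 3 after the CDS end
    "v_utr3",    11150, "T", "G", "utr3",            FALSE, FALSE, FALSE,
    # 6th intronic base after exon 1 of gene A: donor window
    "v_donor",   10106, "A", "G", "splice_donor",    FALSE, FALSE, FALSE,
    # 20th intronic base before exon 2 of txA1: acceptor window
    "v_accept",  10482, "T", "C", "splice_acceptor", FALSE, FALSE, FALSE,
    # promoter of the minus-strand gene lies above its last exon
    "v_promB",   20900, "A", "C", "promoter",        FALSE, FALSE, FALSE,
    # inside the target interval on an ENCODE+conserved element, off repeats
    "v_target",  40560, "G", "T", "intron_target",   FALSE, FALSE, TRUE,
    # in target and on an ENCODE element but also in a repeat
    "v_rep",     42050, "C", "A", "intron_target",   FALSE, FALSE, FALSE,
    # insertion anchored in a repeat region
    "v_repins",  50100, "A", "AT", "intergenic_or_other", FALSE, TRUE, FALSE,
    # SNV in a homopolymer context
    "v_poly",    60000, "A", "G", "intergenic_or_other", TRUE, FALSE, FALSE,
    # plain intergenic SNV
    "v_bg",      70000, "C", "G", "intergenic_or_other", FALSE, FALSE, FALSE
  ) |> mutate(chrom = "chr1", .after = "id")

  flanks <- c(
    v_poly = "ACGTGAAAAAAGTCA",   # run of 6 A centred on the variant
    v_bg   = "ATGCATGCATGCATG"
  )

  list(models = models, cds_sequences = cds_sequences, target = target,
       tracks = tracks, flanks = flanks, variants = variants)
}
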