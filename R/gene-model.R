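#' Build a transcript model
#'
#' A transcript model is the substrate of all region-window logic: an ordered,
#' strand-aware exon structure with an optional coding region (CDS). Models
#' are stored one-per-row in a tibble with the exon table nested in a list
#' column, so a set of isoforms is just `dplyr::bind_rows()` of models.
#'
#' @param id Transcript identifier.
#' @param gene Gene symbol the isoform belongs to.
#' @param chrom Chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param exons Data frame with columns `start`, `end` (1-based, closed);
#'   exons must be sorted, non-overlapping and non-empty.
#' @param cds_start,cds_end Genomic span of the coding region, or `NA` for a
#'   non-coding transcript. Must lie within the exon union.
#'
#' @return A one-row tibble with columns `transcript_id`, `gene`, `chrom`,
#'   `strand`, `is_coding`, `cds_start`, `cds_end` and a list column `exons`.
#' @export
#' @examples
#' transcript_model("tx1", "GENE1", "chr1", "+",
#'                  exons = data.frame(start = c(101, 301), end = c(200, 400)),
#'                  cds_start = 151, cds_end = 350)
transcript_model <- function(id, gene, chrom, strand, exons,
                             cds_start = NA_real_, cds_end = NA_real_) {
  stopifnot(strand %in% c("+", "-"))
  exons <- as_tibble(exons)[, c("start", "end")]
  exons <- arrange(exons, .data$start)
  if (any(exons$start > exons$end)) abort("empty exon in transcript model")
  if (nrow(exons) > 1 && any(exons$start[-1] <= exons$end[-nrow(exons)])) {
    abort("exons must be non-overlapping and sorted")
  }
  is_coding <- !is.na(cds_start) && !is.na(cds_end)
  if (is_coding) {
    if (cds_start > cds_end) abort("cds_start must not exceed cds_end")
    covered <- any(exons$start <= cds_start & exons$end >= cds_start) &&
      any(exons$start <= cds_end & exons$end >= cds_end)
    if (!covered) abort("CDS endpoints must fall inside exons")
  }
  tibble(
    transcript_id = as.character(id), gene = as.character(gene),
    chrom = as.character(chrom), strand = strand, is_coding = is_coding,
    cds_start = if (is_coding) as.numeric(cds_start) else NA_real_,
    cds_end = if (is_coding) as.numeric(cds_end) else NA_real_,
    exons = list(exons)
  )
}

#' Promoter interval of each coding isoform
#'
#' The promoter is taken as the `window` bases immediately upstream, in
#' transcription direction, of the transcription start (the 5' end of the
#' first exon). On the minus strand this lies at genomic coordinates above
#' the transcript.
#'
#' @param models Tibble of transcript models (see [transcript_model()]).
#' @param window Promoter width in bases (default 1000). `window = 0` yields
#'   an empty interval (`end < start`, `width = 0`).
#'
#' @return A tibble with one row per transcript: `transcript_id`, `gene`,
#'   `chrom`, `strand`, `start`, `end`, `width`, `is_coding`. Non-coding
#'   transcripts have no promoter; their coordinates are `NA`.
#' @export
promoter_interval <- function(models, window = 1000) {
  stopifnot(window >= 0)
  pmap(models, function(transcript_id, gene, chrom, strand, is_coding,
                        exons, ...) {
    if (!is_coding) {
      return(tibble(transcript_id = transcript_id, gene = gene, chrom = chrom,
                    strand = strand, start = NA_real_, end = NA_real_,
                    width = 0, is_coding = FALSE))
    }
    if (strand == "+") {
      tss <- min(exons$start)                 # first transcribed base
      start <- tss - window; end <- tss - 1
    } else {
      tss <- max(exons$end)
      start <- tss + 1; end <- tss + window
    }
    tibble(transcript_id = transcript_id, gene = gene, chrom = chrom,
           strand = strand, start = start, end = end,
           width = max(end - start + 1, 0), is_coding = TRUE)
  }) |> list_rbind()
}

#' Splice donor and acceptor windows
#'
#' For every internal exon-intron junction, the donor window spans the last 5
#' exonic and first 6 intronic bases in transcription direction (11 bp); the
#' acceptor window spans the last 20 intronic and first 3 exonic bases
#' (23 bp). Single-exon transcripts have no windows.
#'
#' @param models Tibble of transcript models.
#' @return Tibble with columns `transcript_id`, `gene`, `chrom`, `strand`,
#'   `site` (`"donor"` or `"acceptor"`), `exon_index` (in transcription
#'   order), `start`, `end`.
#' @export
splice_windows <- function(models) {
  pmap(models, function(transcript_id, gene, chrom, strand, exons, ...) {
    n <- nrow(exons)
    if (n < 2) return(NULL)
    # exons in transcription order
    ord <- if (strand == "+") seq_len(n) else rev(seq_len(n))
    ex <- exons[ord, ]
    out <- vector("list", 2L * (n - 1L))
    for (i in seq_len(n - 1L)) {
      if (strand == "+") {
        donor <- c(ex$end[i] - 4, ex$end[i] + 6)
        accept <- c(ex$start[i + 1] - 20, ex$start[i + 1] + 2)
      } else {
        donor <- c(ex$start[i] - 6, ex$start[i] + 4)
        accept <- c(ex$end[i + 1] - 2, ex$end[i + 1] + 20)
      }
      out[[2L * i - 1L]] <- tibble(site = "donor", exon_index = i,
                                   start = donor[1], end = donor[2])
      out[[2L * i]] <- tibble(site = "acceptor", exon_index = i + 1L,
                              start = accept[1], end = accept[2])
    }
    mutate(list_rbind(out), transcript_id = transcript_id, gene = gene,
           chrom = chrom, strand = strand,
           .before = 1)
  }) |> list_rbind()
}

# genomic positions of CDS bases in transcription order (5' -> 3' of mRNA)
cds_positions <- function(model_row) {
  exons <- model_row$exons[[1]]
  cs <- model_row$cds_start; ce <- model_row$cds_end
  pieces <- filter(exons, .data$end >= cs, .data$start <= ce)
  pos <- unlist(map2(pmax(pieces$start, cs), pmin(pieces$end, ce), seq))
  if (model_row$strand == "-") pos <- rev(pos)
  pos
}

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

#' Amino-acid consequence of a coding substitution
#'
#' Translates the affected codon before and after the substitution with the
#' standard genetic code, complementing the alternate allele on minus-strand
#' transcripts. Indels inside the CDS are out of scope and return an
#' unsupported marker.
#'
#' @param variant One-row data frame with `chrom`, `pos`, `ref`, `alt`
#'   (1-based position; single-base ref/alt for a substitution).
#' @param model One-row transcript-model tibble with a CDS.
#' @param cds_sequence The spliced coding sequence of the transcript, 5' to
#'   3' (sense strand), length divisible by 3.
#'
#' @return A one-row tibble: `aa_position` (1-based codon index), `ref_aa`,
#'   `alt_aa`, `consequence` (`"synonymous"`, `"nonsynonymous"` or
#'   `"unsupported_indel"`) and `hgvs_p` (e.g. `"N2643S"`).
#' @export
amino_acid_change <- function(variant, model, cds_sequence) {
  variant <- as_tibble(variant)
  stopifnot(nrow(variant) == 1, model$is_coding)
  if (nchar(variant$ref) != 1 || nchar(variant$alt) != 1) {
    return(tibble(aa_position = NA_integer_, ref_aa = NA_character_,
                  alt_aa = NA_character_, consequence = "unsupported_indel",
                  hgvs_p = NA_character_))
  }
  cds_sequence <- toupper(cds_sequence)
  if (nchar(cds_sequence) %% 3 != 0) abort("CDS length must be a multiple of 3")
  pos_map <- cds_positions(model)
  offset <- match(variant$pos, pos_map)
  if (is.na(offset)) abort("variant does not fall in the CDS of this transcript")
  if (nchar(cds_sequence) != length(pos_map)) {
    abort("cds_sequence length does not match the CDS span of the model")
  }
  alt_base <- toupper(variant$alt)
  if (model$strand == "-") alt_base <- COMPLEMENT[[alt_base]]
  codon_idx <- (offset - 1) %/% 3 + 1
  within <- (offset - 1) %% 3 + 1
  codon <- substr(cds_sequence, 3 * codon_idx - 2, 3 * codon_idx)
  new_codon <- codon
  substr(new_codon, within, within) <- alt_base
  ref_aa <- translate_codon(codon)
  alt_aa <- translate_codon(new_codon)
  tibble(
    aa_position = as.integer(codon_idx), ref_aa = ref_aa, alt_aa = alt_aa,
    consequence = if (ref_aa == alt_aa) "synonymous" else "nonsynonymous",
    hgvs_p = paste0(ref_aa, codon_idx, alt_aa)
  )
}

translate_codon <- function(codon) {
  unname(Biostrings::GENETIC_CODE[codon])
}

in_span <- function(chrom, span_start, span_end, iv_chrom, iv_start, iv_end) {
  chrom == iv_chrom & span_start <= iv_end & span_end >= iv_start
}

# affected reference span of a variant, 1-based closed; insertions use the
# anchor base to the left (VCF anchoring)
variant_span <- function(variants) {
  mutate(variants,
         span_start = .data$pos,
         span_end = .data$pos + pmax(nchar(.data$ref), 1L) - 1L)
}

#' Classify variants into region categories
#'
#' Labels each variant per isoform and unions the labels: `promoter`, `utr5`,
#' `utr3`, `splice_donor`, `splice_acceptor`, `coding_synonymous`,
#' `coding_nonsynonymous`, `intron_target`, falling back to
#' `intergenic_or_other` when nothing applies. Membership is tested with the
#' variant's affected reference span, so deletions overlapping a window edge
#' are caught.
#'
#' @param variants Tibble with `id`, `chrom`, `pos`, `ref`, `alt`.
#' @param models Tibble of transcript models; may be empty if
#'   `target_interval` is given.
#' @param target_interval Optional one-row data frame (`chrom`, `start`,
#'   `end`) marking a target intron interval (label `intron_target`).
#' @param promoter_window Promoter width passed to [promoter_interval()].
#' @param cds_sequences Named list (by transcript id) of spliced CDS
#'   sequences, used to resolve coding consequences. A CDS variant without a
#'   sequence is labelled `coding_unresolved`.
#'
#' @return A long tibble: one row per (variant, isoform, label), with
#'   `variant_id`, `chrom`, `pos`, `transcript_id`, `gene`, `label` and
#'   `protein_change` (non-`NA` for coding labels). Rows with
#'   `transcript_id = NA` carry the model-free labels (`intron_target`,
#'   `intergenic_or_other`).
#' @export
classify_variants <- function(variants, models = NULL, target_interval = NULL,
                              promoter_window = 1000, cds_sequences = NULL) {
  variants <- variant_span(as_tibble(variants))
  if (is.null(models) && is.null(target_interval)) {
    abort("supply transcript models or a target interval")
  }
  have_models <- !is.null(models) && nrow(models) > 0
  promoters <- if (have_models) promoter_interval(models, promoter_window)
  splices <- if (have_models) splice_windows(models)

  rows <- pmap(variants, function(id, chrom, pos, ref, alt,
                                  span_start, span_end, ...) {
    hits <- list()
    add <- function(tx, gene, label, pc = NA_character_) {
      tibble(variant_id = id, chrom = chrom, pos = pos, transcript_id = tx,
             gene = gene, label = label, protein_change = pc)
    }
    if (!is.null(target_interval) &&
        in_span(chrom, span_start, span_end, target_interval$chrom,
                target_interval$start, target_interval$end)) {
      hits <- c(hits, list(add(NA_character_, NA_character_, "intron_target")))
    }
    if (have_models) {
      for (k in seq_len(nrow(models))) {
        m <- models[k, ]
        if (m$chrom != chrom) next
        ex <- m$exons[[1]]
        # promoter
        pr <- promoters[k, ]
        if (isTRUE(pr$is_coding) && pr$width > 0 &&
            in_span(chrom, span_start, span_end, pr$chrom, pr$start, pr$end)) {
          hits <- c(hits, list(add(m$transcript_id, m$gene, "promoter")))
        }
        # splice windows
        if (!is.null(splices)) {
          sw <- filter(splices, .data$transcript_id == m$transcript_id,
                       span_start <= .data$end, span_end >= .data$start)
          for (s in seq_len(nrow(sw))) {
            hits <- c(hits, list(add(m$transcript_id, m$gene,
                                     paste0("splice_", sw$site[s]))))
          }
        }
        exonic <- any(span_start <= ex$end & span_end >= ex$start)
        if (!exonic) next
        if (m$is_coding && span_start <= m$cds_end && span_end >= m$cds_start) {
          seq <- cds_sequences[[m$transcript_id]]
          if (is.null(seq)) {
            hits <- c(hits, list(add(m$transcript_id, m$gene,
                                     "coding_unresolved")))
          } else {
            aac <- amino_acid_change(
              tibble(chrom = chrom, pos = pos, ref = ref, alt = alt), m, seq)
            lab <- switch(aac$consequence,
                          synonymous = "coding_synonymous",
                          nonsynonymous = "coding_nonsynonymous",
                          "coding_unresolved")
            hits <- c(hits, list(add(m$transcript_id, m$gene, lab,
                                     aac$hgvs_p)))
          }
        } else if (m$is_coding) {
          # exonic but outside the CDS: which UTR depends on strand
          five_prime <- if (m$strand == "+") span_end < m$cds_start
                        else span_start > m$cds_end
          hits <- c(hits, list(add(m$transcript_id, m$gene,
                                   if (five_prime) "utr5" else "utr3")))
        }
      }
    }
    if (length(hits) == 0) {
      hits <- list(add(NA_character_, NA_character_, "intergenic_or_other"))
    }
    list_rbind(hits)
  })
  distinct(list_rbind(rows))
}

#' Summarise classification labels per variant
#'
#' @param classified Output of [classify_variants()].
#' @return One row per variant with `labels` (semicolon-joined, sorted
#'   unique) and `protein_change` (first non-missing).
#' @export
annotation_summary <- function(classified) {
  classified |>
    group_by(.data$variant_id, .data$chrom, .data$pos) |>
    summarise(
      labels = paste(sort(unique(.data$label)), collapse = ";"),
      protein_change = {
        pc <- .data$protein_change[!is.na(.data$protein_change)]
        if (length(pc)) pc[1] else NA_character_
      },
      .groups = "drop"
    ) |>
    arrange(.data$chrom, .data$pos)
}
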