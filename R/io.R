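# Readers and writers for the standard formats around the pipeline. GFF3 and
# BED go through rtracklayer, VCF through vcfR; plain tables are TSV with a
# single header line. Internal coordinates are 1-based closed; BED's 0-based
# half-open convention is converted at this boundary.

need_pkg <- function(pkg) {
  if (!requireNamespace(pkg, quietly = TRUE)) {
    abort(paste0("package '", pkg, "' is required for this reader/writer"))
  }
}

#' Read transcript models from GFF3
#'
#' Expects the conventional gene/mRNA/exon/CDS feature hierarchy with
#' `ID`/`Parent` attributes; one model per mRNA.
#'
#' @param path GFF3 file.
#' @return Tibble of transcript models (see [transcript_model()]).
#' @export
read_gff3_models <- function(path) {
  need_pkg("rtracklayer")
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as_tibble(as.data.frame(gr))
  mrna <- filter(df, .data$type == "mRNA")
  genes <- filter(df, .data$type == "gene")
  gene_name <- setNames(
    as.character(genes$Name %||% genes$ID), as.character(genes$ID))
  map(seq_len(nrow(mrna)), function(i) {
    tx_id <- as.character(mrna$ID[i])
    parent <- as.character(unlist(mrna$Parent[i]))[1]
    kids <- filter(df, map_lgl(.data$Parent, function(p) tx_id %in% p))
    exons <- filter(kids, .data$type == "exon")
    cds <- filter(kids, .data$type == "CDS")
    transcript_model(
      tx_id,
      gene = unname(gene_name[parent]) %||% parent,
      chrom = as.character(mrna$seqnames[i]),
      strand = as.character(mrna$strand[i]),
      exons = select(exons, "start", "end"),
      cds_start = if (nrow(cds)) min(cds$start) else NA_real_,
      cds_end = if (nrow(cds)) max(cds$end) else NA_real_
    )
  }) |> list_rbind()
}

#' Write transcript models as GFF3
#'
#' @param models Tibble of transcript models.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_gff3_models <- function(models, path) {
  lines <- c("##gff-version 3")
  for (k in seq_len(nrow(models))) {
    m <- models[k, ]
    ex <- m$exons[[1]]
    span <- c(min(ex$start), max(ex$end))
    gid <- paste0("gene:", m$gene)
    lines <- c(lines,
      paste(m$chrom, "rarescreen", "gene", span[1], span[2], ".", m$strand,
            ".", paste0("ID=", gid, ";Name=", m$gene), sep = "\t"),
      paste(m$chrom, "rarescreen", "mRNA", span[1], span[2], ".", m$strand,
            ".", paste0("ID=", m$transcript_id, ";Parent=", gid), sep = "\t"),
      paste(m$chrom, "rarescreen", "exon", ex$start, ex$end, ".", m$strand,
            ".", paste0("Parent=", m$transcript_id), sep = "\t"))
    if (m$is_coding) {
      cds <- filter(ex, .data$end >= m$cds_start, .data$start <= m$cds_end)
      lines <- c(lines,
        paste(m$chrom, "rarescreen", "CDS",
              pmax(cds$start, m$cds_start), pmin(cds$end, m$cds_end), ".",
              m$strand, "0", paste0("Parent=", m$transcript_id), sep = "\t"))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read an interval track from BED
#'
#' @param path BED file (0-based half-open); converted to 1-based closed.
#' @return Tibble with `chrom`, `start`, `end`.
#' @export
read_bed_track <- function(path) {
  need_pkg("rtracklayer")
  df <- as.data.frame(rtracklayer::import(path, format = "bed"))
  tibble(chrom = as.character(df$seqnames), start = df$start, end = df$end)
}

#' Write an interval track as BED
#'
#' @param track Tibble with `chrom`, `start`, `end` (1-based closed).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_bed_track <- function(track, path) {
  writeLines(sprintf("%s\t%d\t%d", track$chrom,
                     as.integer(track$start - 1), as.integer(track$end)),
             path)
  invisible(path)
}

#' Read variant sites from a VCF
#'
#' Sites-only or genotyped VCF 4.x. Multi-allelic records are expanded one
#' row per alternate allele. When the VCF carries GT fields, per-sample
#' alternate dosages are returned as well.
#'
#' @param path VCF file (may be bgzipped).
#' @return List with `variants` (tibble `id`, `chrom`, `pos`, `ref`, `alt`)
#'   and `genotypes` (long tibble `sample_id`, `id`, `dosage`, or `NULL`).
#' @export
read_variants_vcf <- function(path) {
  need_pkg("vcfR")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as_tibble(as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE))
  record_ids <- ifelse(is.na(fix$ID) | fix$ID == ".",
                       paste0(fix$CHROM, ":", fix$POS), fix$ID)
  variants <- tibble(
    id = record_ids,
    chrom = fix$CHROM, pos = as.numeric(fix$POS),
    ref = fix$REF, alt = fix$ALT
  ) |> tidyr::separate_longer_delim("alt", ",")
  genotypes <- NULL
  if (ncol(v@gt) > 1) {
    gt <- vcfR::extract.gt(v, element = "GT")
    dosage <- apply(gt, 2, function(g) {
      g <- gsub("\\|", "/", g)
      ifelse(is.na(g) | g == "./.", NA_integer_,
             stringr::str_count(g, "1"))
    })
    dosage <- matrix(dosage, nrow = nrow(gt),
                     dimnames = dimnames(gt))
    # dosages are per VCF record (pre-expansion id), counting any
    # alternate allele
    genotypes <- as_tibble(dosage) |>
      mutate(id = record_ids) |>
      tidyr::pivot_longer(-"id", names_to = "sample_id",
                          values_to = "dosage")
  }
  list(variants = variants, genotypes = genotypes)
}

#' Write per-sample genotypes as VCF 4.2
#'
#' @param variants Tibble with `id`, `chrom`, `pos`, `ref`, `alt`.
#' @param genotypes Optional long tibble (`sample_id`, `id`, `dosage`);
#'   omitted for a sites-only VCF.
#' @param path Output file (a `.gz` suffix is appended by the writer).
#' @return The written path, invisibly.
#' @export
write_variants_vcf <- function(variants, genotypes = NULL, path) {
  header <- c("##fileformat=VCFv4.2",
              "##source=rarescreen",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">")
  cols <- c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO")
  body <- tibble(CHROM = variants$chrom, POS = variants$pos,
                 ID = variants$id, REF = variants$ref, ALT = variants$alt,
                 QUAL = ".", FILTER = ".", INFO = ".")
  if (!is.null(genotypes)) {
    gt_code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
    wide <- genotypes |>
      mutate(gt = ifelse(is.na(.data$dosage), "./.",
                         gt_code[as.character(.data$dosage)])) |>
      select("sample_id", "id", "gt") |>
      tidyr::pivot_wider(names_from = "sample_id", values_from = "gt")
    wide <- wide[match(variants$id, wide$id), ]
    body$FORMAT <- "GT"
    body <- bind_rows(body)
    body <- cbind(body, select(wide, -"id"))
    cols <- c(cols, "FORMAT", names(select(wide, -"id")))
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  writeLines(paste(cols, collapse = "\t"), con)
  writeLines(do.call(paste, c(as.list(body), sep = "\t")), con)
  invisible(path)
}

#' Read reference-panel allele counts from TSV
#'
#' Columns: `chrom`, `pos`, `ref`, `alt`, `panel_alt`, `panel_total`.
#'
#' @param path TSV file.
#' @return Tibble of panel counts for [run_screen()].
#' @export
read_panel_tsv <- function(path) {
  as_tibble(read.table(path, header = TRUE, sep = "\t",
                       colClasses = c(chrom = "character")))
}

#' Read a per-sample genotype table from TSV
#'
#' Columns: `sample_id`, `stratum`, `id`, `dosage` (and optionally `gene`).
#'
#' @param path TSV file.
#' @return Tibble of genotype records.
#' @export
read_genotype_tsv <- function(path) {
  as_tibble(read.table(path, header = TRUE, sep = "\t"))
}

#' Write a tibble as a single-header TSV
#'
#' P-value columns (`p`, `mlp`, or ending in `_p`/`_maf`) are printed with 4
#' significant digits and never as 0.
#'
#' @param x Tibble.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_report_tsv <- function(x, path) {
  fmt <- x
  for (cl in names(fmt)) {
    if (grepl("(^p$|^mlp$|_p$|_maf$|^maf$)", cl) && is.numeric(fmt[[cl]])) {
      v <- fmt[[cl]]
      v <- ifelse(!is.na(v) & v > 0 & v < 1e-300, 1e-300, v)
      fmt[[cl]] <- ifelse(is.na(v), NA, signif(v, 4))
    }
  }
  write.table(fmt, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write per-variant annotations as TSV
#'
#' One row per variant: id, chromosome, 1-based position, semicolon-joined
#' labels, contributing isoforms and protein change.
#'
#' @param classified Output of [classify_variants()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(classified, path) {
  write_report_tsv(annotation_summary(classified), path)
}
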