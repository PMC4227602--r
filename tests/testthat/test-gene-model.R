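plus_tx <- transcript_model(
  "tx_plus", "G1", "chr1", "+",
  exons = data.frame(start = c(10001, 10501, 11001),
                     end = c(10100, 10600, 11200)),
  cds_start = 10051, cds_end = 11102)

minus_tx <- transcript_model(
  "tx_minus", "G2", "chr2", "-",
  exons = data.frame(start = c(40001, 49001), end = c(40400, 50000)),
  cds_start = 40101, cds_end = 49600)

test_that("promoter interval sits immediately upstream of the 5' exon", {
  p <- promoter_interval(plus_tx, window = 1000)
  expect_equal(c(p$start, p$end), c(9001, 10000))

  p <- promoter_interval(minus_tx, window = 1000)
  expect_equal(c(p$start, p$end), c(50001, 51000))

  # degenerate window is empty
  expect_equal(promoter_interval(plus_tx, window = 0)$width, 0)

  # non-coding transcripts have no promoter, flagged rather than dropped
  nc <- transcript_model("nc", "G3", "chr1", "+",
                         exons = data.frame(start = 100, end = 500))
  p <- promoter_interval(nc)
  expect_false(p$is_coding)
  expect_true(is.na(p$start))
})

test_that("promoter never intersects the exon union", {
  models <- dplyr::bind_rows(plus_tx, minus_tx)
  for (w in c(1, 50, 1000, 5000)) {
    p <- promoter_interval(models, window = w)
    for (k in seq_len(nrow(models))) {
      ex <- models$exons[[k]]
      expect_false(any(p$start[k] <= ex$end & p$end[k] >= ex$start),
                   info = paste("window", w, "tx", k))
    }
  }
})

test_that("splice windows have the defined widths and strand-mirror", {
  sw <- splice_windows(plus_tx)
  expect_equal(nrow(sw), 2 * (3 - 1))
  expect_equal(sw$end - sw$start + 1,
               ifelse(sw$site == "donor", 11, 23))
  d1 <- sw[sw$site == "donor" & sw$exon_index == 1, ]
  expect_equal(c(d1$start, d1$end), c(10096, 10106))
  a2 <- sw[sw$site == "acceptor" & sw$exon_index == 2, ]
  expect_equal(c(a2$start, a2$end), c(10481, 10503))

  # minus strand: donor window of exon [49001,50000] with downstream (in
  # transcription) intron [40401,49000] spans the 5 exonic bases 49001-49005
  # and the 6 intronic bases 48995-49000
  swm <- splice_windows(minus_tx)
  dm <- swm[swm$site == "donor", ]
  expect_equal(c(dm$start, dm$end), c(48995, 49005))
  am <- swm[swm$site == "acceptor", ]
  expect_equal(c(am$start, am$end), c(40398, 40420))

  single <- transcript_model("s", "G", "chr1", "+",
                             exons = data.frame(start = 1, end = 300))
  expect_equal(NROW(splice_windows(single)), 0)
})

test_that("classification unions labels over isoforms and finds the target", {
  target <- tibble::tibble(chrom = "12", start = 2271532, end = 2425994)
  v <- tibble::tibble(id = "rs79398153", chrom = "12", pos = 2295156,
                      ref = "C", alt = "T")
  cl <- classify_variants(v, models = NULL, target_interval = target)
  expect_true("intron_target" %in% cl$label)

  # promoter of one isoform, 5'UTR of another
  tx1 <- transcript_model("u1", "G", "chr1", "+",
                          exons = data.frame(start = c(5001, 6001),
                                             end = c(5200, 6400)),
                          cds_start = 5101, cds_end = 6300)
  tx2 <- transcript_model("u2", "G", "chr1", "+",
                          exons = data.frame(start = c(4500, 6001),
                                             end = c(5200, 6400)),
                          cds_start = 5101, cds_end = 6300)
  v2 <- tibble::tibble(id = "v", chrom = "chr1", pos = 4800,
                       ref = "A", alt = "G")
  cl2 <- classify_variants(v2, dplyr::bind_rows(tx1, tx2))
  expect_setequal(cl2$label, c("promoter", "utr5"))

  # sixth intronic base of a donor window
  v3 <- tibble::tibble(id = "v3", chrom = "chr1", pos = 10106,
                       ref = "A", alt = "G")
  cl3 <- classify_variants(v3, plus_tx)
  expect_true("splice_donor" %in% cl3$label)

  # chromosome mismatch with all models
  v4 <- tibble::tibble(id = "v4", chrom = "chrX", pos = 10106,
                       ref = "A", alt = "G")
  expect_equal(classify_variants(v4, plus_tx)$label, "intergenic_or_other")
})

test_that("classification is invariant under transcript reordering", {
  ctx <- synth_genome_context(seed = 3)
  a <- classify_variants(ctx$variants, ctx$models, ctx$target,
                         cds_sequences = ctx$cds_sequences)
  b <- classify_variants(ctx$variants, ctx$models[rev(seq_len(nrow(ctx$models))), ],
                         ctx$target, cds_sequences = ctx$cds_sequences)
  key <- function(x) dplyr::arrange(x, variant_id, transcript_id, label)
  expect_equal(key(a), key(b))
})

test_that("amino-acid change translates the affected codon", {
  # codon AAT, substitution at codon position 2, A -> G gives AGT: N -> S
  tx <- transcript_model("t", "G", "chr1", "+",
                         exons = data.frame(start = 101, end = 106),
                         cds_start = 101, cds_end = 106)
  aac <- amino_acid_change(
    tibble::tibble(chrom = "chr1", pos = 105, ref = "A", alt = "G"),
    tx, "GGAAAT")
  expect_equal(aac$ref_aa, "N")
  expect_equal(aac$alt_aa, "S")
  expect_equal(aac$consequence, "nonsynonymous")
  expect_equal(aac$hgvs_p, "N2S")

  # GGA -> GGG is synonymous
  syn <- amino_acid_change(
    tibble::tibble(chrom = "chr1", pos = 103, ref = "A", alt = "G"),
    tx, "GGAAAT")
  expect_equal(syn$consequence, "synonymous")

  # minus strand: genomic C->T at the last genomic base is codon position 1
  # of the reverse-complement codon
  txm <- transcript_model("tm", "G", "chr1", "-",
                          exons = data.frame(start = 201, end = 206),
                          cds_start = 201, cds_end = 206)
  # sense CDS = revcomp(genomic); genomic TTGCAA -> sense TTGCAA
  aacm <- amino_acid_change(
    tibble::tibble(chrom = "chr1", pos = 206, ref = "A", alt = "G"),
    txm, "TTGCAA")
  # sense base 1 is complement of genomic 206: A->G becomes T->C; TTG -> CTG
  expect_equal(aacm$ref_aa, codon_oracle("TTG"))
  expect_equal(aacm$alt_aa, codon_oracle("CTG"))

  expect_equal(amino_acid_change(
    tibble::tibble(chrom = "chr1", pos = 103, ref = "AG", alt = "A"),
    tx, "GGAAAT")$consequence, "unsupported_indel")
  expect_error(amino_acid_change(
    tibble::tibble(chrom = "chr1", pos = 999, ref = "A", alt = "G"),
    tx, "GGAAAT"), "CDS")
})

test_that("translation agrees with a hand-written codon table on random triples", {
  withr::with_seed(42, {
    bases <- c("A", "C", "G", "T")
    for (i in 1:1000) {
      codon <- paste(sample(bases, 3, replace = TRUE), collapse = "")
      posn <- sample(3, 1)
      alt <- sample(setdiff(bases, substr(codon, posn, posn)), 1)
      tx <- transcript_model("t", "G", "chr1", "+",
                             exons = data.frame(start = 1, end = 3),
                             cds_start = 1, cds_end = 3)
      got <- amino_acid_change(
        tibble::tibble(chrom = "chr1", pos = posn,
                       ref = substr(codon, posn, posn), alt = alt),
        tx, codon)
      new_codon <- codon
      substr(new_codon, posn, posn) <- alt
      expect_equal(got$ref_aa, codon_oracle(codon))
      expect_equal(got$alt_aa, codon_oracle(new_codon))
    }
  })
})
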