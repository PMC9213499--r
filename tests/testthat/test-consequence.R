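test_that("minus-strand G>A at the base pairing with c.478 gives c.478C>T / p.Arg160Cys", {
  tx <- copa_fixture()
  g <- genomic_position(478, tx)
  expect_equal(substr(tx$seq, g, g), "G")
  cons <- annotate_snv(list(contig = tx$contig, pos = g, ref = "G", alt = "A"), tx)
  expect_equal(cons$hgvs_c, "c.478C>T")
  expect_equal(cons$codon_index, 160L)
  expect_equal(cons$ref_codon, "CGC")
  expect_equal(cons$alt_codon, "TGC")
  expect_equal(cons$hgvs_p, "p.Arg160Cys")
  expect_equal(cons$category, "missense")
})

test_that("first intronic base after the exon ending at c.33 is a splice donor", {
  tx <- mitf_fixture()
  g <- genomic_position(33, tx) + 1
  cons <- annotate_snv(list(contig = tx$contig, pos = g,
                            ref = substr(tx$seq, g, g), alt = "A"), tx)
  expect_equal(cons$hgvs_c, "c.33+1G>A")
  expect_equal(cons$category, "splice_donor")
  # past the window it is plain intronic; near the downstream exon, acceptor
  mid <- annotate_snv(list(contig = tx$contig, pos = g + 49, ref = "A", alt = "G"),
                      tx)
  expect_equal(mid$category, "intronic")
  g34 <- genomic_position(34, tx)
  acc <- annotate_snv(list(contig = tx$contig, pos = g34 - 1,
                           ref = substr(tx$seq, g34 - 1, g34 - 1), alt = "C"), tx)
  expect_equal(acc$category, "splice_acceptor")
  expect_equal(acc$cdna_offset, -1L)
})

test_that("synonymous and stop-gain substitutions are classified from the codon table", {
  tx <- generate_transcript(
    toy_transcript_spec("TOY", strand = "+", cds_length = 30,
                        codon_constraints = list(list(index = 3, codon = "CTG"),
                                                 list(index = 5, codon = "CGA"))),
    seed = 4)
  # third position CTG -> CTA, Leu -> Leu
  g <- genomic_position(9, tx)
  syn <- annotate_snv(list(contig = tx$contig, pos = g, ref = "G", alt = "A"), tx)
  expect_equal(syn$category, "synonymous")
  expect_equal(syn$ref_aa, "L")
  # CGA -> TGA at first codon position
  g2 <- genomic_position(13, tx)
  stp <- annotate_snv(list(contig = tx$contig, pos = g2, ref = "C", alt = "T"), tx)
  expect_equal(stp$category, "stop_gained")
  expect_equal(stp$hgvs_p, "p.Arg5Ter")
})

test_that("indels and off-transcript contigs are rejected explicitly", {
  tx <- mitf_fixture()
  expect_error(annotate_snv(list(contig = tx$contig, pos = 200, ref = "GA", alt = "G"), tx),
               "unsupported")
  expect_error(annotate_snv(list(contig = "elsewhere", pos = 200, ref = "G", alt = "A"), tx),
               "contig")
})

test_that("codon arithmetic maps cDNA positions to codon index and offset", {
  expect_equal(codon_of(478), list(codon_index = 160L, offset_in_codon = 0L))
  expect_equal(codon_of(1), list(codon_index = 1L, offset_in_codon = 0L))
  expect_equal(codon_of(3), list(codon_index = 1L, offset_in_codon = 2L))
  expect_error(codon_of(0), ">= 1")
  expect_error(codon_of(31, cds_len = 30), "beyond")
})

test_that("cdna_position is a bijection onto 1..CDS-length on both strands", {
  for (strand in c("+", "-")) {
    tx <- generate_transcript(
      toy_transcript_spec("BIJ", strand = strand, cds_length = 90,
                          n_exons = 3, utr5_length = 12, utr3_length = 9),
      seed = 8)
    len <- cds_length(tx)
    coding <- integer(0)
    for (p in seq_len(nchar(tx$seq))) {
      cp <- cdna_position(p, tx)
      if (cp$region == "cds") {
        coding <- c(coding, cp$pos)
        expect_equal(genomic_position(cp$pos, tx), p)
      }
    }
    expect_equal(sort(coding), seq_len(len))
    expect_equal(length(coding), len)  # each position hit exactly once
  }
})

test_that("amino acids agree with an independent translation for every coding change", {
  tx <- generate_transcript(
    toy_transcript_spec("ORA", strand = "-", cds_length = 60, n_exons = 2),
    seed = 15)
  cds <- cds_sequence(tx)
  for (cpos in seq_len(nchar(cds))) {
    gpos <- genomic_position(cpos, tx)
    ref_c <- substr(cds, cpos, cpos)
    ref_g <- chartr("ACGT", "TGCA", ref_c)  # minus strand
    for (alt_c in setdiff(c("A", "C", "G", "T"), ref_c)) {
      alt_g <- chartr("ACGT", "TGCA", alt_c)
      cons <- annotate_snv(list(contig = tx$contig, pos = gpos,
                                ref = ref_g, alt = alt_g), tx)
      mutated <- cds
      substr(mutated, cpos, cpos) <- alt_c
      ci <- cons$codon_index
      aa_ref <- seqinr::translate(strsplit(cds, "")[[1]])[ci]
      aa_alt <- seqinr::translate(strsplit(mutated, "")[[1]])[ci]
      expect_equal(cons$ref_aa, aa_ref)
      expect_equal(cons$alt_aa, aa_alt)
    }
  }
})

test_that("strand symmetry: mirrored fixtures annotate identically in cDNA space", {
  base_spec <- function(strand) {
    toy_transcript_spec("SYM", strand = strand, cds_length = 60, n_exons = 2)
  }
  txp <- generate_transcript(base_spec("+"), seed = 21)
  txm <- generate_transcript(base_spec("-"), seed = 21)
  expect_equal(cds_sequence(txp), cds_sequence(txm))
  cds <- cds_sequence(txp)
  for (cpos in c(1, 17, 33, 60)) {
    ref_c <- substr(cds, cpos, cpos)
    alt_c <- setdiff(c("A", "C", "G", "T"), ref_c)[1]
    cp <- annotate_snv(list(contig = txp$contig, pos = genomic_position(cpos, txp),
                            ref = ref_c, alt = alt_c), txp)
    cm <- annotate_snv(list(contig = txm$contig, pos = genomic_position(cpos, txm),
                            ref = chartr("ACGT", "TGCA", ref_c),
                            alt = chartr("ACGT", "TGCA", alt_c)), txm)
    expect_equal(cm$hgvs_c, cp$hgvs_c)
    expect_equal(cm$hgvs_p, cp$hgvs_p)
    expect_equal(cm$category, cp$category)
  }
})

test_that("UTR and intergenic positions are categorised without c. numbering", {
  tx <- generate_transcript(
    toy_transcript_spec("UTR", strand = "+", cds_length = 30,
                        utr5_length = 10, utr3_length = 10),
    seed = 3)
  utr_pos <- min(tx$exons$start)  # first transcribed base, 5' UTR
  cons <- annotate_snv(list(contig = tx$contig, pos = utr_pos,
                            ref = substr(tx$seq, utr_pos, utr_pos),
                            alt = setdiff(c("A", "C", "G", "T"),
                                          substr(tx$seq, utr_pos, utr_pos))[1]), tx)
  expect_equal(cons$category, "utr")
  out <- annotate_snv(list(contig = tx$contig, pos = 1, ref = substr(tx$seq, 1, 1),
                           alt = setdiff(c("A", "C", "G", "T"),
                                         substr(tx$seq, 1, 1))[1]), tx)
  expect_equal(out$category, "intergenic")
})

test_that("annotate_variants degrades gracefully over mixed inputs", {
  tx <- mitf_fixture()
  variants <- data.frame(
    contig = c(tx$contig, tx$contig, "nowhere"),
    pos = c(genomic_position(10, tx), 500L, 5L),
    ref = c(substr(tx$seq, genomic_position(10, tx), genomic_position(10, tx)),
            "GATT", "G"),
    alt = c("A", "G", "A"), stringsAsFactors = FALSE)
  if (variants$ref[1] == "A") variants$alt[1] <- "C"
  cons <- annotate_variants(variants, list(tx))
  expect_equal(nrow(cons), 3L)
  expect_equal(cons$category[2], "unsupported")
  expect_equal(cons$category[3], "intergenic")
})
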