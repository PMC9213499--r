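test_that("cohort generation honours the planted genotypes and edge specs", {
  # no background: matrix is just the causal site with prescribed calls
  spec0 <- cohort_spec(n_background_variants = 0)
  m0 <- generate_cohort(spec0, seed = 5)
  expect_equal(nrow(m0$variants), 1L)
  expect_equal(m0$gt[1, ], c("hom_alt", rep("hom_ref", 8)))
  expect_equal(m0$variants$pos, spec0$causal$pos)
  # alt frequency 0: every background call hom_ref (bar missing masking)
  mono <- generate_cohort(cohort_spec(n_background_variants = 50,
                                      background_alt_freq = 0,
                                      missing_rate = 0), seed = 6)
  bg <- mono$gt[-attr(mono, "causal_index"), ]
  expect_true(all(bg == "hom_ref"))
  # causal-site case calls are never masked and always callable
  risky <- generate_cohort(cohort_spec(missing_rate = 0.5, mean_depth = 3),
                           seed = 7)
  ci <- attr(risky, "causal_index")
  expect_equal(risky$gt[ci, 1], "hom_alt")
  expect_gte(risky$depth[ci, 1], 3)
})

test_that("background genotypes follow Hardy-Weinberg proportions", {
  spec <- cohort_spec(n_cases = 1, n_controls = 9,
                      n_background_variants = 200,
                      background_alt_freq = 0.5, missing_rate = 0)
  m <- generate_cohort(spec, seed = 13)
  bg <- m$gt[-attr(m, "causal_index"), ]
  n <- length(bg)  # 2000 draws
  for (cls in list(c("hom_ref", 0.25), c("het", 0.5), c("hom_alt", 0.25))) {
    p <- as.numeric(cls[2])
    expect_lt(abs(mean(bg == cls[1]) - p), 4 * sqrt(p * (1 - p) / n))
  }
})

test_that("cohorts and transcripts are deterministic under a fixed seed", {
  spec <- cohort_spec(n_background_variants = 30)
  m1 <- generate_cohort(spec, seed = 3)
  m2 <- generate_cohort(spec, seed = 3)
  expect_identical(m1$gt, m2$gt)
  expect_identical(m1$depth, m2$depth)
  expect_identical(m1$variants, m2$variants)
  # file-level determinism, byte for byte
  d1 <- tempfile(); d2 <- tempfile()
  for (d in c(d1, d2)) {
    dir.create(d)
    tx <- generate_transcript(toy_transcript_spec("DET", n_exons = 3,
                                                  cds_length = 120), seed = 17)
    write_transcript_files(tx, file.path(d, "t.gff3"), file.path(d, "t.fa"))
    write_vcf(generate_cohort(spec, seed = 3), file.path(d, "c.vcf"))
  }
  for (f in c("t.gff3", "t.fa", "c.vcf")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  }
})

test_that("generated transcripts satisfy their constraints and validate", {
  for (seed in 1:5) {
    strand <- if (seed %% 2) "+" else "-"
    tx <- generate_transcript(
      toy_transcript_spec("GEN", strand = strand, cds_length = 150,
                          codon_constraints = list(list(index = 10, codon = "TGG")),
                          n_exons = 3, utr5_length = 5, utr3_length = 5),
      seed = seed)
    cds <- cds_sequence(tx)
    expect_equal(substr(cds, 1, 3), "ATG")
    expect_true(substr(cds, 148, 150) %in% c("TAA", "TAG", "TGA"))
    expect_equal(substr(cds, 28, 30), "TGG")
    # no internal stop codons
    internal <- substring(cds, seq(4, 144, 3), seq(6, 146, 3))
    expect_false(any(internal %in% c("TAA", "TAG", "TGA")))
    # introns start GT and end AG in transcript orientation
    ex <- tx$exons
    for (i in seq_len(nrow(ex) - 1)) {
      intron <- substr(tx$seq, ex$end[i] + 1, ex$start[i + 1] - 1)
      if (strand == "-") intron <- chartr("ACGT", "TGCA",
                                          paste(rev(strsplit(intron, "")[[1]]),
                                                collapse = ""))
      expect_equal(substr(intron, 1, 2), "GT")
      expect_equal(substr(intron, nchar(intron) - 1, nchar(intron)), "AG")
    }
  }
})

test_that("unsatisfiable codon constraints are rejected up front", {
  expect_error(toy_transcript_spec("X", cds_length = 30,
                                   codon_constraints = list(list(index = 20, codon = "CGC"))),
               "unsatisfiable")
  expect_error(toy_transcript_spec("X", cds_length = 30,
                                   codon_constraints = list(list(index = 5, codon = "TAA"))),
               "internal stop")
  expect_error(toy_transcript_spec("X", cds_length = 30,
                                   codon_constraints = list(list(index = 1, codon = "CGC"))),
               "ATG")
})

test_that("single-exon transcripts have no splice sites", {
  tx <- generate_transcript(toy_transcript_spec("ONE", cds_length = 60), seed = 2)
  expect_equal(nrow(tx$exons), 1L)
  outside <- max(tx$exons$end) + 1
  cons <- annotate_snv(list(contig = tx$contig, pos = outside,
                            ref = substr(tx$seq, outside, outside),
                            alt = setdiff(c("A", "C", "G", "T"),
                                          substr(tx$seq, outside, outside))[1]), tx)
  expect_equal(cons$category, "intergenic")
})

test_that("end-to-end causal recovery rate meets the closed-form expectation", {
  n_seeds <- 50
  spec <- cohort_spec()  # 1 case, 8 controls, 200 background @ q = 0.2
  unique_hits <- 0
  for (seed in seq_len(n_seeds)) {
    m <- generate_cohort(spec, seed = 1000 + seed)
    s1 <- stage1_segregation(m, filter_config())
    if (nrow(s1) == 1 && s1$pos == spec$causal$pos) unique_hits <- unique_hits + 1
  }
  q <- spec$background_alt_freq
  p_case <- q^2 * (1 - spec$missing_rate) * ppois(2, spec$mean_depth,
                                                  lower.tail = FALSE)
  p_ctrl <- (1 - spec$missing_rate) * (1 - q)^2 + spec$missing_rate
  p_bg_pass <- p_case^spec$n_cases * p_ctrl^spec$n_controls
  expected <- (1 - p_bg_pass)^spec$n_background_variants
  sigma <- sqrt(expected * (1 - expected) / n_seeds)
  expect_gte(unique_hits / n_seeds, expected - 4 * sigma)
})

test_that("simulated crosses aggregate into conserved genotype-count tables", {
  crosses <- list(
    list(parent1 = list(copa = "TT", mitf = "GG"),
         parent2 = list(copa = "CC", mitf = "GG"), n = 10),
    list(parent1 = list(copa = "CT", mitf = "GA"),
         parent2 = list(copa = "CC", mitf = "GG"), n = 30)
  )
  tab <- generate_genotyping_table(crosses = crosses, seed = 4)
  expect_equal(sum(tab$n_animals), 40)
  # forced cross: all offspring are white-hat T/C G/G cases
  forced <- generate_genotyping_table(crosses = crosses[1], seed = 4)
  expect_equal(nrow(forced), 1L)
  expect_equal(forced$phenotype_label, "white_hat")
  expect_equal(forced$genotype_copa, "C/T")
  expect_equal(forced$group, "case")
  expect_equal(nrow(generate_genotyping_table(crosses = list(), seed = 1)), 0L)
})
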