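test_that("stage 1 enforces the case-unique homozygous rule with strict depth", {
  cfg <- filter_config()
  # case hom_alt DP 5, four hom_ref controls -> pass
  m <- make_matrix(c("hom_alt", rep("hom_ref", 4)), c(5L, 9L, 9L, 9L, 9L))
  expect_equal(nrow(stage1_segregation(m, cfg)), 1L)
  # depth exactly 2 is not "greater than 2" -> fail
  m <- make_matrix(c("hom_alt", rep("hom_ref", 4)), c(2L, 9L, 9L, 9L, 9L))
  expect_equal(nrow(stage1_segregation(m, cfg)), 0L)
  # one het control disqualifies
  m <- make_matrix(c("hom_alt", "het", "hom_ref", "hom_ref", "hom_ref"),
                   c(9L, 9L, 9L, 9L, 9L))
  expect_equal(nrow(stage1_segregation(m, cfg)), 0L)
  # case het is never a homozygous candidate
  m <- make_matrix(c("het", rep("hom_ref", 4)), c(9L, 9L, 9L, 9L, 9L))
  expect_equal(nrow(stage1_segregation(m, cfg)), 0L)
  # missing control passes by default, fails under the strict switch
  m <- make_matrix(c("hom_alt", "missing", "hom_ref", "hom_ref", "hom_ref"),
                   c(9L, 0L, 9L, 9L, 9L))
  expect_equal(nrow(stage1_segregation(m, cfg)), 1L)
  strict <- filter_config(treat_missing_control_as = "fail")
  expect_equal(nrow(stage1_segregation(m, strict)), 0L)
})

test_that("stage 1 requires at least one case and one control", {
  m <- make_matrix(c("hom_alt", "hom_ref"), c(9L, 9L), n_case = 2)
  expect_error(stage1_segregation(m), "at least one case and one control")
})

test_that("stage 1 matches the brute-force oracle on random fixtures", {
  configs <- list(
    filter_config(),
    filter_config(min_case_depth = 0),
    filter_config(treat_missing_control_as = "fail"),
    filter_config(require_case_hom_alt = FALSE),
    filter_config(control_min_depth = 2)
  )
  for (seed in 1:100) {
    m <- random_gt_matrix(50, n_case = 2, n_ctrl = 4, seed = seed)
    cfg <- configs[[(seed %% length(configs)) + 1]]
    expect_equal(attr(stage1_segregation(m, cfg), "pass"),
                 oracle_stage1(m, cfg),
                 info = paste("seed", seed))
  }
})

test_that("pass set shrinks monotonically with more controls and higher depth threshold", {
  for (seed in 1:20) {
    m <- random_gt_matrix(60, n_case = 1, n_ctrl = 6, seed = seed)
    # dropping the last control can only grow the pass set
    fewer <- m
    keep <- seq_len(nrow(m$samples) - 1)
    fewer$samples <- m$samples[keep, ]
    fewer$gt <- m$gt[, keep, drop = FALSE]
    fewer$depth <- m$depth[, keep, drop = FALSE]
    p_full <- attr(stage1_segregation(m), "pass")
    p_fewer <- attr(stage1_segregation(fewer), "pass")
    expect_true(all(p_fewer | !p_full), info = paste("controls, seed", seed))
    # raising min_case_depth never adds variants
    p_lo <- attr(stage1_segregation(m, filter_config(min_case_depth = 2)), "pass")
    p_hi <- attr(stage1_segregation(m, filter_config(min_case_depth = 6)), "pass")
    expect_true(all(p_lo | !p_hi), info = paste("depth, seed", seed))
  }
})

test_that("stage 2 keeps CDS and splice-window positions, drops deep introns", {
  tx <- mitf_fixture()
  g33 <- genomic_position(33, tx)
  variants <- data.frame(
    contig = tx$contig,
    pos = c(genomic_position(10, tx),  # CDS
            g33 + 1,                   # donor +1
            g33 + 2,                   # donor +2, edge of window
            g33 + 50,                  # mid-intron
            1L),                       # flank, intergenic
    id = NA, ref = "G", alt = "A", stringsAsFactors = FALSE)
  kept <- stage2_region_restriction(variants, list(tx), splice_window = 2)
  expect_equal(kept$pos, variants$pos[1:3])
  # order preserved, empty transcript list yields empty output
  expect_equal(nrow(stage2_region_restriction(variants, list())), 0L)
})

test_that("stage 3 ranks gene-list membership above severity above input order", {
  variants <- data.frame(contig = "c1", pos = c(10L, 20L, 30L, 40L),
                         id = NA, ref = "G", alt = "A",
                         stringsAsFactors = FALSE)
  cons <- data.frame(
    gene = c("OTHER1", "COPA", "OTHER2", "OTHER3"),
    category = c("synonymous", "missense", "stop_gained", "missense"),
    stringsAsFactors = FALSE)
  ranked <- stage3_prioritize(variants, cons, gene_list = "COPA")
  expect_equal(ranked$gene, c("COPA", "OTHER2", "OTHER3", "OTHER1"))
  expect_equal(ranked$rank, 1:4)
  # identical keys keep input order (stable tie-break)
  cons2 <- data.frame(gene = c("A", "B", "C"), category = "missense",
                      stringsAsFactors = FALSE)
  ranked2 <- stage3_prioritize(variants[1:3, ], cons2)
  expect_equal(ranked2$pos, c(10L, 20L, 30L))
  expect_error(stage3_prioritize(variants, cons2), "align 1:1")
})

test_that("the funnel recovers a planted causal variant inside a transcript CDS", {
  tx <- copa_fixture()
  g <- genomic_position(478, tx)
  spec <- cohort_spec(causal = list(contig = tx$contig, pos = g,
                                    ref = "G", alt = "A"),
                      contig_length = nchar(tx$seq) * 100L,
                      n_background_variants = 200)
  m <- generate_cohort(spec, seed = 77)
  report <- run_filter(m, filter_config(), list(tx), gene_list = "COPA",
                       quiet = TRUE)
  expect_equal(report$n_input, 201L)
  expect_true(report$n_pass_stage2 <= report$n_pass_stage1)
  expect_true(g %in% report$candidates$pos)
  top <- report$candidates[1, ]
  expect_equal(top$pos, g)
  expect_equal(top$gene, "COPA")
  expect_equal(top$category, "missense")
})

test_that("degenerate inputs: all-hom-ref matrix and zero depth threshold", {
  m <- make_matrix(matrix("hom_ref", 3, 5), matrix(9L, 3, 5))
  report <- run_filter(m, quiet = TRUE)
  expect_equal(report$n_pass_stage1, 0L)
  # depth-0 planted call passes when the threshold is relaxed to 0
  m2 <- make_matrix(c("hom_alt", rep("hom_ref", 4)), c(0L, 9L, 9L, 9L, 9L))
  expect_equal(nrow(stage1_segregation(m2, filter_config(min_case_depth = 0))), 1L)
  expect_equal(nrow(stage1_segregation(m2, filter_config())), 0L)
})
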