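# Fixture builders and independent oracles used across the suite.

GT4 <- c("hom_ref", "het", "hom_alt", "missing")

# Small genotype matrix from explicit call strings; rows are variants,
# columns samples (first n_case columns are cases).
make_matrix <- function(gt, depth, n_case = 1,
                        pos = NULL, ref = "G", alt = "A") {
  gt <- rbind(gt)
  depth <- rbind(depth)
  n_var <- nrow(gt); n_samp <- ncol(gt)
  if (is.null(pos)) pos <- seq_len(n_var) * 100L
  variants <- data.frame(contig = rep_len("c1", n_var), pos = pos,
                         id = rep_len(NA_character_, n_var),
                         ref = rep_len(ref, n_var), alt = rep_len(alt, n_var),
                         stringsAsFactors = FALSE)
  roles <- c(rep("case", n_case), rep("control", n_samp - n_case))
  samples <- data.frame(sample_id = sprintf("s%d", seq_len(n_samp)),
                        phenotype_label = ifelse(roles == "case", "Black crystal", "other"),
                        role = roles, stringsAsFactors = FALSE)
  genotype_matrix(variants, samples, gt, depth)
}

# Random genotype matrix for property tests.
random_gt_matrix <- function(n_var, n_case, n_ctrl, seed) {
  set.seed(seed)
  n_samp <- n_case + n_ctrl
  gt <- matrix(sample(GT4, n_var * n_samp, replace = TRUE,
                      prob = c(0.35, 0.25, 0.3, 0.1)),
               n_var, n_samp)
  depth <- matrix(rpois(n_var * n_samp, 4), n_var, n_samp)
  make_matrix(gt, depth, n_case = n_case,
              pos = sort(sample.int(1e6, n_var)))
}

# Naive double-loop re-implementation of the stage-1 segregation rule,
# deliberately structured sample-by-sample.
oracle_stage1 <- function(mat, config) {
  pass <- logical(nrow(mat$variants))
  for (i in seq_along(pass)) {
    ok <- TRUE
    for (j in seq_len(nrow(mat$samples))) {
      gt <- mat$gt[i, j]; dp <- mat$depth[i, j]
      role <- mat$samples$role[j]
      if (role == "case") {
        if (config$require_case_hom_alt) {
          if (gt != "hom_alt") ok <- FALSE
        } else if (!gt %in% c("het", "hom_alt")) ok <- FALSE
        if (dp < config$min_case_depth) ok <- FALSE
      } else if (role == "control") {
        g <- gt
        if (config$control_min_depth > 0 && dp < config$control_min_depth) {
          g <- "missing"
        }
        if (g %in% config$control_disallowed) ok <- FALSE
        if (g == "missing" && config$treat_missing_control_as == "fail") ok <- FALSE
      }
    }
    pass[i] <- ok
  }
  pass
}

# Transcript fixtures reproducing the two worked annotation cases.
copa_fixture <- function(seed = 42) {
  generate_transcript(
    toy_transcript_spec("COPA", strand = "-", cds_length = 489,
                        codon_constraints = list(list(index = 160, codon = "CGC")),
                        n_exons = 6, intron_lengths = 120),
    seed = seed
  )
}

mitf_fixture <- function(seed = 11) {
  generate_transcript(
    toy_transcript_spec("MITF", strand = "+", cds_length = 120,
                        exon_breaks = 33),
    seed = seed
  )
}

# Exact table probability at fixed margins via log-factorials -- an
# arithmetic route independent of dhyper.
table_prob_factorial <- function(a, b, c, d) {
  exp(lfactorial(a + b) + lfactorial(c + d) + lfactorial(a + c) + lfactorial(b + d) -
        lfactorial(a + b + c + d) - lfactorial(a) - lfactorial(b) -
        lfactorial(c) - lfactorial(d))
}

# Fisher two-sided p by explicit enumeration of every table with the
# observed margins, using the factorial formula above.
oracle_fisher <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c
  support <- max(0, c1 - r2):min(r1, c1)
  probs <- vapply(support, function(x) {
    table_prob_factorial(x, r1 - x, c1 - x, r2 - c1 + x)
  }, numeric(1))
  p_obs <- probs[match(a, support)]
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

# Minimal VCF writer for hand-built records (header + given body lines).
write_test_vcf <- function(path, body, samples = c("s1", "s2")) {
  writeLines(c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"),
    body
  ), path)
  path
}

pheno_df <- function(ids, roles) {
  data.frame(sample_id = ids,
             phenotype_label = ifelse(roles == "case", "Black crystal", "other"),
             role = roles, stringsAsFactors = FALSE)
}
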