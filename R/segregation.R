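# Candidate-selection funnel for a Mendelian coat-colour trait:
#   stage 1 — variants homozygous-alternate with adequate depth in every
#             case and never het/hom-alt in any control;
#   stage 2 — restriction to CDS exons and splice-window positions;
#   stage 3 — ranking by membership in a pigmentation-gene list, then by
#             consequence severity, then input order.

#' Segregation filter configuration
#'
#' @param min_case_depth minimum read depth required of every case call
#'   (default 3, i.e. coverage strictly greater than 2).
#' @param require_case_hom_alt if `TRUE` (default) cases must be homozygous
#'   for the alternate allele; if `FALSE` any carrier call (het or hom_alt)
#'   is accepted, for dominant-model reanalysis.
#' @param control_disallowed genotype states that disqualify a variant when
#'   seen in any control (default `het` and `hom_alt`).
#' @param treat_missing_control_as `"pass"` (default) or `"fail"`: whether a
#'   missing control call leaves a variant eligible. The selection criterion
#'   names only observed het/hom states, so missing passes by default.
#' @param control_min_depth controls with depth below this are treated as
#'   missing (default 0, i.e. the depth requirement applies to cases only).
#' @param splice_window intronic bases from an exon boundary kept by stage 2.
#' @return Object of class `filter_config`.
#' @export
filter_config <- function(min_case_depth = 3,
                          require_case_hom_alt = TRUE,
                          control_disallowed = c("het", "hom_alt"),
                          treat_missing_control_as = c("pass", "fail"),
                          control_min_depth = 0,
                          splice_window = 2) {
  treat_missing_control_as <- match.arg(treat_missing_control_as)
  if (min_case_depth < 0) stop("min_case_depth must be >= 0")
  if (!all(control_disallowed %in% GT_STATES)) {
    stop("control_disallowed must be a subset of: ", paste(GT_STATES, collapse = ", "))
  }
  if (splice_window < 0) stop("splice_window must be >= 0")
  structure(list(min_case_depth = min_case_depth,
                 require_case_hom_alt = require_case_hom_alt,
                 control_disallowed = control_disallowed,
                 treat_missing_control_as = treat_missing_control_as,
                 control_min_depth = control_min_depth,
                 splice_window = splice_window),
            class = "filter_config")
}

#' Stage 1: case-unique homozygous segregation filter
#'
#' A variant passes iff every case sample is homozygous-alternate with depth
#' at least `min_case_depth`, and no control sample shows a disallowed
#' genotype. Input order is preserved.
#'
#' @param matrix a [genotype_matrix()] with at least one case and one
#'   control sample.
#' @param config a [filter_config()].
#' @return data.frame of passing variants (subset of `matrix$variants`),
#'   with the logical pass vector in attribute `"pass"`.
#' @export
stage1_segregation <- function(matrix, config = filter_config()) {
  stopifnot(inherits(matrix, "genotype_matrix"))
  roles <- matrix$samples$role
  case_idx <- which(roles == "case")
  ctrl_idx <- which(roles == "control")
  if (length(case_idx) == 0 || length(ctrl_idx) == 0) {
    stop("segregation filter undefined: need at least one case and one control sample")
  }
  gt <- matrix$gt
  dp <- matrix$depth
  n <- nrow(gt)
  if (n == 0) {
    out <- matrix$variants
    attr(out, "pass") <- logical(0)
    return(out)
  }

  case_gt <- gt[, case_idx, drop = FALSE]
  case_state_ok <- if (config$require_case_hom_alt) {
    case_gt == "hom_alt"
  } else {
    array(case_gt %in% c("het", "hom_alt"), dim = dim(case_gt))
  }
  case_ok <- case_state_ok & (dp[, case_idx, drop = FALSE] >= config$min_case_depth)

  ctrl_gt <- gt[, ctrl_idx, drop = FALSE]
  if (config$control_min_depth > 0) {
    ctrl_gt[dp[, ctrl_idx, drop = FALSE] < config$control_min_depth] <- "missing"
  }
  bad <- array(ctrl_gt %in% config$control_disallowed, dim = dim(ctrl_gt))
  if (config$treat_missing_control_as == "fail") {
    bad <- bad | (ctrl_gt == "missing")
  }

  pass <- row_all(case_ok) & row_all(!bad)
  out <- matrix$variants[pass, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "pass") <- pass
  out
}

#' Stage 2: restrict to coding exons and splice windows
#'
#' Keeps variants located in any CDS exon part of any transcript, or within
#' `splice_window` bases of an exon/intron boundary on the intron side.
#'
#' @param variants data.frame of variants (`contig`, `pos`, ...).
#' @param transcripts list of [transcript_model()] objects.
#' @param splice_window non-negative integer (default 2).
#' @return the kept variants, input order preserved.
#' @export
stage2_region_restriction <- function(variants, transcripts, splice_window = 2) {
  if (splice_window < 0) stop("splice_window must be >= 0")
  n <- nrow(variants)
  keep <- logical(n)
  for (tx in transcripts) {
    on_contig <- variants$contig == tx$contig
    if (!any(on_contig)) next
    pos <- variants$pos
    segs <- cds_segments(tx)
    in_cds <- rep(FALSE, n)
    for (j in seq_len(nrow(segs))) {
      in_cds <- in_cds | (pos >= segs$start[j] & pos <= segs$end[j])
    }
    in_splice <- rep(FALSE, n)
    ex <- tx$exons
    if (nrow(ex) > 1 && splice_window > 0) {
      for (j in seq_len(nrow(ex) - 1)) {
        intron <- c(ex$end[j] + 1, ex$start[j + 1] - 1)
        lo1 <- intron[1]; hi1 <- min(intron[2], intron[1] + splice_window - 1)
        hi2 <- intron[2]; lo2 <- max(intron[1], intron[2] - splice_window + 1)
        in_splice <- in_splice |
          (pos >= lo1 & pos <= hi1) | (pos >= lo2 & pos <= hi2)
      }
    }
    keep <- keep | (on_contig & (in_cds | in_splice))
  }
  out <- variants[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

severity_rank <- function(category) {
  rank <- c(stop_gained = 1, stop_lost = 1,
            splice_donor = 2, splice_acceptor = 2,
            missense = 3, synonymous = 4)
  out <- unname(rank[category])
  out[is.na(out)] <- 5  # non-coding / intronic / utr / intergenic
  out
}

#' Stage 3: prioritise candidates
#'
#' Deterministic ranking: (1) variant's gene on the supplied gene list,
#' (2) consequence severity (stop > splice > missense > synonymous >
#' non-coding), (3) input order as tie-break.
#'
#' @param variants data.frame of variants.
#' @param consequences data.frame aligned 1:1 with `variants` (columns
#'   `gene`, `category` at minimum), as from [annotate_variants()].
#' @param gene_list character vector of gene symbols of interest.
#' @return data.frame of variants joined to their consequences, ordered by
#'   rank, with columns `rank`, `in_gene_list`, `severity`.
#' @export
stage3_prioritize <- function(variants, consequences, gene_list = character()) {
  if (nrow(variants) != nrow(consequences)) {
    stop("variants and consequences must align 1:1 (",
         nrow(variants), " vs ", nrow(consequences), " rows)")
  }
  in_list <- !is.na(consequences$gene) & consequences$gene %in% gene_list
  sev <- severity_rank(consequences$category)
  ord <- order(!in_list, sev, seq_len(nrow(variants)))
  keep_cols <- setdiff(names(consequences), c("contig", "pos", "ref", "alt"))
  out <- cbind(variants, consequences[, keep_cols, drop = FALSE])
  out <- out[ord, , drop = FALSE]
  out$in_gene_list <- in_list[ord]
  out$severity <- sev[ord]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Run the full candidate-selection funnel
#'
#' @param matrix a [genotype_matrix()].
#' @param config a [filter_config()].
#' @param transcripts list of [transcript_model()] objects.
#' @param gene_list character vector of pigmentation-gene symbols.
#' @param quiet suppress per-stage count messages.
#' @return Object of class `filter_report` with `n_input`, `n_pass_stage1`,
#'   `n_pass_stage2` and the ranked `candidates` data.frame.
#' @export
run_filter <- function(matrix, config = filter_config(), transcripts = list(),
                       gene_list = character(), quiet = FALSE) {
  s1 <- stage1_segregation(matrix, config)
  s2 <- stage2_region_restriction(s1, transcripts, config$splice_window)
  cons <- annotate_variants(s2, transcripts, config$splice_window)
  candidates <- stage3_prioritize(s2, cons, gene_list)
  report <- structure(
    list(n_input = nrow(matrix$variants),
         n_pass_stage1 = nrow(s1),
         n_pass_stage2 = nrow(s2),
         stage1_variants = s1,
         candidates = candidates),
    class = "filter_report"
  )
  if (!quiet) {
    message(sprintf("segregation funnel: %d input -> %d segregating -> %d coding/splice",
                    report$n_input, report$n_pass_stage1, report$n_pass_stage2))
  }
  report
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf("<filter_report> input %d | stage1 %d | stage2 %d\n",
              x$n_input, x$n_pass_stage1, x$n_pass_stage2))
  if (nrow(x$candidates) > 0) {
    top <- x$candidates[1, ]
    cat(sprintf("  top candidate: %s:%d %s>%s (%s, %s)\n",
                top$contig, top$pos, top$ref, top$alt,
                ifelse(is.na(top$gene), "no gene", top$gene), top$category))
  }
  invisible(x)
}
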