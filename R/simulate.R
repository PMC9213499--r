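# Synthetic cohorts and toy transcripts, so every pipeline stage runs
# end-to-end without external data. A cohort is a multi-sample genotype
# matrix with one planted causal variant perfectly concordant with case
# status (full penetrance, as expected of a Mendelian trait), background
# variants drawn from Hardy-Weinberg proportions, Poisson read depths and
# occasional missing calls. A toy transcript is a random CDS satisfying
# user-imposed codon constraints, embedded in a genomic contig with GT/AG
# introns on either strand.

#' Specification for a synthetic case/control cohort
#'
#' Defaults mirror a single-case discovery design: one sequenced case
#' against eight controls, 200 background variants at alternate-allele
#' frequency 0.2, mean depth 8x and 2% missing calls.
#'
#' @param n_cases number of case samples (>= 1).
#' @param n_controls number of control samples (>= 1).
#' @param n_background_variants background (non-causal) variant count.
#' @param background_alt_freq alternate-allele frequency for background
#'   genotypes, drawn per sample from Hardy-Weinberg proportions.
#' @param mean_depth Poisson mean of per-call read depth.
#' @param missing_rate probability a call is masked to missing; causal-site
#'   case calls are never masked.
#' @param causal list with `contig`, `pos`, `ref`, `alt` for the planted
#'   variant (hom_alt in every case, hom_ref in every control).
#' @param causal_min_case_depth lower bound on causal case depth (depths
#'   are drawn from the truncated Poisson), so the planted signal is always
#'   callable; default 3.
#' @param contig_length coordinate space for background positions.
#' @param seed default RNG seed used by [generate_cohort()].
#' @return Object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_cases = 1, n_controls = 8,
                        n_background_variants = 200,
                        background_alt_freq = 0.2,
                        mean_depth = 8, missing_rate = 0.02,
                        causal = list(contig = "ctg1", pos = 4876673L,
                                      ref = "G", alt = "A"),
                        causal_min_case_depth = 3,
                        contig_length = 10000000L, seed = 1L) {
  if (n_cases < 1 || n_controls < 1) stop("need n_cases >= 1 and n_controls >= 1")
  if (n_background_variants < 0) stop("n_background_variants must be >= 0")
  if (background_alt_freq < 0 || background_alt_freq > 1) {
    stop("background_alt_freq must be in [0, 1]")
  }
  if (missing_rate < 0 || missing_rate > 1) stop("missing_rate must be in [0, 1]")
  if (mean_depth <= 0) stop("mean_depth must be positive")
  stopifnot(all(c("contig", "pos", "ref", "alt") %in% names(causal)))
  if (causal$pos > contig_length) stop("causal position beyond contig_length")
  structure(list(n_cases = n_cases, n_controls = n_controls,
                 n_background_variants = n_background_variants,
                 background_alt_freq = background_alt_freq,
                 mean_depth = mean_depth, missing_rate = missing_rate,
                 causal = causal,
                 causal_min_case_depth = causal_min_case_depth,
                 contig_length = contig_length, seed = seed),
            class = "cohort_spec")
}

# Poisson deviates conditioned on >= lower.
rpois_truncated <- function(n, lambda, lower) {
  x <- stats::rpois(n, lambda)
  while (any(x < lower)) {
    x[x < lower] <- stats::rpois(sum(x < lower), lambda)
  }
  x
}

#' Generate a synthetic cohort
#'
#' @param spec a [cohort_spec()].
#' @param seed RNG seed; defaults to `spec$seed`.
#' @return A [genotype_matrix()] with case samples labelled
#'   `"Black crystal"` and controls `"Standard dark brown"`; the planted
#'   variant's row index is in attribute `"causal_index"`.
#' @export
generate_cohort <- function(spec, seed = spec$seed) {
  stopifnot(inherits(spec, "cohort_spec"))
  n_samp <- spec$n_cases + spec$n_controls
  samples <- data.frame(
    sample_id = c(sprintf("case_%d", seq_len(spec$n_cases)),
                  sprintf("control_%d", seq_len(spec$n_controls))),
    phenotype_label = c(rep("Black crystal", spec$n_cases),
                        rep("Standard dark brown", spec$n_controls)),
    role = c(rep("case", spec$n_cases), rep("control", spec$n_controls)),
    stringsAsFactors = FALSE
  )
  with_rng_seed(seed, {
    nb <- spec$n_background_variants
    pos <- integer(0)
    if (nb > 0) {
      pos <- sample.int(spec$contig_length, nb)
      while (any(dup <- pos == spec$causal$pos | duplicated(pos))) {
        pos[dup] <- sample.int(spec$contig_length, sum(dup))
      }
    }
    ref <- sample(DNA_BASES, nb, replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(DNA_BASES, r), 1),
                  character(1), USE.NAMES = FALSE)
    variants <- data.frame(
      contig = rep(spec$causal$contig, nb + 1L),
      pos = c(pos, spec$causal$pos),
      id = NA_character_,
      ref = c(ref, spec$causal$ref),
      alt = c(alt, spec$causal$alt),
      stringsAsFactors = FALSE
    )
    ord <- order(variants$pos)
    variants <- variants[ord, , drop = FALSE]
    rownames(variants) <- NULL
    causal_row <- which(variants$pos == spec$causal$pos)

    # background genotypes: per-sample alternate-allele dosage ~ Binom(2, q)
    dosage <- matrix(stats::rbinom(nb * n_samp, 2, spec$background_alt_freq),
                     nrow = nb, ncol = n_samp)
    gt <- matrix("hom_ref", nb + 1L, n_samp)
    if (nb > 0) {
      gt[-causal_row, ] <- c("hom_ref", "het", "hom_alt")[dosage + 1L]
    }
    gt[causal_row, ] <- c(rep("hom_alt", spec$n_cases),
                          rep("hom_ref", spec$n_controls))

    depth <- matrix(stats::rpois((nb + 1L) * n_samp, spec$mean_depth),
                    nrow = nb + 1L, ncol = n_samp)
    case_cols <- seq_len(spec$n_cases)
    depth[causal_row, case_cols] <- rpois_truncated(
      spec$n_cases, spec$mean_depth, spec$causal_min_case_depth)

    mask <- matrix(stats::runif((nb + 1L) * n_samp) < spec$missing_rate,
                   nrow = nb + 1L, ncol = n_samp)
    mask[causal_row, case_cols] <- FALSE
    gt[mask] <- "missing"

    out <- genotype_matrix(variants, samples, gt, depth)
    attr(out, "causal_index") <- causal_row
    out
  })
}

#' Specification for a toy transcript
#'
#' @param gene gene symbol for the fixture.
#' @param strand `"+"` or `"-"`.
#' @param cds_length CDS length in bases, a multiple of 3 (includes start
#'   and stop codons).
#' @param codon_constraints list of `list(index =, codon =)` requirements;
#'   e.g. `list(list(index = 160, codon = "CGC"))` pins an Arg codon at
#'   residue 160. Constraints on the first codon must be ATG, on the last a
#'   stop codon; internal constraints must be sense codons.
#' @param exon_breaks coding positions after which an intron is inserted
#'   (strictly increasing, inside 1..cds_length-1 after UTR shift); `NULL`
#'   with `n_exons` splits the transcript evenly.
#' @param n_exons exon count when `exon_breaks` is `NULL`.
#' @param intron_lengths intron length(s), recycled (minimum 10).
#' @param utr5_length,utr3_length untranslated flanks inside the terminal
#'   exons.
#' @param flank intergenic padding on each side of the transcript.
#' @param transcript_id,contig identifiers (defaults derived from `gene`).
#' @return Object of class `toy_transcript_spec`.
#' @export
toy_transcript_spec <- function(gene, strand = "+", cds_length = 300,
                                codon_constraints = list(),
                                exon_breaks = NULL, n_exons = 1,
                                intron_lengths = 150,
                                utr5_length = 0, utr3_length = 0,
                                flank = 100,
                                transcript_id = paste0(gene, ".t1"),
                                contig = paste0(gene, "_ctg")) {
  if (cds_length %% 3 != 0 || cds_length < 6) {
    stop("cds_length must be a multiple of 3 and >= 6")
  }
  n_codons <- cds_length / 3
  for (con in codon_constraints) {
    if (con$index < 1 || con$index > n_codons) {
      stop("unsatisfiable codon constraint: index ", con$index,
           " outside 1..", n_codons)
    }
    if (con$index == 1 && con$codon != "ATG") {
      stop("unsatisfiable codon constraint: first codon must be ATG")
    }
    if (con$index == n_codons && !con$codon %in% STOP_CODONS) {
      stop("unsatisfiable codon constraint: last codon must be a stop")
    }
    if (con$index > 1 && con$index < n_codons && con$codon %in% STOP_CODONS) {
      stop("unsatisfiable codon constraint: internal stop codon at ", con$index)
    }
  }
  if (is.null(exon_breaks) && n_exons > 1) {
    mrna_len <- utr5_length + cds_length + utr3_length
    exon_breaks <- round(seq_len(n_exons - 1) * mrna_len / n_exons)
  }
  if (!is.null(exon_breaks)) {
    mrna_len <- utr5_length + cds_length + utr3_length
    breaks <- utr5_length + exon_breaks  # given in coding coordinates
    if (any(diff(c(0, breaks, mrna_len)) < 1)) {
      stop("exon_breaks must be strictly increasing inside the transcript")
    }
    exon_breaks <- breaks
  }
  if (any(intron_lengths < 10)) stop("intron_lengths must be >= 10")
  structure(list(gene = gene, strand = strand, cds_length = cds_length,
                 codon_constraints = codon_constraints,
                 exon_breaks = exon_breaks,
                 intron_lengths = intron_lengths,
                 utr5_length = utr5_length, utr3_length = utr3_length,
                 flank = flank, transcript_id = transcript_id,
                 contig = contig),
            class = "toy_transcript_spec")
}

#' Generate a toy transcript and its genomic contig
#'
#' Builds a random CDS (ATG start, sense internal codons, single terminal
#' stop) honouring every codon constraint, splits it into exons at the
#' requested break points, inserts GT/AG-bounded introns and flanking
#' sequence, and, for minus-strand specs, reverse-complements the whole
#' construct so the genomic contig carries the transcript on the minus
#' strand.
#'
#' @param spec a [toy_transcript_spec()].
#' @param seed RNG seed (deterministic output for a given spec + seed).
#' @return A [transcript_model()] carrying the contig sequence.
#' @export
generate_transcript <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "toy_transcript_spec"))
  with_rng_seed(seed, {
    n_codons <- spec$cds_length / 3
    sense <- setdiff(names(Biostrings::GENETIC_CODE), STOP_CODONS)
    codons <- c("ATG",
                sample(sense, n_codons - 2, replace = TRUE),
                sample(STOP_CODONS, 1))
    for (con in spec$codon_constraints) codons[con$index] <- con$codon
    cds <- paste(codons, collapse = "")
    mrna <- paste0(random_dna(spec$utr5_length), cds, random_dna(spec$utr3_length))
    mrna_len <- nchar(mrna)

    breaks <- spec$exon_breaks
    starts <- c(1, breaks + 1)
    ends <- c(breaks, mrna_len)
    n_ex <- length(starts)
    intron_len <- rep_len(spec$intron_lengths, max(0, n_ex - 1))
    introns <- vapply(intron_len, function(l) {
      paste0("GT", random_dna(l - 4), "AG")
    }, character(1))

    # transcript-oriented layout
    pieces <- character(0)
    exon_t <- data.frame(start = integer(n_ex), end = integer(n_ex))
    offset <- spec$flank
    pieces <- random_dna(spec$flank)
    for (i in seq_len(n_ex)) {
      ex_seq <- substr(mrna, starts[i], ends[i])
      exon_t$start[i] <- offset + 1
      exon_t$end[i] <- offset + nchar(ex_seq)
      offset <- offset + nchar(ex_seq)
      pieces <- paste0(pieces, ex_seq)
      if (i < n_ex) {
        pieces <- paste0(pieces, introns[i])
        offset <- offset + nchar(introns[i])
      }
    }
    pieces <- paste0(pieces, random_dna(spec$flank))
    total <- nchar(pieces)

    # genomic position of a transcript-oriented mRNA coordinate
    mrna_to_t <- function(m) {
      cum <- cumsum(ends - starts + 1)
      i <- which(m <= cum)[1]
      into <- m - (if (i > 1) cum[i - 1] else 0)
      exon_t$start[i] + into - 1
    }
    cds_t <- c(mrna_to_t(spec$utr5_length + 1),
               mrna_to_t(spec$utr5_length + spec$cds_length))

    if (spec$strand == "+") {
      contig_seq <- pieces
      exons <- exon_t
      cds_bounds <- cds_t
    } else {
      contig_seq <- revcomp(pieces)
      exons <- data.frame(start = total - exon_t$end + 1,
                          end = total - exon_t$start + 1)
      cds_bounds <- total - cds_t + 1
    }
    transcript_model(
      gene = spec$gene, transcript_id = spec$transcript_id,
      contig = spec$contig, strand = spec$strand,
      exons = exons,
      cds_start = min(cds_bounds), cds_end = max(cds_bounds),
      seq = contig_seq, validate = TRUE
    )
  })
}

#' Write a transcript model as GFF3 + FASTA
#'
#' @param tx a [transcript_model()] carrying its contig sequence.
#' @param gff3_path,fasta_path output paths.
#' @return named character vector of the two paths, invisibly.
#' @export
write_transcript_files <- function(tx, gff3_path, fasta_path) {
  gid <- paste0("gene:", tx$gene)
  tid <- paste0("transcript:", tx$transcript_id)
  span <- c(min(tx$exons$start), max(tx$exons$end))
  lines <- c(
    "##gff-version 3",
    sprintf("%s\tminkseg\tgene\t%d\t%d\t.\t%s\t.\tID=%s;Name=%s",
            tx$contig, span[1], span[2], tx$strand, gid, tx$gene),
    sprintf("%s\tminkseg\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
            tx$contig, span[1], span[2], tx$strand, tid, gid)
  )
  for (i in seq_len(nrow(tx$exons))) {
    lines <- c(lines, sprintf("%s\tminkseg\texon\t%d\t%d\t.\t%s\t.\tParent=%s",
                              tx$contig, tx$exons$start[i], tx$exons$end[i],
                              tx$strand, tid))
  }
  segs <- cds_segments(tx)
  seg_order <- if (tx$strand == "+") seq_len(nrow(segs)) else rev(seq_len(nrow(segs)))
  cum <- 0
  phase <- integer(nrow(segs))
  for (i in seg_order) {
    phase[i] <- (3 - cum %% 3) %% 3
    cum <- cum + segs$end[i] - segs$start[i] + 1
  }
  for (i in seq_len(nrow(segs))) {
    lines <- c(lines, sprintf("%s\tminkseg\tCDS\t%d\t%d\t.\t%s\t%d\tParent=%s",
                              tx$contig, segs$start[i], segs$end[i],
                              tx$strand, phase[i], tid))
  }
  writeLines(lines, gff3_path)
  seqs <- Biostrings::DNAStringSet(stats::setNames(tx$seq, tx$contig))
  Biostrings::writeXStringSet(seqs, fasta_path, width = 70)
  invisible(c(gff3 = gff3_path, fasta = fasta_path))
}

#' Generate a genotype-count table from simulated crosses
#'
#' Offspring genotypes come from [simulate_cross()], phenotype labels from
#' [predict_phenotype()], and rows are aggregated by (phenotype, genotype
#' pair). Animals whose predicted class involves the Cr-driven white
#' phenotypes (`white_hat`, `completely_white`) are grouped as cases.
#'
#' @param rules a [phenotype_rules()] rule set.
#' @param crosses list of `list(parent1 =, parent2 =, n =)` cross
#'   specifications (parents as in [simulate_cross()]).
#' @param seed RNG seed.
#' @return data.frame of genotype count rows (`phenotype_label`, `group`,
#'   `genotype_copa`, `genotype_mitf`, `n_animals`).
#' @export
generate_genotyping_table <- function(rules = phenotype_rules(), crosses,
                                      seed = 1L) {
  offspring <- with_rng_seed(seed, {
    do.call(rbind, lapply(crosses, function(cr) {
      simulate_cross(cr$parent1, cr$parent2, cr$n)
    }))
  })
  if (is.null(offspring) || nrow(offspring) == 0) {
    return(data.frame(phenotype_label = character(0), group = character(0),
                      genotype_copa = character(0), genotype_mitf = character(0),
                      n_animals = integer(0), stringsAsFactors = FALSE))
  }
  pred <- predict_phenotype(offspring$copa, offspring$mitf, rules)
  fmt <- function(g) paste(substr(g, 1, 1), substr(g, 2, 2), sep = "/")
  tab <- stats::aggregate(
    list(n_animals = rep(1L, nrow(pred))),
    by = list(phenotype_label = pred$class,
              genotype_copa = fmt(pred$copa),
              genotype_mitf = fmt(pred$mitf)),
    FUN = sum
  )
  tab$group <- ifelse(tab$phenotype_label %in% c("white_hat", "completely_white"),
                      "case", "control")
  tab[order(tab$group, tab$phenotype_label, tab$genotype_copa, tab$genotype_mitf),
      c("phenotype_label", "group", "genotype_copa", "genotype_mitf", "n_animals")]
}
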