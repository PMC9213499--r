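# Minimal coding-consequence annotator for SNVs. Translates a genomic
# substitution into HGVS-style c. and p. descriptions against a transcript
# model: missense / synonymous / stop gain-loss in the CDS, donor/acceptor
# calls within the canonical 2-bp splice window, UTR and intergenic
# otherwise. Minus-strand transcripts have their genomic alleles
# reverse-complemented into cDNA space before codon lookup, which is how a
# genomic G>A can surface as c.478C>T.

#' Annotate a single-nucleotide variant against a transcript
#'
#' @param variant list or one-row data.frame with `contig`, `pos`, `ref`,
#'   `alt` (single bases; anything longer is rejected as unsupported).
#' @param transcript a [transcript_model()].
#' @param splice_window intronic distance (bases) from an exon boundary
#'   within which a variant is called splice_donor / splice_acceptor.
#'   Default 2, the canonical GT/AG dinucleotide.
#' @return Object of class `consequence`: gene, category, c. position and
#'   offset, cDNA-strand alleles, codon and amino-acid change where coding,
#'   plus formatted `hgvs_c` / `hgvs_p` strings.
#' @export
annotate_snv <- function(variant, transcript, splice_window = 2) {
  v <- as.list(variant)
  tx <- transcript
  if (nchar(v$ref) != 1 || nchar(v$alt) != 1 ||
      !v$ref %in% DNA_BASES || !v$alt %in% DNA_BASES) {
    stop("unsupported variant (not a SNV): ", v$ref, ">", v$alt)
  }
  if (v$contig != tx$contig) {
    stop("variant contig ", v$contig, " does not match transcript contig ", tx$contig)
  }
  if (v$pos < 1 || v$pos > nchar(tx$seq)) stop("variant position off contig")

  cp <- cdna_position(v$pos, tx)
  ref_c <- if (tx$strand == "-") revcomp(v$ref) else v$ref
  alt_c <- if (tx$strand == "-") revcomp(v$alt) else v$alt

  res <- list(
    gene = tx$gene, transcript_id = tx$transcript_id,
    contig = v$contig, pos = v$pos, ref = v$ref, alt = v$alt,
    region = cp$region, cdna_pos = cp$pos, cdna_offset = cp$offset,
    ref_cdna = ref_c, alt_cdna = alt_c,
    codon_index = NA_integer_, ref_codon = NA_character_,
    alt_codon = NA_character_, ref_aa = NA_character_, alt_aa = NA_character_,
    category = NA_character_, hgvs_c = NA_character_, hgvs_p = NA_character_
  )

  if (cp$region == "intergenic") {
    res$category <- "intergenic"
  } else if (cp$region == "utr") {
    res$category <- "utr"
  } else if (cp$region == "intronic") {
    if (abs(cp$offset) <= splice_window) {
      res$category <- if (cp$offset > 0) "splice_donor" else "splice_acceptor"
    } else {
      res$category <- "intronic"
    }
    if (!is.na(cp$pos)) {
      res$hgvs_c <- sprintf("c.%d%+d%s>%s", cp$pos, cp$offset, ref_c, alt_c)
    }
  } else { # cds
    cds <- cds_sequence(tx)
    tx_ref <- substr(cds, cp$pos, cp$pos)
    if (tx_ref != ref_c) {
      warning(sprintf(
        "reference mismatch at c.%d of %s: transcript has %s, variant ref (cDNA) is %s",
        cp$pos, tx$transcript_id, tx_ref, ref_c))
    }
    cd <- codon_of(cp$pos, nchar(cds))
    ref_codon <- substr(cds, (cd$codon_index - 1) * 3 + 1, cd$codon_index * 3)
    alt_codon <- ref_codon
    substr(alt_codon, cd$offset_in_codon + 1, cd$offset_in_codon + 1) <- alt_c
    ref_aa <- translate_codon(ref_codon)
    alt_aa <- translate_codon(alt_codon)
    res$codon_index <- cd$codon_index
    res$ref_codon <- ref_codon
    res$alt_codon <- alt_codon
    res$ref_aa <- ref_aa
    res$alt_aa <- alt_aa
    res$category <- if (ref_aa == alt_aa) {
      "synonymous"
    } else if (alt_aa == "*") {
      "stop_gained"
    } else if (ref_aa == "*") {
      "stop_lost"
    } else {
      "missense"
    }
    res$hgvs_c <- sprintf("c.%d%s>%s", cp$pos, ref_c, alt_c)
    res$hgvs_p <- sprintf("p.%s%d%s",
                          aa_three_letter(ref_aa), cd$codon_index,
                          aa_three_letter(alt_aa))
  }
  structure(res, class = "consequence")
}

#' @export
print.consequence <- function(x, ...) {
  cat(sprintf("<consequence> %s %s %s%s\n",
              ifelse(is.na(x$gene), "(no gene)", x$gene), x$category,
              ifelse(is.na(x$hgvs_c), sprintf("%s:%d %s>%s", x$contig, x$pos, x$ref, x$alt), x$hgvs_c),
              ifelse(is.na(x$hgvs_p), "", paste0(" ", x$hgvs_p))))
  invisible(x)
}

#' @export
as.data.frame.consequence <- function(x, ...) {
  data.frame(
    contig = x$contig, pos = x$pos, ref = x$ref, alt = x$alt,
    gene = x$gene, transcript_id = x$transcript_id,
    category = x$category, cdna_pos = x$cdna_pos, cdna_offset = x$cdna_offset,
    codon_index = x$codon_index,
    ref_codon = x$ref_codon, alt_codon = x$alt_codon,
    ref_aa = x$ref_aa, alt_aa = x$alt_aa,
    hgvs_c = x$hgvs_c, hgvs_p = x$hgvs_p,
    stringsAsFactors = FALSE
  )
}

# Intergenic placeholder used when a variant overlaps no transcript.
intergenic_consequence <- function(variant) {
  v <- as.list(variant)
  structure(list(
    gene = NA_character_, transcript_id = NA_character_,
    contig = v$contig, pos = v$pos, ref = v$ref, alt = v$alt,
    region = "intergenic", cdna_pos = NA_integer_, cdna_offset = 0L,
    ref_cdna = v$ref, alt_cdna = v$alt,
    codon_index = NA_integer_, ref_codon = NA_character_,
    alt_codon = NA_character_, ref_aa = NA_character_, alt_aa = NA_character_,
    category = "intergenic", hgvs_c = NA_character_, hgvs_p = NA_character_
  ), class = "consequence")
}

#' Annotate variants against a set of transcripts
#'
#' Each variant is annotated against the first transcript whose exon span
#' contains it (on the same contig); variants overlapping no transcript get
#' an intergenic row, and non-SNVs (indels) are flagged `unsupported`
#' rather than raising.
#'
#' @param variants data.frame with `contig`, `pos`, `ref`, `alt`.
#' @param transcripts list of [transcript_model()] objects.
#' @param splice_window see [annotate_snv()].
#' @return data.frame with one consequence row per variant.
#' @export
annotate_variants <- function(variants, transcripts, splice_window = 2) {
  if (nrow(variants) == 0) {
    out <- as.data.frame(intergenic_consequence(
      list(contig = "x", pos = 1L, ref = "A", alt = "C")))
    return(out[0, , drop = FALSE])
  }
  rows <- lapply(seq_len(nrow(variants)), function(i) {
    v <- variants[i, ]
    if (nchar(v$ref) != 1 || nchar(v$alt) != 1) {
      out <- as.data.frame(intergenic_consequence(v))
      out$category <- "unsupported"
      return(out)
    }
    for (tx in transcripts) {
      if (tx$contig == v$contig &&
          v$pos >= min(tx$exons$start) && v$pos <= max(tx$exons$end)) {
        return(as.data.frame(annotate_snv(v, tx, splice_window)))
      }
    }
    as.data.frame(intergenic_consequence(v))
  })
  do.call(rbind, rows)
}
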