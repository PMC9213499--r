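# Strand-aware transcript model: exon/CDS intervals on a genomic contig plus
# the contig sequence. All genomic coordinates are 1-based inclusive (VCF/GFF3
# convention); coding-DNA (c.) positions run 1..CDS-length from the A of the
# start codon in transcript orientation.

#' Construct a transcript model
#'
#' @param gene gene symbol.
#' @param transcript_id transcript identifier.
#' @param contig contig name.
#' @param strand `"+"` or `"-"`.
#' @param exons data.frame with `start`, `end` (1-based inclusive genomic),
#'   non-overlapping; stored sorted by genomic position.
#' @param cds_start,cds_end genomic coordinates bounding the CDS.
#' @param seq genomic sequence of the contig (character).
#' @param validate if `TRUE`, require CDS length divisible by 3, a leading
#'   ATG and a terminal stop codon in transcript orientation. Relax for toy
#'   fixtures that deliberately break these.
#' @return Object of class `transcript_model`.
#' @export
transcript_model <- function(gene, transcript_id, contig, strand, exons,
                             cds_start, cds_end, seq, validate = TRUE) {
  stopifnot(strand %in% c("+", "-"))
  exons <- as.data.frame(exons)[, c("start", "end")]
  exons <- exons[order(exons$start), , drop = FALSE]
  rownames(exons) <- NULL
  if (any(exons$end < exons$start)) stop("exon end < start")
  if (nrow(exons) > 1 && any(exons$start[-1] <= exons$end[-nrow(exons)])) {
    stop("exons must be non-overlapping and sorted")
  }
  seq <- toupper(as.character(seq))
  if (max(exons$end) > nchar(seq)) stop("exons extend past contig sequence")
  if (cds_start > cds_end) stop("cds_start > cds_end")

  tx <- structure(
    list(gene = gene, transcript_id = transcript_id, contig = contig,
         strand = strand, exons = exons,
         cds_start = cds_start, cds_end = cds_end, seq = seq),
    class = "transcript_model"
  )
  if (validate) {
    len <- cds_length(tx)
    if (len %% 3 != 0) stop("CDS length ", len, " not divisible by 3")
    cds <- cds_sequence(tx)
    if (substr(cds, 1, 3) != "ATG") stop("CDS does not begin with ATG")
    last <- substr(cds, len - 2, len)
    if (!last %in% STOP_CODONS) stop("CDS does not end with a stop codon")
  }
  tx
}

#' @export
print.transcript_model <- function(x, ...) {
  cat(sprintf("<transcript_model> %s (%s) %s:%d-%d strand %s, %d exon(s), CDS %d bp\n",
              x$gene, x$transcript_id, x$contig,
              min(x$exons$start), max(x$exons$end), x$strand,
              nrow(x$exons), cds_length(x)))
  invisible(x)
}

#' CDS segments of a transcript (genomic, ascending)
#' @param tx transcript model.
#' @return data.frame `start`, `end` of exon parts overlapping the CDS.
#' @export
cds_segments <- function(tx) {
  s <- pmax(tx$exons$start, tx$cds_start)
  e <- pmin(tx$exons$end, tx$cds_end)
  keep <- s <= e
  data.frame(start = s[keep], end = e[keep])
}

#' Total CDS length in bases
#' @param tx transcript model.
#' @export
cds_length <- function(tx) {
  segs <- cds_segments(tx)
  sum(segs$end - segs$start + 1)
}

#' CDS nucleotide sequence in transcript orientation
#' @param tx transcript model.
#' @export
cds_sequence <- function(tx) {
  segs <- cds_segments(tx)
  parts <- substring(tx$seq, segs$start, segs$end)
  fwd <- paste(parts, collapse = "")
  if (tx$strand == "-") revcomp(fwd) else fwd
}

# c. index of a genomic position known to fall in the CDS
coding_index <- function(pos, tx) {
  segs <- cds_segments(tx)
  w <- segs$end - segs$start + 1
  i <- which(pos >= segs$start & pos <= segs$end)
  if (length(i) != 1) stop("position not in CDS")
  if (tx$strand == "+") {
    before <- if (i > 1) sum(w[seq_len(i - 1)]) else 0
    before + (pos - segs$start[i] + 1)
  } else {
    n <- length(w)
    after <- if (i < n) sum(w[seq(i + 1, n)]) else 0
    after + (segs$end[i] - pos + 1)
  }
}

#' Map a genomic position to coding-DNA coordinates
#'
#' Coding positions are numbered 1..CDS-length from the start-codon A in
#' transcript orientation. Intronic positions are expressed relative to the
#' nearest exon boundary: `+offset` from the last exonic base on the donor
#' side, `-offset` from the first exonic base on the acceptor side, choosing
#' whichever boundary is nearer (donor wins ties). Positions in exons but
#' outside the CDS are UTR; positions outside the transcript span are
#' intergenic (a marker, not an error).
#'
#' @param genomic_pos 1-based genomic position.
#' @param transcript a [transcript_model()].
#' @return list with `region` (`"cds"`, `"utr"`, `"intronic"`,
#'   `"intergenic"`), `pos` (anchor c. position, `NA` unless cds/intronic)
#'   and `offset` (signed intronic distance, 0 for exonic).
#' @export
cdna_position <- function(genomic_pos, transcript) {
  tx <- transcript
  exons <- tx$exons
  if (genomic_pos < min(exons$start) || genomic_pos > max(exons$end)) {
    return(list(region = "intergenic", pos = NA_integer_, offset = 0L))
  }
  in_exon <- any(genomic_pos >= exons$start & genomic_pos <= exons$end)
  if (in_exon) {
    if (genomic_pos >= tx$cds_start && genomic_pos <= tx$cds_end) {
      return(list(region = "cds",
                  pos = as.integer(coding_index(genomic_pos, tx)),
                  offset = 0L))
    }
    return(list(region = "utr", pos = NA_integer_, offset = 0L))
  }
  # intronic: flanking exon boundaries
  prev_end <- max(exons$end[exons$end < genomic_pos])
  next_start <- min(exons$start[exons$start > genomic_pos])
  d_prev <- genomic_pos - prev_end
  d_next <- next_start - genomic_pos
  if (tx$strand == "+") {
    donor <- list(anchor = prev_end, dist = d_prev)
    acceptor <- list(anchor = next_start, dist = d_next)
  } else {
    donor <- list(anchor = next_start, dist = d_next)
    acceptor <- list(anchor = prev_end, dist = d_prev)
  }
  side <- if (donor$dist <= acceptor$dist) "donor" else "acceptor"
  pick <- if (side == "donor") donor else acceptor
  anchor_c <- if (pick$anchor >= tx$cds_start && pick$anchor <= tx$cds_end) {
    as.integer(coding_index(pick$anchor, tx))
  } else {
    NA_integer_
  }
  list(region = "intronic", pos = anchor_c,
       offset = as.integer(if (side == "donor") pick$dist else -pick$dist))
}

#' Map a coding-DNA position back to its genomic position
#' @param cdna_pos coding position in 1..CDS-length.
#' @param transcript a [transcript_model()].
#' @export
genomic_position <- function(cdna_pos, transcript) {
  tx <- transcript
  len <- cds_length(tx)
  if (cdna_pos < 1 || cdna_pos > len) stop("cdna_pos out of range 1..", len)
  segs <- cds_segments(tx)
  w <- segs$end - segs$start + 1
  if (tx$strand == "-") {
    segs <- segs[rev(seq_len(nrow(segs))), , drop = FALSE]
    w <- rev(w)
  }
  cum <- cumsum(w)
  i <- which(cdna_pos <= cum)[1]
  into <- cdna_pos - (if (i > 1) cum[i - 1] else 0)
  if (tx$strand == "+") segs$start[i] + into - 1 else segs$end[i] - into + 1
}

#' Codon index and within-codon offset of a coding position
#'
#' @param cdna_pos coding-DNA position (1-based).
#' @param cds_len optional CDS length for range checking.
#' @return list with `codon_index` (1-based amino-acid number) and
#'   `offset_in_codon` (0, 1 or 2).
#' @export
codon_of <- function(cdna_pos, cds_len = NULL) {
  if (cdna_pos < 1) stop("cdna_pos must be >= 1")
  if (!is.null(cds_len) && cdna_pos > cds_len) {
    stop("cdna_pos ", cdna_pos, " beyond CDS length ", cds_len)
  }
  list(codon_index = as.integer((cdna_pos - 1) %/% 3 + 1),
       offset_in_codon = as.integer((cdna_pos - 1) %% 3))
}

#' Read transcript models from GFF3 + FASTA
#'
#' Expects gene/mRNA/exon/CDS features with ID/Parent attributes, one
#' contig sequence per transcript contig in the FASTA.
#'
#' @param gff3_path GFF3 file.
#' @param fasta_path genomic FASTA.
#' @param validate passed to [transcript_model()].
#' @return list of [transcript_model()] objects, one per mRNA feature.
#' @export
read_transcripts <- function(gff3_path, fasta_path, validate = TRUE) {
  gr <- rtracklayer::import(gff3_path)
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))

  types <- as.character(gr$type)
  mrna_idx <- which(types == "mRNA")
  genes <- gr[types == "gene"]
  out <- list()
  for (i in mrna_idx) {
    m <- gr[i]
    tid <- m$ID
    parent <- unlist(m$Parent)
    g <- genes[genes$ID == parent]
    gene_name <- if (length(g) && !is.null(g$Name) && !is.na(g$Name[1])) {
      g$Name[1]
    } else if (length(parent)) sub("^gene:", "", parent) else NA_character_
    children <- gr[vapply(gr$Parent, function(p) tid %in% p, logical(1))]
    ex <- children[as.character(children$type) == "exon"]
    cds <- children[as.character(children$type) == "CDS"]
    if (length(ex) == 0 || length(cds) == 0) {
      stop("transcript ", tid, " lacks exon or CDS features")
    }
    contig <- as.character(GenomicRanges::seqnames(m))[1]
    if (!contig %in% names(seqs)) stop("contig ", contig, " not in FASTA")
    out[[length(out) + 1L]] <- transcript_model(
      gene = gene_name,
      transcript_id = sub("^transcript:", "", tid),
      contig = contig,
      strand = as.character(BiocGenerics::strand(m))[1],
      exons = data.frame(start = BiocGenerics::start(ex), end = BiocGenerics::end(ex)),
      cds_start = min(BiocGenerics::start(cds)),
      cds_end = max(BiocGenerics::end(cds)),
      seq = as.character(seqs[[contig]]),
      validate = validate
    )
  }
  out
}
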