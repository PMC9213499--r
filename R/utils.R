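# Internal helpers shared across modules.

GT_STATES <- c("hom_ref", "het", "hom_alt", "missing")
DNA_BASES <- c("A", "C", "G", "T")
STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Evaluate an expression under a temporary RNG seed
#'
#' Restores the caller's `.Random.seed` afterwards, so seeded simulation
#' functions do not disturb the global RNG stream.
#' @noRd
with_rng_seed <- function(seed, expr) {
  if (is.null(seed)) {
    return(expr)
  }
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  expr
}

#' Reverse-complement nucleotide strings
#' @noRd
revcomp <- function(x) {
  vapply(
    x,
    function(s) as.character(Biostrings::reverseComplement(Biostrings::DNAString(s))),
    character(1),
    USE.NAMES = FALSE
  )
}

#' Random DNA string of length n from the current RNG stream
#' @noRd
random_dna <- function(n) {
  if (n <= 0) return("")
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

#' Translate a codon with the standard nuclear genetic code
#' @noRd
translate_codon <- function(codon) {
  aa <- Biostrings::GENETIC_CODE[[toupper(codon)]]
  if (is.null(aa)) stop("not a valid codon: ", codon, call. = FALSE)
  aa
}

#' One-letter to three-letter amino-acid code ("*" -> "Ter")
#' @noRd
aa_three_letter <- function(aa) {
  vapply(aa, function(a) {
    if (a == "*") return("Ter")
    out <- Biostrings::AMINO_ACID_CODE[[a]]
    if (is.null(out)) stop("unknown amino acid code: ", a, call. = FALSE)
    out
  }, character(1), USE.NAMES = FALSE)
}

# all() over matrix rows that behaves for zero-column matrices
row_all <- function(m) {
  if (ncol(m) == 0) return(rep(TRUE, nrow(m)))
  rowSums(!m) == 0
}
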