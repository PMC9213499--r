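# Two-locus genotype-to-phenotype rule engine for the COPA Black crystal
# (Cr, codominant; allele T at the c.478 SNV) and MITF Hedlund white
# (h, recessive white with heterozygous ventral spotting; allele A at the
# c.33+1 splice donor) interaction. Double heterozygotes are completely
# white with dark eyes and normal hearing -- the epistatic phenotype that
# makes single-locus genotype-phenotype maps fail on this trait.

COPA_GENOTYPES <- c("CC", "CT", "TT")
MITF_GENOTYPES <- c("GG", "GA", "AA")

# Normalise "T/C", "CT", "tc" etc. to canonical two-letter form with a
# fixed allele order (wild-type first).
normalize_genotype <- function(x, alleles) {
  vapply(x, function(g) {
    chars <- strsplit(toupper(gsub("[/|]", "", g)), "")[[1]]
    if (length(chars) != 2 || !all(chars %in% alleles)) {
      stop("invalid genotype '", g, "' for alleles ", paste(alleles, collapse = "/"))
    }
    paste(chars[order(match(chars, alleles))], collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Normalise COPA genotypes to CC/CT/TT
#' @param x character vector, e.g. `"T/C"`.
#' @export
copa_genotype <- function(x) normalize_genotype(x, c("C", "T"))

#' Normalise MITF genotypes to GG/GA/AA
#' @param x character vector, e.g. `"G/A"`.
#' @export
mitf_genotype <- function(x) normalize_genotype(x, c("G", "A"))

#' Default two-locus phenotype rule set
#'
#' Total, deterministic map of all nine (COPA, MITF) genotype pairs to coat
#' phenotype classes. Eyes are dark in every class of this model; hearing
#' is impaired only in Hedlund white homozygotes. The two genotype pairs
#' never observed in genotyped cohorts -- (CT, AA) and (TT, AA) -- are
#' mapped to completely_white on the rationale that full depigmentation
#' from either locus dominates, and carry `extrapolated = TRUE` so callers
#' can tell observation-backed rules from extrapolation.
#'
#' @return data.frame of class `phenotype_rules` with columns `copa`,
#'   `mitf`, `class`, `hearing`, `eye_colour`, `extrapolated`.
#' @export
phenotype_rules <- function() {
  rules <- data.frame(
    copa = c("CC", "CC", "CC", "CT", "CT", "CT", "TT", "TT", "TT"),
    mitf = rep(c("GG", "GA", "AA"), 3),
    class = c("standard", "ventral_spotting", "hedlund_white_deaf",
              "white_hat", "completely_white", "completely_white",
              "completely_white", "completely_white", "completely_white"),
    hearing = c("normal", "normal", "impaired",
                "normal", "normal", "normal",
                "normal", "normal", "normal"),
    eye_colour = "dark",
    extrapolated = c(FALSE, FALSE, FALSE,
                     FALSE, FALSE, TRUE,
                     FALSE, FALSE, TRUE),
    stringsAsFactors = FALSE
  )
  class(rules) <- c("phenotype_rules", "data.frame")
  rules
}

validate_rules <- function(rules) {
  key <- paste(rules$copa, rules$mitf)
  all_keys <- paste(rep(COPA_GENOTYPES, each = 3), rep(MITF_GENOTYPES, 3))
  missing <- setdiff(all_keys, key)
  if (length(missing) > 0) {
    stop("rule set not total; missing genotype(s): ", paste(missing, collapse = ", "))
  }
  if (anyDuplicated(key)) stop("rule set has duplicate genotype rows")
  invisible(rules)
}

#' Predict coat phenotype from a two-locus genotype
#'
#' @param copa COPA genotypes (any of `"CC"`, `"C/T"`, `"T/C"`, ...).
#' @param mitf MITF genotypes (`"GG"`, `"G/A"`, ...).
#' @param rules rule set, default [phenotype_rules()].
#' @return data.frame with normalised genotypes and the predicted `class`,
#'   `hearing`, `eye_colour`, `extrapolated` columns, one row per input.
#' @export
predict_phenotype <- function(copa, mitf, rules = phenotype_rules()) {
  validate_rules(rules)
  copa <- copa_genotype(copa)
  mitf <- mitf_genotype(mitf)
  if (length(copa) != length(mitf)) stop("copa and mitf must have equal length")
  idx <- match(paste(copa, mitf), paste(rules$copa, rules$mitf))
  out <- rules[idx, c("class", "hearing", "eye_colour", "extrapolated")]
  out <- cbind(data.frame(copa = copa, mitf = mitf, stringsAsFactors = FALSE), out)
  rownames(out) <- NULL
  out
}

#' Check observed genotype-phenotype rows against a rule set
#'
#' @param observations data.frame with columns `genotype_copa`,
#'   `genotype_mitf`, `phenotype_label`, `n_animals`.
#' @param label_map named character vector mapping observed phenotype
#'   labels to rule classes (default [mink_label_map()]).
#' @param rules rule set, default [phenotype_rules()].
#' @return Object of class `concordance_report`: the row-level data.frame
#'   (`predicted`, `observed_class`, `consistent`) plus summary counts
#'   `n_rows`, `n_consistent`, `n_inconsistent`, `n_animals_inconsistent`.
#' @export
concordance_check <- function(observations, label_map = mink_label_map(),
                              rules = phenotype_rules()) {
  obs <- as.data.frame(observations)
  if (nrow(obs) == 0) {
    return(structure(list(rows = obs, n_rows = 0L, n_consistent = 0L,
                          n_inconsistent = 0L, n_animals_inconsistent = 0L),
                     class = "concordance_report"))
  }
  unmapped <- setdiff(unique(obs$phenotype_label), names(label_map))
  if (length(unmapped) > 0) {
    stop("phenotype label(s) not in label map: ", paste(unmapped, collapse = ", "))
  }
  pred <- predict_phenotype(obs$genotype_copa, obs$genotype_mitf, rules)
  rows <- data.frame(
    obs,
    predicted = pred$class,
    observed_class = unname(label_map[obs$phenotype_label]),
    stringsAsFactors = FALSE
  )
  rows$consistent <- rows$predicted == rows$observed_class
  structure(
    list(rows = rows,
         n_rows = nrow(rows),
         n_consistent = sum(rows$consistent),
         n_inconsistent = sum(!rows$consistent),
         n_animals_inconsistent = sum(rows$n_animals[!rows$consistent])),
    class = "concordance_report"
  )
}

#' @export
print.concordance_report <- function(x, ...) {
  cat(sprintf("<concordance_report> %d row(s): %d consistent, %d inconsistent (%d animal(s))\n",
              x$n_rows, x$n_consistent, x$n_inconsistent, x$n_animals_inconsistent))
  invisible(x)
}

#' Default label map for the mink genotyping table
#'
#' Collapses coat-colour names to the classes of the two-locus model:
#' the starred Black crystal labels distinguish white-hat carriers from
#' completely white animals, and every colour produced by loci outside
#' this model (Violet, Moyle, Silverblue, ...) maps to `standard` since
#' those animals are wild-type at both COPA and MITF.
#' @return named character vector.
#' @export
mink_label_map <- function() {
  c("Black crystal*" = "white_hat",
    "Black crystal**" = "completely_white",
    "Standard dark brown" = "standard",
    "Violet" = "standard",
    "Royle pastel" = "standard",
    "Hedlund white" = "hedlund_white_deaf",
    "Moyle" = "standard",
    "Silverblue" = "standard",
    "Shadow silverblue" = "standard",
    "Black cross" = "standard")
}

#' Simulate a two-locus cross
#'
#' Each offspring draws one allele per locus from each parent. With the
#' default recombination fraction 0.5 the loci segregate independently
#' (COPA and MITF sit on different chromosomes in carnivores); smaller
#' values simulate linkage assuming the parental phase is as written
#' (first allele of each locus on the same haplotype).
#'
#' @param parent1,parent2 lists with `copa` and `mitf` genotype strings.
#' @param n_offspring number of offspring (>= 0).
#' @param seed optional integer for reproducible sampling.
#' @param recombination recombination fraction in [0, 0.5], default 0.5.
#' @return data.frame with normalised `copa` and `mitf` genotypes, one row
#'   per offspring.
#' @export
simulate_cross <- function(parent1, parent2, n_offspring, seed = NULL,
                           recombination = 0.5) {
  if (n_offspring < 0) stop("n_offspring must be >= 0")
  if (recombination < 0 || recombination > 0.5) {
    stop("recombination fraction must be in [0, 0.5]")
  }
  p <- lapply(list(parent1, parent2), function(par) {
    list(copa = strsplit(copa_genotype(par$copa), "")[[1]],
         mitf = strsplit(mitf_genotype(par$mitf), "")[[1]])
  })
  with_rng_seed(seed, {
    gam <- lapply(p, function(par) {
      i <- sample.int(2, n_offspring, replace = TRUE)
      swap <- stats::runif(n_offspring) < recombination
      j <- ifelse(swap, 3L - i, i)
      list(copa = par$copa[i], mitf = par$mitf[j])
    })
    copa <- paste0(gam[[1]]$copa, gam[[2]]$copa)
    mitf <- paste0(gam[[1]]$mitf, gam[[2]]$mitf)
    data.frame(copa = if (n_offspring) copa_genotype(copa) else character(0),
               mitf = if (n_offspring) mitf_genotype(mitf) else character(0),
               stringsAsFactors = FALSE)
  })
}

#' Write a phenotype rule set to a plain-text table
#' @param rules a [phenotype_rules()] data.frame.
#' @param path output TSV path.
#' @export
write_phenotype_rules <- function(rules, path) {
  validate_rules(rules)
  utils::write.table(as.data.frame(rules), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a phenotype rule set from a plain-text table
#' @param path TSV path as written by [write_phenotype_rules()].
#' @export
read_phenotype_rules <- function(path) {
  rules <- utils::read.table(path, sep = "\t", header = TRUE,
                             stringsAsFactors = FALSE)
  class(rules) <- c("phenotype_rules", "data.frame")
  validate_rules(rules)
  rules
}
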