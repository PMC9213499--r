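# Allele-count association statistics for a candidate locus: 2x2 table of
# allele counts (case/control x allele-of-interest/other), Haldane-Anscombe
# continuity correction when a cell is empty, odds ratio with Wald
# confidence interval and two-sided Wald p-value, plus Fisher's exact test
# as a labelled alternative.

#' Construct a 2x2 allele-count contingency table
#'
#' @param a case-group count of the allele of interest.
#' @param b case-group count of the other allele.
#' @param c control-group count of the allele of interest.
#' @param d control-group count of the other allele.
#' @return Object of class `contingency_2x2`.
#' @export
contingency_2x2 <- function(a, b, c, d) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(cells < 0)) stop("cell counts must be non-negative")
  structure(as.list(cells), class = "contingency_2x2")
}

#' @export
print.contingency_2x2 <- function(x, ...) {
  cat(sprintf("<contingency_2x2>\n          allele other\n  case    %6d %5d\n  control %6d %5d\n",
              x$a, x$b, x$c, x$d))
  invisible(x)
}

#' Build the allele table from genotype count rows
#'
#' Each diploid animal contributes two allele observations to its group;
#' counts are summed over rows. Genotype strings are two alleles separated
#' by `/` (e.g. `"T/C"`), and each may carry 0, 1 or 2 copies of `allele`.
#'
#' @param rows data.frame with columns `group` (`"case"`/`"control"`),
#'   `n_animals`, and the genotype column named by `genotype_col`.
#' @param allele the allele of interest (e.g. `"T"`).
#' @param genotype_col name of the genotype column (default
#'   `"genotype_copa"`).
#' @return A [contingency_2x2()].
#' @export
build_allele_table <- function(rows, allele, genotype_col = "genotype_copa") {
  rows <- as.data.frame(rows)
  if (nrow(rows) == 0) return(contingency_2x2(0, 0, 0, 0))
  if (!genotype_col %in% names(rows)) stop("no column named ", genotype_col)
  if (!all(rows$group %in% c("case", "control"))) {
    stop("group must be 'case' or 'control'")
  }
  alleles <- strsplit(rows[[genotype_col]], "/", fixed = TRUE)
  if (any(lengths(alleles) != 2)) {
    stop("genotype strings must be two alleles separated by '/'")
  }
  copies <- vapply(alleles, function(x) sum(x == allele), numeric(1))
  if (all(copies == 0)) {
    warning("allele '", allele, "' absent from every genotype")
  }
  n <- rows$n_animals
  if (any(n < 1)) stop("n_animals must be >= 1")
  is_case <- rows$group == "case"
  a <- sum(copies[is_case] * n[is_case])
  b <- sum((2 - copies[is_case]) * n[is_case])
  c <- sum(copies[!is_case] * n[!is_case])
  d <- sum((2 - copies[!is_case]) * n[!is_case])
  contingency_2x2(a, b, c, d)
}

# Haldane-Anscombe: add 0.5 to all four cells iff any cell is zero.
haldane_correct <- function(table) {
  cells <- c(table$a, table$b, table$c, table$d)
  applied <- any(cells == 0)
  if (applied) cells <- cells + 0.5
  list(a = cells[1], b = cells[2], c = cells[3], d = cells[4],
       correction_applied = applied)
}

#' Odds ratio with Haldane-Anscombe correction
#'
#' If any cell is zero, 0.5 is added to all four cells before the
#' cross-product ratio; tables without an empty cell are used unmodified.
#'
#' @param table a [contingency_2x2()].
#' @return list with `odds_ratio`, `correction_applied` and the (possibly
#'   corrected) `cells`.
#' @export
odds_ratio_haldane <- function(table) {
  if (table$a + table$b == 0 || table$c + table$d == 0) {
    stop("odds ratio undefined: one group has no allele observations")
  }
  h <- haldane_correct(table)
  list(odds_ratio = (h$a * h$d) / (h$b * h$c),
       correction_applied = h$correction_applied,
       cells = h[c("a", "b", "c", "d")])
}

# Normal critical value used for reporting: the confidence quantile rounded
# to two decimals (1.96 at 95%), the convention the summary statistics in
# this field are printed with. Pass z_crit to override with full precision.
reporting_z <- function(confidence) {
  round(stats::qnorm(1 - (1 - confidence) / 2), 2)
}

#' Wald confidence interval for the odds ratio
#'
#' Computed on the log scale from the (Haldane-corrected) cells:
#' `SE = sqrt(1/a + 1/b + 1/c + 1/d)`, `CI = exp(log(OR) +/- z * SE)`.
#'
#' @param table a [contingency_2x2()].
#' @param confidence coverage in (0, 1); default 0.95.
#' @param z_crit normal critical value; defaults to the two-decimal
#'   quantile (1.96 at 95%).
#' @return numeric vector `c(ci_low, ci_high)`.
#' @export
wald_interval <- function(table, confidence = 0.95, z_crit = NULL) {
  if (confidence <= 0 || confidence >= 1) stop("confidence must be in (0, 1)")
  if (is.null(z_crit)) z_crit <- reporting_z(confidence)
  est <- odds_ratio_haldane(table)
  h <- est$cells
  se <- sqrt(1 / h$a + 1 / h$b + 1 / h$c + 1 / h$d)
  lo <- exp(log(est$odds_ratio) - z_crit * se)
  hi <- exp(log(est$odds_ratio) + z_crit * se)
  c(ci_low = lo, ci_high = hi)
}

#' Two-sided Wald p-value for association
#'
#' `z = log(OR) / SE` on the corrected cells, `p = 2 * (1 - Phi(|z|))`.
#'
#' @param table a [contingency_2x2()].
#' @return p-value in [0, 1].
#' @export
wald_p <- function(table) {
  est <- odds_ratio_haldane(table)
  h <- est$cells
  se <- sqrt(1 / h$a + 1 / h$b + 1 / h$c + 1 / h$d)
  z <- log(est$odds_ratio) / se
  2 * stats::pnorm(-abs(z))
}

#' Fisher's exact test on a 2x2 table
#'
#' Two-sided p by summation of all hypergeometric table probabilities (at
#' fixed margins) not exceeding the observed table's probability.
#'
#' @param table a [contingency_2x2()].
#' @return exact p-value.
#' @export
fisher_exact <- function(table) {
  a <- table$a; b <- table$b; c <- table$c; d <- table$d
  r1 <- a + b; r2 <- c + d; c1 <- a + c
  if (r1 == 0 || r2 == 0 || c1 == 0 || b + d == 0) return(1)
  support <- max(0, c1 - r2):min(r1, c1)
  probs <- stats::dhyper(support, r1, r2, c1)
  p_obs <- stats::dhyper(a, r1, r2, c1)
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

#' Full association analysis of an allele table
#'
#' @param table a [contingency_2x2()], or a genotype-count data.frame (then
#'   `allele` and `genotype_col` are used to build the table first).
#' @param allele allele of interest, when `table` is a data.frame.
#' @param confidence CI coverage (default 0.95).
#' @param method `"wald_haldane"` (default) or `"fisher"` (exact p;
#'   OR/CI still from the corrected cross-product).
#' @param genotype_col genotype column used when building from counts.
#' @param z_crit optional normal critical value override.
#' @return Object of class `assoc_result`: `odds_ratio`, `ci_low`,
#'   `ci_high`, `p_value`, `z`, `se`, `correction_applied`, `method`,
#'   `confidence`, `table`.
#' @export
associate <- function(table, allele = NULL, confidence = 0.95,
                      method = c("wald_haldane", "fisher"),
                      genotype_col = "genotype_copa", z_crit = NULL) {
  method <- match.arg(method)
  if (is.data.frame(table)) {
    if (is.null(allele)) stop("allele must be given when building from genotype counts")
    table <- build_allele_table(table, allele, genotype_col)
  }
  est <- odds_ratio_haldane(table)
  h <- est$cells
  se <- sqrt(1 / h$a + 1 / h$b + 1 / h$c + 1 / h$d)
  z <- log(est$odds_ratio) / se
  ci <- wald_interval(table, confidence, z_crit)
  p <- if (method == "fisher") fisher_exact(table) else wald_p(table)
  structure(
    list(odds_ratio = est$odds_ratio,
         ci_low = unname(ci[1]), ci_high = unname(ci[2]),
         p_value = p, z = z, se = se,
         correction_applied = est$correction_applied,
         method = method, confidence = confidence, table = table),
    class = "assoc_result"
  )
}

#' Format an association result the way genotyping tables report it
#'
#' OR to three significant figures, CI bounds to two decimals, p to two
#' significant figures; full precision is retained in the object itself.
#'
#' @param x an `assoc_result`.
#' @return single formatted line, e.g.
#'   `"OR = 218; 95% CI 12.45-3825.13; p = 0.00023"`.
#' @export
format_association <- function(x) {
  sprintf("OR = %s; %d%% CI %.2f-%.2f; p = %s",
          format(signif(x$odds_ratio, 3), big.mark = ""),
          round(100 * x$confidence),
          round(x$ci_low, 2), round(x$ci_high, 2),
          format(signif(x$p_value, 2), scientific = FALSE))
}

#' @export
print.assoc_result <- function(x, ...) {
  cat("<assoc_result> ", format_association(x),
      if (x$correction_applied) " [Haldane-corrected]" else "",
      " (", x$method, ")\n", sep = "")
  invisible(x)
}

#' Reference COPA/MITF genotyping counts for the Black crystal cohort
#'
#' The genotype-count table for 51 farm minks typed at the COPA Black
#' crystal SNV (alleles C/T, T the Cr allele) and the MITF splice-donor SNV
#' (alleles G/A, A the Hedlund allele): 17 Black-crystal-phenotype animals
#' as cases (both the white-hat carriers and the completely white animals)
#' and 34 animals of other coat colours as controls.
#'
#' @return data.frame with columns `phenotype_label`, `colour_symbol`,
#'   `group`, `genotype_copa`, `genotype_mitf`, `n_animals`.
#' @export
mink_genotyping_counts <- function() {
  data.frame(
    phenotype_label = c("Black crystal*", "Black crystal**", "Black crystal**",
                        "Black crystal**", "Standard dark brown", "Violet",
                        "Royle pastel", "Hedlund white", "Moyle", "Silverblue",
                        "Shadow silverblue", "Black cross"),
    colour_symbol = c("Cr/+", "Cr/Cr", "Cr/Cr", "Cr/Cr", "+/+", "a/a m/m p/p",
                      "b/b", "h/h", "m/m", "p/p", "Sh/+ p/p", "S/+"),
    group = c(rep("case", 4), rep("control", 8)),
    genotype_copa = c("T/C", "T/T", "T/T", "T/C",
                      "C/C", "C/C", "C/C", "C/C", "C/C", "C/C", "C/C", "C/C"),
    genotype_mitf = c("G/G", "G/G", "G/A", "G/A",
                      "G/G", "G/G", "G/G", "A/A", "G/G", "G/G", "G/G", "G/G"),
    n_animals = c(10, 3, 1, 3, 25, 1, 1, 1, 1, 3, 1, 1),
    stringsAsFactors = FALSE
  )
}

#' Read a genotype-count table (TSV/CSV)
#'
#' Expects header columns `phenotype_label`, `group`, one or two genotype
#' columns (`genotype_copa`, optionally `genotype_mitf`) and `n_animals`.
#'
#' @param path file path.
#' @return data.frame of genotype count rows.
#' @export
read_genotyping_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- utils::read.table(path, sep = sep, header = TRUE,
                          stringsAsFactors = FALSE, comment.char = "")
  need <- c("phenotype_label", "group", "genotype_copa", "n_animals")
  if (!all(need %in% names(df))) {
    stop("genotyping table must have columns: ", paste(need, collapse = ", "))
  }
  df$group <- tolower(trimws(df$group))
  df
}
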