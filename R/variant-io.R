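# Genotype-matrix container and VCF / phenotype-table input-output.
#
# The in-memory substrate of the segregation filter is a dense matrix of
# diploid genotype calls (hom_ref / het / hom_alt / missing) with a parallel
# matrix of per-sample read depths (the VCF DP field). Multi-allelic records
# are decomposed into one bi-allelic site per alternate allele on input, so
# every downstream operation sees simple ref/alt sites.

#' Construct a genotype matrix
#'
#' @param variants data.frame with columns `contig`, `pos` (1-based),
#'   `id` (may be `NA`), `ref`, `alt`; one row per bi-allelic site.
#' @param samples data.frame with columns `sample_id`, `phenotype_label`,
#'   `role` (`"case"`, `"control"` or `"unassigned"`).
#' @param gt character matrix (variants x samples) with entries
#'   `"hom_ref"`, `"het"`, `"hom_alt"` or `"missing"`.
#' @param depth integer matrix of per-sample read depth, same shape as `gt`.
#'   Calls absent from the source record carry depth 0.
#'
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(variants, samples, gt, depth) {
  variants <- as.data.frame(variants, stringsAsFactors = FALSE)
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  gt <- as.matrix(gt)
  depth <- as.matrix(depth)
  storage.mode(depth) <- "integer"

  need_v <- c("contig", "pos", "ref", "alt")
  if (!all(need_v %in% names(variants))) {
    stop("variants must have columns: ", paste(need_v, collapse = ", "))
  }
  if (is.null(variants$id)) variants$id <- NA_character_
  need_s <- c("sample_id", "phenotype_label", "role")
  if (!all(need_s %in% names(samples))) {
    stop("samples must have columns: ", paste(need_s, collapse = ", "))
  }
  if (anyDuplicated(samples$sample_id)) {
    stop("duplicate sample_id in cohort: ",
         paste(unique(samples$sample_id[duplicated(samples$sample_id)]), collapse = ", "))
  }
  if (!all(samples$role %in% c("case", "control", "unassigned"))) {
    stop("sample role must be one of case/control/unassigned")
  }
  if (nrow(variants) > 0) {
    if (any(variants$pos < 1)) stop("variant pos must be >= 1")
    if (any(variants$ref == variants$alt)) stop("ref and alt alleles must differ")
  }
  if (!identical(dim(gt), c(nrow(variants), nrow(samples))) ||
      !identical(dim(depth), c(nrow(variants), nrow(samples)))) {
    stop("gt/depth dimensions must be n_variants x n_samples")
  }
  if (nrow(gt) > 0 && !all(gt %in% GT_STATES)) {
    stop("gt entries must be one of: ", paste(GT_STATES, collapse = ", "))
  }
  if (nrow(depth) > 0 && any(depth < 0)) stop("depth must be non-negative")

  structure(
    list(variants = variants, samples = samples, gt = gt, depth = depth),
    class = "genotype_matrix"
  )
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf(
    "<genotype_matrix> %d variant(s) x %d sample(s) [%d case, %d control]\n",
    nrow(x$variants), nrow(x$samples),
    sum(x$samples$role == "case"), sum(x$samples$role == "control")
  ))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) c(nrow(x$variants), nrow(x$samples))

#' Read a phenotype table
#'
#' Tab- or comma-delimited text with header columns `sample_id`,
#' `phenotype_label` and `role`. Roles are parsed case-insensitively and
#' normalised to `case` / `control` / `unassigned`. Assigning roles is an
#' analysis decision (which coat colours count as cases), so it always comes
#' from this table, never from the labels themselves.
#'
#' @param path file path.
#' @return data.frame of sample records in file order.
#' @export
read_phenotype_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- utils::read.table(path, sep = sep, header = TRUE,
                          stringsAsFactors = FALSE, comment.char = "")
  need <- c("sample_id", "phenotype_label", "role")
  if (!all(need %in% names(df))) {
    stop("phenotype table must have columns: ", paste(need, collapse = ", "))
  }
  df$sample_id <- as.character(df$sample_id)
  if (anyDuplicated(df$sample_id)) {
    stop("duplicate sample_id in phenotype table: ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "))
  }
  role <- tolower(trimws(df$role))
  bad <- setdiff(unique(role), c("case", "control", "unassigned"))
  if (length(bad) > 0) {
    stop("unknown role token(s): ", paste(bad, collapse = ", "))
  }
  df$role <- role
  df[, need]
}

# Light structural validation so parse failures name a line number; vcfR
# does the heavy lifting afterwards.
validate_vcf_lines <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0 || !startsWith(lines[1], "##fileformat=VCF")) {
    stop("malformed VCF at line 1: missing ##fileformat header in ", path)
  }
  body <- which(!startsWith(lines, "#"))
  for (i in body) {
    nf <- length(strsplit(lines[i], "\t", fixed = TRUE)[[1]])
    if (nf < 8) {
      stop(sprintf("malformed VCF record at line %d of %s (%d field(s), expected >= 8)",
                   i, path, nf))
    }
  }
  chrom_line <- grep("^#CHROM\t", lines, value = TRUE)
  if (length(chrom_line) != 1) stop("malformed VCF: no #CHROM header line in ", path)
  fields <- strsplit(chrom_line, "\t", fixed = TRUE)[[1]]
  list(n_body = length(body),
       samples = if (length(fields) > 9) fields[-(1:9)] else character(0))
}

# Recode one diploid GT string against alternate allele k (1-based ALT index).
# Any missing allele index makes the whole call missing.
recode_gt_string <- function(gt, k) {
  if (is.na(gt) || gt == "" || gt == ".") return("missing")
  idx <- strsplit(gt, "[/|]")[[1]]
  if (any(idx == ".") || length(idx) != 2) return("missing")
  n_alt <- sum(idx == as.character(k))
  c("hom_ref", "het", "hom_alt")[n_alt + 1L]
}

#' Read a VCF into a genotype matrix
#'
#' Multi-allelic records are decomposed into one site per alternate allele;
#' the genotype is recoded per allele (so a `1/2` call is `het` with respect
#' to each of the two alternates). `./.` is `missing` regardless of depth,
#' and an absent DP field is read as depth 0, which a coverage filter then
#' fails conservatively.
#'
#' @param path VCF 4.x file with GT (and optionally DP) FORMAT fields.
#' @param phenotype_map data.frame as returned by [read_phenotype_table()].
#'   VCF samples not present in the map are dropped with a warning; map
#'   entries missing from the VCF are an error.
#' @return A [genotype_matrix()].
#' @export
read_vcf <- function(path, phenotype_map) {
  if (!file.exists(path)) stop("file not found: ", path)
  phenotype_map <- as.data.frame(phenotype_map, stringsAsFactors = FALSE)
  info <- validate_vcf_lines(path)

  if (info$n_body == 0) {
    keep <- intersect(info$samples, phenotype_map$sample_id)
    missing_ids <- setdiff(phenotype_map$sample_id, info$samples)
    if (length(missing_ids) > 0) {
      stop("sample(s) in phenotype map but not in VCF: ",
           paste(missing_ids, collapse = ", "))
    }
    samples <- phenotype_map[match(keep, phenotype_map$sample_id), , drop = FALSE]
    empty <- data.frame(contig = character(0), pos = integer(0), id = character(0),
                        ref = character(0), alt = character(0),
                        stringsAsFactors = FALSE)
    return(genotype_matrix(empty, samples,
                           matrix(character(0), 0, nrow(samples)),
                           matrix(integer(0), 0, nrow(samples))))
  }

  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- t(as.matrix(fix))  # single-record VCF
  gt_raw <- vcfR::extract.gt(vcf, element = "GT")
  dp_raw <- tryCatch(
    vcfR::extract.gt(vcf, element = "DP", as.numeric = TRUE),
    error = function(e) matrix(NA_real_, nrow(gt_raw), ncol(gt_raw),
                               dimnames = dimnames(gt_raw))
  )
  dp_raw[is.na(dp_raw)] <- 0

  vcf_samples <- colnames(gt_raw)
  missing_ids <- setdiff(phenotype_map$sample_id, vcf_samples)
  if (length(missing_ids) > 0) {
    stop("sample(s) in phenotype map but not in VCF: ",
         paste(missing_ids, collapse = ", "))
  }
  dropped <- setdiff(vcf_samples, phenotype_map$sample_id)
  if (length(dropped) > 0) {
    warning("dropping VCF sample(s) absent from phenotype map: ",
            paste(dropped, collapse = ", "))
  }
  keep <- vcf_samples[vcf_samples %in% phenotype_map$sample_id]
  samples <- phenotype_map[match(keep, phenotype_map$sample_id), , drop = FALSE]
  rownames(samples) <- NULL
  gt_raw <- gt_raw[, keep, drop = FALSE]
  dp_raw <- dp_raw[, keep, drop = FALSE]

  # decompose multi-allelic records
  v_contig <- character(0); v_pos <- integer(0); v_id <- character(0)
  v_ref <- character(0); v_alt <- character(0)
  gt_rows <- list(); dp_rows <- list()
  for (i in seq_len(nrow(fix))) {
    alts <- strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1]]
    for (k in seq_along(alts)) {
      v_contig <- c(v_contig, fix[i, "CHROM"])
      v_pos <- c(v_pos, as.integer(fix[i, "POS"]))
      id <- fix[i, "ID"]
      v_id <- c(v_id, if (is.na(id) || id == ".") NA_character_ else id)
      v_ref <- c(v_ref, fix[i, "REF"])
      v_alt <- c(v_alt, alts[k])
      gt_rows[[length(gt_rows) + 1L]] <-
        vapply(gt_raw[i, ], recode_gt_string, character(1), k = k)
      dp_rows[[length(dp_rows) + 1L]] <- as.integer(dp_raw[i, ])
    }
  }
  variants <- data.frame(contig = v_contig, pos = v_pos, id = v_id,
                         ref = v_ref, alt = v_alt, stringsAsFactors = FALSE)
  gt <- do.call(rbind, gt_rows)
  depth <- do.call(rbind, dp_rows)
  dimnames(gt) <- NULL; dimnames(depth) <- NULL
  genotype_matrix(variants, samples, gt, depth)
}

#' Write a genotype matrix as plain-text VCF 4.2
#'
#' Emits one bi-allelic record per variant with GT:DP per sample, so
#' `read_vcf(write_vcf(m))` round-trips genotypes and depths exactly.
#'
#' @param matrix a [genotype_matrix()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(matrix, path) {
  stopifnot(inherits(matrix, "genotype_matrix"))
  gt_map <- c(hom_ref = "0/0", het = "0/1", hom_alt = "1/1", missing = "./.")
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=minkseg",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
    sprintf("##contig=<ID=%s>", unique(matrix$variants$contig)),
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", matrix$samples$sample_id), collapse = "\t")
  )
  body <- character(nrow(matrix$variants))
  for (i in seq_len(nrow(matrix$variants))) {
    v <- matrix$variants[i, ]
    calls <- paste(gt_map[matrix$gt[i, ]], matrix$depth[i, ], sep = ":")
    body[i] <- paste(c(v$contig, v$pos,
                       if (is.na(v$id)) "." else v$id,
                       v$ref, v$alt, ".", "PASS", ".", "GT:DP", calls),
                     collapse = "\t")
  }
  writeLines(c(header, body), path)
  invisible(path)
}

#' Write a phenotype table (TSV)
#' @param samples data.frame with `sample_id`, `phenotype_label`, `role`.
#' @param path output path.
#' @export
write_phenotype_table <- function(samples, path) {
  utils::write.table(samples[, c("sample_id", "phenotype_label", "role")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
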