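# Pipeline orchestration: each subcommand is a plain R function over a
# config list (or YAML path), writing its outputs to files; the exec script
# shipped with the package dispatches to these. Every subcommand is pure
# with respect to its inputs -- rerunning with identical inputs and seed
# reproduces identical outputs.

#' Load a pipeline configuration
#'
#' @param config a named list, or path to a YAML file of one.
#' @return the configuration list.
#' @export
pipeline_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("config must be a list or a YAML file path")
  config
}

require_path <- function(config, key) {
  p <- config[[key]]
  if (is.null(p)) stop("config is missing required entry '", key, "'")
  if (!file.exists(p)) stop("file not found: ", p)
  p
}

config_filter_config <- function(config) {
  fc <- config$filter
  if (is.null(fc)) fc <- list()
  filter_config(
    min_case_depth = fc$min_case_depth %||% 3,
    require_case_hom_alt = fc$require_case_hom_alt %||% TRUE,
    treat_missing_control_as = fc$treat_missing_control_as %||% "pass",
    control_min_depth = fc$control_min_depth %||% 0,
    splice_window = fc$splice_window %||% 2
  )
}

`%||%` <- function(x, y) if (is.null(x)) y else x

out_dir <- function(config) {
  dir <- config$output_dir %||% "."
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  dir
}

#' Run the candidate-selection funnel from files
#'
#' Reads the VCF, phenotype table and transcript model named in the config,
#' runs [run_filter()], and writes `candidates.tsv` plus
#' `filter_counts.json` (the three funnel counts) to the output directory.
#'
#' @param config list or YAML path with entries `vcf`, `phenotype_table`,
#'   optional `gff3` + `fasta`, optional `gene_list` (one symbol per line),
#'   optional `filter` overrides and `output_dir`.
#' @return the [run_filter()] report, invisibly.
#' @export
cmd_filter <- function(config) {
  config <- pipeline_config(config)
  vcf_path <- require_path(config, "vcf")
  pheno <- read_phenotype_table(require_path(config, "phenotype_table"))
  mat <- read_vcf(vcf_path, pheno)
  transcripts <- if (!is.null(config$gff3)) {
    read_transcripts(require_path(config, "gff3"), require_path(config, "fasta"))
  } else {
    list()
  }
  gene_list <- if (!is.null(config$gene_list)) {
    readLines(require_path(config, "gene_list"))
  } else {
    character(0)
  }
  report <- run_filter(mat, config_filter_config(config), transcripts, gene_list)
  dir <- out_dir(config)
  utils::write.table(report$candidates, file.path(dir, "candidates.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(n_input = report$n_input,
         n_pass_stage1 = report$n_pass_stage1,
         n_pass_stage2 = report$n_pass_stage2),
    file.path(dir, "filter_counts.json"), auto_unbox = TRUE)
  invisible(report)
}

#' Annotate candidate variants from files
#'
#' One consequence row per candidate against the first overlapping
#' transcript; candidates overlapping no transcript are reported as
#' intergenic and indels are flagged unsupported rather than failing.
#'
#' @param config list or YAML path with `candidates` (TSV with contig, pos,
#'   ref, alt; e.g. the output of [cmd_filter()]) or `vcf` +
#'   `phenotype_table`, plus `gff3`, `fasta`, optional `output_dir`.
#' @return the consequences data.frame, invisibly.
#' @export
cmd_annotate <- function(config) {
  config <- pipeline_config(config)
  variants <- if (!is.null(config$candidates)) {
    utils::read.table(require_path(config, "candidates"), sep = "\t",
                      header = TRUE, stringsAsFactors = FALSE)
  } else {
    mat <- read_vcf(require_path(config, "vcf"),
                    read_phenotype_table(require_path(config, "phenotype_table")))
    mat$variants
  }
  transcripts <- read_transcripts(require_path(config, "gff3"),
                                  require_path(config, "fasta"))
  cons <- annotate_variants(variants, transcripts,
                            config$filter$splice_window %||% 2)
  dir <- out_dir(config)
  utils::write.table(cons, file.path(dir, "consequences.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(cons)
}

#' Run the association analysis from a genotype-count table
#'
#' Writes `association.json` with the odds ratio, CI, p-value and method,
#' and prints a one-line caption-style summary.
#'
#' @param config list or YAML path with `genotyping_table`, optional
#'   `allele` (default `"T"`), `confidence` (default 0.95), `method`
#'   (`"wald_haldane"` or `"fisher"`), `genotype_col`, `output_dir`.
#' @return the [associate()] result, invisibly.
#' @export
cmd_associate <- function(config) {
  config <- pipeline_config(config)
  rows <- read_genotyping_table(require_path(config, "genotyping_table"))
  res <- associate(rows,
                   allele = config$allele %||% "T",
                   confidence = config$confidence %||% 0.95,
                   method = config$method %||% "wald_haldane",
                   genotype_col = config$genotype_col %||% "genotype_copa")
  dir <- out_dir(config)
  jsonlite::write_json(
    list(odds_ratio = res$odds_ratio, ci_low = res$ci_low,
         ci_high = res$ci_high, p_value = res$p_value,
         correction_applied = res$correction_applied,
         confidence = res$confidence, method = res$method),
    file.path(dir, "association.json"), auto_unbox = TRUE, digits = NA)
  message(format_association(res))
  invisible(res)
}

#' Generate a self-contained fixture directory
#'
#' Writes a synthetic cohort (VCF + phenotype TSV), a toy transcript
#' (GFF3 + FASTA) and a `manifest.json` recording the seed and the MD5 of
#' every file, so identical seeds give identical checksums.
#'
#' @param config list or YAML path with optional `cohort` (arguments to
#'   [cohort_spec()]), `transcript` (arguments to [toy_transcript_spec()];
#'   default a 2-exon plus-strand gene), `seed` and `output_dir`.
#' @return named list of written paths, invisibly.
#' @export
cmd_simulate <- function(config) {
  config <- pipeline_config(config)
  seed <- config$seed %||% 1L
  cspec <- do.call(cohort_spec, c(config$cohort %||% list(), list(seed = seed)))
  mat <- generate_cohort(cspec)
  tspec_args <- config$transcript %||% list(gene = "TOY", n_exons = 2,
                                            cds_length = 300)
  tspec <- do.call(toy_transcript_spec, tspec_args)
  tx <- generate_transcript(tspec, seed = seed)
  dir <- out_dir(config)
  paths <- c(vcf = file.path(dir, "cohort.vcf"),
             phenotypes = file.path(dir, "phenotypes.tsv"),
             gff3 = file.path(dir, "transcript.gff3"),
             fasta = file.path(dir, "transcript.fa"))
  write_vcf(mat, paths[["vcf"]])
  write_phenotype_table(mat$samples, paths[["phenotypes"]])
  write_transcript_files(tx, paths[["gff3"]], paths[["fasta"]])
  manifest <- list(seed = seed,
                   files = as.list(stats::setNames(
                     unname(tools::md5sum(paths)), basename(paths))))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE)
  invisible(as.list(c(paths, manifest = file.path(dir, "manifest.json"))))
}
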