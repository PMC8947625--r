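# One-call pipeline orchestration: triage -> landscape -> pathways, with a
# YAML-configurable run and an end-of-run report whose numbers are always
# recomputed from the stage outputs on disk.

#' Build a run configuration
#'
#' @param calls_path Path to the annotated-call TSV.
#' @param samples_path Path to the sample sheet TSV.
#' @param out_dir Output directory.
#' @param gmt_path Path to a GMT gene-set file (default: the shipped
#'   pathway sets).
#' @param rules_path Path to a resistance-rule TSV (default: shipped
#'   rules).
#' @param depth_min,qual_min,maf_max,consensus_min Threshold overrides
#'   (see [triage_thresholds()]).
#' @param denominator_mode Denominator convention for gene case fractions
#'   (see [gene_summaries()]).
#' @param seed Integer seed recorded with the run.
#' @return A list of class `run_config`.
#' @export
run_config <- function(calls_path, samples_path, out_dir,
                       gmt_path = crctriage_resource("pathways"),
                       rules_path = crctriage_resource("rules"),
                       depth_min = 200, qual_min = 100, maf_max = 0.01,
                       consensus_min = 2L,
                       denominator_mode = "mutated_cases",
                       seed = 1L) {
  stopifnot(depth_min > 0, qual_min > 0, maf_max > 0, consensus_min >= 1)
  structure(list(calls_path = calls_path, samples_path = samples_path,
                 out_dir = out_dir, gmt_path = gmt_path,
                 rules_path = rules_path, depth_min = depth_min,
                 qual_min = qual_min, maf_max = maf_max,
                 consensus_min = as.integer(consensus_min),
                 denominator_mode = denominator_mode,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Every key of [run_config()] may appear in the YAML file; `overrides`
#' (typically command-line flags) win over YAML values.
#'
#' @param path Path to a YAML file.
#' @param overrides Named list of values overriding the YAML keys.
#' @return A `run_config`.
#' @export
read_run_config <- function(path, overrides = list()) {
  raw <- yaml::read_yaml(path)
  raw[names(overrides)] <- overrides
  do.call(run_config, raw)
}

#' Run the full pipeline
#'
#' Executes, in order: sample QC, pooled-normal construction from the
#' control group, the somatic filtering cascade, landscape summaries
#' (partition, diagnostic yield, burden, gene summaries, novelty,
#' resistance flags, oncoplot matrix), and pathway over-representation.
#' All stage outputs are written as TSV/JSON under `out_dir`, and a report
#' recomputed from those outputs is returned (and written as Markdown and
#' JSON).
#'
#' @param config A `run_config` from [run_config()] or
#'   [read_run_config()].
#' @return The report, a named list (invisibly identical to the JSON
#'   written to `out_dir/report.json`).
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  thresholds <- triage_thresholds(depth_min = config$depth_min,
                                  qual_min = config$qual_min,
                                  maf_max = config$maf_max,
                                  consensus_min = config$consensus_min)

  calls <- read_variant_calls(config$calls_path)
  samples <- read_sample_sheet(config$samples_path)

  qc <- qc_samples(samples, thresholds)
  message("qc_sample: ", sum(qc$qc_pass), "/", nrow(qc), " samples accepted")
  accepted <- qc[qc$qc_pass, ]
  calls <- calls[calls$sample_id %in% accepted$sample_id, ]

  pool <- build_pooled_normal(calls, samples, thresholds)
  message("pooled_normal: ", length(pool$keys), " control variant keys")

  lesion_calls <- calls[calls$sample_id %in%
                          accepted$sample_id[accepted$group != "COLITIS"], ]
  cascade <- run_cascade(lesion_calls, pool, thresholds)
  for (i in seq_len(nrow(cascade$stage_counts))) {
    message("cascade stage ", cascade$stage_counts$stage[i], ": ",
            cascade$stage_counts$entered[i], " entered, ",
            cascade$stage_counts$survived[i], " survived")
  }
  retained <- cascade$retained

  out <- function(name) file.path(config$out_dir, name)
  write_maf(retained[CALL_COLUMNS], out("retained.maf.tsv"))
  readr::write_tsv(retained, out("retained.tsv"), progress = FALSE)
  readr::write_tsv(cascade$trace, out("trace.tsv"), progress = FALSE)
  jsonlite::write_json(cascade$stage_counts, out("stage_counts.json"),
                       dataframe = "rows", auto_unbox = TRUE)

  partition <- partition_by_group_occupancy(retained, samples)
  yield <- diagnostic_yield(retained, samples)
  burden_all <- mutation_burden(retained, samples)
  burden_crc_only <- mutation_burden(retained, samples, scope = "CRC_ONLY")
  genes_all <- gene_summaries(retained, samples, config$denominator_mode)
  novel <- retained[flag_novel(retained$cosmic_id, retained$pop_max_maf,
                               retained$clinvar_class,
                               retained$hgmd_class), ]
  rules <- readr::read_tsv(config$rules_path, progress = FALSE,
                           show_col_types = FALSE)
  resistance <- egfr_resistance_flags(retained, samples, rules)
  onco <- oncoplot_matrix(retained, samples)

  readr::write_tsv(partition, out("partition.tsv"), progress = FALSE)
  readr::write_tsv(yield, out("diagnostic_yield.tsv"), progress = FALSE)
  readr::write_tsv(burden_all, out("burden.tsv"), progress = FALSE)
  readr::write_tsv(genes_all, out("gene_summaries.tsv"), progress = FALSE)
  readr::write_tsv(novel, out("novel.tsv"), progress = FALSE)
  readr::write_tsv(resistance$flags, out("resistance.tsv"),
                   progress = FALSE)
  utils::write.table(onco, out("oncoplot_matrix.tsv"), sep = "\t",
                     quote = FALSE, col.names = NA)

  sets <- read_gmt(config$gmt_path)
  panel <- readr::read_tsv(crctriage_resource("panel"), progress = FALSE,
                           show_col_types = FALSE)
  crc_samples <- samples$sample_id[samples$group == "CRC"]
  crc_genes <- unique(retained$gene[retained$sample_id %in% crc_samples])
  ora <- if (length(crc_genes)) {
    hypergeometric_ora(crc_genes, sets, panel$gene)
  } else {
    tibble::tibble(set_id = character(), set_name = character(),
                   k = integer(), K = integer(), n = integer(),
                   N = integer(), p_value = double(), q_value = double(),
                   genes = character())
  }
  readr::write_tsv(ora, out("pathways.tsv"), progress = FALSE)
  pgm <- pathway_gene_matrix(
    retained[retained$sample_id %in% crc_samples, ], sets)
  readr::write_tsv(pgm, out("pathway_gene_matrix.tsv"), progress = FALSE)

  report <- compile_report(config$out_dir)
  jsonlite::write_json(report, out("report.json"), auto_unbox = TRUE,
                       digits = NA)
  writeLines(render_report_md(report), out("report.md"))
  invisible(report)
}

#' Recompute the run report from on-disk stage outputs
#'
#' Report numbers are never cached: this reads the stage TSVs a finished
#' run wrote and re-derives the headline counts, so regenerating the
#' report from disk is idempotent.
#'
#' @param out_dir A directory previously written by [run_all()].
#' @return A named list of report sections.
#' @export
compile_report <- function(out_dir) {
  rd <- function(name) readr::read_tsv(file.path(out_dir, name),
                                       progress = FALSE,
                                       show_col_types = FALSE)
  retained <- rd("retained.tsv")
  partition <- rd("partition.tsv")
  yield <- rd("diagnostic_yield.tsv")
  burden <- rd("burden.tsv")
  genes <- rd("gene_summaries.tsv")
  novel <- rd("novel.tsv")
  resistance <- rd("resistance.tsv")
  pathways <- rd("pathways.tsv")
  stage_counts <- jsonlite::read_json(file.path(out_dir,
                                                "stage_counts.json"),
                                      simplifyVector = TRUE)
  part_n <- function(label) sum(partition$partition == label)
  list(
    stage_counts = stage_counts,
    n_retained_occurrences = nrow(retained),
    n_distinct_variants = nrow(partition),
    partitions = list(
      common_crc_precursor = part_n("COMMON_CRC_PRECURSOR"),
      crc_only = part_n("CRC_ONLY"), cp_only = part_n("CP_ONLY"),
      ibd_only = part_n("IBD_ONLY"), other = part_n("OTHER")),
    diagnostic_yield = yield,
    burden = burden,
    top_genes = head(genes, 10),
    n_novel_distinct = nrow(dplyr::distinct(novel, .data$chrom, .data$pos,
                                            .data$ref, .data$alt)),
    resistance = list(n_flagged = sum(resistance$flagged),
                      n_crc = nrow(resistance)),
    pathways = pathways
  )
}

render_report_md <- function(report) {
  fmt_tbl <- function(df) {
    c(paste(names(df), collapse = " | "),
      paste(rep("---", ncol(df)), collapse = " | "),
      apply(df, 1, function(r) paste(r, collapse = " | ")))
  }
  c("# Somatic triage run report", "",
    paste0("Retained variant occurrences: ", report$n_retained_occurrences),
    paste0("Distinct retained variants: ", report$n_distinct_variants),
    "",
    "## Filter cascade", "", fmt_tbl(as.data.frame(report$stage_counts)),
    "",
    "## Variant partitions by group occupancy", "",
    paste0("- shared CRC/precursor: ",
           report$partitions$common_crc_precursor),
    paste0("- CRC-specific: ", report$partitions$crc_only),
    paste0("- CP only: ", report$partitions$cp_only),
    paste0("- IBD only: ", report$partitions$ibd_only),
    paste0("- other: ", report$partitions$other),
    "",
    "## Diagnostic yield", "", fmt_tbl(report$diagnostic_yield), "",
    "## Mutational burden", "", fmt_tbl(report$burden), "",
    "## Top mutated genes", "", fmt_tbl(report$top_genes), "",
    paste0("Novel (database-absent) distinct variants: ",
           report$n_novel_distinct),
    paste0("Anti-EGFR resistance markers: ", report$resistance$n_flagged,
           " of ", report$resistance$n_crc, " CRC samples"),
    "",
    "## Pathway over-representation", "", fmt_tbl(report$pathways))
}
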