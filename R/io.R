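# Readers and writers for the flat annotated-variant dialect, sample sheets,
# GMT gene-set files, and a MAF-style export for downstream landscape tools.

CALL_COLUMNS <- c(
  "sample_id", "chrom", "pos", "ref", "alt", "gene", "transcript",
  "hgvs_c", "hgvs_p", "depth", "quality", "caller",
  "cosmic_id", "pop_max_maf", "clinvar_class", "hgmd_class",
  "func_class", "consequence", "sift", "polyphen", "cadd", "exon"
)

CLINVAR_CLASSES <- c("pathogenic", "likely_pathogenic", "VUS", "conflicting",
                     "benign", "likely_benign", "absent")
HGMD_CLASSES <- c("disease_causing", "benign", "absent")
FUNC_CLASSES <- c("exonic", "splicing", "intronic", "UTR", "intergenic",
                  "other")
CONSEQUENCES <- c("synonymous", "missense", "stopgain", "frameshift",
                  "nonframeshift_indel", "splice_site", "other")
GROUPS <- c("COLITIS", "IBD", "CP", "CRC")

#' Validate a table of annotated variant calls
#'
#' Checks the 22-column annotated-call layout: column presence, positive
#' positions, `ref != alt`, non-negative depth and quality, population MAF
#' within `[0, 1]`, and controlled vocabularies for the annotation classes.
#'
#' @param calls A data frame in the annotated-call layout (see
#'   [read_variant_calls()] for the column list).
#' @return The validated calls as a tibble (invisibly usable in pipes).
#' @export
validate_calls <- function(calls) {
  calls <- tibble::as_tibble(calls)
  missing <- setdiff(CALL_COLUMNS, names(calls))
  if (length(missing)) {
    stop("annotated-call table lacks columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  calls <- calls[CALL_COLUMNS]
  if (nrow(calls) == 0L) return(calls)
  if (any(calls$pos < 1L)) stop("pos must be >= 1", call. = FALSE)
  if (any(calls$ref == calls$alt)) stop("ref must differ from alt",
                                        call. = FALSE)
  if (any(calls$depth < 0)) stop("depth must be >= 0", call. = FALSE)
  if (any(calls$quality < 0)) stop("quality must be >= 0", call. = FALSE)
  maf <- calls$pop_max_maf
  if (any(!is.na(maf) & (maf < 0 | maf > 1))) {
    stop("pop_max_maf must lie in [0, 1]", call. = FALSE)
  }
  bad_vocab <- function(x, allowed, what) {
    x <- x[!is.na(x)]
    bad <- setdiff(unique(x), allowed)
    if (length(bad)) stop("invalid ", what, ": ",
                          paste(bad, collapse = ", "), call. = FALSE)
  }
  bad_vocab(calls$clinvar_class, CLINVAR_CLASSES, "clinvar_class")
  bad_vocab(calls$hgmd_class, HGMD_CLASSES, "hgmd_class")
  bad_vocab(calls$func_class, FUNC_CLASSES, "func_class")
  bad_vocab(calls$consequence, CONSEQUENCES, "consequence")
  if (any(!is.na(calls$exon) & calls$exon < 1L)) {
    stop("exon must be >= 1 when present", call. = FALSE)
  }
  calls
}

#' Read annotated variant calls from the flat TSV dialect
#'
#' One row per (sample, variant), with columns `sample_id, chrom, pos, ref,
#' alt, gene, transcript, hgvs_c, hgvs_p, depth, quality, caller, cosmic_id,
#' pop_max_maf, clinvar_class, hgmd_class, func_class, consequence, sift,
#' polyphen, cadd, exon`. Empty strings and `"."` are read as missing in the
#' annotation columns.
#'
#' @param path Path to a tab-separated file.
#' @return A validated tibble of calls.
#' @export
read_variant_calls <- function(path) {
  calls <- readr::read_tsv(
    path,
    na = c("", "NA", "."),
    col_types = readr::cols(
      sample_id = readr::col_character(), chrom = readr::col_character(),
      pos = readr::col_integer(), ref = readr::col_character(),
      alt = readr::col_character(), gene = readr::col_character(),
      transcript = readr::col_character(), hgvs_c = readr::col_character(),
      hgvs_p = readr::col_character(), depth = readr::col_integer(),
      quality = readr::col_double(), caller = readr::col_character(),
      cosmic_id = readr::col_character(),
      pop_max_maf = readr::col_double(),
      clinvar_class = readr::col_character(),
      hgmd_class = readr::col_character(),
      func_class = readr::col_character(),
      consequence = readr::col_character(),
      sift = readr::col_double(), polyphen = readr::col_double(),
      cadd = readr::col_double(), exon = readr::col_integer()
    ),
    progress = FALSE, show_col_types = FALSE
  )
  # hgvs_p uses the literal string "NA" for splice variants without a protein
  # consequence; restore it so downstream parsing sees the sentinel.
  calls$hgvs_p[is.na(calls$hgvs_p)] <- "NA"
  calls$clinvar_class[is.na(calls$clinvar_class)] <- "absent"
  calls$hgmd_class[is.na(calls$hgmd_class)] <- "absent"
  validate_calls(calls)
}

#' Read variant calls from a VCF with a sidecar annotation table
#'
#' Core fields (sample, coordinates, alleles, depth, quality) come from the
#' VCF; gene-level and database annotations are joined from a sidecar TSV
#' keyed by (chrom, pos, ref, alt). Multi-allelic records are split into one
#' row per alternate allele. Requires the `vcfR` package.
#'
#' @param vcf_path Path to a VCF file (the `DP` INFO/format field supplies
#'   depth; `QUAL` supplies quality).
#' @param annotation_path Path to a TSV with columns `chrom, pos, ref, alt`
#'   plus the annotation columns of the flat dialect.
#' @param sample_id Sample identifier to assign (VCFs here are per-sample).
#' @param caller Provenance tag recorded in the `caller` column.
#' @return A validated tibble of calls.
#' @export
read_variant_calls_vcf <- function(vcf_path, annotation_path, sample_id,
                                   caller = "vcf") {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("reading VCF input requires the 'vcfR' package", call. = FALSE)
  }
  vcf <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- tibble::as_tibble(as.data.frame(vcfR::getFIX(vcf),
                                         stringsAsFactors = FALSE))
  dp <- suppressWarnings(as.integer(vcfR::extract.info(vcf, "DP")))
  core <- tibble::tibble(
    chrom = fix$CHROM,
    pos = as.integer(fix$POS),
    ref = fix$REF,
    alt = fix$ALT,
    depth = ifelse(is.na(dp), 0L, dp),
    quality = suppressWarnings(as.numeric(fix$QUAL))
  )
  core$quality[is.na(core$quality)] <- 0
  core <- tidyr::separate_rows(core, "alt", sep = ",")
  ann <- readr::read_tsv(annotation_path, na = c("", "NA", "."),
                         progress = FALSE, show_col_types = FALSE)
  ann$pos <- as.integer(ann$pos)
  out <- dplyr::left_join(core, ann, by = c("chrom", "pos", "ref", "alt"))
  out$sample_id <- sample_id
  out$caller <- caller
  out$hgvs_p[is.na(out$hgvs_p)] <- "NA"
  out$clinvar_class[is.na(out$clinvar_class)] <- "absent"
  out$hgmd_class[is.na(out$hgmd_class)] <- "absent"
  out$exon <- as.integer(out$exon)
  validate_calls(out)
}

#' Read a sample sheet
#'
#' Expects columns `sample_id, group, mean_depth, coverage_fraction`, where
#' `group` is one of `COLITIS`, `IBD`, `CP`, `CRC`.
#'
#' @param path Path to a tab-separated sample sheet.
#' @return A validated tibble.
#' @export
read_sample_sheet <- function(path) {
  sheet <- readr::read_tsv(path, progress = FALSE, show_col_types = FALSE)
  validate_sample_sheet(sheet)
}

#' @rdname read_sample_sheet
#' @param sheet A data frame to validate in place of reading a file.
#' @export
validate_sample_sheet <- function(sheet) {
  sheet <- tibble::as_tibble(sheet)
  need <- c("sample_id", "group", "mean_depth", "coverage_fraction")
  missing <- setdiff(need, names(sheet))
  if (length(missing)) {
    stop("sample sheet lacks columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  bad <- setdiff(unique(sheet$group), GROUPS)
  if (length(bad)) {
    stop("unknown sample group(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  cf <- sheet$coverage_fraction
  if (any(!is.na(cf) & (cf < 0 | cf > 1))) {
    stop("coverage_fraction must lie in [0, 1]", call. = FALSE)
  }
  if (anyDuplicated(sheet$sample_id)) {
    stop("duplicate sample_id in sample sheet", call. = FALSE)
  }
  sheet
}

#' Write retained variants as a MAF-style table
#'
#' Emits a Mutation Annotation Format-like TSV (the column subset oncoplot
#' and lollipop tools consume): Hugo_Symbol, Chromosome, Start_Position,
#' Reference_Allele, Tumor_Seq_Allele2, Variant_Classification,
#' Variant_Type, Tumor_Sample_Barcode, HGVSc, HGVSp, Transcript_ID, Exon.
#'
#' @param calls A validated calls tibble (typically the retained set).
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_maf <- function(calls, path) {
  calls <- validate_calls(calls)
  classification <- vapply(seq_len(nrow(calls)), function(i) {
    switch(calls$consequence[i],
           missense = "Missense_Mutation",
           stopgain = "Nonsense_Mutation",
           frameshift = if (nchar(calls$ref[i]) > nchar(calls$alt[i]))
             "Frame_Shift_Del" else "Frame_Shift_Ins",
           nonframeshift_indel = "In_Frame_Indel",
           splice_site = "Splice_Site",
           synonymous = "Silent",
           "Targeted_Region")
  }, character(1))
  vtype <- ifelse(nchar(calls$ref) == 1L & nchar(calls$alt) == 1L, "SNP",
                  ifelse(nchar(calls$ref) > nchar(calls$alt), "DEL", "INS"))
  maf <- tibble::tibble(
    Hugo_Symbol = calls$gene,
    Chromosome = calls$chrom,
    Start_Position = calls$pos,
    Reference_Allele = calls$ref,
    Tumor_Seq_Allele2 = calls$alt,
    Variant_Classification = classification,
    Variant_Type = vtype,
    Tumor_Sample_Barcode = calls$sample_id,
    HGVSc = calls$hgvs_c,
    HGVSp = calls$hgvs_p,
    Transcript_ID = calls$transcript,
    Exon = calls$exon
  )
  readr::write_tsv(maf, path, progress = FALSE)
  invisible(path)
}

#' Read a GMT gene-set file
#'
#' Standard tab-separated GMT: one set per line — id, description, then
#' member gene symbols.
#'
#' @param path Path to a `.gmt` file.
#' @return A named list of `gene_set` lists, each with `id`, `name`,
#'   `members`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  sets <- lapply(lines, function(line) {
    parts <- strsplit(line, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3L) {
      stop("GMT line needs id, description and at least one member: '",
           substr(line, 1, 60), "'", call. = FALSE)
    }
    members <- unique(parts[-(1:2)])
    members <- members[nzchar(members)]
    if (!length(members)) stop("empty gene set: ", parts[1], call. = FALSE)
    list(id = parts[1], name = parts[2], members = members)
  })
  stats::setNames(sets, vapply(sets, `[[`, character(1), "id"))
}
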