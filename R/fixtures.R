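# Bundled mutation catalogs: three published-style tables of recurrent CRC
# panel mutations (shared CRC/precursor mutations, variants not previously
# reported in CRC, and likely-novel variants), shipped as plain TSV with
# checksums, plus a loader that expands printed per-group occurrence counts
# into per-sample annotated calls.

CATALOG_FILES <- c(
  common = "catalog_common_crc_precursor.tsv",
  crc_unreported = "catalog_crc_unreported.tsv",
  novel = "catalog_novel.tsv"
)

CATALOG_MD5 <- c(
  common = "df7ad6ad4b7fb088ce1aa0792275dd04",
  crc_unreported = "404fd98697863d42e832cdbe0a0a1b37",
  novel = "3ddeabbc8d30b245863b4869d0a3894e"
)

# transcripts the catalog coordinates refer to, where known
CATALOG_TRANSCRIPTS <- c(
  TP53 = "NM_001126115", APC = "NM_001127511", PIK3CA = "NM_006218",
  FBXW7 = "NM_001013415", CTNNB1 = "NM_001098209"
)

catalog_path <- function(which) {
  which <- match.arg(which, names(CATALOG_FILES))
  path <- system.file("extdata", CATALOG_FILES[[which]],
                      package = "crctriage", mustWork = TRUE)
  sum <- unname(tools::md5sum(path))
  if (!identical(sum, unname(CATALOG_MD5[[which]]))) {
    stop("catalog fixture '", which, "' fails its checksum (", sum, ")",
         call. = FALSE)
  }
  path
}

#' Read a bundled mutation catalog
#'
#' The package ships three catalogs of recurrent CRC-panel somatic
#' mutations as plain TSV fixtures: `"common"` (mutations seen both in CRC
#' and in precursor-lesion groups, with per-group occurrence counts),
#' `"crc_unreported"` (COSMIC-known variants whose association with CRC was
#' previously unreported), and `"novel"` (variants absent from every public
#' database). Files are checksum-verified on read.
#'
#' @param which One of `"common"`, `"crc_unreported"`, `"novel"`.
#' @return The catalog as a tibble with its printed columns (gene,
#'   position, id, type, class, HGVS.c, HGVS.p, occurrence counts).
#' @export
study_catalog <- function(which = c("common", "crc_unreported", "novel")) {
  which <- match.arg(which)
  readr::read_tsv(catalog_path(which), progress = FALSE,
                  show_col_types = FALSE)
}

# derive VCF-convention placeholder alleles from an HGVS.c event; the
# reference sequence is not shipped, so non-substitution alleles use 'N'
# anchors — identity stays consistent because every consumer derives
# alleles the same way.
alleles_from_event <- function(event) {
  switch(event$kind,
    substitution = list(ref = event$ref_base, alt = event$alt_base),
    deletion = {
      ndel <- event$end - event$start + 1L
      list(ref = paste0("N", strrep("N", ndel)), alt = "N")
    },
    duplication = {
      base <- if (!is.na(event$inserted)) event$inserted else "N"
      list(ref = substr(base, 1L, 1L),
           alt = paste0(substr(base, 1L, 1L), base))
    },
    insertion = list(ref = "N", alt = paste0("N", event$inserted)),
    delins = list(ref = paste0("N", strrep("N", event$end - event$start + 1L)),
                  alt = paste0("N", event$inserted))
  )
}

clinvar_from_class <- function(class) {
  vapply(class, function(cl) {
    if (is.na(cl)) return("absent")
    token <- strsplit(strsplit(cl, "/", fixed = TRUE)[[1]][1], "-",
                      fixed = TRUE)[[1]][1]
    token <- sub("#", "", token, fixed = TRUE)
    switch(token,
           PV = "pathogenic", LPV = "likely_pathogenic", VUS = "VUS",
           CIP = "conflicting", N = "absent", "absent")
  }, character(1), USE.NAMES = FALSE)
}

consequence_from_protein <- function(hgvs_p) {
  vapply(hgvs_p, function(h) {
    switch(parse_hgvs_p(h)$klass,
           missense = "missense", nonsense = "stopgain",
           frameshift = "frameshift", synonymous = "synonymous",
           splice_or_NA = "splice_site")
  }, character(1), USE.NAMES = FALSE)
}

#' Expand a bundled catalog into per-sample annotated calls
#'
#' Each catalog row is expanded into one call per printed occurrence, with
#' deterministic synthetic sample identifiers (rolling assignment within
#' each group so the per-row per-group occupancy matches the printed
#' counts). Alleles are placeholder VCF-convention alleles derived from the
#' HGVS.c string (`N`-anchored for indels, since no reference sequence is
#' shipped). Annotations encode the printed database id and class columns;
#' depth and quality are set comfortably above the cascade thresholds, and
#' database-absent variants carry damaging prediction scores, so a run
#' through the triage cascade retains every expanded call.
#'
#' @param which One of `"common"`, `"crc_unreported"`, `"novel"`.
#' @param group_sizes Named integer vector of group sizes used for the
#'   synthetic sample identifiers.
#' @return A validated calls tibble.
#' @export
load_catalog_calls <- function(which = c("common", "crc_unreported",
                                         "novel"),
                               group_sizes = c(COLITIS = 20, IBD = 20,
                                               CP = 38, CRC = 62)) {
  which <- match.arg(which)
  tab <- study_catalog(which)

  pos_split <- strsplit(tab$position, ":", fixed = TRUE)
  tab$chrom <- vapply(pos_split, `[[`, character(1), 1)
  tab$pos <- as.integer(vapply(pos_split, `[[`, character(1), 2))

  occ <- switch(which,
    common = tidyr::pivot_longer(
      tab, dplyr::all_of(c("n_ibd", "n_cp", "n_crc")),
      names_to = "occ_group", values_to = "occ_n") |>
      dplyr::mutate(occ_group = toupper(sub("^n_", "", .data$occ_group))),
    crc_unreported = dplyr::mutate(tab, occ_group = "CRC",
                                   occ_n = .data$crc_cases),
    novel = tab
  )
  occ <- occ[occ$occ_n > 0, ]

  counters <- stats::setNames(rep(0L, length(group_sizes)),
                              names(group_sizes))
  rows <- vector("list", nrow(occ))
  for (i in seq_len(nrow(occ))) {
    g <- occ$occ_group[i]
    n <- occ$occ_n[i]
    size <- group_sizes[[g]]
    idx <- ((counters[[g]] + seq_len(n) - 1L) %% size) + 1L
    counters[[g]] <- counters[[g]] + n
    event <- parse_hgvs_c(occ$hgvs_c[i])
    al <- alleles_from_event(event)
    cosmic <- occ$id[i]
    if (!is.na(cosmic) && !startsWith(cosmic, "COSM")) cosmic <- NA_character_
    has_class <- "class" %in% names(occ)
    clv <- if (has_class) clinvar_from_class(occ$class[i]) else "absent"
    novel_row <- is.na(cosmic)
    rows[[i]] <- tibble::tibble(
      sample_id = sprintf("%s%02d", g, idx),
      chrom = occ$chrom[i], pos = occ$pos[i],
      ref = al$ref, alt = al$alt,
      gene = occ$gene[i],
      transcript = unname(CATALOG_TRANSCRIPTS[occ$gene[i]]),
      hgvs_c = occ$hgvs_c[i], hgvs_p = occ$hgvs_p[i],
      depth = 500L, quality = 150,
      caller = "merged",
      cosmic_id = cosmic,
      pop_max_maf = NA_real_,
      clinvar_class = clv,
      hgmd_class = "absent",
      func_class = if (consequence_from_protein(occ$hgvs_p[i]) ==
                       "splice_site") "splicing" else "exonic",
      consequence = consequence_from_protein(occ$hgvs_p[i]),
      sift = if (novel_row) 0.01 else NA_real_,
      polyphen = if (novel_row) 0.95 else NA_real_,
      cadd = if (novel_row) 28 else NA_real_,
      exon = if ("exon" %in% names(occ)) as.integer(occ$exon[i])
             else NA_integer_
    )
  }
  validate_calls(dplyr::bind_rows(rows))
}

#' Sample sheet for the bundled catalogs
#'
#' A full-cohort sample sheet with the default group sizes and QC metrics
#' that pass sample-level QC, matching the synthetic sample identifiers
#' used by [load_catalog_calls()].
#'
#' @param group_sizes Named integer vector of group sizes.
#' @return A validated sample sheet tibble.
#' @export
catalog_sample_sheet <- function(group_sizes = c(COLITIS = 20, IBD = 20,
                                                 CP = 38, CRC = 62)) {
  rows <- lapply(names(group_sizes), function(g) {
    tibble::tibble(
      sample_id = sprintf("%s%02d", g, seq_len(group_sizes[[g]])),
      group = g, mean_depth = 700, coverage_fraction = 0.99
    )
  })
  validate_sample_sheet(dplyr::bind_rows(rows))
}

#' Path to a bundled resource file
#'
#' Convenience accessor for the package's shipped gene panel (mock
#' intervals), pathway GMT, protein-region map and resistance rules.
#'
#' @param name One of `"panel"`, `"pathways"`, `"regions"`, `"rules"`.
#' @return A file path.
#' @export
crctriage_resource <- function(name = c("panel", "pathways", "regions",
                                        "rules")) {
  name <- match.arg(name)
  file <- switch(name, panel = "panel_genes_mock.tsv",
                 pathways = "pathways.gmt",
                 regions = "protein_regions.tsv",
                 rules = "resistance_rules.tsv")
  system.file("extdata", file, package = "crctriage", mustWork = TRUE)
}
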