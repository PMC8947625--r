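# Cohort mutation-landscape summaries over retained somatic calls:
# group-occupancy partitions, diagnostic yield, burden, gene summaries,
# hotspots, novelty flags, anti-EGFR resistance rules, and the oncoplot /
# lollipop matrices.

PARTITION_LABELS <- c("COMMON_CRC_PRECURSOR", "CRC_ONLY", "CP_ONLY",
                      "IBD_ONLY", "OTHER")

join_groups <- function(calls, samples) {
  samples <- validate_sample_sheet(samples)
  unknown <- setdiff(unique(calls$sample_id), samples$sample_id)
  if (length(unknown)) {
    stop("calls reference samples absent from the sample sheet: ",
         paste(head(unknown, 5), collapse = ", "), call. = FALSE)
  }
  dplyr::left_join(calls,
                   samples[c("sample_id", "group")], by = "sample_id")
}

#' Partition retained variants by group occupancy
#'
#' Every distinct variant key is assigned exactly one label from its
#' occupancy pattern across cohort groups:
#' `COMMON_CRC_PRECURSOR` — seen in at least one CRC sample and at least one
#' IBD or CP sample; `CRC_ONLY` / `CP_ONLY` / `IBD_ONLY` — seen in exactly
#' one non-control group; `OTHER` — any remaining pattern (e.g. shared
#' between IBD and CP without CRC, or seen in controls only).
#'
#' @param retained Retained calls tibble (with `sample_id`).
#' @param samples Sample sheet tibble.
#' @return A tibble with one row per distinct variant key: the key columns,
#'   per-group occupancy sample counts (`n_colitis`, `n_ibd`, `n_cp`,
#'   `n_crc`) and `partition`.
#' @export
partition_by_group_occupancy <- function(retained, samples) {
  calls <- join_groups(tibble::as_tibble(retained), samples)
  if (nrow(calls) == 0L) {
    return(tibble::tibble(chrom = character(), pos = integer(),
                          ref = character(), alt = character(),
                          gene = character(), hgvs_c = character(),
                          n_colitis = integer(), n_ibd = integer(),
                          n_cp = integer(), n_crc = integer(),
                          partition = character()))
  }
  occ <- calls |>
    dplyr::distinct(.data$chrom, .data$pos, .data$ref, .data$alt,
                    .data$sample_id, .data$group,
                    gene = .data$gene, hgvs_c = .data$hgvs_c) |>
    dplyr::group_by(.data$chrom, .data$pos, .data$ref, .data$alt) |>
    dplyr::summarise(
      gene = dplyr::first(.data$gene),
      hgvs_c = dplyr::first(.data$hgvs_c),
      n_colitis = dplyr::n_distinct(.data$sample_id[.data$group == "COLITIS"]),
      n_ibd = dplyr::n_distinct(.data$sample_id[.data$group == "IBD"]),
      n_cp = dplyr::n_distinct(.data$sample_id[.data$group == "CP"]),
      n_crc = dplyr::n_distinct(.data$sample_id[.data$group == "CRC"]),
      .groups = "drop"
    )
  in_crc <- occ$n_crc > 0L
  in_prec <- occ$n_ibd > 0L | occ$n_cp > 0L
  occ$partition <- dplyr::case_when(
    in_crc & in_prec ~ "COMMON_CRC_PRECURSOR",
    in_crc & !in_prec ~ "CRC_ONLY",
    occ$n_cp > 0L & occ$n_ibd == 0L ~ "CP_ONLY",
    occ$n_ibd > 0L & occ$n_cp == 0L ~ "IBD_ONLY",
    TRUE ~ "OTHER"
  )
  # IBD and CP together without CRC is a multi-group pattern, not "_ONLY"
  occ$partition[!in_crc & occ$n_ibd > 0L & occ$n_cp > 0L] <- "OTHER"
  occ
}

#' Diagnostic yield per group
#'
#' Fraction of samples in each group carrying at least one retained somatic
#' variant. The denominator is the enrolled group size from the sample
#' sheet; percentages are rounded half-up to a whole percent. Empty groups
#' report an absent fraction.
#'
#' @param retained Retained calls tibble.
#' @param samples Sample sheet tibble.
#' @return A tibble with `group`, `n_samples`, `n_mutated`, `fraction`,
#'   `percent`.
#' @export
diagnostic_yield <- function(retained, samples) {
  samples <- validate_sample_sheet(samples)
  calls <- join_groups(tibble::as_tibble(retained), samples)
  mutated <- unique(calls$sample_id)
  samples |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(
      n_samples = dplyr::n(),
      n_mutated = sum(.data$sample_id %in% mutated),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      fraction = ifelse(.data$n_samples > 0,
                        .data$n_mutated / .data$n_samples, NA_real_),
      percent = round_half_up(100 * .data$fraction, 0)
    )
}

# round half away from zero at `digits` decimals (matches how whole-percent
# and one-decimal figures are conventionally printed; base round() ties to
# even)
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Per-group mutational burden
#'
#' Mean number of retained variant occurrences per mutated sample (samples
#' with zero retained variants are excluded from the denominator), reported
#' to one decimal.
#'
#' @param retained Retained calls tibble.
#' @param samples Sample sheet tibble.
#' @param scope `"all"`, or one of the partition labels to restrict the
#'   numerator to variants in that occupancy partition (e.g. `"CRC_ONLY"`
#'   for the cancer-specific burden).
#' @return A tibble with `group`, `n_mutated_samples`,
#'   `n_variant_occurrences`, `mean_per_mutated_sample` (NA when no sample
#'   is mutated) and `mean_rounded`.
#' @export
mutation_burden <- function(retained, samples, scope = "all") {
  calls <- join_groups(tibble::as_tibble(retained), samples)
  if (!identical(scope, "all")) {
    stopifnot(scope %in% PARTITION_LABELS)
    part <- partition_by_group_occupancy(retained, samples)
    keep <- part[part$partition == scope, c("chrom", "pos", "ref", "alt")]
    calls <- dplyr::semi_join(calls, keep,
                              by = c("chrom", "pos", "ref", "alt"))
  }
  groups <- unique(validate_sample_sheet(samples)$group)
  out <- calls |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(
      n_mutated_samples = dplyr::n_distinct(.data$sample_id),
      n_variant_occurrences = dplyr::n(),
      .groups = "drop"
    )
  out <- dplyr::right_join(out, tibble::tibble(group = groups),
                           by = "group") |>
    dplyr::mutate(
      n_mutated_samples = dplyr::coalesce(.data$n_mutated_samples, 0L),
      n_variant_occurrences = dplyr::coalesce(.data$n_variant_occurrences,
                                              0L),
      mean_per_mutated_sample = ifelse(
        .data$n_mutated_samples > 0,
        .data$n_variant_occurrences / .data$n_mutated_samples, NA_real_),
      mean_rounded = round_half_up(.data$mean_per_mutated_sample, 1)
    )
  dplyr::arrange(out, .data$group)
}

#' Per-gene mutation summaries
#'
#' For each gene: number of distinct mutated samples, the case fraction,
#' number of distinct variants and of variant occurrences, and the
#' SNP/INDEL split of the distinct variants (typed from HGVS.c). Sorted by
#' case count descending, ties alphabetical.
#'
#' @param retained Retained calls tibble.
#' @param samples Sample sheet tibble.
#' @param denominator_mode `"mutated_cases"` (samples with at least one
#'   retained variant — the convention used for per-gene case percentages)
#'   or `"enrolled"` (all samples in scope).
#' @param groups Optional subset of groups to restrict to (e.g. `"CRC"`).
#' @return A tibble of per-gene summaries with a `case_percent` column
#'   rounded half-up to whole percent.
#' @export
gene_summaries <- function(retained, samples,
                           denominator_mode = c("mutated_cases", "enrolled"),
                           groups = NULL) {
  denominator_mode <- match.arg(denominator_mode)
  samples <- validate_sample_sheet(samples)
  calls <- join_groups(tibble::as_tibble(retained), samples)
  if (!is.null(groups)) {
    calls <- calls[calls$group %in% groups, ]
    samples <- samples[samples$group %in% groups, ]
  }
  denom <- if (denominator_mode == "mutated_cases")
    dplyr::n_distinct(calls$sample_id) else nrow(samples)
  if (nrow(calls) == 0L) {
    return(tibble::tibble(gene = character(), n_cases_with_mutation = integer(),
                          case_fraction = double(), case_percent = double(),
                          n_distinct_variants = integer(),
                          n_variant_occurrences = integer(),
                          snp_count = integer(), indel_count = integer()))
  }
  typed <- calls |>
    dplyr::distinct(.data$gene, .data$chrom, .data$pos, .data$ref,
                    .data$alt, .data$hgvs_c) |>
    dplyr::mutate(vtype = vapply(.data$hgvs_c, function(h) {
      classify_variant_type(parse_hgvs_c(h))
    }, character(1)))
  type_tally <- typed |>
    dplyr::group_by(.data$gene) |>
    dplyr::summarise(snp_count = sum(.data$vtype == "SNP"),
                     indel_count = sum(.data$vtype == "INDEL"),
                     .groups = "drop")
  out <- calls |>
    dplyr::group_by(.data$gene) |>
    dplyr::summarise(
      n_cases_with_mutation = dplyr::n_distinct(.data$sample_id),
      n_distinct_variants = dplyr::n_distinct(
        variant_key(.data$chrom, .data$pos, .data$ref, .data$alt)),
      n_variant_occurrences = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::left_join(type_tally, by = "gene") |>
    dplyr::mutate(
      case_fraction = if (denom > 0)
        .data$n_cases_with_mutation / denom else NA_real_,
      case_percent = round_half_up(100 * .data$case_fraction, 0)
    ) |>
    dplyr::arrange(dplyr::desc(.data$n_cases_with_mutation), .data$gene)
  out[c("gene", "n_cases_with_mutation", "case_fraction", "case_percent",
        "n_distinct_variants", "n_variant_occurrences", "snp_count",
        "indel_count")]
}

#' Per-exon hotspot summary for one gene
#'
#' Distinct-variant counts per exon and their fractions of the gene's total.
#' Variants without an exon number are tallied under `"unassigned"` and
#' excluded from the fractions.
#'
#' @param gene Gene symbol.
#' @param retained Retained calls tibble.
#' @return A tibble with `exon` (character; `"unassigned"` possible),
#'   `n_distinct_variants` and `fraction` (NA for unassigned).
#' @export
hotspot_by_exon <- function(gene, retained) {
  calls <- tibble::as_tibble(retained)
  calls <- calls[calls$gene == gene, ]
  distinct <- dplyr::distinct(calls, .data$chrom, .data$pos, .data$ref,
                              .data$alt, .data$exon)
  tab <- distinct |>
    dplyr::mutate(exon = ifelse(is.na(.data$exon), "unassigned",
                                as.character(.data$exon))) |>
    dplyr::count(.data$exon, name = "n_distinct_variants")
  assigned_total <- sum(tab$n_distinct_variants[tab$exon != "unassigned"])
  tab$fraction <- ifelse(
    tab$exon == "unassigned", NA_real_,
    tab$n_distinct_variants / assigned_total)
  numeric_exon <- suppressWarnings(as.numeric(tab$exon))
  tab[order(is.na(numeric_exon), numeric_exon), ]
}

#' Per-protein-region hotspot summary for one gene
#'
#' Counts distinct variants whose protein residue (parsed from HGVS.p)
#' falls within each user-supplied region.
#'
#' @param gene Gene symbol.
#' @param retained Retained calls tibble.
#' @param regions A data frame with columns `region`, `start`, `end`
#'   (residue coordinates, closed interval).
#' @return A tibble with `region`, `n_distinct_variants`, `fraction` (of
#'   the gene's residue-mapped distinct variants).
#' @export
hotspot_by_region <- function(gene, retained, regions) {
  regions <- tibble::as_tibble(regions)
  stopifnot(all(c("region", "start", "end") %in% names(regions)))
  calls <- tibble::as_tibble(retained)
  calls <- calls[calls$gene == gene, ]
  distinct <- dplyr::distinct(calls, .data$chrom, .data$pos, .data$ref,
                              .data$alt, .data$hgvs_p)
  residues <- vapply(distinct$hgvs_p, function(h) {
    ev <- parse_hgvs_p(h)
    if (is.na(ev$residue)) NA_integer_ else ev$residue
  }, integer(1))
  residues <- residues[!is.na(residues)]
  n_total <- length(residues)
  counts <- vapply(seq_len(nrow(regions)), function(i) {
    sum(residues >= regions$start[i] & residues <= regions$end[i])
  }, integer(1))
  tibble::tibble(region = regions$region, n_distinct_variants = counts,
                 fraction = if (n_total > 0) counts / n_total else NA_real_)
}

#' Lollipop data for one gene
#'
#' Per-residue stacked occurrence counts by protein-event class, suitable
#' for a lollipop rendering. Variants whose HGVS.p carries no residue
#' (splice or unknown) are skipped with a message.
#'
#' @param gene Gene symbol.
#' @param retained Retained calls tibble.
#' @return A tibble with `residue`, `klass`, `n_occurrences`, sorted by
#'   residue.
#' @export
lollipop_data <- function(gene, retained) {
  calls <- tibble::as_tibble(retained)
  calls <- calls[calls$gene == gene, ]
  if (nrow(calls) == 0L) {
    return(tibble::tibble(residue = integer(), klass = character(),
                          n_occurrences = integer()))
  }
  events <- lapply(calls$hgvs_p, parse_hgvs_p)
  residue <- vapply(events, function(e) e$residue, integer(1))
  klass <- vapply(events, function(e) e$klass, character(1))
  skipped <- sum(is.na(residue))
  if (skipped > 0) {
    message("lollipop_data: skipping ", skipped,
            " occurrence(s) without a protein residue (splice or NA)")
  }
  tibble::tibble(residue = residue, klass = klass)[!is.na(residue), ] |>
    dplyr::count(.data$residue, .data$klass, name = "n_occurrences") |>
    dplyr::arrange(.data$residue, .data$klass)
}

#' Flag variants absent from every public database
#'
#' A variant is novel when it has no COSMIC id, no population frequency
#' record, and no ClinVar or HGMD classification.
#'
#' @param cosmic_id,pop_max_maf,clinvar_class,hgmd_class Annotation vectors
#'   (`NA`/`"absent"` meaning no record).
#' @return Logical vector.
#' @export
flag_novel <- function(cosmic_id, pop_max_maf, clinvar_class, hgmd_class) {
  is.na(cosmic_id) & is.na(pop_max_maf) &
    (is.na(clinvar_class) | clinvar_class == "absent") &
    (is.na(hgmd_class) | hgmd_class == "absent")
}

#' Default anti-EGFR resistance-marker rules
#'
#' Gene/exon combinations whose mutations predict resistance to anti-EGFR
#' monoclonal-antibody therapy in metastatic CRC: KRAS and NRAS exons 2, 3
#' and 4, BRAF exon 15, and PIK3CA exon 20.
#'
#' @return A tibble with columns `gene` and `exon`.
#' @export
default_resistance_rules <- function() {
  tibble::tibble(
    gene = c(rep("KRAS", 3), rep("NRAS", 3), "BRAF", "PIK3CA"),
    exon = c(2L, 3L, 4L, 2L, 3L, 4L, 15L, 20L)
  )
}

#' Flag samples carrying anti-EGFR resistance markers
#'
#' A sample is flagged when it carries at least one retained variant whose
#' (gene, exon) matches a rule. The cohort fraction uses the CRC group's
#' enrolled size as denominator.
#'
#' @param retained Retained calls tibble.
#' @param samples Sample sheet tibble.
#' @param rules A data frame with columns `gene` and `exon` (defaults to
#'   [default_resistance_rules()]).
#' @param panel_genes Optional character vector of panel genes; rule genes
#'   outside it trigger a warning but are kept.
#' @return A list with `flags` (per-CRC-sample tibble: `sample_id`,
#'   `flagged`), `n_flagged`, `fraction` and `percent` (of the CRC group).
#' @export
egfr_resistance_flags <- function(retained, samples,
                                  rules = default_resistance_rules(),
                                  panel_genes = NULL) {
  rules <- tibble::as_tibble(rules)
  stopifnot(all(c("gene", "exon") %in% names(rules)), nrow(rules) > 0)
  if (!is.null(panel_genes)) {
    off_panel <- setdiff(unique(rules$gene), panel_genes)
    if (length(off_panel)) {
      warning("resistance-rule gene(s) not on the panel: ",
              paste(off_panel, collapse = ", "), call. = FALSE)
    }
  }
  samples <- validate_sample_sheet(samples)
  calls <- join_groups(tibble::as_tibble(retained), samples)
  crc_samples <- samples$sample_id[samples$group == "CRC"]
  crc_calls <- calls[calls$group == "CRC" & !is.na(calls$exon), ]
  hits <- dplyr::semi_join(crc_calls, rules, by = c("gene", "exon"))
  flags <- tibble::tibble(
    sample_id = crc_samples,
    flagged = crc_samples %in% hits$sample_id
  )
  n_flagged <- sum(flags$flagged)
  fraction <- if (length(crc_samples)) n_flagged / length(crc_samples)
              else NA_real_
  list(flags = flags, n_flagged = n_flagged, fraction = fraction,
       percent = round_half_up(100 * fraction, 0))
}

CONSEQUENCE_SEVERITY <- c(stopgain = 3, frameshift = 3, splice_site = 2,
                          missense = 1, nonframeshift_indel = 1,
                          synonymous = 0, other = 0)

#' Gene-by-sample oncoplot matrix
#'
#' One cell per (gene, sample): the most severe consequence class among
#' that sample's retained variants in the gene (truncating classes —
#' stopgain/frameshift — outrank splice, which outranks missense and
#' in-frame indels). Genes are ordered by mutated-case count descending;
#' samples are grouped by cohort group.
#'
#' @param retained Retained calls tibble.
#' @param samples Sample sheet tibble.
#' @return A character matrix (genes x samples; `NA` for wild-type cells)
#'   with a `groups` attribute giving each column's cohort group.
#' @export
oncoplot_matrix <- function(retained, samples) {
  samples <- validate_sample_sheet(samples)
  calls <- join_groups(tibble::as_tibble(retained), samples)
  if (nrow(calls) == 0L) {
    m <- matrix(NA_character_, nrow = 0, ncol = 0)
    attr(m, "groups") <- character(0)
    return(m)
  }
  gene_order <- gene_summaries(retained, samples)$gene
  sample_order <- samples[order(factor(samples$group, levels = GROUPS),
                                samples$sample_id), ]
  cells <- calls |>
    dplyr::group_by(.data$gene, .data$sample_id) |>
    dplyr::summarise(
      cell = .data$consequence[which.max(
        CONSEQUENCE_SEVERITY[.data$consequence])],
      .groups = "drop"
    )
  m <- matrix(NA_character_, nrow = length(gene_order),
              ncol = nrow(sample_order),
              dimnames = list(gene_order, sample_order$sample_id))
  m[cbind(match(cells$gene, gene_order),
          match(cells$sample_id, sample_order$sample_id))] <- cells$cell
  attr(m, "groups") <- stats::setNames(sample_order$group,
                                       sample_order$sample_id)
  m
}
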