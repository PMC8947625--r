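test_that("occupancy partition labels match a direct re-derivation on random patterns", {
  set.seed(99)
  sheet <- make_sheet(
    c(paste0("I", 1:4), paste0("P", 1:4), paste0("C", 1:6), paste0("N", 1:2)),
    c(rep("IBD", 4), rep("CP", 4), rep("CRC", 6), rep("COLITIS", 2)))
  calls <- dplyr::bind_rows(lapply(1:100, function(i) {
    pos <- sample(1:40, 1) * 10L
    make_call(sample_id = sample(sheet$sample_id, 1), pos = pos,
              hgvs_c = paste0("c.", pos, "G>A"))
  }))
  part <- partition_by_group_occupancy(calls, sheet)

  # oracle: direct set-membership per key
  for (i in seq_len(nrow(part))) {
    k <- variant_key(part$chrom[i], part$pos[i], part$ref[i], part$alt[i])
    carriers <- calls$sample_id[variant_key(calls$chrom, calls$pos,
                                            calls$ref, calls$alt) == k]
    groups <- unique(sheet$group[sheet$sample_id %in% carriers])
    # control-group occupancy plays no role in the lesion partition
    groups <- setdiff(groups, "COLITIS")
    want <- if (length(groups) == 0) "OTHER"
    else if ("CRC" %in% groups && any(c("IBD", "CP") %in% groups))
      "COMMON_CRC_PRECURSOR"
    else if (identical(groups, "CRC")) "CRC_ONLY"
    else if (setequal(groups, "CP")) "CP_ONLY"
    else if (setequal(groups, "IBD")) "IBD_ONLY"
    else "OTHER"
    expect_equal(part$partition[i], want, label = k)
  }
  # labels are exhaustive and mutually exclusive over distinct keys
  expect_equal(nrow(part),
               length(unique(variant_key(calls$chrom, calls$pos,
                                         calls$ref, calls$alt))))
})

test_that("a variant in a single CRC sample is CRC_ONLY", {
  sheet <- make_sheet(c("T1", "I1"), c("CRC", "IBD"))
  part <- partition_by_group_occupancy(make_call(sample_id = "T1"), sheet)
  expect_equal(part$partition, "CRC_ONLY")
  expect_error(
    partition_by_group_occupancy(make_call(sample_id = "ghost"), sheet),
    "absent from the sample sheet")
})

test_that("diagnostic yield uses enrolled group sizes and half-up percent rounding", {
  sheet <- make_sheet(
    c(sprintf("T%02d", 1:62), sprintf("I%02d", 1:20)),
    c(rep("CRC", 62), rep("IBD", 20)))
  calls <- dplyr::bind_rows(
    lapply(sprintf("T%02d", 1:45), function(s) make_call(sample_id = s)),
    lapply(sprintf("I%02d", 1:8), function(s) make_call(sample_id = s)))
  yield <- diagnostic_yield(calls, sheet)
  crc <- yield[yield$group == "CRC", ]
  expect_equal(crc$n_mutated, 45L)
  expect_equal(crc$percent, 73)   # 45/62 = 72.58 -> 73
  ibd <- yield[yield$group == "IBD", ]
  expect_equal(ibd$percent, 40)   # 8/20
})

test_that("burden is occurrences per mutated sample to one decimal", {
  # 84 occurrences spread over 35 mutated CRC samples -> 2.4
  sheet <- make_sheet(sprintf("T%02d", 1:40), rep("CRC", 40))
  per_sample <- rep(84 %/% 35, 35)
  per_sample[seq_len(84 - sum(per_sample))] <-
    per_sample[seq_len(84 - sum(per_sample))] + 1L
  calls <- dplyr::bind_rows(lapply(1:35, function(i) {
    dplyr::bind_rows(lapply(seq_len(per_sample[i]), function(j) {
      pos <- i * 100L + j
      make_call(sample_id = sprintf("T%02d", i), pos = pos,
                hgvs_c = paste0("c.", pos, "G>A"))
    }))
  }))
  b <- mutation_burden(calls, sheet)
  expect_equal(b$n_variant_occurrences[b$group == "CRC"], 84L)
  expect_equal(b$n_mutated_samples[b$group == "CRC"], 35L)
  expect_equal(b$mean_rounded[b$group == "CRC"], 2.4)

  empty <- mutation_burden(calls[0, ], sheet)
  expect_true(is.na(empty$mean_per_mutated_sample))
})

test_that("gene summaries equal a brute-force tally and sort by case count", {
  set.seed(123)
  sheet <- make_sheet(paste0("S", 1:12), rep(c("CRC", "CP"), 6))
  genes <- c("TP53", "APC", "KRAS")
  calls <- dplyr::bind_rows(lapply(1:60, function(i) {
    g <- sample(genes, 1)
    pos <- sample(1:15, 1) * 3L
    type <- sample(c("snp", "del"), 1)
    make_call(sample_id = sample(sheet$sample_id, 1), gene = g,
              chrom = paste0("chr", match(g, genes)), pos = pos,
              ref = if (type == "snp") "G" else "GT",
              alt = if (type == "snp") "A" else "G",
              hgvs_c = if (type == "snp") paste0("c.", pos, "G>A")
                       else paste0("c.", pos, "del"))
  }))
  gs <- gene_summaries(calls, sheet)
  for (g in genes) {
    sub <- calls[calls$gene == g, ]
    keys <- unique(variant_key(sub$chrom, sub$pos, sub$ref, sub$alt))
    row <- gs[gs$gene == g, ]
    expect_equal(row$n_cases_with_mutation, length(unique(sub$sample_id)))
    expect_equal(row$n_distinct_variants, length(keys))
    expect_equal(row$n_variant_occurrences, nrow(sub))
    expect_equal(row$snp_count + row$indel_count, row$n_distinct_variants)
  }
  expect_true(all(diff(gs$n_cases_with_mutation) <= 0))
  # SNP/indel conservation across genes
  all_keys <- dplyr::distinct(calls, chrom, pos, ref, alt, hgvs_c)
  n_snp <- sum(grepl(">", all_keys$hgvs_c, fixed = TRUE))
  expect_equal(sum(gs$snp_count), n_snp)
  expect_equal(sum(gs$indel_count), nrow(all_keys) - n_snp)
})

test_that("exon hotspot fractions are per-gene distinct-variant shares", {
  set.seed(5)
  calls <- dplyr::bind_rows(lapply(1:30, function(i) {
    make_call(gene = "APC", pos = i * 10L,
              hgvs_c = paste0("c.", i, "G>A"),
              exon = if (i <= 26) 14L else sample(c(3L, 7L, NA), 1))
  }))
  hs <- hotspot_by_exon("APC", calls)
  assigned <- hs[hs$exon != "unassigned", ]
  expect_equal(sum(assigned$fraction), 1)
  ex14 <- hs$fraction[hs$exon == "14"]
  expect_equal(ex14, 26 / sum(assigned$n_distinct_variants))
  expect_gte(ex14, 0.85)
  # all variants in one exon
  one <- hotspot_by_exon("APC", make_call(gene = "APC", exon = 14L))
  expect_equal(one$fraction, 1)
})

test_that("region hotspots count residues inside user-supplied intervals", {
  calls <- dplyr::bind_rows(
    make_call(gene = "APC", pos = 1L, hgvs_p = "p.E1100K"),
    make_call(gene = "APC", pos = 2L, hgvs_p = "p.C1312fs"),
    make_call(gene = "APC", pos = 3L, hgvs_p = "p.R223X"))
  regions <- tibble::tibble(
    region = c("beta_catenin_binding", "beta_catenin_downregulation"),
    start = c(1020L, 1262L), end = c(1169L, 2033L))
  hr <- hotspot_by_region("APC", calls, regions)
  expect_equal(hr$n_distinct_variants, c(1L, 1L))
  expect_equal(hr$fraction, c(1 / 3, 1 / 3))
})

test_that("lollipop data stacks occurrence counts per residue and class", {
  calls <- dplyr::bind_rows(
    make_call(sample_id = "A", hgvs_p = "p.P46fs"),
    make_call(sample_id = "B", hgvs_p = "p.P46fs"),
    make_call(sample_id = "C", hgvs_p = "p.P46fs"),
    make_call(sample_id = "D", pos = 200L, hgvs_p = "p.R141C"),
    make_call(sample_id = "E", pos = 300L, hgvs_p = "p:NA"))
  expect_message(lp <- lollipop_data("TP53", calls), "skipping 1")
  expect_equal(lp$n_occurrences[lp$residue == 46], 3L)
  expect_equal(lp$klass[lp$residue == 46], "frameshift")
  expect_equal(lp$klass[lp$residue == 141], "missense")
  expect_equal(nrow(lollipop_data("TP53", calls[0, ])), 0L)
})

test_that("novelty means absence from every public database", {
  expect_true(flag_novel(NA, NA, "absent", "absent"))
  expect_false(flag_novel("COSM532", NA, "absent", "absent"))
  expect_false(flag_novel(NA, 0.001, "absent", "absent"))
  expect_false(flag_novel(NA, NA, "VUS", "absent"))
  expect_false(flag_novel(NA, NA, "absent", "disease_causing"))
})

test_that("resistance flags match gene/exon rules over CRC samples and are rule-monotone", {
  sheet <- make_sheet(c("T1", "T2", "T3", "P1"),
                      c("CRC", "CRC", "CRC", "CP"))
  calls <- dplyr::bind_rows(
    make_call(sample_id = "T1", gene = "KRAS", hgvs_c = "c.35G>A",
              exon = 2L),
    make_call(sample_id = "T2", gene = "PIK3CA", pos = 200L,
              hgvs_c = "c.200G>A", exon = 21L),
    make_call(sample_id = "P1", gene = "KRAS", pos = 300L,
              hgvs_c = "c.300G>A", exon = 2L))
  res <- egfr_resistance_flags(calls, sheet)
  expect_equal(res$flags$flagged[res$flags$sample_id == "T1"], TRUE)
  expect_equal(res$flags$flagged[res$flags$sample_id == "T2"], FALSE)
  expect_equal(res$n_flagged, 1L)
  expect_equal(res$fraction, 1 / 3)

  # adding a rule can only add flags
  wider <- dplyr::bind_rows(default_resistance_rules(),
                            tibble::tibble(gene = "PIK3CA", exon = 21L))
  res2 <- egfr_resistance_flags(calls, sheet, wider)
  expect_true(all(res$flags$flagged <= res2$flags$flagged))
  expect_warning(
    egfr_resistance_flags(calls, sheet, panel_genes = c("TP53")),
    "not on the panel")
})

test_that("oncoplot cells carry the most severe consequence per gene and sample", {
  sheet <- make_sheet(c("T1", "T2"), c("CRC", "CRC"))
  calls <- dplyr::bind_rows(
    make_call(sample_id = "T1", consequence = "missense"),
    make_call(sample_id = "T1", pos = 200L, hgvs_c = "c.200del",
              ref = "GT", alt = "G", consequence = "frameshift"),
    make_call(sample_id = "T2", gene = "APC", chrom = "chr5",
              consequence = "missense"))
  m <- oncoplot_matrix(calls, sheet)
  expect_equal(m["TP53", "T1"], "frameshift")
  expect_equal(m["APC", "T2"], "missense")
  expect_true(is.na(m["APC", "T1"]))
  expect_equal(unname(attr(m, "groups")["T1"]), "CRC")
  empty <- oncoplot_matrix(calls[0, ], sheet)
  expect_equal(dim(empty), c(0L, 0L))
})

test_that("landscape summaries are invariant to sample row order", {
  cohort <- generate_cohort(generator_config(seed = 21, group_sizes =
    c(COLITIS = 4, IBD = 4, CP = 4, CRC = 8)))
  res <- run_cascade(cohort$calls,
                     build_pooled_normal(cohort$calls, cohort$samples))
  set.seed(2)
  perm <- res$retained[sample(nrow(res$retained)), ]
  expect_equal(gene_summaries(res$retained, cohort$samples),
               gene_summaries(perm, cohort$samples))
  expect_equal(mutation_burden(res$retained, cohort$samples),
               mutation_burden(perm, cohort$samples))
  expect_equal(
    dplyr::arrange(partition_by_group_occupancy(res$retained,
                                                cohort$samples),
                   chrom, pos, ref, alt),
    dplyr::arrange(partition_by_group_occupancy(perm, cohort$samples),
                   chrom, pos, ref, alt))
})
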