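test_that("sample QC requires depth strictly above 100x and coverage strictly above 95%", {
  sheet <- make_sheet(paste0("S", 1:4), rep("CRC", 4),
                      mean_depth = c(500, 100, 500, NA),
                      coverage_fraction = c(0.99, 0.99, 0.95, 0.99))
  qc <- qc_samples(sheet)
  expect_equal(qc$qc_pass, c(TRUE, FALSE, FALSE, FALSE))
  expect_equal(qc$qc_reason,
               c(NA, "low_mean_depth", "low_coverage", "unmeasured"))
})

test_that("depth/quality gate fails below 200x depth or quality 100, boundaries pass", {
  res <- filter_depth_quality(depth = c(500, 199, 200, 200),
                              quality = c(150, 150, 99, 100))
  expect_equal(res$pass, c(TRUE, FALSE, FALSE, TRUE))
  expect_equal(res$reason, c(NA, "low_depth", "low_quality", NA))
})

test_that("functional gate keeps exonic/splicing non-synonymous variants only", {
  res <- filter_functional_class(
    func_class = c("exonic", "exonic", "intronic", "splicing", "UTR"),
    consequence = c("missense", "synonymous", "other", "splice_site",
                    "other"))
  expect_equal(res$pass, c(TRUE, FALSE, FALSE, TRUE, FALSE))
  expect_equal(res$reason,
               c(NA, "synonymous", "non_exonic_non_splicing", NA,
                 "non_exonic_non_splicing"))
})

test_that("damaging consensus needs two tool votes among at least two available tools", {
  # two of three damaging
  expect_equal(damaging_consensus(0.01, 0.9, 5, "missense")$consensus,
               "damaging")
  # one of three
  expect_equal(damaging_consensus(0.01, 0.1, 5, "missense")$consensus,
               "tolerated")
  # only one tool available
  expect_equal(damaging_consensus(0.01, NA, NA, "missense")$consensus,
               "insufficient")
  # two available, both damaging
  expect_equal(damaging_consensus(0.01, NA, 30, "missense")$consensus,
               "damaging")
  # truncating consequences are damaging regardless of scores
  for (csq in c("stopgain", "frameshift", "splice_site")) {
    expect_equal(damaging_consensus(NA, NA, NA, csq)$consensus, "damaging")
  }
  # boundary semantics: sift 0.05 and polyphen 0.446 are not damaging,
  # cadd 20 is
  d <- damaging_consensus(0.05, 0.446, 20, "missense")
  expect_equal(d$sift_damaging, "no")
  expect_equal(d$polyphen_damaging, "no")
  expect_equal(d$cadd_damaging, "yes")
})

test_that("database triage matches its documented rule examples", {
  known <- database_triage("COSM532", NA, "pathogenic", "absent",
                           "insufficient", FALSE)
  expect_equal(known$decision, "retained_known_somatic")

  common <- database_triage(NA_character_, 0.05, "absent", "absent",
                            "damaging", FALSE)
  expect_equal(common$decision, "excluded")
  expect_equal(common$reason, "common_polymorphism")

  novel <- database_triage(NA_character_, NA, "absent", "absent",
                           "damaging", FALSE)
  expect_equal(novel$decision, "retained_novel_candidate")

  benign_known <- database_triage("COSM1", NA, "benign", "absent",
                                  "damaging", FALSE)
  expect_equal(benign_known$reason, "benign_known")

  pooled <- database_triage(NA_character_, 0.005, "VUS", "absent",
                            "damaging", TRUE)
  expect_equal(pooled$reason, "pooled_normal")

  # exactly 1% population frequency passes ("larger than 1%" excludes)
  at_boundary <- database_triage(NA_character_, 0.01, "absent", "absent",
                                 "damaging", FALSE)
  expect_equal(at_boundary$decision, "retained_novel_candidate")
})

test_that("database triage equals exhaustive rule-table enumeration", {
  clinvar_classes <- c("pathogenic", "likely_pathogenic", "VUS",
                       "conflicting", "benign", "likely_benign", "absent")
  hgmd_classes <- c("disease_causing", "benign", "absent")
  grid <- expand.grid(
    cosmic_present = c(TRUE, FALSE), clinvar = clinvar_classes,
    hgmd = hgmd_classes, maf = c(NA, 0.005, 0.05),
    in_pool = c(TRUE, FALSE),
    consensus = c("damaging", "tolerated", "insufficient"),
    stringsAsFactors = FALSE)
  got <- database_triage(
    cosmic_id = ifelse(grid$cosmic_present, "COSM1", NA_character_),
    pop_max_maf = grid$maf, clinvar_class = grid$clinvar,
    hgmd_class = grid$hgmd, consensus = grid$consensus,
    in_pooled_normal = grid$in_pool)
  for (i in seq_len(nrow(grid))) {
    want <- oracle_triage_one(grid$cosmic_present[i], grid$clinvar[i],
                              grid$hgmd[i], grid$maf[i], grid$in_pool[i],
                              grid$consensus[i])
    expect_equal(got$decision[i], want$decision,
                 label = paste("decision, case", i))
    expect_equal(got$reason[i], want$reason,
                 label = paste("reason, case", i))
  }
})

test_that("dual-caller merge unions by genomic key with max depth/quality on collision", {
  v1 <- make_call(pos = 100L, depth = 300L, quality = 120, caller = "a")
  v2a <- make_call(pos = 200L, hgvs_c = "c.200G>A", depth = 250L,
                   quality = 110, caller = "a")
  v2b <- make_call(pos = 200L, hgvs_c = "c.200G>A", depth = 400L,
                   quality = 105, caller = "b")
  v3 <- make_call(pos = 300L, hgvs_c = "c.300G>A", depth = 500L,
                  quality = 130, caller = "b")
  merged <- merge_callsets(dplyr::bind_rows(v1, v2a),
                           dplyr::bind_rows(v2b, v3))
  expect_equal(nrow(merged), 3L)
  dup <- merged[merged$pos == 200L, ]
  expect_equal(dup$caller, "merged")
  expect_equal(dup$depth, 400L)   # max of the two callers
  expect_equal(dup$quality, 110)  # max, fields taken independently
  expect_equal(merged$pos, c(100L, 200L, 300L))

  expect_equal(nrow(merge_callsets(v1[0, ], v1)), 1L)
  expect_error(merge_callsets(v1, make_call(sample_id = "S2")),
               "more than one sample")
})

test_that("merge equals brute-force nested-loop de-duplication on random splits", {
  set.seed(42)
  calls <- dplyr::bind_rows(lapply(1:50, function(i) {
    make_call(pos = sample(1:30, 1) * 10L,
              chrom = sample(c("chr1", "chr2"), 1),
              depth = sample(200:900, 1), quality = sample(100:300, 1),
              caller = sample(c("a", "b"), 1))
  }))
  calls$hgvs_c <- paste0("c.", calls$pos, "G>A")
  half <- sample(c(TRUE, FALSE), 50, replace = TRUE)
  merged <- merge_callsets(calls[half, ], calls[!half, ])

  # oracle: naive scan collecting unique keys and per-key maxima
  keys <- unique(variant_key(calls$chrom, calls$pos, calls$ref, calls$alt))
  expect_equal(nrow(merged), length(keys))
  for (k in keys) {
    idx <- variant_key(calls$chrom, calls$pos, calls$ref, calls$alt) == k
    row <- merged[variant_key(merged$chrom, merged$pos, merged$ref,
                              merged$alt) == k, ]
    expect_equal(row$depth, max(calls$depth[idx]))
    expect_equal(row$quality, max(calls$quality[idx]))
  }
})

test_that("the pooled normal is the union of QC-passing control variants", {
  sheet <- make_sheet(c("C1", "C2", "T1"), c("COLITIS", "COLITIS", "CRC"))
  calls <- dplyr::bind_rows(
    make_call(sample_id = "C1", pos = 100L),
    make_call(sample_id = "C1", pos = 200L, hgvs_c = "c.200G>A"),
    make_call(sample_id = "C2", pos = 200L, hgvs_c = "c.200G>A"),
    make_call(sample_id = "C2", pos = 300L, hgvs_c = "c.300G>A"),
    make_call(sample_id = "C2", pos = 400L, hgvs_c = "c.400G>A",
              depth = 150L),  # below depth gate: not pooled
    make_call(sample_id = "T1", pos = 999L, hgvs_c = "c.999G>A")
  )
  pool <- build_pooled_normal(calls, sheet)
  expect_setequal(pool$keys, variant_key("chr1", c(100L, 200L, 300L),
                                         "G", "A"))
  expect_setequal(pool$source_samples, c("C1", "C2"))

  no_ctrl <- make_sheet("T1", "CRC")
  expect_error(build_pooled_normal(calls[6, ], no_ctrl), "no pooled normal")
})

test_that("every input call gets exactly one final verdict and one trace per stage", {
  set.seed(7)
  cohort <- generate_cohort(generator_config(seed = 7, group_sizes =
    c(COLITIS = 5, IBD = 5, CP = 5, CRC = 10)))
  pool <- build_pooled_normal(cohort$calls, cohort$samples)
  lesions <- cohort$calls[cohort$calls$sample_id %in%
    cohort$samples$sample_id[cohort$samples$group != "COLITIS"], ]
  res <- run_cascade(lesions, pool)

  expect_equal(nrow(res$verdicts), nrow(lesions))
  expect_equal(sum(res$verdicts$final == "excluded") + nrow(res$retained),
               nrow(lesions))
  # one trace row per call per stage
  expect_equal(nrow(res$trace), 3L * nrow(lesions))
  # first fail decides: no retained call has a fail anywhere
  retained_keys <- paste(res$retained$sample_id, res$retained$chrom,
                         res$retained$pos, res$retained$ref,
                         res$retained$alt)
  trace_keys <- paste(res$trace$sample_id, res$trace$chrom, res$trace$pos,
                      res$trace$ref, res$trace$alt)
  expect_false(any(res$trace$verdict == "fail" &
                     trace_keys %in% retained_keys))
  # excluded reasons tally with the verdict table
  t1 <- table(res$verdicts$reason[res$verdicts$final == "excluded"])
  t2 <- table(res$trace$reason[res$trace$verdict == "fail"])
  expect_equal(t1[sort(names(t1))], t2[sort(names(t2))])
})

test_that("permuting input order never changes the retained set or verdicts", {
  cohort <- generate_cohort(generator_config(seed = 11, group_sizes =
    c(COLITIS = 5, IBD = 3, CP = 3, CRC = 8)))
  pool <- build_pooled_normal(cohort$calls, cohort$samples)
  res1 <- run_cascade(cohort$calls, pool)
  set.seed(1)
  shuffled <- cohort$calls[sample(nrow(cohort$calls)), ]
  res2 <- run_cascade(shuffled, pool)
  key <- function(v) sort(paste(v$sample_id, v$chrom, v$pos, v$ref, v$alt,
                                v$final))
  expect_equal(key(res1$verdicts), key(res2$verdicts))
})

test_that("raising thresholds only ever shrinks the retained set", {
  cohort <- generate_cohort(generator_config(seed = 3, group_sizes =
    c(COLITIS = 5, IBD = 5, CP = 5, CRC = 10)))
  pool <- build_pooled_normal(cohort$calls, cohort$samples)
  base <- run_cascade(cohort$calls, pool)
  key <- function(v) paste(v$sample_id, v$chrom, v$pos, v$ref, v$alt)
  for (th in list(triage_thresholds(depth_min = 400),
                  triage_thresholds(qual_min = 200),
                  triage_thresholds(maf_max = 0.001))) {
    stricter <- run_cascade(cohort$calls, pool, th)
    expect_true(all(key(stricter$retained) %in% key(base$retained)))
  }
})

test_that("no retained novel candidate's key sits in the pooled normal", {
  cohort <- generate_cohort(generator_config(seed = 5))
  pool <- build_pooled_normal(cohort$calls, cohort$samples)
  res <- run_cascade(cohort$calls, pool)
  novel <- res$retained[res$retained$final == "retained_novel_candidate", ]
  expect_gt(nrow(novel), 0)
  expect_false(any(variant_key(novel$chrom, novel$pos, novel$ref,
                               novel$alt) %in% pool$keys))
})

test_that("calls without functional annotation are excluded as unannotated", {
  call <- make_call()
  call$func_class <- NA_character_
  res <- run_cascade(call)
  expect_equal(res$verdicts$final, "excluded")
  expect_equal(res$verdicts$reason, "unannotated")
})
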