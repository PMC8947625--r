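# The tumor-only somatic filtering cascade: sample QC, dual-caller merge,
# depth/quality and functional-class gates, database triage against
# COSMIC/ClinVar/HGMD and population frequency, pooled-normal subtraction,
# and a damaging-prediction consensus. Every variant gets an ordered audit
# trace; the first failing stage decides its fate.

CASCADE_STAGES <- c("depth_quality", "functional_class", "database_triage")

#' Default triage thresholds
#'
#' Depth and quality minima for variant retention, the population
#' minor-allele-frequency ceiling for novel candidates, sample-level QC
#' minima, and the damaging-prediction consensus settings. Boundary
#' semantics: a variant fails when `depth < depth_min` or
#' `quality < qual_min` (values equal to the threshold pass); a novel
#' candidate is excluded when `pop_max_maf > maf_max` (exactly `maf_max`
#' passes); sample QC uses strict inequalities (`mean_depth > qc_depth_min`,
#' `coverage_fraction > qc_coverage_min`).
#'
#' @param depth_min Minimum read depth for a variant call (default 200).
#' @param qual_min Minimum variant quality (default 100).
#' @param maf_max Maximum population MAF for a novel candidate
#'   (default 0.01).
#' @param qc_depth_min Sample mean on-target depth must exceed this
#'   (default 100).
#' @param qc_coverage_min Fraction of target regions covered must exceed
#'   this (default 0.95).
#' @param consensus_min Number of damaging votes required (default 2).
#' @param sift_max SIFT score below which a variant is called damaging
#'   (default 0.05).
#' @param polyphen_min PolyPhen-2 score above which a variant is called
#'   damaging (default 0.446).
#' @param cadd_min CADD phred at or above which a variant is called damaging
#'   (default 20).
#' @return A list of thresholds.
#' @export
triage_thresholds <- function(depth_min = 200, qual_min = 100,
                              maf_max = 0.01, qc_depth_min = 100,
                              qc_coverage_min = 0.95, consensus_min = 2L,
                              sift_max = 0.05, polyphen_min = 0.446,
                              cadd_min = 20) {
  stopifnot(depth_min > 0, qual_min > 0, maf_max > 0, consensus_min >= 1)
  list(depth_min = depth_min, qual_min = qual_min, maf_max = maf_max,
       qc_depth_min = qc_depth_min, qc_coverage_min = qc_coverage_min,
       consensus_min = as.integer(consensus_min), sift_max = sift_max,
       polyphen_min = polyphen_min, cadd_min = cadd_min)
}

#' Sample-level sequencing QC
#'
#' A sample is accepted only if its mean on-target depth strictly exceeds
#' `qc_depth_min` and its target coverage strictly exceeds
#' `qc_coverage_min`. Missing metrics reject with reason `"unmeasured"`.
#'
#' @param samples A sample sheet tibble (see [read_sample_sheet()]).
#' @param thresholds Output of [triage_thresholds()].
#' @return The sheet with added columns `qc_pass` (logical) and `qc_reason`.
#' @export
qc_samples <- function(samples, thresholds = triage_thresholds()) {
  samples <- validate_sample_sheet(samples)
  unmeasured <- is.na(samples$mean_depth) | is.na(samples$coverage_fraction)
  pass <- !unmeasured &
    samples$mean_depth > thresholds$qc_depth_min &
    samples$coverage_fraction > thresholds$qc_coverage_min
  reason <- rep(NA_character_, nrow(samples))
  reason[unmeasured] <- "unmeasured"
  reason[!unmeasured & !pass &
           samples$mean_depth <= thresholds$qc_depth_min] <- "low_mean_depth"
  low_cov <- !unmeasured & !pass & is.na(reason)
  reason[low_cov] <- "low_coverage"
  samples$qc_pass <- pass
  samples$qc_reason <- reason
  samples
}

#' Merge variant lists from two callers for one sample
#'
#' Union keyed by genomic identity (chrom, pos, ref, alt). A variant seen by
#' both callers collapses to one record with `caller = "merged"` and the
#' per-field maximum of depth and quality; annotation fields are taken from
#' the first caller's record. Output is sorted by (chrom, pos, ref, alt).
#'
#' @param calls_a,calls_b Calls tibbles from the same sample.
#' @return A merged, sorted calls tibble.
#' @export
merge_callsets <- function(calls_a, calls_b) {
  calls_a <- validate_calls(calls_a)
  calls_b <- validate_calls(calls_b)
  both <- dplyr::bind_rows(calls_a, calls_b)
  if (nrow(both) == 0L) return(both)
  if (length(unique(both$sample_id)) > 1L) {
    stop("merge_callsets: calls come from more than one sample",
         call. = FALSE)
  }
  both$.key <- variant_key(both$chrom, both$pos, both$ref, both$alt)
  merged <- both |>
    dplyr::group_by(.data$.key) |>
    dplyr::summarise(
      dplyr::across(!c("depth", "quality", "caller"), dplyr::first),
      depth = max(.data$depth),
      quality = max(.data$quality),
      caller = if (dplyr::n() > 1L) "merged" else dplyr::first(.data$caller),
      .groups = "drop"
    )
  merged$.key <- NULL
  merged <- merged[order(merged$chrom, merged$pos, merged$ref, merged$alt), ]
  validate_calls(merged)
}

#' Depth/quality gate for a variant call
#'
#' @param depth,quality Numeric vectors.
#' @param thresholds Output of [triage_thresholds()].
#' @return A tibble with columns `pass` and `reason` (`"low_depth"` when
#'   depth fails, else `"low_quality"` when quality fails, else `NA`).
#' @export
filter_depth_quality <- function(depth, quality,
                                 thresholds = triage_thresholds()) {
  low_depth <- depth < thresholds$depth_min
  low_qual <- quality < thresholds$qual_min
  tibble::tibble(
    pass = !low_depth & !low_qual,
    reason = dplyr::case_when(low_depth ~ "low_depth",
                              low_qual ~ "low_quality",
                              TRUE ~ NA_character_)
  )
}

#' Functional-class gate
#'
#' Retains exonic and splicing variants that are not synonymous; non-exonic,
#' non-splicing, and synonymous variants are dropped.
#'
#' @param func_class,consequence Character vectors (controlled vocabulary,
#'   see [validate_calls()]).
#' @return A tibble with columns `pass` and `reason`
#'   (`"non_exonic_non_splicing"` or `"synonymous"`).
#' @export
filter_functional_class <- function(func_class, consequence) {
  non_coding <- !(func_class %in% c("exonic", "splicing"))
  syn <- consequence == "synonymous"
  tibble::tibble(
    pass = !non_coding & !syn,
    reason = dplyr::case_when(non_coding ~ "non_exonic_non_splicing",
                              syn ~ "synonymous",
                              TRUE ~ NA_character_)
  )
}

#' Damaging-prediction consensus over SIFT, PolyPhen-2 and CADD
#'
#' Per-tool calls are tri-state (yes / no / unknown when the score is
#' absent): SIFT damaging when `score < sift_max`, PolyPhen-2 damaging when
#' `score > polyphen_min`, CADD damaging when `phred >= cadd_min`. The
#' consensus is `"damaging"` when at least `consensus_min` of the available
#' tools vote yes and at least `consensus_min` tools are available;
#' `"insufficient"` when fewer tools carry scores; otherwise `"tolerated"`.
#' Truncating consequences (stopgain, frameshift, splice_site) are damaging
#' regardless of scores.
#'
#' @param sift,polyphen,cadd Numeric score vectors (`NA` = unknown).
#' @param consequence Character vector of consequence classes.
#' @param thresholds Output of [triage_thresholds()].
#' @return A tibble with per-tool tri-state columns and a `consensus`
#'   column in `{"damaging", "tolerated", "insufficient"}`.
#' @export
damaging_consensus <- function(sift, polyphen, cadd, consequence,
                               thresholds = triage_thresholds()) {
  tri <- function(x, yes) {
    dplyr::case_when(is.na(x) ~ "unknown", yes ~ "yes", TRUE ~ "no")
  }
  sift_call <- tri(sift, sift < thresholds$sift_max)
  poly_call <- tri(polyphen, polyphen > thresholds$polyphen_min)
  cadd_call <- tri(cadd, cadd >= thresholds$cadd_min)
  yes_n <- (sift_call == "yes") + (poly_call == "yes") + (cadd_call == "yes")
  avail_n <- (sift_call != "unknown") + (poly_call != "unknown") +
    (cadd_call != "unknown")
  truncating <- consequence %in% c("stopgain", "frameshift", "splice_site")
  consensus <- dplyr::case_when(
    truncating ~ "damaging",
    avail_n < thresholds$consensus_min ~ "insufficient",
    yes_n >= thresholds$consensus_min ~ "damaging",
    TRUE ~ "tolerated"
  )
  tibble::tibble(sift_damaging = sift_call, polyphen_damaging = poly_call,
                 cadd_damaging = cadd_call, consensus = consensus)
}

#' Database triage of a variant
#'
#' The decision logic, applied in order:
#' \enumerate{
#'   \item COSMIC id present and not benign in ClinVar or HGMD →
#'     `retained_known_somatic`;
#'   \item COSMIC id present but benign in ClinVar/HGMD →
#'     `excluded` (`benign_known`);
#'   \item no COSMIC id and population MAF above `maf_max` →
#'     `excluded` (`common_polymorphism`);
#'   \item no COSMIC id and benign in ClinVar or HGMD →
#'     `excluded` (`benign`);
#'   \item no COSMIC id, MAF at most `maf_max` (or absent), key not in the
#'     pooled normal, and damaging consensus → `retained_novel_candidate`;
#'   \item otherwise `excluded` (`pooled_normal` or `not_damaging`).
#' }
#' Absent ClinVar/HGMD classes are not benign; an absent MAF is treated as
#' rare.
#'
#' @param cosmic_id Character vector (`NA` = absent).
#' @param pop_max_maf Numeric vector (`NA` = absent).
#' @param clinvar_class,hgmd_class Character vectors (controlled
#'   vocabulary).
#' @param consensus Damaging consensus per variant (from
#'   [damaging_consensus()]).
#' @param in_pooled_normal Logical vector: variant key observed in the
#'   pooled normal.
#' @param thresholds Output of [triage_thresholds()].
#' @return A tibble with columns `decision` in `{"retained_known_somatic",
#'   "retained_novel_candidate", "excluded"}` and `reason`.
#' @export
database_triage <- function(cosmic_id, pop_max_maf, clinvar_class,
                            hgmd_class, consensus, in_pooled_normal,
                            thresholds = triage_thresholds()) {
  has_cosmic <- !is.na(cosmic_id)
  benign <- clinvar_class %in% c("benign", "likely_benign") |
    hgmd_class == "benign"
  maf_high <- !is.na(pop_max_maf) & pop_max_maf > thresholds$maf_max
  decision <- character(length(cosmic_id))
  reason <- rep(NA_character_, length(cosmic_id))

  rule <- dplyr::case_when(
    has_cosmic & !benign ~ "a",
    has_cosmic & benign ~ "b",
    maf_high ~ "c",
    benign ~ "d",
    !in_pooled_normal & consensus == "damaging" ~ "e",
    in_pooled_normal ~ "f_pool",
    TRUE ~ "f_dmg"
  )
  decision <- dplyr::case_when(
    rule == "a" ~ "retained_known_somatic",
    rule == "e" ~ "retained_novel_candidate",
    TRUE ~ "excluded"
  )
  reason <- dplyr::case_when(
    rule == "b" ~ "benign_known",
    rule == "c" ~ "common_polymorphism",
    rule == "d" ~ "benign",
    rule == "f_pool" ~ "pooled_normal",
    rule == "f_dmg" ~ "not_damaging",
    TRUE ~ NA_character_
  )
  tibble::tibble(decision = decision, reason = reason)
}

#' Build the pooled normal from control-group samples
#'
#' Combines the variants of all QC-passing control (`COLITIS`) samples into
#' one set of genomic keys representing shared germline and systematic
#' calls. Control calls are depth/quality-filtered first, so sequencing
#' noise in controls cannot mask true somatic variants; the database-triage
#' stage is not applied to the pool.
#'
#' @param cohort_calls Calls tibble covering the whole cohort (controls
#'   included).
#' @param samples Sample sheet tibble.
#' @param thresholds Output of [triage_thresholds()].
#' @return A list of class `pooled_normal` with `keys` (character set of
#'   variant keys) and `source_samples`.
#' @export
build_pooled_normal <- function(cohort_calls, samples,
                                thresholds = triage_thresholds()) {
  cohort_calls <- validate_calls(cohort_calls)
  samples <- qc_samples(samples, thresholds)
  controls <- samples$sample_id[samples$group == "COLITIS" & samples$qc_pass]
  if (!length(samples$sample_id[samples$group == "COLITIS"])) {
    stop("no pooled normal: cohort contains no COLITIS control samples",
         call. = FALSE)
  }
  ctrl <- cohort_calls[cohort_calls$sample_id %in% controls, ]
  dq <- filter_depth_quality(ctrl$depth, ctrl$quality, thresholds)
  ctrl <- ctrl[dq$pass, ]
  keys <- sort(unique(variant_key(ctrl$chrom, ctrl$pos, ctrl$ref, ctrl$alt)))
  structure(list(keys = keys, source_samples = sort(controls)),
            class = "pooled_normal")
}

#' Run the full somatic filtering cascade
#'
#' Applies, in order, the depth/quality gate, the functional-class gate, and
#' database triage with pooled-normal membership and the damaging consensus.
#' Calls lacking the annotation columns needed at a stage are excluded with
#' reason `"unannotated"`. Each input call receives exactly one trace row
#' per applicable stage; the first failing stage fixes the final verdict.
#'
#' @param sample_calls Calls tibble (any number of samples).
#' @param pool A `pooled_normal` from [build_pooled_normal()], or `NULL` to
#'   skip pool membership (no key is then considered germline-shared).
#' @param thresholds Output of [triage_thresholds()].
#' @return A list with elements:
#'   \describe{
#'     \item{retained}{calls tibble of retained variants, plus columns
#'       `final` and `consensus`;}
#'     \item{trace}{long tibble of per-variant stage decisions
#'       (`sample_id`, key columns, `stage`, `verdict`, `reason`);}
#'     \item{verdicts}{one row per input call with `final` in
#'       `{"retained_known_somatic", "retained_novel_candidate",
#'       "excluded"}` and the deciding `reason`;}
#'     \item{stage_counts}{tibble of variants entering and surviving each
#'       stage.}
#'   }
#' @export
run_cascade <- function(sample_calls, pool = NULL,
                        thresholds = triage_thresholds()) {
  calls <- validate_calls(sample_calls)
  n <- nrow(calls)
  empty_trace <- tibble::tibble(sample_id = character(), chrom = character(),
                                pos = integer(), ref = character(),
                                alt = character(), stage = character(),
                                verdict = character(), reason = character())
  if (n == 0L) {
    return(list(
      retained = dplyr::mutate(calls, final = character(0),
                               consensus = character(0)),
      trace = empty_trace,
      verdicts = tibble::tibble(sample_id = character(), chrom = character(),
                                pos = integer(), ref = character(),
                                alt = character(), final = character(),
                                reason = character()),
      stage_counts = tibble::tibble(stage = CASCADE_STAGES,
                                    entered = 0L, survived = 0L)
    ))
  }

  key_cols <- calls[c("sample_id", "chrom", "pos", "ref", "alt")]
  unannotated <- is.na(calls$func_class) | is.na(calls$consequence)

  dq <- filter_depth_quality(calls$depth, calls$quality, thresholds)
  fc <- filter_functional_class(calls$func_class, calls$consequence)
  fc$pass[unannotated] <- FALSE
  fc$reason[unannotated] <- "unannotated"
  dmg <- damaging_consensus(calls$sift, calls$polyphen, calls$cadd,
                            calls$consequence, thresholds)
  in_pool <- if (is.null(pool)) rep(FALSE, n) else
    variant_key(calls$chrom, calls$pos, calls$ref, calls$alt) %in% pool$keys
  db <- database_triage(calls$cosmic_id, calls$pop_max_maf,
                        calls$clinvar_class, calls$hgmd_class,
                        dmg$consensus, in_pool, thresholds)

  # stage applicability: a stage only runs if every earlier stage passed
  s1_applies <- rep(TRUE, n)
  s2_applies <- dq$pass
  s3_applies <- dq$pass & fc$pass

  stage_tbl <- function(stage, applies, pass, reason) {
    out <- key_cols
    out$stage <- stage
    out$verdict <- dplyr::case_when(!applies ~ "not_applicable",
                                    pass ~ "pass", TRUE ~ "fail")
    out$reason <- ifelse(applies & !pass, reason, NA_character_)
    out
  }
  trace <- dplyr::bind_rows(
    stage_tbl("depth_quality", s1_applies, dq$pass, dq$reason),
    stage_tbl("functional_class", s2_applies, fc$pass, fc$reason),
    stage_tbl("database_triage", s3_applies,
              db$decision != "excluded", db$reason)
  )

  final <- dplyr::case_when(
    !dq$pass ~ "excluded",
    !fc$pass ~ "excluded",
    TRUE ~ db$decision
  )
  reason <- dplyr::case_when(
    !dq$pass ~ dq$reason,
    !fc$pass ~ fc$reason,
    final == "excluded" ~ db$reason,
    TRUE ~ NA_character_
  )
  verdicts <- dplyr::mutate(key_cols, final = final, reason = reason)

  stage_counts <- tibble::tibble(
    stage = CASCADE_STAGES,
    entered = c(sum(s1_applies), sum(s2_applies), sum(s3_applies)),
    survived = c(sum(dq$pass), sum(s2_applies & fc$pass),
                 sum(s3_applies & db$decision != "excluded"))
  )

  retained <- calls[final != "excluded", ]
  retained$final <- final[final != "excluded"]
  retained$consensus <- dmg$consensus[final != "excluded"]

  list(retained = retained, trace = trace, verdicts = verdicts,
       stage_counts = stage_counts)
}
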