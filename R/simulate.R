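# Seeded synthetic-cohort generator with ground-truth labels. The generator
# emulates the cohort structure the analysis assumes: four groups (a
# non-neoplastic colitis control group plus IBD, colonic-polyp and CRC
# lesions), group-dependent fractions of mutated samples and mutational
# burden, gene-weighted driver placement dominated by TP53 and APC, a 73/27
# SNP/indel split, and admixed germline and low-depth artifact calls.

#' Synthetic-cohort generator configuration
#'
#' Defaults encode the study conditions the package targets: group sizes
#' 20/20/38/62 (COLITIS/IBD/CP/CRC); per-group probability that a sample
#' carries at least one somatic mutation (CRC 0.73, CP 0.79, IBD 0.40);
#' per-group mean somatic burden among mutated samples (CRC 3.0, CP 2.7,
#' IBD 2.4; zero-truncated Poisson); SNP fraction 0.73 among somatic
#' variants; and gene weights from the shipped panel table (TP53 and APC
#' heaviest). Artifact and common-polymorphism calls are sprinkled into all
#' groups (controls included) at per-sample Poisson rates, and a pool of
#' shared germline variants is planted across the whole cohort so that
#' pooled-normal subtraction has work to do.
#'
#' @param seed Integer seed; the generator is deterministic given it.
#' @param group_sizes Named integer vector (COLITIS, IBD, CP, CRC).
#' @param mutated_prob Named per-group probability of being mutated
#'   (groups without an entry are never somatically mutated).
#' @param burden_mean Named per-group mean somatic variants per mutated
#'   sample.
#' @param snp_fraction Fraction of somatic variants that are SNPs.
#' @param novel_fraction Fraction of somatic catalog variants that are
#'   database-absent novel candidates (the rest are COSMIC-known).
#' @param artifact_rate Mean artifact calls (low depth or low quality) per
#'   sample.
#' @param common_polymorphism_rate Mean common-germline calls (population
#'   MAF above 1%, no COSMIC id) per sample.
#' @param shared_germline_n Number of distinct shared-germline variant
#'   keys planted cohort-wide.
#' @param shared_germline_carrier_prob Probability each sample carries each
#'   shared-germline variant.
#' @param somatic_catalog_n Number of distinct somatic variants available
#'   for sampling (recurrence across samples and groups arises from
#'   drawing out of this finite catalog).
#' @param panel Data frame of panel genes (gene, chrom, start, end,
#'   n_exons, weight); defaults to the shipped mock panel.
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(seed = 1L,
                             group_sizes = c(COLITIS = 20, IBD = 20,
                                             CP = 38, CRC = 62),
                             mutated_prob = c(CRC = 0.73, CP = 0.79,
                                              IBD = 0.40),
                             burden_mean = c(CRC = 3.0, CP = 2.7,
                                             IBD = 2.4),
                             snp_fraction = 0.73,
                             novel_fraction = 0.2,
                             artifact_rate = 0.8,
                             common_polymorphism_rate = 1.0,
                             shared_germline_n = 25L,
                             shared_germline_carrier_prob = 0.3,
                             somatic_catalog_n = 150L,
                             panel = NULL) {
  if (is.null(panel)) {
    panel <- readr::read_tsv(crctriage_resource("panel"),
                             progress = FALSE, show_col_types = FALSE)
  }
  stopifnot(
    all(group_sizes >= 0),
    all(mutated_prob >= 0 & mutated_prob <= 1),
    all(burden_mean > 0),
    snp_fraction >= 0, snp_fraction <= 1,
    novel_fraction >= 0, novel_fraction <= 1,
    artifact_rate >= 0, common_polymorphism_rate >= 0,
    shared_germline_n >= 0,
    shared_germline_carrier_prob >= 0, shared_germline_carrier_prob <= 1,
    somatic_catalog_n >= 1,
    all(c("gene", "chrom", "start", "end", "n_exons", "weight") %in%
          names(panel))
  )
  structure(
    list(seed = as.integer(seed), group_sizes = group_sizes,
         mutated_prob = mutated_prob, burden_mean = burden_mean,
         snp_fraction = snp_fraction, novel_fraction = novel_fraction,
         artifact_rate = artifact_rate,
         common_polymorphism_rate = common_polymorphism_rate,
         shared_germline_n = as.integer(shared_germline_n),
         shared_germline_carrier_prob = shared_germline_carrier_prob,
         somatic_catalog_n = as.integer(somatic_catalog_n),
         panel = tibble::as_tibble(panel)),
    class = "generator_config"
  )
}

# lambda of a zero-truncated Poisson with the requested mean:
# solve lambda / (1 - exp(-lambda)) = m
ztp_lambda <- function(m) {
  stopifnot(m > 1)
  stats::uniroot(function(l) l / (1 - exp(-l)) - m,
                 lower = 1e-8, upper = m, tol = 1e-10)$root
}

# draw from a zero-truncated Poisson by resampling zeros
rztpois <- function(n, lambda) {
  out <- stats::rpois(n, lambda)
  while (any(out == 0L)) {
    zero <- out == 0L
    out[zero] <- stats::rpois(sum(zero), lambda)
  }
  out
}

draw_panel_variant <- function(panel, type, gene_idx = NULL) {
  i <- if (is.null(gene_idx))
    sample.int(nrow(panel), 1L, prob = panel$weight) else gene_idx
  pos <- sample(panel$start[i]:panel$end[i], 1L)
  bases <- c("A", "C", "G", "T")
  if (type == "SNP") {
    ref <- sample(bases, 1L)
    alt <- sample(setdiff(bases, ref), 1L)
  } else if (stats::runif(1) < 0.5) {            # deletion
    ref <- paste0(sample(bases, 1L),
                  paste(sample(bases, sample(1:2, 1L), replace = TRUE),
                        collapse = ""))
    alt <- substr(ref, 1L, 1L)
  } else {                                        # insertion
    ref <- sample(bases, 1L)
    alt <- paste0(ref, paste(sample(bases, sample(1:2, 1L), replace = TRUE),
                             collapse = ""))
  }
  list(gene_idx = i, gene = panel$gene[i], chrom = panel$chrom[i],
       pos = pos, ref = ref, alt = alt,
       exon = sample.int(panel$n_exons[i], 1L))
}

hgvs_for <- function(type, ref, alt, cpos) {
  if (type == "SNP") {
    list(hgvs_c = paste0("c.", cpos, substr(ref, 1, 1), ">",
                         substr(alt, 1, 1)),
         hgvs_p = paste0("p.", sample(c("A", "D", "E", "F", "G", "I", "K",
                                        "L", "M", "N", "P", "Q", "S", "T",
                                        "V", "Y"), 1L),
                         max(1L, cpos %/% 3L),
                         sample(c("W", "R", "C", "H"), 1L)),
         consequence = "missense")
  } else if (nchar(ref) > nchar(alt)) {
    k <- nchar(ref) - nchar(alt)
    rng <- if (k == 1L) as.character(cpos) else
      paste0(cpos, "_", cpos + k - 1L)
    list(hgvs_c = paste0("c.", rng, "del"),
         hgvs_p = paste0("p.", sample(LETTERS[1:20], 1L),
                         max(1L, cpos %/% 3L), "fs"),
         consequence = "frameshift")
  } else {
    list(hgvs_c = paste0("c.", cpos, "_", cpos + 1L, "ins",
                         substring(alt, 2L)),
         hgvs_p = paste0("p.", sample(LETTERS[1:20], 1L),
                         max(1L, cpos %/% 3L), "fs"),
         consequence = "frameshift")
  }
}

blank_annotation <- function() {
  list(cosmic_id = NA_character_, pop_max_maf = NA_real_,
       clinvar_class = "absent", hgmd_class = "absent",
       sift = NA_real_, polyphen = NA_real_, cadd = NA_real_)
}

# one catalog entry: a distinct variant with fixed annotations shared by
# every sample that draws it
catalog_entry <- function(config, label, id) {
  type <- if (stats::runif(1) < config$snp_fraction) "SNP" else "INDEL"
  v <- draw_panel_variant(config$panel, type)
  cpos <- (v$pos - config$panel$start[v$gene_idx]) %/% 3L + 1L
  hg <- hgvs_for(type, v$ref, v$alt, cpos)
  ann <- blank_annotation()
  if (label == "somatic_known") {
    ann$cosmic_id <- sprintf("COSM%07d", id)
    ann$clinvar_class <- sample(c("pathogenic", "likely_pathogenic", "VUS",
                                  "conflicting"), 1L,
                                prob = c(0.4, 0.2, 0.3, 0.1))
    if (stats::runif(1) < 0.3) ann$pop_max_maf <- stats::runif(1, 0, 0.005)
  } else if (label == "somatic_novel") {
    ann$sift <- stats::runif(1, 0, 0.04)
    ann$polyphen <- stats::runif(1, 0.6, 1)
    ann$cadd <- stats::runif(1, 21, 35)
  } else if (label == "germline_common") {
    ann$pop_max_maf <- stats::runif(1, 0.011, 0.4)
    if (stats::runif(1) < 0.4) ann$clinvar_class <- "benign"
  } else if (label == "germline_shared") {
    # rare, damaging-looking, database-absent: only the pooled normal
    # can catch these
    ann$sift <- stats::runif(1, 0, 0.04)
    ann$polyphen <- stats::runif(1, 0.6, 1)
    ann$cadd <- stats::runif(1, 21, 35)
  }
  c(list(label = label, type = type, gene = v$gene, chrom = v$chrom,
         pos = v$pos, ref = v$ref, alt = v$alt, exon = v$exon,
         hgvs_c = hg$hgvs_c, hgvs_p = hg$hgvs_p,
         consequence = hg$consequence), ann)
}

#' Generate a synthetic annotated cohort with ground-truth labels
#'
#' Produces, deterministically for a fixed seed, the full input bundle the
#' pipeline consumes plus a truth table: per-sample annotated calls, a
#' sample sheet, and one ground-truth label per (sample, variant) from
#' `{somatic_known, somatic_novel, germline_common, germline_shared,
#' artifact}`. Somatic variants are drawn from a finite gene-weighted
#' catalog so the same variant recurs across samples and groups; mutated
#' samples draw a zero-truncated Poisson number of somatic variants with
#' their group's configured mean. Labels are consistent with annotations by
#' construction: artifacts have depth below 200 or quality below 100,
#' common polymorphisms have population MAF above 1% and no COSMIC id, and
#' shared germline variants are rare, damaging-looking, database-absent and
#' planted across all groups including the controls.
#'
#' @param config A [generator_config()].
#' @return A list with `calls` (validated calls tibble), `samples`
#'   (sample sheet), `truth` (tibble: sample_id, chrom, pos, ref, alt,
#'   label) and `config`.
#' @export
generate_cohort <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         globalenv()))
  set.seed(config$seed)

  groups <- names(config$group_sizes)
  samples <- dplyr::bind_rows(lapply(groups, function(g) {
    n <- config$group_sizes[[g]]
    if (n == 0L) return(NULL)
    tibble::tibble(
      sample_id = sprintf("S_%s_%03d", g, seq_len(n)),
      group = g,
      mean_depth = round(stats::runif(n, 400, 900)),
      coverage_fraction = round(stats::runif(n, 0.96, 0.999), 3)
    )
  }))

  # somatic catalog: finite set of distinct variants, known vs novel
  n_cat <- config$somatic_catalog_n
  labels <- ifelse(stats::runif(n_cat) < config$novel_fraction,
                   "somatic_novel", "somatic_known")
  somatic_catalog <- lapply(seq_len(n_cat), function(i) {
    catalog_entry(config, labels[i], i)
  })
  shared_catalog <- lapply(seq_len(config$shared_germline_n), function(i) {
    catalog_entry(config, "germline_shared", 10000L + i)
  })

  ztl <- lapply(config$burden_mean, ztp_lambda)

  call_rows <- list()
  truth_rows <- list()
  emit <- function(sample_id, entry, depth, quality) {
    row <- tibble::tibble(
      sample_id = sample_id, chrom = entry$chrom, pos = entry$pos,
      ref = entry$ref, alt = entry$alt, gene = entry$gene,
      transcript = NA_character_, hgvs_c = entry$hgvs_c,
      hgvs_p = entry$hgvs_p, depth = as.integer(depth), quality = quality,
      caller = "merged", cosmic_id = entry$cosmic_id,
      pop_max_maf = entry$pop_max_maf,
      clinvar_class = entry$clinvar_class, hgmd_class = entry$hgmd_class,
      func_class = "exonic", consequence = entry$consequence,
      sift = entry$sift, polyphen = entry$polyphen, cadd = entry$cadd,
      exon = as.integer(entry$exon)
    )
    call_rows[[length(call_rows) + 1L]] <<- row
    truth_rows[[length(truth_rows) + 1L]] <<- tibble::tibble(
      sample_id = sample_id, chrom = entry$chrom, pos = entry$pos,
      ref = entry$ref, alt = entry$alt, label = entry$label)
  }

  for (i in seq_len(nrow(samples))) {
    sid <- samples$sample_id[i]
    g <- samples$group[i]

    # somatic component (lesion groups only)
    p_mut <- if (g %in% names(config$mutated_prob))
      config$mutated_prob[[g]] else 0
    if (p_mut > 0 && stats::runif(1) < p_mut) {
      n_som <- rztpois(1L, ztl[[g]])
      picks <- sample.int(n_cat, min(n_som, n_cat))
      for (j in picks) {
        emit(sid, somatic_catalog[[j]],
             depth = round(stats::runif(1, 300, 1000)),
             quality = round(stats::runif(1, 110, 400)))
      }
    }

    # shared germline (all groups, controls included)
    carry <- stats::runif(config$shared_germline_n) <
      config$shared_germline_carrier_prob
    for (j in which(carry)) {
      emit(sid, shared_catalog[[j]],
           depth = round(stats::runif(1, 300, 1000)),
           quality = round(stats::runif(1, 110, 400)))
    }

    # private common polymorphisms
    n_common <- stats::rpois(1L, config$common_polymorphism_rate)
    for (j in seq_len(n_common)) {
      entry <- catalog_entry(config, "germline_common", 0L)
      emit(sid, entry, depth = round(stats::runif(1, 300, 1000)),
           quality = round(stats::runif(1, 110, 400)))
    }

    # artifacts: low depth and/or low quality
    n_art <- stats::rpois(1L, config$artifact_rate)
    for (j in seq_len(n_art)) {
      entry <- catalog_entry(config, "artifact", 0L)
      mode <- sample(c("depth", "quality", "both"), 1L)
      depth <- if (mode %in% c("depth", "both"))
        round(stats::runif(1, 20, 199)) else round(stats::runif(1, 300, 900))
      quality <- if (mode %in% c("quality", "both"))
        round(stats::runif(1, 5, 99)) else round(stats::runif(1, 110, 400))
      emit(sid, entry, depth = depth, quality = quality)
    }
  }

  calls <- validate_calls(dplyr::bind_rows(call_rows))
  truth <- dplyr::bind_rows(truth_rows)
  list(calls = calls, samples = validate_sample_sheet(samples),
       truth = truth, config = config)
}

#' Write a generated cohort to disk
#'
#' Emits the annotated-call TSV dialect, the sample sheet, and the
#' ground-truth label table.
#'
#' @param cohort Output of [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_tsv(cohort$calls, file.path(dir, "calls.tsv"),
                   progress = FALSE)
  readr::write_tsv(cohort$samples, file.path(dir, "samples.tsv"),
                   progress = FALSE)
  readr::write_tsv(cohort$truth, file.path(dir, "truth.tsv"),
                   progress = FALSE)
  invisible(dir)
}
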