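# In-code fixtures: a single annotated call with sensible defaults, small
# sample sheets, and a brute-force rule-table oracle for database triage.

make_call <- function(sample_id = "S1", chrom = "chr1", pos = 100L,
                      ref = "G", alt = "A", gene = "TP53",
                      transcript = NA_character_, hgvs_c = "c.100G>A",
                      hgvs_p = "p.G34R", depth = 500L, quality = 150,
                      caller = "merged", cosmic_id = NA_character_,
                      pop_max_maf = NA_real_, clinvar_class = "absent",
                      hgmd_class = "absent", func_class = "exonic",
                      consequence = "missense", sift = NA_real_,
                      polyphen = NA_real_, cadd = NA_real_,
                      exon = NA_integer_) {
  tibble::tibble(
    sample_id = sample_id, chrom = chrom, pos = as.integer(pos), ref = ref,
    alt = alt, gene = gene, transcript = transcript, hgvs_c = hgvs_c,
    hgvs_p = hgvs_p, depth = as.integer(depth), quality = quality,
    caller = caller, cosmic_id = cosmic_id, pop_max_maf = pop_max_maf,
    clinvar_class = clinvar_class, hgmd_class = hgmd_class,
    func_class = func_class, consequence = consequence, sift = sift,
    polyphen = polyphen, cadd = cadd, exon = as.integer(exon)
  )
}

make_sheet <- function(sample_ids, groups, mean_depth = 500,
                       coverage_fraction = 0.99) {
  tibble::tibble(sample_id = sample_ids, group = groups,
                 mean_depth = mean_depth,
                 coverage_fraction = coverage_fraction)
}

# independent single-case re-statement of the database-triage rule table,
# written as plain nested conditionals
oracle_triage_one <- function(cosmic_present, clinvar, hgmd, maf, in_pool,
                              consensus, maf_max = 0.01) {
  benign <- clinvar %in% c("benign", "likely_benign") || hgmd == "benign"
  if (cosmic_present) {
    if (!benign) return(list(decision = "retained_known_somatic",
                             reason = NA_character_))
    return(list(decision = "excluded", reason = "benign_known"))
  }
  if (!is.na(maf) && maf > maf_max) {
    return(list(decision = "excluded", reason = "common_polymorphism"))
  }
  if (benign) return(list(decision = "excluded", reason = "benign"))
  if (!in_pool && consensus == "damaging") {
    return(list(decision = "retained_novel_candidate",
                reason = NA_character_))
  }
  if (in_pool) return(list(decision = "excluded", reason = "pooled_normal"))
  list(decision = "excluded", reason = "not_damaging")
}

# exact upper-tail hypergeometric probability by the combinatorial formula
oracle_hyper_upper <- function(k, K, N, n) {
  js <- seq.int(k, min(K, n))
  if (k > min(K, n)) return(0)
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}
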