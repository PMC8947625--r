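# Gene-set over-representation analysis: one-sided upper-tail
# hypergeometric test of mutated genes against a background universe
# (default: the panel's gene list), with Benjamini-Hochberg adjustment.

#' Hypergeometric over-representation analysis
#'
#' For each gene set, tests whether the mutated genes (`hits`) are enriched
#' relative to the background universe using the upper-tail hypergeometric
#' probability `P(X >= k)` with `N` background genes, `K` of them in the
#' set, and `n` hits. Each set is intersected with the background before
#' testing; results are sorted by ascending p-value and adjusted across all
#' tested sets by Benjamini-Hochberg.
#'
#' @param hits Character vector of mutated gene symbols (must be a subset
#'   of `background`).
#' @param sets A list of gene sets as returned by [read_gmt()] (each a list
#'   with `id`, `name`, `members`).
#' @param background Character vector: the gene universe (e.g. the panel).
#' @return A tibble with columns `set_id`, `set_name`, `k`, `K`, `n`, `N`,
#'   `p_value`, `q_value`, `genes` (comma-separated hit genes in the set).
#' @export
hypergeometric_ora <- function(hits, sets, background) {
  background <- unique(background)
  hits <- unique(hits)
  if (!length(background)) stop("empty background universe", call. = FALSE)
  if (!length(hits)) stop("no mutated genes to test", call. = FALSE)
  stray <- setdiff(hits, background)
  if (length(stray)) {
    stop("hit gene(s) outside the background universe: ",
         paste(head(stray, 5), collapse = ", "), call. = FALSE)
  }
  N <- length(background)
  n <- length(hits)
  rows <- lapply(sets, function(s) {
    members <- intersect(s$members, background)
    K <- length(members)
    in_set <- intersect(hits, members)
    k <- length(in_set)
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    tibble::tibble(set_id = s$id, set_name = s$name, k = k, K = K,
                   n = n, N = N, p_value = p,
                   genes = paste(sort(in_set), collapse = ","))
  })
  out <- dplyr::bind_rows(rows)
  out$q_value <- benjamini_hochberg(out$p_value)
  dplyr::arrange(out, .data$p_value, .data$set_id)[
    c("set_id", "set_name", "k", "K", "n", "N", "p_value", "q_value",
      "genes")]
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up false-discovery-rate adjustment with monotonicity
#' enforcement, clipped at 1.
#'
#' @param p_values Numeric vector of p-values in `(0, 1]`.
#' @return Adjusted q-values in the input order.
#' @export
benjamini_hochberg <- function(p_values) {
  stopifnot(is.numeric(p_values))
  if (any(is.na(p_values) | p_values <= 0 | p_values > 1)) {
    stop("p-values must lie in (0, 1]", call. = FALSE)
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Pathway-by-gene somatic variant counts
#'
#' For each gene set, counts the distinct retained variants per member
#' gene (the per-gene tallies a pathway mutation-map displays). Genes
#' outside every set are absent from the result.
#'
#' @param retained Retained calls tibble.
#' @param sets A list of gene sets as returned by [read_gmt()].
#' @return A tibble with `set_id`, `gene`, `n_distinct_variants`.
#' @export
pathway_gene_matrix <- function(retained, sets) {
  calls <- tibble::as_tibble(retained)
  per_gene <- calls |>
    dplyr::distinct(.data$gene, .data$chrom, .data$pos, .data$ref,
                    .data$alt) |>
    dplyr::count(.data$gene, name = "n_distinct_variants")
  rows <- lapply(sets, function(s) {
    sub <- per_gene[per_gene$gene %in% s$members, ]
    if (nrow(sub) == 0L) return(NULL)
    tibble::tibble(set_id = s$id, gene = sub$gene,
                   n_distinct_variants = sub$n_distinct_variants)
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0L) {
    return(tibble::tibble(set_id = character(), gene = character(),
                          n_distinct_variants = integer()))
  }
  dplyr::arrange(out, .data$set_id, .data$gene)
}
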