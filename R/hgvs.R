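# HGVS coding-DNA and protein notation: a deliberately small grammar that
# covers substitutions, del, dup, ins, delins and single intronic-offset
# substitutions. Anything else is rejected loudly rather than guessed at.

#' Parse an HGVS coding-DNA change string
#'
#' Parses strings such as `"c.38G>A"`, `"c.4337_4338del"`, `"c.1252dupA"`,
#' `"c.76_77insT"`, `"c.100_101delinsTT"` and intronic-offset substitutions
#' such as `"c.3671+1G>A"` into a structured coding event.
#'
#' The supported grammar is intentionally narrow: substitution, deletion,
#' duplication, insertion, deletion-insertion, and substitutions at a single
#' intronic offset (`+k`/`-k`, flagged as not coding-exact). Unsupported
#' notation raises an error naming the offending string; nothing is silently
#' guessed.
#'
#' @param hgvs_c A single HGVS coding-DNA string beginning with `"c."`.
#' @return A list of class `coding_event` with elements `kind` (one of
#'   `"substitution"`, `"deletion"`, `"duplication"`, `"insertion"`,
#'   `"delins"`), `start`, `end` (coding positions, `start <= end`),
#'   `ref_base`/`alt_base` (set for substitutions, otherwise `NA`),
#'   `offset` (intronic offset, 0 for exonic positions) and
#'   `coding_exact` (`FALSE` when the position carries an intronic offset).
#' @examples
#' parse_hgvs_c("c.38G>A")
#' parse_hgvs_c("c.4337_4338del")
#' parse_hgvs_c("c.3671+1G>A")
#' @seealso [render_hgvs_c()], [parse_hgvs_p()], [classify_variant_type()]
#' @export
parse_hgvs_c <- function(hgvs_c) {
  stopifnot(is.character(hgvs_c), length(hgvs_c) == 1L, !is.na(hgvs_c))
  if (!startsWith(hgvs_c, "c.")) {
    stop("not an HGVS.c string (must begin with 'c.'): '", hgvs_c, "'",
         call. = FALSE)
  }
  body <- substring(hgvs_c, 3L)

  event <- function(kind, start, end, ref = NA_character_, alt = NA_character_,
                    offset = 0L, inserted = NA_character_) {
    structure(
      list(kind = kind, start = as.integer(start), end = as.integer(end),
           ref_base = ref, alt_base = alt, offset = as.integer(offset),
           coding_exact = offset == 0L, inserted = inserted),
      class = "coding_event"
    )
  }

  # substitution, optionally at an intronic offset: 38G>A, 3671+1G>A, 100-2A>T
  m <- regmatches(body, regexec("^(\\d+)([+-]\\d+)?([ACGT])>([ACGT])$", body))[[1]]
  if (length(m)) {
    off <- if (nzchar(m[3])) as.integer(m[3]) else 0L
    return(event("substitution", m[2], m[2], ref = m[4], alt = m[5],
                 offset = off))
  }

  # del / dup / ins / delins over a position or a range, with optional
  # trailing sequence (c.2916delT, c.1252dupA, c.100_101insTT, c.5_6delinsAG)
  m <- regmatches(
    body,
    regexec("^(\\d+)(?:_(\\d+))?(delins|del|dup|ins)([ACGT]*)$", body)
  )[[1]]
  if (length(m)) {
    start <- as.integer(m[2])
    end <- if (nzchar(m[3])) as.integer(m[3]) else start
    if (start > end) {
      stop("HGVS.c range start exceeds end in '", hgvs_c, "'", call. = FALSE)
    }
    kind <- switch(m[4],
                   del = "deletion", dup = "duplication",
                   ins = "insertion", delins = "delins")
    if (kind == "insertion" && !nzchar(m[5])) {
      stop("HGVS.c insertion without inserted sequence: '", hgvs_c, "'",
           call. = FALSE)
    }
    seq <- if (nzchar(m[5])) m[5] else NA_character_
    return(event(kind, start, end, inserted = seq))
  }

  stop("unsupported HGVS.c notation: '", hgvs_c, "'", call. = FALSE)
}

#' Render a coding event back to canonical HGVS.c
#'
#' Inverse of [parse_hgvs_c()] up to canonical form: parsing the rendered
#' string yields an identical event.
#'
#' @param event A `coding_event` as returned by [parse_hgvs_c()].
#' @return A single HGVS.c string.
#' @export
render_hgvs_c <- function(event) {
  stopifnot(inherits(event, "coding_event"))
  pos <- function(p) {
    off <- event$offset
    if (off == 0L) as.character(p)
    else paste0(p, ifelse(off > 0, "+", ""), off)
  }
  if (event$kind == "substitution") {
    return(paste0("c.", pos(event$start), event$ref_base, ">", event$alt_base))
  }
  range <- if (event$start == event$end) as.character(event$start)
           else paste0(event$start, "_", event$end)
  suffix <- switch(event$kind,
                   deletion = "del", duplication = "dup",
                   insertion = "ins", delins = "delins")
  seq <- if (is.na(event$inserted)) "" else event$inserted
  paste0("c.", range, suffix, seq)
}

#' Parse an HGVS protein change string
#'
#' Classifies protein-level changes into missense, nonsense (trailing `X` or
#' `*`), frameshift (trailing `fs`), synonymous (`p.X123X` with identical
#' residues, or `p.(=)`), or `splice_or_NA` for the `"NA"`/`"p:NA"` spellings
#' used for splice-site variants without a defined protein consequence.
#'
#' @param hgvs_p A single HGVS protein string beginning `"p."`, or one of
#'   `"NA"`, `"p:NA"`.
#' @return A list of class `protein_event` with elements `klass` (one of
#'   `"missense"`, `"nonsense"`, `"frameshift"`, `"synonymous"`,
#'   `"splice_or_NA"`) and `residue` (positive integer, `NA` for
#'   `splice_or_NA`).
#' @examples
#' parse_hgvs_p("p.G13D")
#' parse_hgvs_p("p.R64X")
#' parse_hgvs_p("p.P46fs")
#' @export
parse_hgvs_p <- function(hgvs_p) {
  stopifnot(is.character(hgvs_p), length(hgvs_p) == 1L)
  pe <- function(klass, residue = NA_integer_) {
    structure(list(klass = klass, residue = as.integer(residue)),
              class = "protein_event")
  }
  if (is.na(hgvs_p) || hgvs_p %in% c("NA", "p:NA", "p.?", ".")) {
    return(pe("splice_or_NA"))
  }
  if (!startsWith(hgvs_p, "p.")) {
    stop("not an HGVS.p string (must begin with 'p.' or be 'NA'): '",
         hgvs_p, "'", call. = FALSE)
  }
  body <- substring(hgvs_p, 3L)
  # one-letter amino-acid codes plus X/* for stop
  m <- regmatches(body, regexec("^([A-Z])(\\d+)(fs|[A-Z*])$", body))[[1]]
  if (!length(m)) {
    stop("malformed HGVS.p residue token: '", hgvs_p, "'", call. = FALSE)
  }
  residue <- as.integer(m[3])
  if (residue < 1L) stop("protein residue must be positive: '", hgvs_p, "'",
                         call. = FALSE)
  suffix <- m[4]
  klass <- if (suffix == "fs") "frameshift"
           else if (suffix %in% c("X", "*")) "nonsense"
           else if (suffix == m[2]) "synonymous"
           else "missense"
  pe(klass, residue)
}

#' Classify a coding event as SNP or INDEL
#'
#' Substitutions are SNPs; deletions, duplications, insertions and
#' deletion-insertions are INDELs.
#'
#' @param event A `coding_event` from [parse_hgvs_c()].
#' @return `"SNP"` or `"INDEL"`.
#' @export
classify_variant_type <- function(event) {
  stopifnot(inherits(event, "coding_event"))
  if (event$kind == "substitution") "SNP" else "INDEL"
}

#' Classify a base substitution as transition or transversion
#'
#' Purine–purine (A/G) and pyrimidine–pyrimidine (C/T) changes are
#' transitions; all purine–pyrimidine changes are transversions.
#'
#' @param ref_base,alt_base Single bases in `A`, `C`, `G`, `T`.
#' @return `"transition"` or `"transversion"`.
#' @export
classify_substitution_change <- function(ref_base, alt_base) {
  bases <- c(ref_base, alt_base)
  if (!all(bases %in% c("A", "C", "G", "T"))) {
    stop("substitution bases must be one of A, C, G, T (got '",
         ref_base, "'>'", alt_base, "')", call. = FALSE)
  }
  if (ref_base == alt_base) {
    stop("reference and alternative base are identical", call. = FALSE)
  }
  purines <- c("A", "G")
  same_family <- (ref_base %in% purines) == (alt_base %in% purines)
  if (same_family) "transition" else "transversion"
}

#' Genomic identity key for a variant
#'
#' Two calls with equal (chrom, pos, ref, alt) are the same variant for all
#' cross-sample and cross-group set logic; gene and HGVS.c are display-only
#' (transcript-numbering ambiguity makes HGVS unsafe as a key).
#'
#' @param chrom,pos,ref,alt Vectors of equal length.
#' @return A character vector of keys.
#' @export
variant_key <- function(chrom, pos, ref, alt) {
  paste(chrom, pos, ref, alt, sep = ":")
}
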