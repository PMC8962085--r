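#' Parse HGVS coding (c.) descriptions
#'
#' Extracts coding positions, intron offsets, the edit kind and the edit
#' length from an HGVS c. string. The parser covers the descriptions that
#' occur in clinical exome reports (substitutions, deletions, duplications,
#' insertions and delins, with optional intronic offsets); it is not a full
#' HGVS grammar. Whitespace anywhere inside the string is ignored, since
#' published tables frequently typeset spaces around ">".
#'
#' @param x character vector of HGVS c. descriptions (each starting "c.").
#' @return A tibble with one row per input: `raw`, `parsed` (logical),
#'   `start`, `end` (coding positions), `offset_start`, `offset_end`
#'   (signed intron offsets, `NA` when exonic), `edit_kind` (one of
#'   "substitution", "deletion", "duplication", "insertion", "delins",
#'   or `NA` when unparsed), `edit_length` (nucleotides affected) and
#'   `net_change` (signed change in coding length, 0 for substitutions,
#'   `NA` when unknown).
#' @examples
#' parse_hgvs_c(c("c.966del", "c.1608-2A > G", "c.2161_2183dup"))
#' @export
parse_hgvs_c <- function(x) {
  stopifnot(is.character(x))
  purrr::map_dfr(x, parse_hgvs_c_one)
}

# one coding position with optional intron offset: 123, 123+5, 123-2
.pos_re <- "(\\d+)([+-]\\d+)?"

parse_hgvs_c_one <- function(raw) {
  unparsed <- tibble::tibble(
    raw = raw, parsed = FALSE,
    start = NA_integer_, end = NA_integer_,
    offset_start = NA_integer_, offset_end = NA_integer_,
    edit_kind = NA_character_, edit_length = NA_integer_,
    net_change = NA_integer_
  )
  if (is.na(raw)) return(unparsed)
  s <- gsub("\\s+", "", raw)
  if (!startsWith(s, "c.")) return(unparsed)
  body <- substr(s, 3L, nchar(s))

  span_re <- paste0("^", .pos_re, "(?:_", .pos_re, ")?")
  m <- regexpr(span_re, body, perl = TRUE)
  if (m == -1L) return(unparsed)
  span <- regmatches(body, m)
  rest <- substr(body, attr(m, "match.length") + 1L, nchar(body))
  g <- regmatches(span, regexec(span_re, span, perl = TRUE))[[1]]
  start <- as.integer(g[2])
  off_s <- if (nzchar(g[3])) as.integer(g[3]) else NA_integer_
  end <- if (nzchar(g[4])) as.integer(g[4]) else start
  off_e <- if (nzchar(g[5])) as.integer(g[5]) else if (nzchar(g[4])) NA_integer_ else off_s
  if (isTRUE(off_s == 0L) || isTRUE(off_e == 0L)) return(unparsed)
  span_len <- end - start + 1L
  if (span_len < 1L) return(unparsed)

  out <- function(kind, len, net) {
    tibble::tibble(
      raw = raw, parsed = TRUE, start = start, end = end,
      offset_start = off_s, offset_end = off_e,
      edit_kind = kind, edit_length = as.integer(len),
      net_change = as.integer(net)
    )
  }

  if (grepl("^[ACGTN]>[ACGTN]$", rest)) {
    if (start != end) return(unparsed)
    return(out("substitution", 1L, 0L))
  }
  if (grepl("^del[ACGTN]*ins[ACGTN]+$", rest)) {
    ins_len <- nchar(sub("^del[ACGTN]*ins", "", rest))
    return(out("delins", span_len, ins_len - span_len))
  }
  if (grepl("^del([ACGTN]*|\\d*)$", rest)) {
    return(out("deletion", span_len, -span_len))
  }
  if (grepl("^dup[ACGTN]*$", rest)) {
    return(out("duplication", span_len, span_len))
  }
  if (grepl("^ins[ACGTN]+$", rest)) {
    ins_len <- nchar(sub("^ins", "", rest))
    return(out("insertion", ins_len, ins_len))
  }
  if (grepl("^ins", rest)) {
    # inserted sequence of unknown length (e.g. "ins(20)") stays unparsed
    return(unparsed)
  }
  unparsed
}

#' Derive the structural consequence category of a coding variant
#'
#' Maps a parsed HGVS c. description (and, for substitutions, an optional
#' protein-level description) onto one structural category. Splice
#' assignment takes precedence: an intron offset of +/-1 or +/-2 is a
#' canonical splice-site change, any other nonzero offset a splice-region
#' change. Exonic length-changing edits are frameshift when the net length
#' change is not a multiple of three, in-frame otherwise. Substitutions
#' resolve to missense / stop-gain / synonymous only when a protein
#' annotation is supplied; transcript sequences are not bundled, so without
#' one the category is `substitution_unresolved`.
#'
#' @param parsed tibble from [parse_hgvs_c()].
#' @param hgvs_p optional character vector of HGVS p. descriptions
#'   (recycled `NA` when absent).
#' @return character vector of categories: one of `missense`, `stop_gain`,
#'   `synonymous`, `substitution_unresolved`, `frameshift`, `inframe_indel`,
#'   `canonical_splice`, `splice_region`, `other`.
#' @examples
#' classify_consequence(parse_hgvs_c("c.1608-2A>G"))   # canonical_splice
#' classify_consequence(parse_hgvs_c("c.966del"))      # frameshift
#' @export
classify_consequence <- function(parsed, hgvs_p = NULL) {
  n <- nrow(parsed)
  if (is.null(hgvs_p)) hgvs_p <- rep(NA_character_, n)
  hgvs_p <- rep_len(hgvs_p, n)
  purrr::map2_chr(seq_len(n), hgvs_p, function(i, p) {
    classify_consequence_one(parsed[i, ], p)
  })
}

classify_consequence_one <- function(h, hgvs_p) {
  if (!isTRUE(h$parsed)) return("other")
  offs <- c(h$offset_start, h$offset_end)
  offs <- offs[!is.na(offs)]
  if (length(offs) > 0) {
    if (any(abs(offs) <= 2L)) return("canonical_splice")
    return("splice_region")
  }
  if (h$edit_kind == "substitution") {
    if (is.na(hgvs_p) || !nzchar(hgvs_p)) return("substitution_unresolved")
    p <- gsub("\\s+", "", hgvs_p)
    if (grepl("Ter|\\*$|\\*\\)?$", p)) return("stop_gain")
    if (grepl("=\\)?$", p)) return("synonymous")
    return("missense")
  }
  if (is.na(h$net_change)) return("other")
  if (h$net_change %% 3L != 0L) return("frameshift")
  "inframe_indel"
}

#' @noRd
normalize_gene <- function(gene) {
  g <- toupper(gsub("\\s+", "", gene))
  # published tables occasionally carry transposed spellings; map known
  # aliases onto one key so assertions and entries join correctly
  aliases <- c(HUEW1 = "HUWE1")
  hit <- unname(aliases[g])
  as.character(ifelse(is.na(hit), g, hit))
}

#' Normalised variant key
#'
#' Builds the `GENE|TRANSCRIPT|c.` key used to join variants with
#' knowledge-base assertions and frequencies. Whitespace is stripped, the
#' c. string is otherwise byte-preserved (no 3'-shifting or other HGVS
#' canonicalisation), and known gene-symbol aliases are collapsed.
#'
#' @param gene,transcript,hgvs_c character vectors (recycled).
#' @return character vector of keys.
#' @export
variant_key <- function(gene, transcript, hgvs_c) {
  paste(
    normalize_gene(gene),
    gsub("\\s+", "", transcript),
    gsub("\\s+", "", hgvs_c),
    sep = "|"
  )
}

#' Annotate a variant table with keys and consequence categories
#'
#' @param variants tibble with columns `gene`, `transcript`, `hgvs_c` and
#'   optionally `hgvs_p`.
#' @return the input with `variant_key` and `consequence` columns added.
#' @export
annotate_variants <- function(variants) {
  stopifnot(all(c("gene", "transcript", "hgvs_c") %in% names(variants)))
  hp <- if ("hgvs_p" %in% names(variants)) variants$hgvs_p else NULL
  parsed <- parse_hgvs_c(variants$hgvs_c)
  variants |>
    dplyr::mutate(
      variant_key = variant_key(.data$gene, .data$transcript, .data$hgvs_c),
      consequence = classify_consequence(parsed, hp)
    )
}

#' Enumerate potential compound heterozygotes in one gene
#'
#' For an autosomal-recessive (or dominant-and/or-recessive) gene, returns
#' every unordered pair of heterozygous variants a patient carries plus a
#' self-pair for each homozygous variant. A pair is phase-known when either
#' member's allele origin confirms trans configuration; otherwise the pair
#' is a *potential* compound heterozygote.
#'
#' @param variants tibble of one patient's variants in one gene, with
#'   columns `variant_key`, `zygosity`, `allele_origin`.
#' @param inheritance the gene-disease inheritance mode ("AD", "AR", "XL",
#'   "AD_AR").
#' @return tibble with columns `key1`, `key2`, `homozygous`, `phase_known`;
#'   zero rows for non-recessive inheritance.
#' @export
potential_comp_het <- function(variants, inheritance) {
  empty <- tibble::tibble(
    key1 = character(), key2 = character(),
    homozygous = logical(), phase_known = logical()
  )
  if (!inheritance %in% c("AR", "AD_AR")) return(empty)
  hom <- variants |> dplyr::filter(.data$zygosity == "homozygous")
  het <- variants |> dplyr::filter(.data$zygosity == "heterozygous")
  self_pairs <- tibble::tibble(
    key1 = hom$variant_key, key2 = hom$variant_key,
    homozygous = TRUE,
    phase_known = TRUE
  )
  pairs <- empty
  if (nrow(het) >= 2) {
    idx <- utils::combn(nrow(het), 2)
    pairs <- tibble::tibble(
      key1 = het$variant_key[idx[1, ]],
      key2 = het$variant_key[idx[2, ]],
      homozygous = FALSE,
      phase_known = het$allele_origin[idx[1, ]] == "trans_confirmed" |
        het$allele_origin[idx[2, ]] == "trans_confirmed"
    )
  }
  dplyr::bind_rows(self_pairs, pairs)
}
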