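#' @title HGVS parsing for ARMC5 variant curation
#' @description
#' Tolerant parsers for the cDNA ("c.") and protein ("p.") variant
#' descriptions used in published ARMC5 variant tables (transcript
#' NM_001105247.1, 935-residue protein). The lexer absorbs common
#' typesetting artifacts: stray whitespace ("c.407 T>C"), trailing explicit
#' bases on dup/del ("c.2697dupG"), a parenthesized alias form
#' ("c.170del (= c.165del)"), protein descriptions with the parenthesis
#' around "p." ("(p.Ala110Asp)") and frameshift tokens with a misplaced
#' asterisk ("fs44*" read as "fs*44").
#' @name hgvs
NULL

# three-letter amino-acid codes accepted in protein descriptions
AA3 <- c("Ala", "Arg", "Asn", "Asp", "Cys", "Gln", "Glu", "Gly", "His",
         "Ile", "Leu", "Lys", "Met", "Phe", "Pro", "Ser", "Thr", "Trp",
         "Tyr", "Val", "Sec", "Ter")

.aa_rx <- paste0("(?:", paste(AA3, collapse = "|"), ")")

#' Parse an HGVS cDNA description
#'
#' Accepts substitutions, deletions, duplications, insertions and
#' deletion-insertions on c. coordinates, including intronic offsets
#' (`c.475+1G>A`, `c.476-2A>G`) and spans whose end lies in an intron
#' (`c.456_475+5del`). Unsupported HGVS constructs (inversions, extensions,
#' repeats) raise an error rather than misparse.
#'
#' @param text a single HGVS cDNA string beginning with `"c."`, optionally
#'   carrying typesetting whitespace or a parenthesized alias.
#' @return an object of class `cdna_change`: a list with `raw_text`,
#'   `start`, `start_offset`, `end`, `end_offset`, `edit_kind` (one of
#'   `"substitution"`, `"deletion"`, `"duplication"`, `"insertion"`,
#'   `"delins"`), `ref_bases`, `alt_bases` and `alias_of`.
#' @examples
#' parse_cdna("c.799C>T")
#' parse_cdna("c.475 + 1G>A")$start_offset
#' format(parse_cdna("c.2697dupG"))  # normalized: "c.2697dup"
#' @export
parse_cdna <- function(text) {
  stopifnot(is.character(text), length(text) == 1L, !is.na(text))
  raw <- text
  s <- gsub("[[:space:]]+", "", text)

  alias_of <- NA_character_
  m <- regmatches(s, regexec("^(.*?)\\(=(c\\.[^)]+)\\)$", s))[[1]]
  if (length(m) == 3L) {
    s <- m[2]
    alias_of <- m[3]
  }

  if (!startsWith(s, "c.")) {
    stop("not a cDNA description (expected leading 'c.'): '", raw, "'",
         call. = FALSE)
  }
  body <- substring(s, 3L)

  if (grepl("inv|ext|\\[", body)) {
    stop("unsupported HGVS cDNA construct in '", raw,
         "' (inversions, extensions and repeats are not modeled)",
         call. = FALSE)
  }

  pos_rx <- "([-*]?\\d+)([+-]\\d+)?"
  full_rx <- paste0("^", pos_rx, "(?:_", pos_rx, ")?",
                    "(delins|del|dup|ins|>)([ACGTacgt]*)$")
  mm <- regmatches(body, regexec(full_rx, body))[[1]]

  # substitution has the form <pos><ref>><alt>
  sub_rx <- paste0("^", pos_rx, "([ACGTacgt])>([ACGTacgt])$")
  ms <- regmatches(body, regexec(sub_rx, body))[[1]]

  if (length(ms) == 5L) {
    out <- list(
      raw_text = raw,
      start = as.integer(ms[2]), start_offset = .parse_offset(ms[3]),
      end = NA_integer_, end_offset = NA_integer_,
      edit_kind = "substitution",
      ref_bases = toupper(ms[4]), alt_bases = toupper(ms[5]),
      alias_of = alias_of
    )
  } else if (length(mm) == 7L && nzchar(mm[6]) && mm[6] != ">") {
    kind <- switch(mm[6],
      del = "deletion", dup = "duplication",
      ins = "insertion", delins = "delins"
    )
    bases <- toupper(mm[7])
    if (kind %in% c("insertion", "delins") && !nzchar(bases)) {
      stop("HGVS cDNA '", raw, "': '", mm[6], "' requires inserted bases",
           call. = FALSE)
    }
    out <- list(
      raw_text = raw,
      start = as.integer(mm[2]), start_offset = .parse_offset(mm[3]),
      end = if (nzchar(mm[4])) as.integer(mm[4]) else NA_integer_,
      end_offset = .parse_offset(mm[5]),
      edit_kind = kind,
      ref_bases = if (kind %in% c("deletion", "duplication") && nzchar(bases))
        bases else NA_character_,
      alt_bases = if (kind %in% c("insertion", "delins")) bases
        else NA_character_,
      alias_of = alias_of
    )
  } else {
    bad <- sub("^[-*+0-9_]+", "", body)
    if (!nzchar(bad)) bad <- body
    stop("malformed HGVS cDNA '", raw, "': cannot read token '", bad, "'",
         call. = FALSE)
  }

  if (!is.na(out$end) && out$end < out$start) {
    stop("HGVS cDNA '", raw, "': span end precedes start", call. = FALSE)
  }
  class(out) <- "cdna_change"
  out
}

.parse_offset <- function(x) {
  if (is.na(x) || !nzchar(x)) return(NA_integer_)
  as.integer(x)
}

.fmt_offset <- function(x) {
  if (is.na(x)) return("")
  if (x > 0) paste0("+", x) else as.character(x)
}

#' @export
format.cdna_change <- function(x, ...) {
  pos <- paste0(x$start, .fmt_offset(x$start_offset))
  if (!is.na(x$end)) {
    pos <- paste0(pos, "_", x$end, .fmt_offset(x$end_offset))
  }
  edit <- switch(x$edit_kind,
    substitution = paste0(x$ref_bases, ">", x$alt_bases),
    deletion = "del",
    duplication = "dup",
    insertion = paste0("ins", x$alt_bases),
    delins = paste0("delins", x$alt_bases)
  )
  paste0("c.", pos, edit)
}

#' @export
print.cdna_change <- function(x, ...) {
  cat("<cdna_change> ", format(x), "  [", x$edit_kind, "]\n", sep = "")
  invisible(x)
}

#' Normalize a cDNA description to its canonical string
#'
#' Convenience wrapper: parse then format. Whitespace is removed, trailing
#' explicit bases on del/dup are dropped and the parenthesized alias form
#' resolves to its primary description.
#'
#' @param text HGVS cDNA string.
#' @return normalized HGVS cDNA string.
#' @export
normalize_cdna <- function(text) format(parse_cdna(text))

#' Is a parsed cDNA change a single-nucleotide substitution?
#'
#' Single-base duplications and deletions count as indels, not SNVs.
#'
#' @param x a `cdna_change`.
#' @return logical scalar.
#' @export
is_snv <- function(x) {
  stopifnot(inherits(x, "cdna_change"))
  identical(x$edit_kind, "substitution")
}

#' Parse an HGVS protein description
#'
#' Handles missense, nonsense, frameshift (`fs*N`, tolerating the
#' misplaced-asterisk form `fsN*`), in-frame deletion/duplication/delins
#' and synonymous changes, in the `p.(...)`, `p....` and `(p....)`
#' spellings.
#'
#' @param text a single HGVS protein string, or `NA` for variants with no
#'   protein-level description (splice, structural).
#' @return an object of class `protein_change`: list with `raw_text`,
#'   `start_res`, `end_res`, `ref_aa`, `alt_aa`, `kind` (one of
#'   `"missense"`, `"nonsense"`, `"frameshift"`, `"inframe_del"`,
#'   `"inframe_dup"`, `"inframe_delins"`, `"synonymous"`, `"no_protein"`)
#'   and `fs_stop_offset`; or `NULL` when `text` is `NA`.
#' @examples
#' parse_protein("p.(Gly57Glufs*80)")
#' parse_protein("p.(Arg898Trp)")$kind
#' @export
parse_protein <- function(text) {
  if (length(text) != 1L) stop("parse_protein() expects a single string")
  if (is.na(text) || !nzchar(trimws(text))) {
    out <- list(raw_text = NA_character_, start_res = NA_integer_,
                end_res = NA_integer_, ref_aa = NA_character_,
                alt_aa = NA_character_, kind = "no_protein",
                fs_stop_offset = NA_integer_)
    class(out) <- "protein_change"
    return(out)
  }
  raw <- text
  s <- gsub("[[:space:]]+", "", text)
  # tolerate "(p.Xxx)" with the parenthesis around the whole description
  s <- sub("^\\((p\\..*)\\)$", "\\1", s)
  if (!startsWith(s, "p.")) {
    stop("not a protein description (expected leading 'p.'): '", raw, "'",
         call. = FALSE)
  }
  inner <- substring(s, 3L)
  inner <- sub("^\\((.*)\\)$", "\\1", inner)
  if (identical(inner, "?")) {
    out <- list(raw_text = raw, start_res = NA_integer_,
                end_res = NA_integer_, ref_aa = NA_character_,
                alt_aa = NA_character_, kind = "no_protein",
                fs_stop_offset = NA_integer_)
    class(out) <- "protein_change"
    return(out)
  }

  head_rx <- paste0("^(", .aa_rx, ")(\\d+)(?:_(", .aa_rx, ")(\\d+))?(.*)$")
  m <- regmatches(inner, regexec(head_rx, inner, perl = TRUE))[[1]]
  if (length(m) != 6L) {
    stop("malformed HGVS protein '", raw, "'", call. = FALSE)
  }
  ref_aa <- m[2]
  start_res <- as.integer(m[3])
  end_ref <- if (nzchar(m[4])) m[4] else NA_character_
  end_res <- if (nzchar(m[5])) as.integer(m[5]) else NA_integer_
  rest <- m[6]
  if (!is.na(end_res)) ref_aa <- paste0(ref_aa, "_", end_ref)

  out <- list(raw_text = raw, start_res = start_res, end_res = end_res,
              ref_aa = ref_aa, alt_aa = NA_character_, kind = NA_character_,
              fs_stop_offset = NA_integer_)

  fs_rx <- paste0("^(", .aa_rx, ")?fs(?:\\*(\\d+)|(\\d+)\\*)?$")
  fm <- regmatches(rest, regexec(fs_rx, rest, perl = TRUE))[[1]]

  if (identical(rest, "del")) {
    out$kind <- "inframe_del"
  } else if (identical(rest, "dup")) {
    out$kind <- "inframe_dup"
  } else if (grepl("^delins", rest)) {
    alt <- substring(rest, 7L)
    if (!grepl(paste0("^(?:", .aa_rx, ")+$"), alt, perl = TRUE)) {
      stop("malformed delins amino acids in '", raw, "'", call. = FALSE)
    }
    out$kind <- "inframe_delins"
    out$alt_aa <- alt
  } else if (length(fm) == 4L) {
    out$kind <- "frameshift"
    out$alt_aa <- if (nzchar(fm[2])) fm[2] else NA_character_
    off <- c(fm[3], fm[4])
    off <- off[nzchar(off)]
    out$fs_stop_offset <- if (length(off)) as.integer(off[1]) else NA_integer_
  } else if (identical(rest, "*") || identical(rest, "Ter")) {
    out$kind <- "nonsense"
    out$alt_aa <- "*"
  } else if (grepl(paste0("^", .aa_rx, "$"), rest, perl = TRUE)) {
    out$alt_aa <- rest
    out$kind <- if (identical(rest, m[2])) "synonymous" else "missense"
  } else {
    stop("malformed HGVS protein '", raw, "': cannot read token '", rest,
         "'", call. = FALSE)
  }

  if (identical(out$kind, "frameshift") && !grepl("fs", raw, fixed = TRUE)) {
    stop("internal: frameshift without 'fs' token")  # nocov
  }
  class(out) <- "protein_change"
  out
}

#' @export
format.protein_change <- function(x, ...) {
  if (identical(x$kind, "no_protein")) return(NA_character_)
  paste0("p.(", protein_key(x), ")")
}

#' @export
print.protein_change <- function(x, ...) {
  cat("<protein_change> ", format(x), "  [", x$kind, "]\n", sep = "")
  invisible(x)
}

#' Normalized protein-change key
#'
#' Canonical grouping key for a protein change: three-letter codes, no
#' `p.`/parentheses, frameshift offset written `fs*N`. Germline
#' `"p.(Arg619*)"` and somatic `"p.(Arg619*)"` share a key; the misprinted
#' `"p.(Glu59Argfs44*)"` keys as `"Glu59Argfs*44"`.
#'
#' @param x a `protein_change` or a character HGVS protein string.
#' @return character key, or `NA` for records without protein description.
#' @export
protein_key <- function(x) {
  if (is.character(x)) x <- parse_protein(x)
  stopifnot(inherits(x, "protein_change"))
  if (identical(x$kind, "no_protein")) return(NA_character_)
  refs <- strsplit(x$ref_aa, "_", fixed = TRUE)[[1]]
  pos <- paste0(refs[1], x$start_res)
  if (!is.na(x$end_res)) pos <- paste0(pos, "_", refs[2], x$end_res)
  tail <- switch(x$kind,
    missense = x$alt_aa,
    synonymous = x$alt_aa,
    nonsense = "*",
    frameshift = paste0(
      if (!is.na(x$alt_aa)) x$alt_aa else "",
      "fs",
      if (!is.na(x$fs_stop_offset)) paste0("*", x$fs_stop_offset) else ""
    ),
    inframe_del = "del",
    inframe_dup = "dup",
    inframe_delins = paste0("delins", x$alt_aa)
  )
  paste0(pos, tail)
}

#' Consequence categories
#'
#' @return character vector of the recognized consequence categories.
#' @export
consequence_levels <- function() {
  c("missense", "nonsense", "frameshift", "splice", "inframe_indel",
    "synonymous", "large_deletion")
}

.impact_to_consequence <- function(impact) {
  key <- tolower(trimws(impact))
  switch(key,
    "missense" = "missense",
    "nonsense" = "nonsense",
    "frameshift" = "frameshift",
    "splice" = "splice",
    "in frame deletion" = "inframe_indel",
    "in frame insertion" = "inframe_indel",
    "in frame indel" = "inframe_indel",
    "in frame" = "inframe_indel",
    "synonymous" = "synonymous",
    "large deletion" = "large_deletion",
    "deletion" = "large_deletion",
    stop("unknown printed impact: '", impact, "'", call. = FALSE)
  )
}

#' Infer the consequence category of a variant
#'
#' A cDNA position with a canonical intron offset (magnitude 1 or 2) makes
#' the variant a splice variant regardless of protein annotation;
#' structural events map to `large_deletion`; otherwise the protein-level
#' kind decides, with the in-frame kinds collapsed to `inframe_indel`.
#' When a printed impact is supplied and contradicts the inference, the
#' printed impact is retained (curated tables are ground truth) and the
#' disagreement is recorded in the `"conflict"` attribute of the result.
#'
#' @param cdna a `cdna_change`, or `NULL`.
#' @param protein a `protein_change`, or `NULL`.
#' @param printed optional printed impact string (e.g. `"Splice"`).
#' @param structural logical; `TRUE` for large deletions/structural events.
#' @return consequence category (character scalar); attribute `"conflict"`
#'   is `TRUE` when a printed impact overrode the inference.
#' @export
infer_consequence <- function(cdna = NULL, protein = NULL, printed = NULL,
                              structural = FALSE) {
  if (is.null(cdna) && is.null(protein) && !structural && is.null(printed)) {
    stop("infer_consequence() needs at least one of cdna, protein, printed")
  }
  inferred <- NA_character_
  if (structural) {
    inferred <- "large_deletion"
  } else if (!is.null(cdna) && .canonical_splice(cdna)) {
    inferred <- "splice"
  } else if (!is.null(protein) && !identical(protein$kind, "no_protein")) {
    inferred <- switch(protein$kind,
      missense = "missense", nonsense = "nonsense",
      frameshift = "frameshift", synonymous = "synonymous",
      inframe_del = , inframe_dup = , inframe_delins = "inframe_indel"
    )
  }
  if (is.null(printed)) {
    if (is.na(inferred)) {
      stop("cannot infer consequence (no protein annotation, ",
           "non-canonical or absent intron offset, no printed impact)")
    }
    return(inferred)
  }
  printed_cons <- .impact_to_consequence(printed)
  # a contradiction, or an impact the inference alone could not reach
  # (e.g. a printed splice at a non-canonical offset), is flagged; the
  # printed impact is retained because curated tables are ground truth
  conflict <- if (is.na(inferred)) TRUE else !identical(inferred,
                                                        printed_cons)
  structure(printed_cons, conflict = conflict)
}

.canonical_splice <- function(cdna) {
  offs <- c(cdna$start_offset, cdna$end_offset)
  offs <- offs[!is.na(offs)]
  length(offs) > 0 && any(abs(offs) <= 2)
}

#' Premature-termination codon of a truncating protein change
#'
#' For a nonsense change the termination codon is the affected residue;
#' for a frameshift it is `start_res + fs_stop_offset - 1` (the new reading
#' frame runs from the first changed residue to the novel stop).
#'
#' @param p a `protein_change`.
#' @return integer residue position, or `NA` for non-truncating kinds.
#' @export
termination_codon <- function(p) {
  stopifnot(inherits(p, "protein_change"))
  if (identical(p$kind, "nonsense")) return(p$start_res)
  if (identical(p$kind, "frameshift")) {
    if (is.na(p$fs_stop_offset)) return(NA_integer_)
    return(p$start_res + p$fs_stop_offset - 1L)
  }
  NA_integer_
}
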