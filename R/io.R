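#' @title Curated-table I/O
#' @description
#' Readers for the germline and somatic curated variant tables (TSV,
#' UTF-8, `NA` for absent), schema validation with row/column-addressed
#' errors, JSON report writing, and access to the fixture tables packaged
#' with armc5curator (transcribed from the published ARMC5 germline and
#' somatic variant tables).
#' @name io_tables
NULL

GERMLINE_COLUMNS <- c("cdna", "protein", "impact", "class", "criteria",
                      "second_hit", "functional", "context", "novel",
                      "n_index_cases", "polymorphism", "note", "refs")

SOMATIC_COLUMNS <- c("cdna", "protein", "impact", "associated_germline",
                     "context", "note", "refs")

# md5 checksums of the packaged fixture tables, recorded at packaging time
FIXTURE_CHECKSUMS <- c(
  armc5_germline_table1.tsv = "f05b5567576f85a658328d119fe68e14",
  armc5_somatic_table2.tsv = "681540fec41383c84b55e84e92e1676b"
)

.read_tsv <- function(path, required) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          colClasses = "character", na.strings = "NA",
                          check.names = FALSE, quote = "",
                          fileEncoding = "UTF-8")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("table ", basename(path), " is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  df
}

.row_errors <- function(rows, what, details) {
  stop(what, " in row(s) ", paste(rows, collapse = ", "), ":\n  ",
       paste(details, collapse = "\n  "), call. = FALSE)
}

.is_structural_cdna <- function(x) {
  !grepl("^c\\.", gsub("^[[:space:]]+", "", x))
}

.parse_tristate <- function(x) {
  out <- rep("unknown", length(x))
  out[!is.na(x) & tolower(x) == "yes"] <- "yes"
  out[!is.na(x) & tolower(x) == "no"] <- "no"
  out
}

#' Load a curated germline variant table
#'
#' Reads a TSV with the germline schema, parses every HGVS string and
#' criteria string, maps printed classes to the five-class scale and
#' infers consequences. Rows whose cDNA column does not start with `"c."`
#' are treated as structural events (large deletions). Any row that fails
#' parsing is reported with its exact printed text; nothing is silently
#' dropped. Printed-vs-inferred impact contradictions are collected in the
#' `"conflicts"` attribute of the result.
#'
#' @param path TSV file path.
#' @param verify_checksum verify the recorded checksum when loading a
#'   packaged fixture (message on mismatch).
#' @return data frame with one row per record: original columns plus
#'   `structural`, `cdna_norm`, `edit_kind`, `snv`, `protein_key`,
#'   `protein_kind`, `start_res`, `fs_stop_offset`, `term_codon`,
#'   `consequence`, `class_printed`, `criteria_norm`, `second_hit`,
#'   `functional` (tri-states) and typed `novel`/`n_index_cases`/
#'   `polymorphism`.
#' @export
load_germline_table <- function(path, verify_checksum = TRUE) {
  df <- .read_tsv(path, GERMLINE_COLUMNS)
  .verify_fixture(path, verify_checksum)
  n <- nrow(df)
  if (n == 0L) return(.empty_germline(df))

  errs <- character(); err_rows <- integer()
  conflicts <- character()

  structural <- .is_structural_cdna(df$cdna)
  cdna_norm <- rep(NA_character_, n)
  edit_kind <- rep(NA_character_, n)
  snv <- rep(NA, n)
  alias_of <- rep(NA_character_, n)
  protein_key <- rep(NA_character_, n)
  protein_kind <- rep(NA_character_, n)
  start_res <- rep(NA_integer_, n)
  fs_off <- rep(NA_integer_, n)
  term <- rep(NA_integer_, n)
  consequence <- rep(NA_character_, n)
  class_printed <- rep(NA_character_, n)
  criteria_norm <- rep(NA_character_, n)

  for (i in seq_len(n)) {
    res <- tryCatch({
      cd <- NULL
      if (!structural[i]) {
        cd <- parse_cdna(df$cdna[i])
        cdna_norm[i] <- format(cd)
        edit_kind[i] <- cd$edit_kind
        snv[i] <- is_snv(cd)
        alias_of[i] <- cd$alias_of
      } else {
        cdna_norm[i] <- trimws(df$cdna[i])
      }
      pr <- parse_protein(df$protein[i])
      protein_key[i] <- protein_key(pr)
      protein_kind[i] <- pr$kind
      start_res[i] <- pr$start_res
      fs_off[i] <- pr$fs_stop_offset
      term[i] <- termination_codon(pr)
      cons <- infer_consequence(cdna = cd, protein = pr,
                                printed = df$impact[i],
                                structural = structural[i])
      if (isTRUE(attr(cons, "conflict"))) {
        conflicts <- c(conflicts, sprintf(
          "row %d (%s): printed impact '%s' retained over inference",
          i, df$cdna[i], df$impact[i]))
      }
      consequence[i] <- as.character(cons)
      criteria_norm[i] <- format(parse_criteria_string(df$criteria[i]))
      class_printed[i] <- as.character(parse_classification(df$class[i]))
      NULL
    }, error = function(e) conditionMessage(e))
    if (!is.null(res)) {
      errs <- c(errs, sprintf("row %d (%s): %s", i, df$cdna[i], res))
      err_rows <- c(err_rows, i)
    }
  }
  if (length(errs)) .row_errors(err_rows, "germline table parse failure", errs)

  out <- data.frame(
    cdna = df$cdna, cdna_norm = cdna_norm, alias_of = alias_of,
    structural = structural, edit_kind = edit_kind, snv = snv,
    protein = df$protein, protein_key = protein_key,
    protein_kind = protein_kind, start_res = start_res,
    fs_stop_offset = fs_off, term_codon = term,
    impact = df$impact, consequence = consequence,
    class_printed = class_printed, criteria = criteria_norm,
    second_hit = .parse_tristate(df$second_hit),
    functional = .parse_tristate(df$functional),
    context = df$context,
    novel = toupper(trimws(df$novel)) == "TRUE",
    n_index_cases = as.integer(df$n_index_cases),
    polymorphism = toupper(trimws(df$polymorphism)) == "TRUE",
    note = df$note, refs = df$refs,
    stringsAsFactors = FALSE
  )
  if (any(out$n_index_cases < 1L, na.rm = TRUE) ||
      anyNA(out$n_index_cases)) {
    bad <- which(is.na(out$n_index_cases) | out$n_index_cases < 1L)
    .row_errors(bad, "invalid n_index_cases",
                df$n_index_cases[bad])
  }
  attr(out, "conflicts") <- conflicts
  out
}

.empty_germline <- function(df) {
  out <- data.frame(
    cdna = character(), cdna_norm = character(), alias_of = character(),
    structural = logical(), edit_kind = character(), snv = logical(),
    protein = character(), protein_key = character(),
    protein_kind = character(), start_res = integer(),
    fs_stop_offset = integer(), term_codon = integer(),
    impact = character(), consequence = character(),
    class_printed = character(), criteria = character(),
    second_hit = character(), functional = character(),
    context = character(), novel = logical(), n_index_cases = integer(),
    polymorphism = logical(), note = character(), refs = character(),
    stringsAsFactors = FALSE
  )
  attr(out, "conflicts") <- character()
  out
}

#' Load a curated somatic event table
#'
#' Reads a TSV with the somatic schema. `cnLOH` rows and rows whose cDNA
#' column is a textual description are structural events; point events
#' have their HGVS strings parsed and normalized. The
#' `associated_germline` column holds semicolon-separated germline keys
#' (protein descriptions, cDNA descriptions for splice variants, `"large
#' deletion"`, or `"none"`).
#'
#' @param path TSV file path.
#' @param verify_checksum see [load_germline_table()].
#' @return data frame with `event_type` (`"cnLOH"`, `"structural"`,
#'   `"point"`), normalized keys and the association list-column
#'   `associated_keys`.
#' @export
load_somatic_table <- function(path, verify_checksum = TRUE) {
  df <- .read_tsv(path, SOMATIC_COLUMNS)
  .verify_fixture(path, verify_checksum)
  n <- nrow(df)

  event_type <- ifelse(trimws(df$cdna) == "cnLOH", "cnLOH",
                       ifelse(.is_structural_cdna(df$cdna), "structural",
                              "point"))
  cdna_norm <- rep(NA_character_, n)
  protein_key <- rep(NA_character_, n)
  protein_kind <- rep(NA_character_, n)
  start_res <- rep(NA_integer_, n)
  consequence <- rep(NA_character_, n)
  errs <- character(); err_rows <- integer()

  for (i in seq_len(n)) {
    res <- tryCatch({
      if (event_type[i] == "point") {
        cd <- parse_cdna(df$cdna[i])
        cdna_norm[i] <- format(cd)
        pr <- parse_protein(df$protein[i])
        protein_key[i] <- protein_key(pr)
        protein_kind[i] <- pr$kind
        start_res[i] <- pr$start_res
        cons <- infer_consequence(cdna = cd, protein = pr,
                                  printed = df$impact[i])
        consequence[i] <- as.character(cons)
      } else {
        cdna_norm[i] <- trimws(df$cdna[i])
        consequence[i] <- "large_deletion"
      }
      NULL
    }, error = function(e) conditionMessage(e))
    if (!is.null(res)) {
      errs <- c(errs, sprintf("row %d (%s): %s", i, df$cdna[i], res))
      err_rows <- c(err_rows, i)
    }
  }
  if (length(errs)) .row_errors(err_rows, "somatic table parse failure", errs)

  associated_keys <- lapply(df$associated_germline, .normalize_assoc)

  out <- data.frame(
    cdna = df$cdna, cdna_norm = cdna_norm, event_type = event_type,
    protein = df$protein, protein_key = protein_key,
    protein_kind = protein_kind, start_res = start_res,
    impact = df$impact, consequence = consequence,
    context = df$context, note = df$note, refs = df$refs,
    stringsAsFactors = FALSE
  )
  out$associated_keys <- associated_keys
  out
}

.normalize_assoc <- function(x) {
  if (is.na(x) || !nzchar(trimws(x))) return(character())
  parts <- trimws(strsplit(x, ";", fixed = TRUE)[[1]])
  vapply(parts, function(p) {
    if (grepl("^p\\.|^\\(p\\.", p)) protein_key(p)
    else if (grepl("^c\\.", p)) normalize_cdna(p)
    else p  # "none", "large deletion", ...
  }, character(1), USE.NAMES = FALSE)
}

.verify_fixture <- function(path, verify) {
  if (!verify) return(invisible(FALSE))
  base <- basename(path)
  if (!base %in% names(FIXTURE_CHECKSUMS)) return(invisible(FALSE))
  sum <- unname(tools::md5sum(path))
  if (!identical(sum, unname(FIXTURE_CHECKSUMS[base]))) {
    message("checksum of ", base, " differs from the packaged fixture ",
            "(transcribed from published Tables 1-2); treating as ",
            "user-supplied data")
  }
  invisible(TRUE)
}

#' Path to a packaged fixture table
#'
#' @param which `"germline"` or `"somatic"`.
#' @return file path inside the installed package.
#' @export
fixture_path <- function(which = c("germline", "somatic")) {
  which <- match.arg(which)
  fn <- switch(which, germline = "armc5_germline_table1.tsv",
               somatic = "armc5_somatic_table2.tsv")
  system.file("extdata", fn, package = "armc5curator", mustWork = TRUE)
}

#' Load the packaged germline table
#' @return see [load_germline_table()].
#' @export
armc5_germline <- function() load_germline_table(fixture_path("germline"))

#' Load the packaged somatic table
#' @return see [load_somatic_table()].
#' @export
armc5_somatic <- function() load_somatic_table(fixture_path("somatic"))

#' Write a JSON analysis report
#'
#' Serializes a landscape summary together with optional concordance and
#' consistency results, a configuration echo and fixture checksums, with
#' deterministic key order.
#'
#' @param summary a `landscape_summary` (see [summarize_germline()]), or
#'   any serializable list.
#' @param path destination JSON path.
#' @param concordance optional result of [concordance()].
#' @param anomalies optional result of [consistency_report()].
#' @param config optional [engine_config()] echoed into the report.
#' @param checksums optional named character vector of input checksums.
#' @return `path`, invisibly.
#' @export
write_report <- function(summary, path, concordance = NULL,
                         anomalies = NULL, config = NULL,
                         checksums = NULL) {
  payload <- list(summary = unclass(summary))
  if (!is.null(concordance)) payload$concordance <- concordance
  if (!is.null(anomalies)) payload$anomalies <- anomalies
  if (!is.null(config)) payload$config <- unclass(config)
  if (!is.null(checksums)) payload$checksums <- as.list(checksums)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null", pretty = TRUE)
  invisible(path)
}

#' Read back a JSON analysis report
#'
#' @param path JSON path written by [write_report()].
#' @return named list.
#' @export
read_report <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
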