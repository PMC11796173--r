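#' @title ACMG-AMP evidence codes and five-class combination
#' @description
#' Representation of ACMG-AMP evidence criteria (PVS1, PS1-4, PM1-6,
#' PP1-5, BA1, BS1-4, BP1-7) with strength levels, a tokenizer for the
#' run-together criteria strings printed in curated tables ("PVS1PM2PP4"),
#' and the combining rules that map a criteria set onto the five
#' pathogenicity classes. Two combination policies are provided: `strict`
#' follows the published guideline (conflicting or insufficient evidence
#' gives VUS), while `as_curated` reproduces the precedence conventions of
#' expert-curated ARMC5 tables (population-polymorphism override, benign
#' evidence evaluated first, a single strong-benign code sufficing for
#' likely benign).
#' @name acmg
NULL

ACMG_CODES <- c("PVS1",
                paste0("PS", 1:4), paste0("PM", 1:6), paste0("PP", 1:5),
                "BA1", paste0("BS", 1:4), paste0("BP", 1:7))

STRENGTHS <- c("stand_alone", "very_strong", "strong", "moderate",
               "supporting")

.strength_suffix <- c(stand_alone = "SA", very_strong = "VS", strong = "S",
                      moderate = "M", supporting = "P")

#' Default strength of an ACMG evidence code
#'
#' @param code one or more ACMG code strings.
#' @return character vector of default strengths.
#' @export
default_strength <- function(code) {
  vapply(code, function(cc) {
    if (!cc %in% ACMG_CODES) stop("unknown ACMG code: '", cc, "'")
    if (cc == "PVS1") return("very_strong")
    if (cc == "BA1") return("stand_alone")
    switch(substr(cc, 1, 2),
           PS = "strong", PM = "moderate", PP = "supporting",
           BS = "strong", BP = "supporting")
  }, character(1), USE.NAMES = FALSE)
}

#' Construct a single ACMG criterion
#'
#' @param code ACMG code string.
#' @param strength evidence strength; defaults to the code's canonical
#'   strength. A non-default strength marks the criterion as modified
#'   (e.g. PVS1 applied at strong serializes as `"PVS1_S"`).
#' @return object of class `acmg_criterion`.
#' @export
acmg_criterion <- function(code, strength = default_strength(code)) {
  stopifnot(code %in% ACMG_CODES, strength %in% STRENGTHS)
  out <- list(code = code, strength = strength,
              modified = !identical(strength, default_strength(code)))
  class(out) <- "acmg_criterion"
  out
}

#' @export
format.acmg_criterion <- function(x, ...) {
  if (!x$modified) return(x$code)
  paste0(x$code, "_", .strength_suffix[[x$strength]])
}

#' @export
print.acmg_criterion <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' Construct a criteria set
#'
#' @param criteria list of `acmg_criterion` objects; duplicate codes are an
#'   error.
#' @return object of class `criteria_set` (list keyed by code).
#' @export
criteria_set <- function(criteria = list()) {
  codes <- vapply(criteria, `[[`, character(1), "code")
  if (anyDuplicated(codes)) {
    stop("duplicate ACMG code in criteria set: ",
         paste(codes[duplicated(codes)], collapse = ", "))
  }
  names(criteria) <- codes
  class(criteria) <- "criteria_set"
  criteria
}

#' @export
format.criteria_set <- function(x, ...) {
  paste(vapply(unclass(x), format, character(1)), collapse = ";")
}

#' @export
print.criteria_set <- function(x, ...) {
  cat("<criteria_set> {", format(x), "}\n", sep = "")
  invisible(x)
}

#' @export
length.criteria_set <- function(x) length(unclass(x))

#' Tokenize a printed ACMG criteria string
#'
#' Published tables run codes together without separators
#' (`"PVS1PM2PP4"`); semicolon-, comma- or space-delimited lists are also
#' accepted. Tokenization is greedy longest-match, so `"PVS1_S"` is read
#' as a single modified-strength PVS1 token, never as `PVS1` plus residue.
#'
#' @param text criteria string; empty or `NA` gives an empty set.
#' @return a `criteria_set`.
#' @examples
#' format(parse_criteria_string("PVS1_SPM2PS3PP4"))
#' @export
parse_criteria_string <- function(text) {
  if (length(text) != 1L) stop("parse_criteria_string() expects one string")
  if (is.na(text)) return(criteria_set())
  s <- gsub("[;, ]+", "", text)
  if (!nzchar(s)) return(criteria_set())
  token_rx <- paste0(
    "^(", paste(sort(ACMG_CODES, decreasing = TRUE), collapse = "|"), ")",
    "(?:_(SA|VS|S|M|P))?"
  )
  out <- list()
  while (nzchar(s)) {
    m <- regmatches(s, regexec(token_rx, s, perl = TRUE))[[1]]
    if (length(m) == 0L) {
      stop("cannot tokenize ACMG criteria string at '", s, "'",
           call. = FALSE)
    }
    code <- m[2]
    strength <- if (nzchar(m[3])) {
      names(.strength_suffix)[match(m[3], .strength_suffix)]
    } else {
      default_strength(code)
    }
    out[[length(out) + 1L]] <- acmg_criterion(code, strength)
    s <- substring(s, nchar(m[1]) + 1L)
  }
  criteria_set(out)
}

#' Five-class pathogenicity scale
#'
#' @return ordered factor levels from benign (class 1) to pathogenic
#'   (class 5).
#' @export
classification_levels <- function() {
  c("benign", "likely_benign", "vus", "likely_pathogenic", "pathogenic")
}

.as_classification <- function(x) {
  factor(x, levels = classification_levels(), ordered = TRUE)
}

#' Parse a printed classification label
#'
#' @param text printed class ("Pathogenic", "likely benign", "VUS", ...).
#' @return ordered factor on the five-class scale.
#' @export
parse_classification <- function(text) {
  key <- tolower(trimws(text))
  key <- gsub("[[:space:]_]+", " ", key)
  value <- switch(key,
    "benign" = "benign", "class 1" = "benign",
    "likely benign" = "likely_benign", "class 2" = "likely_benign",
    "vus" = "vus", "uncertain significance" = "vus", "class 3" = "vus",
    "likely pathogenic" = "likely_pathogenic", "class 4" = "likely_pathogenic",
    "pathogenic" = "pathogenic", "class 5" = "pathogenic",
    stop("unknown classification label: '", text, "'", call. = FALSE)
  )
  .as_classification(value)
}

# effective-strength tally; a modified PVS1 counts in the strong bin and
# does not satisfy the PVS1-specific combining rules
.tally <- function(cs) {
  crits <- unclass(cs)
  codes <- names(crits)
  strengths <- vapply(crits, `[[`, character(1), "strength")
  pathogenic <- grepl("^P", codes)
  benign <- !pathogenic
  list(
    pvs1 = any(codes == "PVS1" & strengths == "very_strong"),
    n_strong = sum(pathogenic & strengths == "strong"),
    n_moderate = sum(pathogenic & strengths == "moderate"),
    n_supporting = sum(pathogenic & strengths == "supporting"),
    ba1 = any(codes == "BA1"),
    n_bs = sum(benign & strengths == "strong" & codes != "BA1"),
    n_bp = sum(benign & strengths == "supporting")
  )
}

.pathogenic_fires <- function(t) {
  (t$pvs1 && (t$n_strong >= 1 || t$n_moderate >= 2 ||
              (t$n_moderate >= 1 && t$n_supporting >= 1) ||
              t$n_supporting >= 2)) ||
    t$n_strong >= 2 ||
    (t$n_strong == 1 && (t$n_moderate >= 3 ||
                         (t$n_moderate == 2 && t$n_supporting >= 2) ||
                         (t$n_moderate == 1 && t$n_supporting >= 4)))
}

.likely_pathogenic_fires <- function(t) {
  (t$pvs1 && t$n_moderate == 1) ||
    (t$n_strong == 1 && t$n_moderate >= 1 && t$n_moderate <= 2) ||
    (t$n_strong == 1 && t$n_supporting >= 2) ||
    t$n_moderate >= 3 ||
    (t$n_moderate == 2 && t$n_supporting >= 2) ||
    (t$n_moderate == 1 && t$n_supporting >= 4)
}

.benign_fires <- function(t) t$ba1 || t$n_bs >= 2

.likely_benign_fires <- function(t) {
  (t$n_bs == 1 && t$n_bp >= 1) || t$n_bp >= 2
}

#' Combine ACMG criteria into a five-class classification
#'
#' Implements the published combining rules over effective strengths (a
#' modified PVS1 counts as one strong criterion). Under `strict` policy a
#' conflict between fired benign-side and pathogenic-side rules, or no
#' fired rule at all, yields VUS. Under `as_curated` policy the precedence
#' order reverse-engineered from expert-curated ARMC5 tables applies:
#' a population-polymorphism flag forces benign; benign-side rules are
#' evaluated first and win over pathogenic evidence; a single strong
#' benign criterion with no supporting-benign code suffices for likely
#' benign; remaining cases fall through to the pathogenic rules, else VUS.
#'
#' @param cs a `criteria_set` (or criteria string, tokenized on the fly).
#' @param cfg an [engine_config()]; `cfg$conflict_policy` selects the
#'   policy.
#' @param polymorphism logical; `TRUE` when the variant's population
#'   frequency exceeds the polymorphism threshold (`as_curated` only).
#' @return ordered factor on the five-class scale.
#' @examples
#' combine_criteria(parse_criteria_string("PVS1PM2PP4"))
#' combine_criteria(parse_criteria_string("BS3"),
#'                  engine_config(conflict_policy = "as_curated"))
#' @export
combine_criteria <- function(cs, cfg = engine_config(),
                             polymorphism = FALSE) {
  if (is.character(cs)) cs <- parse_criteria_string(cs)
  stopifnot(inherits(cs, "criteria_set"))
  t <- .tally(cs)

  if (identical(cfg$conflict_policy, "as_curated")) {
    if (isTRUE(polymorphism)) return(.as_classification("benign"))
    if (.benign_fires(t)) return(.as_classification("benign"))
    if (.likely_benign_fires(t)) return(.as_classification("likely_benign"))
    if (t$n_bs >= 1) return(.as_classification("likely_benign"))
    if (.pathogenic_fires(t)) return(.as_classification("pathogenic"))
    if (.likely_pathogenic_fires(t)) {
      return(.as_classification("likely_pathogenic"))
    }
    return(.as_classification("vus"))
  }

  path_class <- if (.pathogenic_fires(t)) "pathogenic"
    else if (.likely_pathogenic_fires(t)) "likely_pathogenic"
    else NA_character_
  benign_class <- if (.benign_fires(t)) "benign"
    else if (.likely_benign_fires(t)) "likely_benign"
    else NA_character_

  if (!is.na(path_class) && !is.na(benign_class)) {
    return(.as_classification("vus"))
  }
  if (!is.na(path_class)) return(.as_classification(path_class))
  if (!is.na(benign_class)) return(.as_classification(benign_class))
  .as_classification("vus")
}

#' Compare computed classes against printed classes
#'
#' Runs [combine_criteria()] on each record's printed criteria set and
#' compares the result with the printed class.
#'
#' @param records data frame of curated variant records as returned by
#'   [load_germline_table()] (columns `criteria`, `class_printed`,
#'   `polymorphism`, and an identifier column `cdna_norm` or `cdna`).
#' @param cfg an [engine_config()].
#' @return list with `n_match`, `n_total` and a `mismatches` data frame
#'   (variant, printed class, computed class).
#' @export
concordance <- function(records, cfg = engine_config()) {
  if (nrow(records) == 0L) {
    return(list(n_match = 0L, n_total = 0L,
                mismatches = data.frame(variant = character(),
                                        printed = character(),
                                        computed = character())))
  }
  id_col <- if ("cdna_norm" %in% names(records)) "cdna_norm" else "cdna"
  poly <- if ("polymorphism" %in% names(records)) records$polymorphism
    else rep(FALSE, nrow(records))
  computed <- vapply(seq_len(nrow(records)), function(i) {
    as.character(combine_criteria(parse_criteria_string(records$criteria[i]),
                                  cfg, polymorphism = isTRUE(poly[i])))
  }, character(1))
  printed <- vapply(records$class_printed, function(x) {
    as.character(parse_classification(x))
  }, character(1), USE.NAMES = FALSE)
  ok <- computed == printed
  list(
    n_match = sum(ok),
    n_total = length(ok),
    mismatches = data.frame(
      variant = records[[id_col]][!ok],
      printed = printed[!ok],
      computed = computed[!ok],
      stringsAsFactors = FALSE
    )
  )
}
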