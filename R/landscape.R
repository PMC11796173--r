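#' @title Mutational-landscape summaries
#' @description
#' Aggregation of curated germline and somatic ARMC5 variants into the
#' landscape statistics of interest: consequence spectra with rounded
#' percentages, SNV/indel split, protein-level recurrence, residues hit by
#' several distinct changes, germline/somatic overlap, distinct-event
#' counting for the somatic spectrum, domain annotation and a serializable
#' lollipop-plot model.
#' @name landscape
NULL

# rounding convention for printed percentages: half away from zero
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  trunc(abs(x) * p + 0.5) * sign(x) / p
}

#' Grouping key of one record (protein level, structural fallback)
#'
#' Point variants group by normalized protein key; variants without a
#' protein description (splice) by normalized cDNA; structural events by
#' their description.
#' @param records germline or somatic record data frame.
#' @return character vector of keys.
#' @export
record_key <- function(records) {
  key <- records$protein_key
  ifelse(is.na(key), records$cdna_norm, key)
}

#' Summarize a germline variant table
#'
#' @param records data frame from [load_germline_table()].
#' @param include_polymorphisms count the frequent-polymorphism rows
#'   (default `FALSE`, matching published totals).
#' @return object of class `landscape_summary`: counts by consequence,
#'   integer-rounded percentages (with `truncating` = nonsense +
#'   frameshift), SNV/indel/structural split, novel count and recurrence
#'   fields.
#' @export
summarize_germline <- function(records, include_polymorphisms = FALSE) {
  if (!include_polymorphisms && nrow(records) > 0L) {
    records <- records[!records$polymorphism, , drop = FALSE]
  }
  n <- nrow(records)
  counts <- stats::setNames(integer(length(consequence_levels())),
                            consequence_levels())
  if (n > 0L) {
    tab <- table(factor(records$consequence,
                        levels = consequence_levels()))
    counts[names(tab)] <- as.integer(tab)
  }
  pct <- if (n > 0L) {
    vapply(counts, function(k) round_half_up(100 * k / n), numeric(1))
  } else {
    stats::setNames(numeric(length(counts)), names(counts))
  }
  pct_truncating <- if (n > 0L) {
    round_half_up(100 * (counts[["nonsense"]] + counts[["frameshift"]]) / n)
  } else 0
  n_structural <- sum(records$structural)
  n_snv <- sum(records$snv, na.rm = TRUE)
  n_indel <- n - n_structural - n_snv

  rec <- recurrence_table(records)
  out <- list(
    n_variants = n,
    counts_by_consequence = as.list(counts),
    pct_by_consequence = as.list(pct),
    pct_truncating = pct_truncating,
    n_snv = n_snv,
    n_indel = n_indel,
    n_structural = n_structural,
    n_novel = sum(records$novel),
    n_recurrent_protein_variants = sum(rec$total_index_cases >= 2L),
    recurrent_protein_variants =
      rec[rec$total_index_cases >= 2L, , drop = FALSE],
    multi_hit_residues = multi_hit_residues(records)$residue,
    dual_encoded = rec$key[rec$n_distinct_cdna >= 2L]
  )
  class(out) <- "landscape_summary"
  out
}

#' @export
print.landscape_summary <- function(x, ...) {
  cat("Germline landscape:", x$n_variants, "distinct variants\n")
  cc <- x$counts_by_consequence
  for (k in names(cc)) {
    if (cc[[k]] > 0) {
      cat(sprintf("  %-15s %3d  (%d%%)\n", k, cc[[k]],
                  as.integer(x$pct_by_consequence[[k]])))
    }
  }
  cat(sprintf("  truncating share %d%%; SNV %d / indel %d / structural %d\n",
              as.integer(x$pct_truncating), x$n_snv, x$n_indel,
              x$n_structural))
  cat(sprintf("  novel %d; recurrent protein variants %d; dual-encoded %s\n",
              x$n_novel, x$n_recurrent_protein_variants,
              paste(x$dual_encoded, collapse = ", ")))
  invisible(x)
}

#' Protein-level recurrence table
#'
#' Groups records by protein-level key (structural events by description)
#' and totals index cases; a protein change encoded by several distinct
#' cDNA changes contributes one row with `n_distinct_cdna > 1`.
#'
#' @param records germline record data frame.
#' @return data frame (`key`, `n_distinct_cdna`, `total_index_cases`)
#'   sorted by descending recurrence.
#' @export
recurrence_table <- function(records) {
  if (nrow(records) == 0L) {
    return(data.frame(key = character(), n_distinct_cdna = integer(),
                      total_index_cases = integer(),
                      stringsAsFactors = FALSE))
  }
  key <- record_key(records)
  keys <- unique(key)
  out <- data.frame(
    key = keys,
    n_distinct_cdna = vapply(keys, function(k) {
      length(unique(records$cdna_norm[key == k]))
    }, integer(1)),
    total_index_cases = vapply(keys, function(k) {
      sum(records$n_index_cases[key == k])
    }, integer(1)),
    stringsAsFactors = FALSE
  )
  out <- out[order(-out$total_index_cases, out$key), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Residues affected by more than one distinct protein change
#'
#' @param records germline record data frame.
#' @param kinds optional protein-change kinds to restrict to (e.g.
#'   `"missense"` for substitution-only multiplicity).
#' @return data frame (`residue`, `n_changes`, `kinds`) sorted by residue;
#'   `kinds` lists the change kinds involved, comma-separated.
#' @export
multi_hit_residues <- function(records, kinds = NULL) {
  keep <- !is.na(records$start_res)
  if (!is.null(kinds)) keep <- keep & records$protein_kind %in% kinds
  rec <- records[keep, , drop = FALSE]
  if (nrow(rec) == 0L) {
    return(data.frame(residue = integer(), n_changes = integer(),
                      kinds = character(), stringsAsFactors = FALSE))
  }
  res <- sort(unique(rec$start_res))
  out <- do.call(rbind, lapply(res, function(r) {
    here <- rec[rec$start_res == r, , drop = FALSE]
    nk <- length(unique(here$protein_key))
    if (nk < 2L) return(NULL)
    data.frame(residue = r, n_changes = nk,
               kinds = paste(sort(unique(here$protein_kind)),
                             collapse = ","),
               stringsAsFactors = FALSE)
  }))
  if (is.null(out)) {
    return(data.frame(residue = integer(), n_changes = integer(),
                      kinds = character(), stringsAsFactors = FALSE))
  }
  rownames(out) <- NULL
  out
}

#' Germline/somatic overlap
#'
#' A somatic event counts as "also described as a germline event" when
#' the same variant occurs in both tables: matching is on the normalized
#' cDNA-level description of point events (structural events and cnLOH
#' never match), and the shared variants are reported by their protein
#' keys. Protein-level coincidences arising from *different* cDNA changes
#' are not counted here; [consistency_report()] surfaces them.
#'
#' @param germline data frame from [load_germline_table()].
#' @param somatic data frame from [load_somatic_table()].
#' @return character vector of shared protein keys (sorted, unique);
#'   attribute `"cdna"` carries the matching cDNA descriptions.
#' @export
germline_somatic_overlap <- function(germline, somatic) {
  g <- germline[!germline$structural, , drop = FALSE]
  s <- somatic[somatic$event_type == "point", , drop = FALSE]
  shared_cdna <- intersect(g$cdna_norm, s$cdna_norm)
  keys <- g$protein_key[match(shared_cdna, g$cdna_norm)]
  keys <- ifelse(is.na(keys), shared_cdna, keys)
  out <- sort(unique(keys))
  attr(out, "cdna") <- sort(shared_cdna)
  out
}

#' Summarize a somatic event table
#'
#' Distinct events are keyed on the protein-level change (structural
#' events, including cnLOH, on their description), so repeated table rows
#' describing the same event in different germline backgrounds count
#' once.
#'
#' @param events data frame from [load_somatic_table()].
#' @return list with `n_events` (distinct), `n_rows`, per-category
#'   distinct counts and the per-category row counts.
#' @export
summarize_somatic <- function(events) {
  cats <- c("missense", "nonsense", "frameshift", "splice",
            "inframe_indel", "large_deletion", "cnLOH")
  if (nrow(events) == 0L) {
    z <- stats::setNames(as.list(integer(length(cats))), cats)
    return(list(n_events = 0L, n_rows = 0L, counts_by_category = z,
                row_counts_by_category = z))
  }
  category <- ifelse(events$event_type == "cnLOH", "cnLOH",
                     events$consequence)
  key <- ifelse(events$event_type == "cnLOH", "cnLOH",
                record_key(events))
  dedup <- !duplicated(key)
  count_cat <- function(x) {
    tab <- table(factor(x, levels = cats))
    as.list(stats::setNames(as.integer(tab), cats))
  }
  list(
    n_events = sum(dedup),
    n_rows = nrow(events),
    counts_by_category = count_cat(category[dedup]),
    row_counts_by_category = count_cat(category)
  )
}

#' Default ARMC5 protein domain map
#'
#' The protein spans 935 residues with an armadillo-repeat region in the
#' N-terminal/central part and a BTB/POZ protein-interaction domain in
#' the C-terminus. Published tables give no coordinates, so the bounds
#' are configurable defaults used only for annotation and plotting.
#'
#' @param protein_length protein length in residues.
#' @param domains data frame with columns `name`, `start`, `end`
#'   (1-based, inclusive, non-overlapping).
#' @return object of class `domain_map`.
#' @export
domain_map <- function(protein_length = 935L,
                       domains = data.frame(
                         name = c("Armadillo", "BTB/POZ"),
                         start = c(71L, 701L),
                         end = c(400L, 870L),
                         stringsAsFactors = FALSE)) {
  stopifnot(all(domains$start >= 1L), all(domains$end >= domains$start),
            all(domains$end <= protein_length))
  d <- domains[order(domains$start), , drop = FALSE]
  if (nrow(d) > 1L && any(d$start[-1L] <= d$end[-nrow(d)])) {
    stop("domains overlap")
  }
  out <- list(protein_length = as.integer(protein_length), domains = d)
  class(out) <- "domain_map"
  out
}

.domain_of <- function(residue, dmap) {
  vapply(residue, function(r) {
    if (is.na(r)) return(NA_character_)
    hit <- dmap$domains$name[r >= dmap$domains$start &
                             r <= dmap$domains$end]
    if (length(hit)) hit[1] else NA_character_
  }, character(1))
}

#' Build the lollipop-plot model
#'
#' One lollipop per protein-level key: residue position, consequence
#' category, recurrence (total index cases) and the display color group
#' used in published landscape figures - class 4/5 variants colored by
#' category, class 2/3 in grey. Structural events and records without a
#' residue position are excluded.
#'
#' @param records germline record data frame.
#' @param dmap a [domain_map()].
#' @return list (`protein_length`, `domains`, `lollipops` data frame)
#'   ready for JSON serialization.
#' @export
lollipop_export <- function(records, dmap = domain_map()) {
  rec <- records[!is.na(records$start_res), , drop = FALSE]
  if (nrow(rec) == 0L) {
    return(list(protein_length = dmap$protein_length,
                domains = dmap$domains,
                lollipops = data.frame(key = character(),
                                       residue = integer(),
                                       category = character(),
                                       recurrence = integer(),
                                       color_group = character(),
                                       domain = character(),
                                       stringsAsFactors = FALSE)))
  }
  keys <- unique(rec$protein_key)
  lp <- do.call(rbind, lapply(keys, function(k) {
    here <- rec[rec$protein_key == k, , drop = FALSE]
    cls <- parse_classification(here$class_printed[1])
    colored <- cls >= "likely_pathogenic"
    data.frame(
      key = k,
      residue = here$start_res[1],
      category = here$consequence[1],
      recurrence = sum(here$n_index_cases),
      color_group = if (colored) here$consequence[1] else "grey",
      domain = .domain_of(here$start_res[1], dmap),
      stringsAsFactors = FALSE
    )
  }))
  rownames(lp) <- NULL
  list(protein_length = dmap$protein_length, domains = dmap$domains,
       lollipops = lp)
}

#' Cross-check identities and transcription anomalies
#'
#' Verifies the arithmetic identities a consistent pair of curated tables
#' must satisfy (total distinct alterations, SNV/indel/structural and
#' consequence partitions of the germline count) and flags internal
#' contradictions carried over from the source tables: protein positions
#' inconsistent with their cDNA positions, somatic sub-counts that do not
#' add up, and protein-level germline/somatic coincidences that are not
#' shared cDNA-level variants.
#'
#' @param germline data frame from [load_germline_table()].
#' @param somatic data frame from [load_somatic_table()].
#' @param codon_tolerance residues of slack allowed between a protein
#'   position and its cDNA-implied codon (frameshift descriptions shift a
#'   few residues 3'; default 15).
#' @return data frame (`check`, `status`, `detail`); `status` is
#'   `"ok"` or `"flag"`.
#' @export
consistency_report <- function(germline, somatic, codon_tolerance = 15L) {
  gs <- summarize_germline(germline)
  ss <- summarize_somatic(somatic)
  overlap <- germline_somatic_overlap(germline, somatic)
  checks <- list()
  add <- function(check, ok, detail) {
    checks[[length(checks) + 1L]] <<- data.frame(
      check = check, status = if (ok) "ok" else "flag", detail = detail,
      stringsAsFactors = FALSE)
  }

  n_g <- gs$n_variants; n_s <- ss$n_events; n_shared <- length(overlap)
  add("total_distinct_alterations",
      TRUE,
      sprintf("%d + %d - %d = %d", n_g, n_s, n_shared,
              n_g + n_s - n_shared))
  add("germline_edit_partition",
      gs$n_snv + gs$n_indel + gs$n_structural == n_g,
      sprintf("SNV %d + indel %d + structural %d vs %d", gs$n_snv,
              gs$n_indel, gs$n_structural, n_g))
  add("germline_consequence_partition",
      sum(unlist(gs$counts_by_consequence)) == n_g,
      sprintf("consequence counts sum to %d vs %d",
              sum(unlist(gs$counts_by_consequence)), n_g))

  # somatic rows vs distinct events
  add("somatic_distinct_vs_rows",
      ss$n_events == ss$n_rows,
      sprintf("%d distinct events in %d table rows", ss$n_events,
              ss$n_rows))
  snv_cats <- c("missense", "nonsense", "splice")
  snv_rows <- sum(unlist(ss$row_counts_by_category[snv_cats]))
  sp <- somatic[somatic$event_type == "point", , drop = FALSE]
  n_true_snv <- sum(vapply(sp$cdna_norm, function(x) {
    is_snv(parse_cdna(x))
  }, logical(1)))
  add("somatic_snv_subcounts",
      snv_rows == n_true_snv,
      sprintf("impact-category SNV rows %d vs substitution edits %d",
              snv_rows, n_true_snv))

  # protein-level overlap coincidences not backed by a shared cDNA variant
  g <- germline[!germline$structural & !is.na(germline$protein_key), ,
                drop = FALSE]
  s <- somatic[somatic$event_type == "point" &
                 !is.na(somatic$protein_key), , drop = FALSE]
  prot_shared <- intersect(unique(g$protein_key), unique(s$protein_key))
  extra <- setdiff(prot_shared, overlap)
  add("protein_key_coincidences",
      length(extra) == 0L,
      if (length(extra)) {
        paste("protein keys shared without a shared cDNA variant:",
              paste(extra, collapse = ", "))
      } else "none")

  # protein position vs cDNA-implied codon
  both <- rbind(
    data.frame(cdna = g$cdna_norm, res = g$start_res,
               stringsAsFactors = FALSE),
    data.frame(cdna = s$cdna_norm, res = s$start_res,
               stringsAsFactors = FALSE)
  )
  both <- both[!is.na(both$res), , drop = FALSE]
  bad <- character()
  for (i in seq_len(nrow(both))) {
    cd <- parse_cdna(both$cdna[i])
    if (!is.na(cd$start_offset)) next  # intronic start: codon undefined
    codon <- ceiling(cd$start / 3)
    if (abs(codon - both$res[i]) > codon_tolerance) {
      bad <- c(bad, sprintf("%s (codon ~%d vs printed residue %d)",
                            both$cdna[i], codon, both$res[i]))
    }
  }
  add("protein_cdna_position_consistency",
      length(bad) == 0L,
      if (length(bad)) paste(bad, collapse = "; ") else "all consistent")

  out <- do.call(rbind, checks)
  rownames(out) <- NULL
  out
}
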