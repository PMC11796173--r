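#' @title Seeded synthetic cohort generator
#' @description
#' Generates synthetic germline/somatic variant cohorts with the
#' statistical structure the landscape analysis assumes: a configurable
#' consequence-category mix, a truncated-geometric recurrence
#' distribution (most variants private, the most recurrent seen ~10
#' times), latent five-class truth with criteria profiles sampled
#' conditionally on the class such that the strict combiner recovers the
#' class exactly, and Knudson-style somatic second hits (copy-neutral LOH
#' or point events) attached to pathogenic/likely-pathogenic germline
#' variants. Everything is reproducible from the mandatory seed.
#' @name synthetic_data
NULL

# amino acids used in random HGVS synthesis (no stop codons in missense
# draws)
.SIM_AA <- setdiff(AA3, c("Ter", "Sec"))
.SIM_BASES <- c("A", "C", "G", "T")

#' Specification of a synthetic cohort
#'
#' Defaults reproduce the germline study conditions of the curated ARMC5
#' landscape: 146 variants; category mix 46% missense, 45% truncating
#' (split 42:24 frameshift:nonsense), 3% splice, 4% in-frame, 2% large
#' deletions; recurrence truncated-geometric with maximum 10; latent
#' class mix matching the curated table (64:36:29:17
#' pathogenic:likely-pathogenic:VUS:likely-benign out of 146); 28% of
#' pathogenic/likely-pathogenic variants carrying a somatic second hit,
#' of which 12% are cnLOH.
#'
#' @param n_variants number of germline variants.
#' @param consequence_mix named probability vector over
#'   [consequence_levels()] (minus `synonymous`).
#' @param recurrence_geom_prob success probability of the truncated
#'   geometric recurrence distribution.
#' @param recurrence_max maximum index-case count.
#' @param latent_class_mix named probability vector over
#'   [classification_levels()].
#' @param second_hit_prob probability that a pathogenic/likely-pathogenic
#'   germline variant carries at least one somatic second hit.
#' @param loh_fraction fraction of second hits that are copy-neutral LOH.
#' @param n_shared number of germline point variants replayed verbatim as
#'   somatic events (planted germline/somatic overlap).
#' @param seed integer seed (mandatory).
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_variants = 146L,
                        consequence_mix = c(
                          missense = 0.46,
                          frameshift = 0.45 * 42 / 66,
                          nonsense = 0.45 * 24 / 66,
                          splice = 0.03,
                          inframe_indel = 0.04,
                          large_deletion = 0.02),
                        recurrence_geom_prob = 0.55,
                        recurrence_max = 10L,
                        latent_class_mix = c(
                          benign = 0,
                          likely_benign = 17 / 146,
                          vus = 29 / 146,
                          likely_pathogenic = 36 / 146,
                          pathogenic = 64 / 146),
                        second_hit_prob = 0.28,
                        loh_fraction = 0.12,
                        n_shared = 0L,
                        seed) {
  if (missing(seed)) stop("cohort_spec() requires a seed", call. = FALSE)
  stopifnot(n_variants >= 0L,
            abs(sum(consequence_mix) - 1) < 1e-8,
            abs(sum(latent_class_mix) - 1) < 1e-8,
            all(consequence_mix >= 0), all(latent_class_mix >= 0),
            recurrence_geom_prob > 0, recurrence_geom_prob < 1,
            recurrence_max >= 1L,
            second_hit_prob >= 0, second_hit_prob <= 1,
            loh_fraction >= 0, loh_fraction <= 1,
            n_shared >= 0L, n_shared <= n_variants)
  if (!all(names(consequence_mix) %in% consequence_levels())) {
    stop("consequence_mix names must be consequence levels")
  }
  if (!all(names(latent_class_mix) %in% classification_levels())) {
    stop("latent_class_mix names must be classification levels")
  }
  out <- list(n_variants = as.integer(n_variants),
              consequence_mix = consequence_mix,
              recurrence_geom_prob = recurrence_geom_prob,
              recurrence_max = as.integer(recurrence_max),
              latent_class_mix = latent_class_mix,
              second_hit_prob = second_hit_prob,
              loh_fraction = loh_fraction,
              n_shared = as.integer(n_shared),
              seed = as.integer(seed))
  class(out) <- "cohort_spec"
  out
}

# criteria-profile templates per latent class. Each template maps back to
# its class under combine_criteria(strict); generate_cohort() verifies
# this and refuses infeasible combinations. Truncating templates depend
# on whether the termination codon escapes NMD (PVS1 vs PVS1_S).
.profiles_for <- function(class, consequence, nmd_escape) {
  truncating <- consequence %in% c("nonsense", "frameshift", "splice",
                                   "large_deletion")
  pvs1 <- if (nmd_escape) "PVS1_S" else "PVS1"
  switch(class,
    pathogenic = if (truncating) {
      if (nmd_escape) list("PVS1_S;PS3;PM2", "PVS1_S;PS1;PM2;PP4")
      else list("PVS1;PM2;PP4", "PVS1;PS3;PM2", "PVS1;PM2;PM5")
    } else {
      list("PS1;PS3;PM2", "PS3;PM1;PM2;PP3;PP4")
    },
    likely_pathogenic = if (truncating) {
      if (nmd_escape) list("PVS1_S;PM2", "PVS1_S;PM2;PP4")
      else list("PVS1;PM2")
    } else {
      list("PS3;PM2;PP3", "PM1;PM2;PM5", "PM1;PM2;PP3;PP4")
    },
    vus = list("PM2", "PM2;PP3", "PP3;PP4", "PM2;PP3;PP4"),
    likely_benign = list("BP4;BP6", "BS1;BP4", "BS2;BP6", "BP1;BP3;BP4"),
    benign = list("BA1", "BS1;BS2", "BA1;BP4;BP6")
  )
}

# one random variant of the requested consequence; cDNA positions follow
# the 1-based c. numbering of a 935-codon reading frame
.sim_variant <- function(consequence) {
  res <- sample(5:930, 1L)
  codon_start <- 3L * res - 2L
  pos <- codon_start + sample(0:2, 1L)
  switch(consequence,
    missense = {
      aa <- sample(.SIM_AA, 2L)
      b <- sample(.SIM_BASES, 2L)
      list(cdna = sprintf("c.%d%s>%s", pos, b[1], b[2]),
           protein = sprintf("p.(%s%d%s)", aa[1], res, aa[2]),
           impact = "Missense")
    },
    nonsense = {
      aa <- sample(.SIM_AA, 1L)
      b <- sample(.SIM_BASES, 2L)
      list(cdna = sprintf("c.%d%s>%s", pos, b[1], b[2]),
           protein = sprintf("p.(%s%d*)", aa, res),
           impact = "Nonsense")
    },
    frameshift = {
      aa <- sample(.SIM_AA, 2L)
      off <- sample(1:110, 1L)
      len <- sample(c(1L, 2L, 4L, 5L), 1L)
      edit <- if (stats::runif(1) < 0.5 && len <= 2L) "dup" else "del"
      cdna <- if (len == 1L) sprintf("c.%d%s", pos, edit)
        else sprintf("c.%d_%d%s", pos, pos + len - 1L, edit)
      list(cdna = cdna,
           protein = sprintf("p.(%s%d%sfs*%d)", aa[1], res, aa[2], off),
           impact = "Frameshift")
    },
    splice = {
      b <- sample(.SIM_BASES, 2L)
      offset <- sample(c(-2L, -1L, 1L, 2L), 1L)
      list(cdna = sprintf("c.%d%+d%s>%s", codon_start, offset, b[1], b[2]),
           protein = NA_character_,
           impact = "Splice")
    },
    inframe_indel = {
      aa <- sample(.SIM_AA, 1L)
      list(cdna = sprintf("c.%d_%ddel", codon_start, codon_start + 2L),
           protein = sprintf("p.(%s%ddel)", aa, res),
           impact = "In frame deletion")
    },
    large_deletion = {
      j <- sample(1:8, 1L)
      k <- sample(j:9, 1L)
      list(cdna = sprintf("ARMC5 exons %d-%d deletion", j, k),
           protein = NA_character_,
           impact = "Large deletion")
    }
  )
}

# draw a variant whose cDNA is not yet in `seen` (an environment used as
# a hash set); structural descriptions are exempt from deduplication
.draw_distinct <- function(consequence, seen) {
  repeat {
    v <- .sim_variant(consequence)
    structural <- !startsWith(v$cdna, "c.")
    if (structural || !exists(v$cdna, envir = seen, inherits = FALSE)) {
      if (!structural) assign(v$cdna, TRUE, envir = seen)
      return(v)
    }
  }
}

#' Generate a synthetic cohort
#'
#' Variants receive syntactically valid HGVS strings at random positions
#' of the 935-residue protein; criteria profiles are sampled
#' conditionally on the latent class so that the strict combiner maps
#' each profile back to its class; recurrence counts are drawn from the
#' truncated geometric; second hits are attached per `second_hit_prob`
#' with the cnLOH/point split given by `loh_fraction`. Fully reproducible
#' from `spec$seed`; the caller's RNG state is left untouched.
#'
#' @param spec a [cohort_spec()].
#' @param cfg an [engine_config()]; places the NMD-escape boundary for
#'   truncating profiles.
#' @return object of class `synthetic_cohort`: list with `germline` and
#'   `somatic` data frames (parsed, as returned by the loaders), `truth`
#'   (latent class keyed by normalized cDNA) and the `spec`.
#' @export
generate_cohort <- function(spec, cfg = engine_config()) {
  stopifnot(inherits(spec, "cohort_spec"))
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  })
  set.seed(spec$seed)

  n <- spec$n_variants
  consequences <- if (n > 0L) {
    sample(names(spec$consequence_mix), n, replace = TRUE,
           prob = spec$consequence_mix)
  } else character()
  classes <- if (n > 0L) {
    sample(names(spec$latent_class_mix), n, replace = TRUE,
           prob = spec$latent_class_mix)
  } else character()
  recurrence <- if (n > 0L) {
    sample(spec$recurrence_max, n, replace = TRUE,
           prob = stats::dgeom(seq_len(spec$recurrence_max) - 1L,
                               spec$recurrence_geom_prob))
  } else integer()

  seen <- new.env(parent = emptyenv())
  checked <- new.env(parent = emptyenv())  # profile validations, cached
  cdna <- character(n); protein <- character(n); impact <- character(n)
  criteria <- character(n)
  for (i in seq_len(n)) {
    v <- .draw_distinct(consequences[i], seen)
    cdna[i] <- v$cdna; protein[i] <- v$protein; impact[i] <- v$impact
    term <- termination_codon(parse_protein(v$protein))
    nmd_escape <- !is.na(term) && term >= cfg$nmd_escape_codon
    pool <- .profiles_for(classes[i], consequences[i], nmd_escape)
    profile <- pool[[sample(length(pool), 1L)]]
    ckey <- paste0(classes[i], "|", profile)
    if (!exists(ckey, envir = checked, inherits = FALSE)) {
      got <- as.character(combine_criteria(parse_criteria_string(profile),
                                           engine_config()))
      if (!identical(got, classes[i])) {
        stop("infeasible spec: profile '", profile,
             "' does not map back to latent class '", classes[i], "'")
      }
      assign(ckey, TRUE, envir = checked)
    }
    criteria[i] <- profile
  }

  # Knudson second hits for pathogenic / likely-pathogenic variants
  second_hit <- rep(NA_character_, n)
  s_cdna <- character(); s_protein <- character(); s_impact <- character()
  s_assoc <- character(); s_note <- character()
  eligible <- which(classes %in% c("pathogenic", "likely_pathogenic"))
  for (i in eligible) {
    if (stats::runif(1) >= spec$second_hit_prob) next
    second_hit[i] <- "yes"
    g_key <- if (!is.na(protein[i])) protein[i] else cdna[i]
    if (stats::runif(1) < spec$loh_fraction) {
      s_cdna <- c(s_cdna, "cnLOH"); s_protein <- c(s_protein, NA)
      s_impact <- c(s_impact, "Deletion"); s_assoc <- c(s_assoc, g_key)
      s_note <- c(s_note, NA)
    } else {
      sv <- .draw_distinct(sample(c("nonsense", "frameshift"), 1L), seen)
      s_cdna <- c(s_cdna, sv$cdna); s_protein <- c(s_protein, sv$protein)
      s_impact <- c(s_impact, sv$impact); s_assoc <- c(s_assoc, g_key)
      s_note <- c(s_note, NA)
    }
  }

  # planted germline/somatic overlap: replay point variants verbatim
  if (spec$n_shared > 0L) {
    candidates <- which(startsWith(cdna, "c."))
    if (length(candidates) < spec$n_shared) {
      stop("infeasible spec: fewer point variants than n_shared")
    }
    pick <- candidates[seq_len(spec$n_shared)]
    s_cdna <- c(s_cdna, cdna[pick])
    s_protein <- c(s_protein, protein[pick])
    s_impact <- c(s_impact, impact[pick])
    s_assoc <- c(s_assoc, rep("none", length(pick)))
    s_note <- c(s_note, rep("planted shared event", length(pick)))
  }

  germline_tab <- if (n > 0L) data.frame(
    cdna = cdna, protein = protein, impact = impact,
    class = vapply(classes, .class_label, character(1),
                   USE.NAMES = FALSE),
    criteria = criteria, second_hit = second_hit,
    functional = NA_character_, context = "pbmah", novel = "FALSE",
    n_index_cases = as.character(recurrence), polymorphism = "FALSE",
    note = NA_character_, refs = "SIM", stringsAsFactors = FALSE
  ) else NULL
  somatic_tab <- if (length(s_cdna)) data.frame(
    cdna = s_cdna, protein = s_protein, impact = s_impact,
    associated_germline = s_assoc, context = "pbmah", note = s_note,
    refs = "SIM", stringsAsFactors = FALSE
  ) else NULL

  tmp_g <- tempfile(fileext = ".tsv"); tmp_s <- tempfile(fileext = ".tsv")
  on.exit(unlink(c(tmp_g, tmp_s)), add = TRUE)
  .write_fixture_tsv(germline_tab, GERMLINE_COLUMNS, tmp_g)
  .write_fixture_tsv(somatic_tab, SOMATIC_COLUMNS, tmp_s)
  germline <- load_germline_table(tmp_g, verify_checksum = FALSE)
  somatic <- load_somatic_table(tmp_s, verify_checksum = FALSE)

  truth <- stats::setNames(classes, germline$cdna_norm)
  out <- list(germline = germline, somatic = somatic, truth = truth,
              spec = spec)
  class(out) <- "synthetic_cohort"
  out
}

.write_fixture_tsv <- function(tab, columns, path) {
  if (is.null(tab) || nrow(tab) == 0L) {
    tab <- as.data.frame(stats::setNames(
      rep(list(character()), length(columns)), columns),
      stringsAsFactors = FALSE)
  }
  stopifnot(identical(names(tab), columns))
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA",
                     fileEncoding = "UTF-8")
}

.class_label <- function(x) {
  switch(x, benign = "Benign", likely_benign = "Likely benign",
         vus = "VUS", likely_pathogenic = "Likely pathogenic",
         pathogenic = "Pathogenic")
}

#' Write a synthetic cohort as fixture-schema TSVs
#'
#' Emits `germline.tsv` and `somatic.tsv` in the same schemas as the
#' packaged fixture tables, so the written cohort round-trips through
#' [load_germline_table()] and [load_somatic_table()].
#'
#' @param cohort a `synthetic_cohort`.
#' @param dir output directory (created if needed).
#' @return named character vector of the two file paths.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  gl <- cohort$germline
  g <- data.frame(
    cdna = gl$cdna, protein = gl$protein, impact = gl$impact,
    class = vapply(gl$class_printed, .class_label, character(1),
                   USE.NAMES = FALSE),
    criteria = gl$criteria,
    second_hit = ifelse(gl$second_hit == "yes", "yes", NA_character_),
    functional = ifelse(gl$functional == "yes", "yes", NA_character_),
    context = gl$context,
    novel = ifelse(gl$novel, "TRUE", "FALSE"),
    n_index_cases = as.character(gl$n_index_cases),
    polymorphism = ifelse(gl$polymorphism, "TRUE", "FALSE"),
    note = gl$note, refs = gl$refs, stringsAsFactors = FALSE
  )
  so <- cohort$somatic
  s <- data.frame(
    cdna = so$cdna, protein = so$protein, impact = so$impact,
    associated_germline = vapply(so$associated_keys, function(k) {
      if (!length(k)) "none" else paste(k, collapse = ";")
    }, character(1)),
    context = so$context, note = so$note, refs = so$refs,
    stringsAsFactors = FALSE
  )
  gp <- file.path(dir, "germline.tsv")
  sp <- file.path(dir, "somatic.tsv")
  .write_fixture_tsv(g, GERMLINE_COLUMNS, gp)
  .write_fixture_tsv(s, SOMATIC_COLUMNS, sp)
  c(germline = gp, somatic = sp)
}

#' Recover latent classes from a synthetic cohort
#'
#' Runs the strict combiner over each synthetic record's criteria profile
#' and compares against the latent truth. By construction of the
#' unambiguous profile templates the recovery rate is 1; anything less is
#' a combiner or generator defect.
#'
#' @param cohort a `synthetic_cohort`.
#' @param cfg an [engine_config()]; the policy is forced to `strict`.
#' @return list with `n`, `n_recovered`, `rate` and a `misses` data
#'   frame.
#' @export
recover_classes <- function(cohort, cfg = engine_config()) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  cfg$conflict_policy <- "strict"
  g <- cohort$germline
  n <- nrow(g)
  if (n == 0L) {
    return(list(n = 0L, n_recovered = 0L, rate = NaN,
                misses = data.frame(cdna = character(),
                                    truth = character(),
                                    recovered = character())))
  }
  recovered <- vapply(seq_len(n), function(i) {
    as.character(combine_criteria(parse_criteria_string(g$criteria[i]),
                                  cfg))
  }, character(1))
  # the loaders preserve row order, so truth aligns positionally (names
  # are informative only: structural descriptions may repeat)
  truth <- unname(cohort$truth)
  ok <- recovered == truth
  list(n = n, n_recovered = sum(ok), rate = mean(ok),
       misses = data.frame(cdna = g$cdna_norm[!ok], truth = truth[!ok],
                           recovered = recovered[!ok],
                           stringsAsFactors = FALSE))
}
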