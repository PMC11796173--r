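#' @title Evidence-based criteria assignment
#' @description
#' Turns structured annotations (population frequency, in-silico verdict,
#' segregation, phenotype specificity, tumor second hits, functional data,
#' database reports) into an ACMG criteria set, using the gene-specific
#' conventions of ARMC5 curation: a somatic second hit in tumor DNA fires
#' PS3 (two-hit tumor-suppressor evidence), and truncating variants whose
#' premature termination codon falls in the NMD-escaping 3' region carry
#' PVS1 downgraded to strong ("PVS1_S").
#' @name assign
NULL

#' Engine configuration
#'
#' Thresholds and policy switches for criteria assignment and combination.
#' Allele-frequency tiers: `pm2_max_maf` (absent-from-controls bound for
#' PM2), `bs1_threshold` (frequency greater than expected for the
#' disorder), `polymorphism_maf` (frequent-polymorphism override) and
#' `ba1_threshold` (stand-alone benign). `nmd_escape_codon` is the first
#' residue from which a premature termination codon is taken to escape
#' nonsense-mediated decay; the default 668 is derived from curated ARMC5
#' tables (full PVS1 up to termination 654, downgraded from 684), not from
#' transcript annotation, and is configurable.
#'
#' @param ba1_threshold stand-alone benign MAF (default 0.05).
#' @param bs1_threshold strong benign MAF (default 0.001).
#' @param pm2_max_maf max MAF compatible with PM2 (default 1e-5).
#' @param polymorphism_maf frequent-polymorphism MAF (default 0.02).
#' @param nmd_escape_codon first NMD-escaping termination codon
#'   (default 668).
#' @param conflict_policy `"strict"` or `"as_curated"`.
#' @return object of class `engine_config`.
#' @export
engine_config <- function(ba1_threshold = 0.05,
                          bs1_threshold = 0.001,
                          pm2_max_maf = 1e-5,
                          polymorphism_maf = 0.02,
                          nmd_escape_codon = 668L,
                          conflict_policy = c("strict", "as_curated")) {
  conflict_policy <- match.arg(conflict_policy)
  stopifnot(pm2_max_maf < bs1_threshold,
            bs1_threshold < polymorphism_maf,
            polymorphism_maf < ba1_threshold,
            nmd_escape_codon >= 1)
  out <- list(ba1_threshold = ba1_threshold,
              bs1_threshold = bs1_threshold,
              pm2_max_maf = pm2_max_maf,
              polymorphism_maf = polymorphism_maf,
              nmd_escape_codon = as.integer(nmd_escape_codon),
              conflict_policy = conflict_policy)
  class(out) <- "engine_config"
  out
}

#' Read an engine configuration from YAML or JSON
#'
#' @param path file path; format chosen by extension (`.yml`/`.yaml` or
#'   `.json`).
#' @return an [engine_config()].
#' @export
read_engine_config <- function(path) {
  vals <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  known <- names(formals(engine_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) {
    stop("unknown engine_config fields: ", paste(unknown, collapse = ", "))
  }
  do.call(engine_config, vals)
}

#' Write an engine configuration
#'
#' @param cfg an [engine_config()].
#' @param path destination; `.yml`/`.yaml` or `.json`.
#' @export
write_engine_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "engine_config"))
  vals <- unclass(cfg)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::write_yaml(vals, path)
  } else {
    jsonlite::write_json(vals, path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Structured annotation profile for one variant
#'
#' `maf = NA` means the variant is absent from population databases, which
#' is distinct from an observed frequency of zero.
#'
#' @param maf population minor allele frequency in `[0, 1]`, or `NA`.
#' @param insilico `"deleterious"`, `"benign"`, `"conflicting"` or
#'   `"absent"`.
#' @param segregation cosegregation with disease in the family.
#' @param phenotype_specific phenotype highly specific (PBMAH with
#'   bilateral macronodules and cortisol dysregulation).
#' @param somatic_second_hit somatic second hit found in tumor DNA.
#' @param functional_damaging `"yes"`, `"no"` or `"untested"`.
#' @param reputable_source `"pathogenic_report"`, `"benign_report"` or
#'   `"none"`.
#' @param same_aa_known_pathogenic same amino-acid change previously
#'   established pathogenic (PS1).
#' @param other_missense_at_residue_pathogenic different pathogenic
#'   missense at the residue (PM5).
#' @param in_hotspot_domain residue in a mutational hotspot or critical
#'   domain (PM1).
#' @param inframe_in_repeat in-frame indel inside a repetitive region
#'   (BP3; suppresses PM4).
#' @param missense_in_truncating_gene missense in a gene where truncating
#'   variants cause disease (BP1).
#' @param healthy_adult_carrier observed in a healthy adult (BS2).
#' @return object of class `evidence_profile`.
#' @export
evidence_profile <- function(maf = NA_real_,
                             insilico = c("absent", "deleterious", "benign",
                                          "conflicting"),
                             segregation = FALSE,
                             phenotype_specific = FALSE,
                             somatic_second_hit = FALSE,
                             functional_damaging = c("untested", "yes", "no"),
                             reputable_source = c("none", "pathogenic_report",
                                                  "benign_report"),
                             same_aa_known_pathogenic = FALSE,
                             other_missense_at_residue_pathogenic = FALSE,
                             in_hotspot_domain = FALSE,
                             inframe_in_repeat = FALSE,
                             missense_in_truncating_gene = FALSE,
                             healthy_adult_carrier = FALSE) {
  insilico <- match.arg(insilico)
  functional_damaging <- match.arg(functional_damaging)
  reputable_source <- match.arg(reputable_source)
  stopifnot(is.na(maf) || (maf >= 0 && maf <= 1))
  out <- as.list(environment())
  class(out) <- "evidence_profile"
  out
}

.truncating_consequences <- c("nonsense", "frameshift", "splice",
                              "large_deletion")

#' Assign ACMG criteria from a variant's consequence and annotations
#'
#' Fired rules, in brief: PVS1 for null variants (nonsense, frameshift,
#' canonical splice, large deletion), downgraded to strong (`PVS1_S`) when
#' the premature termination codon is at or beyond the configured
#' NMD-escape boundary; PS1/PM5 from residue-level precedent; PS3 from
#' damaging functional data *or* a somatic second hit (tagged with its
#' provenance); PM1 hotspot/domain; PM2 absent-or-rare; PM4 for in-frame
#' indels outside repeats; PP1 segregation; PP3/BP4 from the in-silico
#' verdict; PP4 phenotype specificity; PP5/BP6 from database reports;
#' BA1/BS1 frequency tiers; BS2 healthy carrier; BS3 functional data
#' showing no damage; BP1/BP3 per flags. Mutually exclusive pairs
#' (PS3/BS3, PP3/BP4, PP5/BP6) can never co-fire.
#'
#' @param consequence one of [consequence_levels()].
#' @param position premature-termination residue for nonsense/frameshift
#'   variants (see [termination_codon()]); ignored otherwise.
#' @param ev an [evidence_profile()].
#' @param cfg an [engine_config()].
#' @return a `criteria_set`; attribute `"polymorphism"` is `TRUE` when
#'   `maf >= cfg$polymorphism_maf`, and attribute `"ps3_provenance"`
#'   records whether PS3 came from `"functional"` or `"second_hit"`
#'   evidence.
#' @examples
#' ev <- evidence_profile(somatic_second_hit = TRUE,
#'                        phenotype_specific = TRUE)
#' format(assign_criteria("nonsense", 267, ev))  # "PVS1;PS3;PM2;PP4"
#' @export
assign_criteria <- function(consequence, position = NULL,
                            ev = evidence_profile(),
                            cfg = engine_config()) {
  stopifnot(consequence %in% consequence_levels(),
            inherits(ev, "evidence_profile"),
            inherits(cfg, "engine_config"))
  crits <- list()
  add <- function(code, strength = default_strength(code)) {
    crits[[length(crits) + 1L]] <<- acmg_criterion(code, strength)
  }

  truncating <- consequence %in% .truncating_consequences
  if (truncating) {
    if (consequence %in% c("nonsense", "frameshift")) {
      if (is.null(position) || is.na(position)) {
        stop("truncating variant requires a termination-codon position",
             call. = FALSE)
      }
      if (position >= cfg$nmd_escape_codon) add("PVS1", "strong")
      else add("PVS1")
    } else {
      # splice and structural deletions: NMD escape not assessable from a
      # residue position; full PVS1
      add("PVS1")
    }
  }

  ps3_provenance <- NULL
  # direct functional evidence outranks the second-hit inference, so an
  # assay showing no damage (BS3 below) suppresses PS3
  if (identical(ev$functional_damaging, "yes")) {
    add("PS3"); ps3_provenance <- "functional"
  } else if (isTRUE(ev$somatic_second_hit) &&
             !identical(ev$functional_damaging, "no")) {
    add("PS3"); ps3_provenance <- "second_hit"
  }
  if (isTRUE(ev$same_aa_known_pathogenic)) add("PS1")
  if (isTRUE(ev$in_hotspot_domain)) add("PM1")
  if (is.na(ev$maf) || ev$maf < cfg$pm2_max_maf) add("PM2")
  if (consequence == "inframe_indel" && !isTRUE(ev$inframe_in_repeat)) {
    add("PM4")
  }
  if (isTRUE(ev$other_missense_at_residue_pathogenic)) add("PM5")
  if (isTRUE(ev$segregation)) add("PP1")
  if (identical(ev$insilico, "deleterious")) add("PP3")
  if (isTRUE(ev$phenotype_specific)) add("PP4")
  if (identical(ev$reputable_source, "pathogenic_report")) add("PP5")

  if (!is.na(ev$maf) && ev$maf >= cfg$ba1_threshold) add("BA1")
  if (!is.na(ev$maf) && ev$maf >= cfg$bs1_threshold &&
      ev$maf < cfg$ba1_threshold) add("BS1")
  if (isTRUE(ev$healthy_adult_carrier)) add("BS2")
  if (identical(ev$functional_damaging, "no")) add("BS3")
  if (consequence == "missense" &&
      isTRUE(ev$missense_in_truncating_gene)) add("BP1")
  if (consequence == "inframe_indel" && isTRUE(ev$inframe_in_repeat)) {
    add("BP3")
  }
  if (identical(ev$insilico, "benign")) add("BP4")
  if (identical(ev$reputable_source, "benign_report")) add("BP6")

  out <- criteria_set(crits)
  attr(out, "polymorphism") <- !is.na(ev$maf) &&
    ev$maf >= cfg$polymorphism_maf
  attr(out, "ps3_provenance") <- ps3_provenance
  out
}
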