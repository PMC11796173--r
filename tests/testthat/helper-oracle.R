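# Independent brute-force evaluator of the five-class combining rules.
# Written as a literal transcription of the published rule list over
# criterion counts; deliberately shares no code with combine_criteria().

oracle_combine <- function(pvs1, n_strong, n_moderate, n_supporting,
                           ba1, n_bs, n_bp) {
  path_rules <- c(
    pvs1 && n_strong >= 1,
    pvs1 && n_moderate >= 2,
    pvs1 && n_moderate >= 1 && n_supporting >= 1,
    pvs1 && n_supporting >= 2,
    n_strong >= 2,
    n_strong == 1 && n_moderate >= 3,
    n_strong == 1 && n_moderate == 2 && n_supporting >= 2,
    n_strong == 1 && n_moderate == 1 && n_supporting >= 4
  )
  lp_rules <- c(
    pvs1 && n_moderate == 1,
    n_strong == 1 && n_moderate >= 1 && n_moderate <= 2,
    n_strong == 1 && n_supporting >= 2,
    n_moderate >= 3,
    n_moderate == 2 && n_supporting >= 2,
    n_moderate == 1 && n_supporting >= 4
  )
  benign_rules <- c(ba1, n_bs >= 2)
  lb_rules <- c(n_bs == 1 && n_bp >= 1, n_bp >= 2)

  p_side <- if (any(path_rules)) "pathogenic"
    else if (any(lp_rules)) "likely_pathogenic" else NA
  b_side <- if (any(benign_rules)) "benign"
    else if (any(lb_rules)) "likely_benign" else NA
  if (!is.na(p_side) && !is.na(b_side)) return("vus")
  if (!is.na(p_side)) return(p_side)
  if (!is.na(b_side)) return(b_side)
  "vus"
}

# materialize a criteria set with the requested multiset of effective
# strengths, using distinct codes for each slot
build_criteria_set <- function(pvs1, n_strong, n_moderate, n_supporting,
                               ba1, n_bs, n_bp,
                               pvs1_modified = FALSE) {
  crits <- list()
  if (pvs1) crits <- c(crits, list(acmg_criterion("PVS1")))
  strong_codes <- c("PS1", "PS2", "PS3", "PS4")
  if (pvs1_modified) {
    crits <- c(crits, list(acmg_criterion("PVS1", "strong")))
    strong_codes <- strong_codes[-1]  # keep total strong count honest
  }
  for (k in seq_len(n_strong - pvs1_modified)) {
    crits <- c(crits, list(acmg_criterion(strong_codes[k])))
  }
  for (k in seq_len(n_moderate)) {
    crits <- c(crits, list(acmg_criterion(paste0("PM", k))))
  }
  for (k in seq_len(n_supporting)) {
    crits <- c(crits, list(acmg_criterion(paste0("PP", k))))
  }
  if (ba1) crits <- c(crits, list(acmg_criterion("BA1")))
  for (k in seq_len(n_bs)) {
    crits <- c(crits, list(acmg_criterion(paste0("BS", k))))
  }
  for (k in seq_len(n_bp)) {
    crits <- c(crits, list(acmg_criterion(paste0("BP", k))))
  }
  criteria_set(crits)
}

# quadratic reference implementations for the landscape aggregations
brute_recurrence <- function(records) {
  key <- ifelse(is.na(records$protein_key), records$cdna_norm,
                records$protein_key)
  out <- NULL
  for (k in unique(key)) {
    rows <- which(key == k)
    out <- rbind(out, data.frame(
      key = k,
      n_distinct_cdna = length(unique(records$cdna_norm[rows])),
      total_index_cases = sum(records$n_index_cases[rows]),
      stringsAsFactors = FALSE))
  }
  out[order(-out$total_index_cases, out$key), , drop = FALSE]
}

brute_overlap <- function(germline, somatic) {
  g <- germline[!germline$structural, , drop = FALSE]
  s <- somatic[somatic$event_type == "point", , drop = FALSE]
  keys <- character()
  for (i in seq_len(nrow(g))) {
    for (j in seq_len(nrow(s))) {
      if (identical(g$cdna_norm[i], s$cdna_norm[j])) {
        keys <- c(keys, if (is.na(g$protein_key[i])) g$cdna_norm[i]
                  else g$protein_key[i])
      }
    }
  }
  sort(unique(keys))
}
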