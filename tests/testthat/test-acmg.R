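test_that("criteria strings tokenize greedily, including modified strengths", {
  cs <- parse_criteria_string("PVS1PM2PP4")
  expect_setequal(names(cs), c("PVS1", "PM2", "PP4"))

  mod <- parse_criteria_string("PVS1_SPM2PS3PP4")
  expect_setequal(names(mod), c("PVS1", "PM2", "PS3", "PP4"))
  expect_equal(mod$PVS1$strength, "strong")
  expect_true(mod$PVS1$modified)
  expect_equal(format(mod$PVS1), "PVS1_S")

  expect_length(parse_criteria_string(""), 0)
  expect_length(parse_criteria_string(NA_character_), 0)
  expect_equal(names(parse_criteria_string("PVS1;PM2;PP4")),
               names(parse_criteria_string("PVS1 PM2 PP4")))
  expect_error(parse_criteria_string("PVS1PMXPP4"), "PMXPP4")
})

test_that("default strengths follow the code prefixes", {
  expect_equal(default_strength("PVS1"), "very_strong")
  expect_equal(default_strength(c("PS3", "PM2", "PP4")),
               c("strong", "moderate", "supporting"))
  expect_equal(default_strength(c("BA1", "BS1", "BP4")),
               c("stand_alone", "strong", "supporting"))
  expect_error(criteria_set(list(acmg_criterion("PM2"),
                                 acmg_criterion("PM2"))),
               "duplicate")
})

test_that("combine reproduces curated classifications for table-style sets", {
  comb <- function(x, policy = "strict", poly = FALSE) {
    as.character(combine_criteria(parse_criteria_string(x),
                                  engine_config(conflict_policy = policy),
                                  polymorphism = poly))
  }
  expect_equal(comb("PVS1PM2PP4"), "pathogenic")
  expect_equal(comb("PVS1PM2"), "likely_pathogenic")
  expect_equal(comb("PM2"), "vus")
  expect_equal(comb("PS3PM2PM5PP3PP5PP4"), "pathogenic")
  expect_equal(comb("PVS1_SPM2PP4"), "likely_pathogenic")
  expect_equal(comb("PVS1_SPM2PS3PP4"), "pathogenic")  # two strong
  expect_equal(comb(""), "vus")
  # benign side
  expect_equal(comb("BA1BP4BP3BP6"), "benign")
  expect_equal(comb("BS3", "as_curated"), "likely_benign")
  expect_equal(comb("BS3"), "vus")  # strict needs a combining rule
  expect_equal(comb("BS2BP6PS3", "as_curated"), "likely_benign")
  # polymorphism override forces benign under as_curated
  expect_equal(comb("BS1BP4BP6", "as_curated", poly = TRUE), "benign")
  expect_equal(comb("BS1BP4BP6", "as_curated"), "likely_benign")
})

test_that("strict combine agrees with the brute-force rule evaluator everywhere", {
  cfg <- engine_config(conflict_policy = "strict")
  grid <- expand.grid(pvs1 = c(FALSE, TRUE), n_strong = 0:2,
                      n_moderate = 0:3, n_supporting = 0:4,
                      ba1 = c(FALSE, TRUE), n_bs = 0:2, n_bp = 0:2)
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    cs <- build_criteria_set(g$pvs1, g$n_strong, g$n_moderate,
                             g$n_supporting, g$ba1, g$n_bs, g$n_bp)
    expect_identical(
      as.character(combine_criteria(cs, cfg)),
      oracle_combine(g$pvs1, g$n_strong, g$n_moderate, g$n_supporting,
                     g$ba1, g$n_bs, g$n_bp),
      label = paste(unlist(g), collapse = "/"))
  }
})

test_that("a modified PVS1 counts as strong, not as PVS1", {
  cfg <- engine_config(conflict_policy = "strict")
  for (ns in 1:2) for (nm in 0:3) for (np in 0:4) {
    cs <- build_criteria_set(FALSE, ns, nm, np, FALSE, 0, 0,
                             pvs1_modified = TRUE)
    expect_identical(
      as.character(combine_criteria(cs, cfg)),
      oracle_combine(FALSE, ns, nm, np, FALSE, 0, 0),
      label = sprintf("PVS1_S with s=%d m=%d p=%d", ns, nm, np))
  }
})

test_that("adding pathogenic evidence never lowers a strict classification", {
  set.seed(42)
  cfg <- engine_config(conflict_policy = "strict")
  addable <- list(c("PS4", "strong"), c("PM6", "moderate"),
                  c("PP5", "supporting"))
  for (rep in 1:200) {
    base <- build_criteria_set(sample(c(TRUE, FALSE), 1), sample(0:2, 1),
                               sample(0:3, 1), sample(0:4, 1),
                               FALSE, 0, 0)
    extra <- addable[[sample(3, 1)]]
    if (extra[1] %in% names(base)) next
    bigger <- criteria_set(c(unclass(base),
                             list(acmg_criterion(extra[1], extra[2]))))
    expect_gte(as.integer(combine_criteria(bigger, cfg)),
               as.integer(combine_criteria(base, cfg)))
  }
})

test_that("combine depends only on the multiset of effective strengths", {
  set.seed(7)
  cfg <- engine_config(conflict_policy = "strict")
  swap <- list(PS1 = "PS4", PM1 = "PM6", PP1 = "PP5", BS1 = "BS4",
               BP1 = "BP7")
  for (rep in 1:200) {
    cs <- build_criteria_set(sample(c(TRUE, FALSE), 1), sample(0:2, 1),
                             sample(0:3, 1), sample(0:4, 1),
                             sample(c(TRUE, FALSE), 1), sample(0:2, 1),
                             sample(0:2, 1))
    renamed <- lapply(unclass(cs), function(cr) {
      if (cr$code %in% names(swap) && !swap[[cr$code]] %in% names(cs)) {
        acmg_criterion(swap[[cr$code]], cr$strength)
      } else cr
    })
    expect_identical(combine_criteria(criteria_set(renamed), cfg),
                     combine_criteria(cs, cfg))
  }
})

test_that("evidence profiles assign the documented gene-specific criteria", {
  cfg <- engine_config()
  # somatic second hit fires PS3 with provenance, phenotype fires PP4
  cs <- assign_criteria("nonsense", 267,
                        evidence_profile(somatic_second_hit = TRUE,
                                         phenotype_specific = TRUE), cfg)
  expect_setequal(names(cs), c("PVS1", "PS3", "PM2", "PP4"))
  expect_false(cs$PVS1$modified)
  expect_equal(attr(cs, "ps3_provenance"), "second_hit")

  # termination beyond the NMD-escape boundary downgrades PVS1
  cs2 <- assign_criteria("nonsense", 730,
                         evidence_profile(phenotype_specific = TRUE), cfg)
  expect_setequal(names(cs2), c("PVS1", "PM2", "PP4"))
  expect_true(cs2$PVS1$modified)
  expect_equal(format(cs2$PVS1), "PVS1_S")

  # frequent variant: polymorphism pathway, no PM2
  cs3 <- assign_criteria("missense", ev = evidence_profile(maf = 0.03), cfg = cfg)
  expect_false("PM2" %in% names(cs3))
  expect_true("BS1" %in% names(cs3))
  expect_true(attr(cs3, "polymorphism"))

  # functional evidence of no damage: BS3, never PS3
  cs4 <- assign_criteria("missense",
                         ev = evidence_profile(functional_damaging = "no"),
                         cfg = cfg)
  expect_true("BS3" %in% names(cs4))
  expect_false("PS3" %in% names(cs4))

  expect_error(assign_criteria("frameshift", NULL, evidence_profile(), cfg),
               "termination-codon")
})

test_that("mutually exclusive evidence pairs never co-fire", {
  set.seed(11)
  cfg <- engine_config()
  for (rep in 1:100) {
    ev <- evidence_profile(
      maf = sample(c(NA, 0, 1e-6, 5e-4, 0.005, 0.03, 0.2), 1),
      insilico = sample(c("absent", "deleterious", "benign",
                          "conflicting"), 1),
      segregation = sample(c(TRUE, FALSE), 1),
      phenotype_specific = sample(c(TRUE, FALSE), 1),
      somatic_second_hit = sample(c(TRUE, FALSE), 1),
      functional_damaging = sample(c("untested", "yes", "no"), 1),
      reputable_source = sample(c("none", "pathogenic_report",
                                  "benign_report"), 1))
    cs <- assign_criteria(sample(c("missense", "inframe_indel"), 1),
                          ev = ev, cfg = cfg)
    nm <- names(cs)
    expect_false(all(c("PS3", "BS3") %in% nm))
    expect_false(all(c("PP3", "BP4") %in% nm))
    expect_false(all(c("PP5", "BP6") %in% nm))
    expect_false(all(c("BA1", "BS1") %in% nm))
  }
})

test_that("criteria with no assignment rule are representable but never emitted", {
  expect_equal(format(acmg_criterion("PS2")), "PS2")
  set.seed(5)
  never <- c("PS2", "PS4", "PM3", "PM6", "PP2", "BS4", "BP2", "BP5",
             "BP7")
  for (rep in 1:50) {
    ev <- evidence_profile(
      maf = sample(c(NA, 1e-6, 0.005, 0.2), 1),
      insilico = sample(c("absent", "deleterious", "benign"), 1),
      segregation = TRUE, phenotype_specific = TRUE,
      somatic_second_hit = TRUE, healthy_adult_carrier = TRUE,
      same_aa_known_pathogenic = TRUE, in_hotspot_domain = TRUE,
      other_missense_at_residue_pathogenic = TRUE)
    cs <- assign_criteria("missense", ev = ev)
    expect_length(intersect(names(cs), never), 0)
  }
})

test_that("concordance compares printed and computed classes deterministically", {
  empty <- concordance(armc5_germline()[0, ], engine_config())
  expect_equal(empty$n_match, 0L)
  expect_equal(nrow(empty$mismatches), 0L)

  g <- armc5_germline()
  r1 <- concordance(g, engine_config(conflict_policy = "as_curated"))
  r2 <- concordance(g, engine_config(conflict_policy = "as_curated"))
  expect_identical(r1, r2)
})
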