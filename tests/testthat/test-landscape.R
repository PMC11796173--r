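germ <- armc5_germline()
soma <- armc5_somatic()

test_that("germline summary reproduces the curated spectrum", {
  s <- summarize_germline(germ)
  expect_equal(s$n_variants, 146L)
  expect_equal(s$counts_by_consequence$missense, 67L)
  expect_equal(s$counts_by_consequence$frameshift, 42L)
  expect_equal(s$counts_by_consequence$nonsense, 24L)
  expect_equal(s$counts_by_consequence$splice, 4L)
  expect_equal(s$counts_by_consequence$inframe_indel, 6L)
  expect_equal(s$counts_by_consequence$large_deletion, 3L)
  expect_equal(s$pct_by_consequence$missense, 46)
  expect_equal(s$pct_truncating, 45)
  expect_equal(s$n_snv, 95L)
  expect_equal(s$n_indel, 48L)
  expect_equal(s$n_structural, 3L)
  expect_equal(s$n_novel, 36L)

  e <- summarize_germline(germ[0, ])
  expect_equal(e$n_variants, 0L)
  expect_equal(sum(unlist(e$counts_by_consequence)), 0L)
})

test_that("summaries are invariant under row permutation", {
  set.seed(99)
  shuffled <- germ[sample(nrow(germ)), ]
  a <- summarize_germline(germ)
  b <- summarize_germline(shuffled)
  expect_equal(a$counts_by_consequence, b$counts_by_consequence)
  expect_equal(a$n_snv, b$n_snv)
  expect_equal(a$recurrent_protein_variants$key,
               b$recurrent_protein_variants$key)
  expect_equal(sort(germline_somatic_overlap(germ, soma)),
               sort(germline_somatic_overlap(shuffled, soma)))
})

test_that("recurrence table totals index cases per protein key", {
  rec <- recurrence_table(germ[!germ$polymorphism, ])
  expect_equal(rec$key[1], "Pro731Arg")
  expect_equal(rec$total_index_cases[1], 10L)
  expect_equal(sum(rec$total_index_cases >= 2L), 34L)
  dual <- rec[rec$n_distinct_cdna >= 2L, ]
  expect_setequal(dual$key, c("Ile58Asnfs*45", "Trp386*"))
  expect_equal(dual$total_index_cases[dual$key == "Ile58Asnfs*45"], 4L)

  # additivity on a synthetic pair with the same protein key
  two <- germ[germ$protein_key %in% "Ile58Asnfs*45", ]
  two$n_index_cases <- c(1L, 2L)
  r2 <- recurrence_table(two)
  expect_equal(nrow(r2), 1L)
  expect_equal(r2$total_index_cases, 3L)

  # recurrence floor: total index cases >= distinct cDNA encodings
  expect_true(all(rec$total_index_cases >= rec$n_distinct_cdna))
})

test_that("recurrence and overlap agree with quadratic brute force on subsamples", {
  set.seed(123)
  for (rep in 1:5) {
    idx <- sample(nrow(germ), 30)
    sub <- germ[idx, ]
    got <- recurrence_table(sub)
    ref <- brute_recurrence(sub)
    rownames(ref) <- NULL
    expect_equal(got, ref)
    sdx <- sample(nrow(soma), 30)
    expect_equal(as.character(germline_somatic_overlap(sub, soma[sdx, ])),
                 brute_overlap(sub, soma[sdx, ]))
  }
})

test_that("multi-hit residues reproduce the curated multiplicity sets", {
  rec <- germ[!germ$polymorphism, ]
  mis <- multi_hit_residues(rec, kinds = "missense")
  expect_setequal(mis$residue, c(315L, 323L, 362L, 593L, 662L))

  all_kinds <- multi_hit_residues(rec)
  mixed <- all_kinds[grepl("missense", all_kinds$kinds) &
                       grepl("nonsense", all_kinds$kinds), ]
  expect_true(all(c(619L, 764L) %in% mixed$residue))
  expect_true(all(c(57L, 132L, 143L, 208L) %in% all_kinds$residue))

  single <- multi_hit_residues(germ[1, ])
  expect_equal(nrow(single), 0L)
})

test_that("germline/somatic overlap matches shared cDNA-level variants", {
  ov <- germline_somatic_overlap(germ, soma)
  expect_length(ov, 12L)
  expect_true("Arg315Trp" %in% ov)
  expect_true("Pro109Serfs*28" %in% ov)  # via fs28*/fs*28 normalization
  expect_false("Ala106Argfs*31" %in% ov)  # protein coincidence only

  expect_length(germline_somatic_overlap(germ[0, ], soma), 0L)
})

test_that("somatic spectrum counts distinct events", {
  s <- summarize_somatic(soma)
  expect_equal(s$n_events, 104L)
  expect_equal(s$n_rows, 106L)
  expect_equal(s$counts_by_category$frameshift, 49L)
  expect_equal(s$counts_by_category$missense, 27L)
  expect_equal(s$counts_by_category$cnLOH, 1L)
  expect_equal(s$counts_by_category$large_deletion, 1L)

  z <- summarize_somatic(soma[0, ])
  expect_equal(z$n_events, 0L)
  expect_equal(sum(unlist(z$counts_by_category)), 0L)
})

test_that("conservation identity holds and is re-checked from set cardinalities", {
  gs <- summarize_germline(germ)
  ss <- summarize_somatic(soma)
  ov <- germline_somatic_overlap(germ, soma)
  expect_equal(gs$n_variants + ss$n_events - length(ov), 238L)
  # independent quadratic recomputation of the shared-variant set
  expect_equal(as.character(ov), brute_overlap(germ, soma))
})

test_that("lollipop model carries residues, recurrence, color groups and domains", {
  lp <- lollipop_export(germ[!germ$polymorphism, ])
  l <- lp$lollipops
  expect_equal(l$recurrence[l$key == "Pro731Arg"], 10L)
  expect_equal(l$domain[l$key == "His808Pro"], "BTB/POZ")
  # class 4/5 colored by category, class 2/3 grey
  expect_equal(l$color_group[l$key == "His808Pro"], "missense")
  expect_equal(l$color_group[l$key == "Pro731Arg"], "grey")
  # structural and protein-less records excluded
  expect_false(any(is.na(l$residue)))

  empty <- lollipop_export(germ[0, ])
  expect_equal(nrow(empty$lollipops), 0L)
})

test_that("consistency report verifies identities and flags transcription anomalies", {
  rep <- consistency_report(germ, soma)
  status <- setNames(rep$status, rep$check)
  expect_equal(status[["total_distinct_alterations"]], "ok")
  expect_equal(status[["germline_edit_partition"]], "ok")
  expect_equal(status[["germline_consequence_partition"]], "ok")
  # known source-table quirks must be flagged, not silently absorbed
  expect_equal(status[["somatic_snv_subcounts"]], "flag")
  expect_equal(status[["protein_key_coincidences"]], "flag")
  expect_match(rep$detail[rep$check == "protein_key_coincidences"],
               "Ala106Argfs\\*31")
  expect_equal(status[["protein_cdna_position_consistency"]], "flag")
  expect_match(rep$detail[rep$check == "protein_cdna_position_consistency"],
               "c\\.1851del")
})

test_that("domain maps validate their bounds", {
  expect_error(domain_map(domains = data.frame(
    name = "X", start = 10L, end = 2000L)), "end")
  expect_error(domain_map(domains = data.frame(
    name = c("A", "B"), start = c(1L, 50L), end = c(100L, 120L))),
    "overlap")
})
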