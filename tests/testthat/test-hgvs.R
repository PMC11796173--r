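test_that("cDNA substitutions, spans and intron offsets parse correctly", {
  x <- parse_cdna("c.799C>T")
  expect_equal(x$edit_kind, "substitution")
  expect_equal(x$start, 799L)
  expect_equal(x$ref_bases, "C")
  expect_equal(x$alt_bases, "T")
  expect_true(is_snv(x))

  d <- parse_cdna("c.286_310dup")
  expect_equal(d$edit_kind, "duplication")
  expect_equal(c(d$start, d$end), c(286L, 310L))
  expect_equal(d$end - d$start + 1L, 25L)
  expect_false(is_snv(d))

  sp <- parse_cdna("c.475 + 1G>A")  # typesetting whitespace tolerated
  expect_equal(sp$edit_kind, "substitution")
  expect_equal(sp$start, 475L)
  expect_equal(sp$start_offset, 1L)

  acc <- parse_cdna("c.476-2A>G")
  expect_equal(acc$start_offset, -2L)

  span <- parse_cdna("c.456_475+5del")  # span ending inside the intron
  expect_equal(span$edit_kind, "deletion")
  expect_equal(span$end_offset, 5L)
})

test_that("cDNA normalization resolves aliases and trailing bases", {
  a <- parse_cdna("c.170del (= c.165del)")
  expect_equal(format(a), "c.170del")
  expect_equal(a$alias_of, "c.165del")

  dup <- parse_cdna("c.2697dupG")
  expect_equal(format(dup), "c.2697dup")
  expect_equal(dup$ref_bases, "G")

  expect_equal(normalize_cdna("c.407 T>C"), "c.407T>C")
  expect_equal(normalize_cdna("c.220_222delinsTT"), "c.220_222delinsTT")
  expect_equal(normalize_cdna("c.237_238insC"), "c.237_238insC")
})

test_that("malformed and unsupported cDNA raise informative errors", {
  expect_error(parse_cdna("c.99xyz"), "xyz")
  expect_error(parse_cdna("c.100_200inv"), "unsupported")
  expect_error(parse_cdna("c.100delinsext"), "unsupported")
  expect_error(parse_cdna("g.100A>T"), "c\\.")
  expect_error(parse_cdna("c.200_100del"), "precedes")
  expect_error(parse_cdna("c.100ins"), "requires inserted bases")
})

test_that("protein descriptions parse into kinds, residues and offsets", {
  fs <- parse_protein("p.(Gly57Glufs*80)")
  expect_equal(fs$kind, "frameshift")
  expect_equal(fs$start_res, 57L)
  expect_equal(fs$fs_stop_offset, 80L)

  del <- parse_protein("p.(Phe700del)")
  expect_equal(del$kind, "inframe_del")
  expect_equal(del$start_res, 700L)

  mis <- parse_protein("p.(Arg898Trp)")
  expect_equal(mis$kind, "missense")
  expect_equal(mis$ref_aa, "Arg")
  expect_equal(mis$alt_aa, "Trp")

  syn <- parse_protein("p.(Ala23Ala)")
  expect_equal(syn$kind, "synonymous")

  non <- parse_protein("p.(Arg267*)")
  expect_equal(non$kind, "nonsense")
  expect_false(grepl("fs", non$raw_text))

  expect_error(parse_protein("p.(Bad123Stuff)"), "malformed")
})

test_that("misplaced frameshift asterisks and parenthesis variants normalize", {
  a <- parse_protein("p.(Glu59Argfs44*)")
  expect_equal(a$kind, "frameshift")
  expect_equal(a$fs_stop_offset, 44L)
  expect_equal(protein_key(a), "Glu59Argfs*44")

  b <- parse_protein("(p.Ala110Asp)")
  expect_equal(b$kind, "missense")
  expect_equal(protein_key(b), "Ala110Asp")

  dl <- parse_protein("p.(Glu623_Leu625delinsValThrSerPhePro)")
  expect_equal(dl$kind, "inframe_delins")
  expect_equal(dl$start_res, 623L)
  expect_equal(dl$end_res, 625L)
})

test_that("consequence inference follows intron offsets, protein kinds and printed impact", {
  # canonical acceptor offset: splice regardless of protein annotation
  expect_equal(as.character(
    infer_consequence(parse_cdna("c.476-2A>G"), parse_protein(NA))),
    "splice")
  expect_equal(as.character(
    infer_consequence(parse_cdna("c.52C>T"), parse_protein("p.(Gln18*)"))),
    "nonsense")
  expect_equal(as.character(
    infer_consequence(structural = TRUE, printed = "Large deletion")),
    "large_deletion")
  # non-canonical -3 offset: only the printed impact makes it splice
  cons <- infer_consequence(parse_cdna("c.1371-3C>A"), parse_protein(NA),
                            printed = "Splice")
  expect_equal(as.character(cons), "splice")
  expect_true(attr(cons, "conflict"))
  # in-frame kinds collapse
  expect_equal(as.character(
    infer_consequence(parse_cdna("c.68_70del"),
                      parse_protein("p.(Ala23del)"))),
    "inframe_indel")
})

test_that("parse/format round-trips are the identity on every fixture string", {
  g <- armc5_germline()
  s <- armc5_somatic()
  cdna <- c(g$cdna[!g$structural], s$cdna[s$event_type == "point"])
  for (x in cdna) {
    norm <- format(parse_cdna(x))
    expect_identical(format(parse_cdna(norm)), norm, label = x)
  }
  prot <- c(g$protein, s$protein)
  prot <- prot[!is.na(prot)]
  for (x in prot) {
    norm <- format(parse_protein(x))
    expect_identical(format(parse_protein(norm)), norm, label = x)
  }
})

test_that("termination codons place nonsense at the residue and frameshifts downstream", {
  expect_equal(termination_codon(parse_protein("p.(Arg267*)")), 267L)
  expect_equal(termination_codon(parse_protein("p.(Gly57Glufs*80)")), 136L)
  expect_equal(termination_codon(parse_protein("p.(Leu683Argfs*2)")), 684L)
  expect_true(is.na(termination_codon(parse_protein("p.(Arg898Trp)"))))
})
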