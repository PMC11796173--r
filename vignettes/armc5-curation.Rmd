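---
title: "Curating the ARMC5 mutational landscape: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Curating the ARMC5 mutational landscape: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(armc5curator)
```

## The problem

ARMC5 is a tumor-suppressor gene at 16p11.2. Germline heterozygous
inactivating variants cause 20–25% of Primary Bilateral Macronodular
Adrenal Hyperplasia (PBMAH); adrenal nodules acquire a somatic second
hit — a point variant or copy-neutral loss of heterozygosity (cnLOH) —
so that both alleles are lost, the classic Knudson two-hit pattern.
Truncating variants are rarely controversial, but roughly half of all
reported ARMC5 variants are missense substitutions whose pathogenicity
must be argued from population frequency, in-silico prediction, familial
segregation, tumor DNA, and functional assays. This package implements
that curation pipeline as tested, reusable code: HGVS parsing,
ACMG-AMP evidence assignment and combination into the five classes
(1 benign, 2 likely benign, 3 VUS, 4 likely pathogenic, 5 pathogenic),
and landscape aggregation.

## HGVS model

Coordinates are 1-based and inclusive on the cDNA of transcript
NM_001105247.1 and its 935-residue protein; genomic (g.) coordinates are
not modeled because curated gene-level tables do not carry them, and no
reference sequence is consulted (`ref_bases` are taken on faith — see
Limitations). The lexer normalizes the typesetting artifacts that real
published tables contain:

* whitespace inside descriptions (`c.407 T>C`, `c.475 + 1G>A`);
* trailing explicit bases on del/dup (`c.2697dupG` keys as `c.2697dup`,
  which also lets a germline `c.170dup` match a somatic `c.170dupG`);
* misplaced frameshift asterisks (`fs44*` read as `fs*44`);
* a parenthesized alias form (`c.170del (= c.165del)`), resolved to the
  primary description with `alias_of` retained.

Unsupported HGVS constructs (inversions, extensions, repeats) raise an
error instead of misparsing. Parsing then formatting is the identity on
every fixture string (a tested invariant), so normalized keys are stable
grouping handles.

**Consequence inference.** A cDNA position with intron offset of
magnitude ≤ 2 is a canonical splice variant regardless of protein
annotation; structural events are `large_deletion`; otherwise the
protein-level kind decides, with in-frame del/dup/delins collapsed to
`inframe_indel`. When a table's printed impact contradicts the
inference, the printed impact is retained (curated tables are ground
truth) and the row is flagged in a warning log. One fixture row
exercises this deliberately: a variant at intron offset −3 printed as
splice, which offset-based inference alone would not call.

## Evidence model and thresholds

`engine_config()` centralizes every tunable (all dimensionless
frequencies except the codon boundary):

| parameter | default | role |
|---|---|---|
| `pm2_max_maf` | 1e-5 | PM2 "absent from controls (or extremely rare)" |
| `bs1_threshold` | 0.001 | BS1 "frequency greater than expected" |
| `polymorphism_maf` | 0.02 | frequent-polymorphism override (benign) |
| `ba1_threshold` | 0.05 | BA1 stand-alone benign |
| `nmd_escape_codon` | 668 | first termination codon escaping NMD |

The MAF tiers mirror how frequency evidence is applied in ARMC5
curation practice: variants with MAF above 0.001 carry BS1, variants
with MAF above 0.02 are treated as frequent benign polymorphisms, and
PM2 is reserved for variants absent from (or extremely rare in)
population databases. `maf = NA` (absent) is distinct from `maf = 0`.

**PS3 from second hits.** Canonically PS3 is functional-assay evidence.
For a tumor suppressor with a proven two-hit model, the detection of a
somatic second hit in tumor DNA is treated as equally strong evidence of
a damaging effect, so `assign_criteria()` fires PS3 for
`somatic_second_hit = TRUE` as well, recording the provenance
(`"functional"` vs `"second_hit"`) on the criteria set. A functional
assay that shows *no* damage outranks the second-hit inference: it fires
BS3 and suppresses PS3, preserving the invariant that PS3/BS3 (likewise
PP3/BP4 and PP5/BP6) never co-fire.

**PVS1 strength and NMD escape.** Truncating variants whose premature
termination codon lies near the 3' end escape nonsense-mediated decay
and may yield a partially functional protein, so PVS1 is downgraded to
strong (`PVS1_S`). The boundary is not printed in curated ARMC5 tables;
it is inferred from them — full PVS1 up to termination codon 654
(p.(Arg654\*)) and `PVS1_S` from 684 (p.(Leu683Argfs\*2)) onward — and
defaulted to the midpoint-consistent 668. It is documented as
fixture-derived, not transcript-derived, and is configurable. For a
frameshift `p.(X n Y fs*N)` the termination codon is `n + N − 1`; for
splice variants and structural deletions no residue position exists and
full PVS1 is applied.

## Combining policies

The five-class combination follows the published rule list over
*effective* strengths (a modified PVS1 counts as one strong criterion
and no longer satisfies the PVS1-specific rules). Two policies:

* **strict** — the guideline as published: if both a benign-side and a
  pathogenic-side rule fire, or none fires, the variant is VUS. The
  strict combiner is verified against an independently written
  brute-force rule evaluator over the full enumeration of criteria
  multisets (PVS1 × ≤2 strong × ≤3 moderate × ≤4 supporting × BA1 ×
  ≤2 BS × ≤2 BP, 2160 cases), and property tests check monotonicity
  (adding pathogenic evidence never lowers the class when the benign
  side is empty) and permutation invariance (only the multiset of
  effective strengths matters).
* **as_curated** — the fixed precedence order reverse-engineered from
  expert-curated ARMC5 tables, needed to reproduce their printed
  classes: polymorphism override > benign rules > pathogenic rules >
  VUS, with two relaxations on the benign side: benign rules are
  evaluated first and win over any pathogenic evidence (e.g. BS2 + BP6 +
  PS3 is likely benign), and a single strong-benign criterion with no
  supporting-benign code suffices for likely benign (e.g. BS3 alone).

Three fixture rows resist *any* single consistent rule set and are
pre-registered as expected mismatches rather than special-cased: an
in-frame duplication whose printed criteria satisfy a likely-pathogenic
combination yet print VUS, and two rows printing likely benign on a
single supporting-benign code (BP6 alone; BP4 + PP4). The concordance
test asserts that as-curated mismatches are exactly these rows and that
strict-mode mismatches are a superset confined to benign-side and
in-frame entries. Whether a downgraded PVS1 should further interact
with PM2 (per later refinements of the guideline) is not decidable from
the source material and is deliberately not implemented.

## Landscape conventions

* **Percentages** round half away from zero to integers (67/146 → 46%,
  66/146 truncating → 45%), matching how such proportions are printed.
* **SNV/indel split**: only substitutions are SNVs; single-base dup/del
  count as indels.
* **Recurrence** groups by normalized protein key; dual-encoded protein
  changes (two distinct cDNA events, one protein change) appear once
  with `n_distinct_cdna = 2`. Index-case counts for the 34 recurrent
  protein variants come from the curated narrative; where a protein
  change has two cDNA encodings the per-cDNA split is editorial (noted
  in the fixture) and only the protein-level total is asserted.
* **Somatic distinct events** are keyed on the protein-level change
  (structural events and cnLOH on their description). This collapses
  repeated rows that describe the same event on different germline
  backgrounds — the two cnLOH rows, and one nonsense change reached by
  two different cDNA deletions — and is the convention under which the
  fixture reproduces its published total of 104.
* **Germline∩somatic overlap** matches on normalized *cDNA-level*
  variant identity and reports protein keys. A protein-level
  coincidence arising from two different cDNA changes is deliberately
  not counted — the fixtures contain exactly one such pair — and is
  surfaced by `consistency_report()` instead. cnLOH and structural
  events never match point variants.
* **`consistency_report()`** re-checks the arithmetic identities
  (146 + 104 − 12 = 238; SNV + indel + structural and the consequence
  partition summing to the germline total) and flags transcription
  anomalies it finds: somatic sub-counts that do not add up, and protein
  positions far from their cDNA-implied codon. The codon check allows
  15 residues of slack because frameshift descriptions legitimately
  shift a few residues 3' of the edit; the one fixture row it flags is
  off by 99 residues, an inconsistency carried over verbatim from the
  source table (the fixture transcribes it as printed; "correcting" it
  would falsify the record).
* **Domain bounds** (armadillo-repeat region 71–400, BTB/POZ 701–870 on
  the 935-residue protein) are configurable approximations — published
  tables print no coordinates — and affect only annotation and the
  lollipop model, never the acceptance counts.

### The reconstructed fixture row

The germline fixture carries one editorially reconstructed row
(`c.1000_1002del` / `p.(Ser334del)`, novel, VUS), flagged
`reconstructed (synthetic)` in its `note` column. The source table's
marginal totals (146 variants = 110 published + 36 novel; 6 in-frame;
48 indels) are mutually consistent and all exceed the recoverable rows
by exactly one novel in-frame indel, so one such row was restored with
a neutral position and the criteria profile typical of its class. All
recurrence, multiplicity, overlap and concordance statistics are
unaffected by this row apart from the totals it restores.

## The synthetic-cohort generator

`cohort_spec()` defaults encode the study conditions of the curated
landscape: 146 variants; consequence mix 46% missense, 45% truncating
split 42:24 frameshift:nonsense, 3% splice, 4% in-frame, 2% large
deletions; recurrence from a truncated geometric (p = 0.55, max 10) —
the simplest heavy-tailed count law consistent with "mostly private,
top recurrence 10"; latent class mix 64:36:29:17
pathogenic:likely-pathogenic:VUS:likely-benign (the curated table's
distribution); 28% of pathogenic/likely-pathogenic variants with a
somatic second hit (the fixture's observed rate), 12% of hits cnLOH.
Criteria profiles are sampled conditionally on the latent class from
templates that the strict combiner provably maps back to that class
(validated at generation time), so latent-class recovery is exact by
construction and any miss is a combiner or generator bug. Frameshift
stop offsets are drawn uniformly from 1–110 (the observed range), and
missense draws never produce stop codons.

What the generator does **not** emulate: the three irreducible curation
quirks (synthetic truth is rule-consistent so recovery can be exact),
mutational hotspots or domain clustering (positions are uniform),
dual-encoded protein changes, and any clinical phenotype structure.
Passing synthetic tests therefore demonstrates pipeline correctness
and closure (generate → write TSV → load → summarize with zero
validation errors), not biological realism of the simulated cohort.

Problem sizes used in the shipped tests: the full enumeration of 2160
criteria multisets for the combiner oracle; 200-replicate randomized
property checks; synthetic cohorts of 40–500 records for recovery,
closure and planted-overlap checks; and a single 10,000-record cohort
for distributional sanity (each category within 0.02 of its target at a
fixed seed).

## Degenerate inputs and numerical choices

Empty tables (header only) load as empty record sets and every summary
returns zeros; `combine_criteria()` is total (the empty set is VUS);
`recover_classes()` on an empty cohort is a vacuous pass. Probability
vectors must sum to 1 within 1e-8. Seeds are mandatory for the
generator, which also restores the caller's RNG state. Tie-breaks:
as-curated precedence is the fixed order given above; recurrence tables
sort by descending index cases then key, making all outputs
deterministic and permutation-invariant.

## Limitations

* No reference-sequence validation: impossible ref residues/bases are
  accepted as printed (by design — the tables are the record), with the
  codon-consistency check as the only guard.
* No genomic liftover, no transcript database, no VCF import/export
  (gene-level tables carry no genomic coordinates).
* The as-curated policy is descriptive of one curation practice, not a
  normative reinterpretation of the guideline; strict mode is always
  available.
* No Bayesian point-based rescaling of the combining rules, and no
  gene-specific VCEP rule packs.
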