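Package: armc5curator
Title: Curation and Mutational-Landscape Analysis of ARMC5 Variants
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for curating germline and somatic variants of the
    tumor-suppressor gene ARMC5, the main genetic cause of Primary Bilateral
    Macronodular Adrenal Hyperplasia (PBMAH). Provides a tolerant HGVS
    parser for cDNA and protein descriptions, consequence inference, an
    ACMG-AMP evidence engine with gene-specific rules (somatic second-hit
    evidence, last-exon PVS1 strength downgrade, allele-frequency tiers),
    five-class criteria combination under strict and as-curated policies,
    mutational-landscape summaries (consequence spectra, protein-level
    recurrence, residue multiplicity, germline/somatic overlap, lollipop
    export), table I/O with validation, and a seeded synthetic-cohort
    generator with Knudson-style second hits for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
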