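Package: venomics
Title: Venom Gland Transcriptome and Proteome Integration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for integrating venom gland transcriptome annotation with
    whole-venom intact-mass proteomics. Provides venom-transcript triage from
    annotation evidence, family classification and systematic nomenclature for
    scorpion venom components, theoretical mass calculation for predicted
    mature peptides (monoisotopic and average, with amidation and disulfide
    corrections), LC-MS intact-mass fingerprint curation that removes adduct
    and modification satellites, transcriptome-to-proteome mass matching,
    in-silico tryptic digestion with sequence-coverage reporting, and
    HeliQuest-style physicochemical descriptors for host-defense peptides.
    Deterministic synthetic-data generators make the full pipeline testable
    without any external download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
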