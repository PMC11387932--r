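Package: amdirtools
Title: Curation Toolkit for AncientMetagenomeDir Metadata Tables
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements the AncientMetagenomeDir library-level metadata
    dialect for ancient metagenomics: tab-separated sample and library
    tables validated against JSON schema documents with controlled
    ('enum') vocabularies, structured per-cell error reporting with fix
    suggestions, autofilling of draft library tables from European
    Nucleotide Archive (ENA) read_run reports, headless sample/library
    filtering and joining, and deterministic conversion of selections
    into FASTQ download scripts with md5 manifests, nf-core/eager input
    sheets, and BibTeX citation files. Ships a seeded generator of
    schema-valid synthetic datasets and systematically corrupted
    variants that mirror metadata errors commonly observed in public
    sequencing archives, used as the oracle for the validator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
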