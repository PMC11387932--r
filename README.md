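# amdirtools

Curation toolkit for **AncientMetagenomeDir**-style metadata tables in
ancient metagenomics.

## The problem

Reusing published ancient metagenomic sequencing data takes more than a
sample list. To reprocess a library correctly a researcher needs
library-level metadata — how the library was built (double- vs
single-stranded), whether deaminated bases were enzymatically removed
(no/half/full UDG treatment, which decides whether damage must be trimmed
in silico), the sequencing platform (2- vs 4-colour chemistry decides
whether poly-G trimming is needed), the layout (SE/PE), and where the
FASTQ files actually live. This information is scattered across archive
records and prose methods sections, and the archive copies are frequently
wrong or inconsistent.

The community answer is a directory of curated, versioned TSV tables —
one samples table and one libraries table per dataset category
(host-associated metagenomes, host-associated single genomes,
environmental metagenomes) — validated against JSON schemas with
controlled vocabularies. `amdirtools` implements that dialect and the
curation workflow around it, for curators (validation, archive autofill,
merging) and for data re-users (filtering, download scripts, pipeline
input sheets, citations).

## What it does

* **Schema model** — strict, byte-stable TSV dialect (UTF-8, LF, tabs, no
  quoting); JSON schema documents and JSON enum vocabularies shipped as
  data under `inst/extdata/schemas/`; release-table retrieval by tag.
* **Validation** — per-cell checks (types, enum membership, URL/md5/byte
  lists), duplicate keys, DOI syntax (`^10\.\d{4,9}/\S+$`, offline by
  default), INSDC accession syntax (`PRJ[EDN][A-Z]\d+`, `SAM(EA|N|D)\w?\d+`,
  `[EDS]RR\d{6,}`), run-accession uniqueness, library→sample linkage and
  project consistency. Errors come back as an ordered table of
  `(error_type, table, line, column, message, suggestion)` with the header
  counted as line 1.
* **ENA autofill** — queries the ENA portal API `filereport` endpoint
  (`result=read_run`) for project/sample accessions and maps the response
  into a draft libraries table; ancient-DNA-specific columns the archive
  cannot know are left `"unknown"` and reported for manual curation. A
  recorded transport replays responses from disk, so everything is
  testable offline.
* **Query** — headless filtering with per-column AND/OR clause chains
  (columns combined with AND), a compact expression syntax
  (`publication_year>=2020 & geo_loc_name=Spain`), the sample→library
  join, and download-footprint summaries.
* **Convert** — deterministic generation of `curl`/`wget` download scripts
  with an md5 verification manifest, nf-core/eager (2.x) input sheets,
  BibTeX citation files, and filtered-table exports under their canonical
  file names; validated merging of new submissions into existing tables.
* **Fixtures** — a seeded generator of schema-valid synthetic datasets
  (with matching recorded archive responses) and a corruption engine that
  plants exactly-located errors mirroring real-world upload mistakes; its
  manifest is the oracle the validator is tested against.
* **CLI** — `inst/cli/amdirtools` with `download`, `validate`, `convert`,
  `autofill`, `merge`, `filter`; exit codes 0 (ok), 1 (validation errors),
  2 (usage), 3 (transport), suitable for CI.

## Worked example

```r
library(amdirtools)

# a synthetic release directory: samples + libraries + archive responses
b <- generate_dataset(n_samples = 30, libs_per_sample = c(1, 3), seed = 42)
#> <amdir_bundle> ancientmetagenome-hostassociated: 30 samples, 62 libraries,
#>                10 project run reports (seed 42)

validate_dataset(b$samples, b$libraries)
#> <amdir_report> PASSED (0 errors)

# select host-associated samples from Spain published since 2020 ...
sel  <- filter_table(b$samples, "publication_year>=2020 & geo_loc_name=Spain")
libs <- join_libraries(sel, b$libraries)
summarize_selection(libs)
#> <selection> 4 library rows, 4 runs, 2.05 GB to download

# ... and emit the artefacts to run them
export_tables(sel, libs, "out")   # writes, deterministically:
#   AncientMetagenomeDir_curl_download_script.sh
#   AncientMetagenomeDir_nf_core_eager_input_table.tsv
#   AncientMetagenomeDir_bibliography.bib
#   AncientMetagenomeDir_filtered_libraries.tsv

# the validator pinpoints seeded corruptions exactly
cd <- corrupt_dataset(b, error_kinds = c("invalid_doi", "orphan_library"),
                      k_per_kind = 1, seed = 9)
validate_dataset(cd$bundle$samples, cd$bundle$libraries)
#> <amdir_report> FAILED (2 errors)
#>       error_type table_name line                   column
#> 1 orphan_library  libraries   23 archive_sample_accession
#> 2    invalid_doi    samples   28          publication_doi
```

The selection summary is what a user checks before launching the download
script; the failed report reads as: the library on line 23 points at a
sample accession that matches no sample row (a library uploaded with its
own sample accession), and the samples table carries a malformed DOI on
line 28.

The same flow from a shell:

```sh
amdirtools validate samples.tsv libraries.tsv \
    inst/extdata/schemas/ancientmetagenome-hostassociated
amdirtools convert --curl --eager --bibliography --librarymetadata \
    --libraries libraries.tsv filtered_samples.tsv ancientmetagenome-hostassociated -o out/
```

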