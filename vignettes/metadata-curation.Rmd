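---
title: "Validating and converting ancient metagenome metadata"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating and converting ancient metagenome metadata}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(amdirtools)
```

## The data model

`amdirtools` works on community-curated directories of ancient metagenomic
metadata: per dataset category (host-associated metagenomes, host-associated
microbial single genomes, environmental metagenomes) a *samples* table and a
*libraries* table, both plain TSV. The library level is what makes the data
reusable: the construction method (double- vs single-stranded), the indexing
polymerase, and the UDG pretreatment (none/half/full) jointly determine how
much cytosine-deamination damage survives in the reads, and therefore whether
a pipeline should trim read ends; the instrument model determines the base
calling chemistry (2-colour platforms emit poly-G artefacts on short ancient
inserts); the layout (SE/PE) determines merging; URLs, md5 checksums and byte
sizes make the files retrievable and verifiable.

The TSV dialect is deliberately rigid — UTF-8, LF endings, tab separators,
no quoting or escaping, mandatory header, trailing newline — so any two
serialisations of the same table are byte-identical and diffs in a reviewed
repository stay minimal. Tabs and newlines inside cells are unrepresentable
and rejected at serialisation time rather than escaped. The package asserts
`write(read(x)) == x` at byte level on every generated fixture.

Schemas are data, not code: JSON documents (one per category and table type)
declare ordered columns with a `value_kind` (`free_text`, `integer`,
`number`, `doi`, `accession_list`, `url_list`, `md5_list`, `byte_size_list`,
`enum`), and controlled vocabularies live in separate JSON enum files. New
columns or tokens therefore never require code changes. The canonical
missing-data token is the string `"unknown"`; numeric columns accept it only
where the column explicitly allows it, which keeps accidental blanks visible.

## The validation model

`validate_dataset()` runs, in a fixed order: per-cell schema validation on
both tables, duplicate-key detection on both, DOI checks on the samples
table, and cross-table accession checks. Reports are ordered by
(table, line, column position) and are byte-stable across repeated runs.
Line numbers are 1-based counting the header as line 1 — the number a user
sees in a text editor.

Design choices worth spelling out:

* **One error per cell.** A single malformed cell fails the first check in
  the order required → missing-token → type/enum, and nothing else, so one
  mistake never cascades into a wall of messages.
* **Ownership of checks.** DOI syntax belongs to `check_doi()` and INSDC
  accession syntax to `check_accessions()`; the per-cell pass checks those
  columns only for presence. Each corrupted cell thus maps to exactly one
  reported error, which is what makes the corruption manifest a usable
  oracle (see below).
* **Patterns are configuration.** Defaults: DOI `^10\.\d{4,9}/\S+$`
  (case-insensitive), project `^PRJ[EDN][A-Z]\d+$`, biosample
  `^SAM(EA|N|D)\w?\d+$`, run `^[EDS]RR\d{6,}$`. Archives evolve; the
  patterns are an argument, not a constant.
* **Linkage rule.** A library row links to its sample by archive sample
  accession (samples may carry a comma-separated accession list) and falls
  back to exact `sample_name` equality only when the accession columns are
  absent. Linked libraries must agree with their sample's project accession
  (`accession_project_mismatch`); unlinked ones are `orphan_library` — the
  signature of uploads where every library was given its own sample
  accession. Run accessions must be unique across library rows
  (`duplicate_accession`).
* **Offline by default.** DOI resolution over the network is opt-in
  (`online = TRUE`) and a network failure there is a warning, never an
  `invalid_doi`: continuous-integration runs must be deterministic and
  network-free. The same holds for the recorded ENA transport.

## The synthetic-data generator and its corruption oracle

`generate_dataset()` emits a complete, valid bundle: samples, linked
libraries, and per-project `read_run` report fixtures that mirror what the
archive would return for the same accessions. Defaults were chosen once to
look like a plausible slice of the real directory: roughly three samples per
project; one to three libraries per sample; publication years 2015–2024; a
quarter of samples located in Spain (so the documented year/geography
filtering workflow exercises a non-trivial subset); 70% paired-end layouts;
a treatment mix of 40% none / 30% half / 20% full / 10% unknown; five common
Illumina platforms. Synthetic DOIs use the reserved-looking prefix
`10.99999/…` — syntactically valid but unresolvable, so an accidental online
check cannot succeed silently. All randomness flows through one seeded
stream and never touches the caller's RNG state; identical arguments and
seed give identical bytes on disk.

`corrupt_dataset()` plants each requested error kind exactly `k` times at
distinct, never-overlapping locations and records every mutation in a
manifest. The mutations mirror error classes repeatedly seen in public
uploads: platform metadata outside the controlled vocabulary, per-library
sample accessions (orphans), duplicated run accessions, malformed DOIs and
accession tokens, duplicated submission rows. Sample-table keys were chosen
as (`project_name`, `sample_name`) precisely so that duplicating a key
cannot side-trip the accession linkage checks; every corruption maps to one
and only one expected error. The central property — *oracle closure* — is
that `validate_dataset()` on a corrupted bundle reports exactly the manifest
(100% recall, zero false positives), and the test suite asserts it across
20+ seeds.

What the generator does **not** emulate: real tables' free-text messiness
(site names, heterogeneous age encodings), multi-run libraries sharing one
library name, mixed archives within one project, and prose/archive
discrepancies that need a human (or the original authors) to resolve.
A green suite therefore demonstrates the mechanics are sound, not that real
submissions will validate on the first try.

## Filtering semantics

The interactive viewer this mirrors lets users stack conditions per column
with AND/OR menus. Since no formal grammar exists for that UI, the package
fixes one and documents it: within a column, clauses chain left-to-right
with their explicit connectives; across columns, results combine with AND;
the empty expression selects all rows. Numeric comparisons (`<`, `<=`, `>`,
`>=`) parse integers and decimals; cells equal to `"unknown"` (or otherwise
non-numeric) never satisfy a numeric predicate, so missing data is never
silently selected. `contains` (`~`) is a case-sensitive fixed substring.
The compact string syntax (`publication_year>=2020 & geo_loc_name=Spain`)
exists for the CLI and scripts; programmatic callers can build predicate
lists directly, including `in_set`, which has no string form.

## Conversion decisions

* **Download scripts** are `#!/usr/bin/env bash` + `set -euo pipefail`,
  one `curl -L -o '<basename>' '<url>'` (or `wget -O`) per FASTQ file in
  row-then-list order, followed by a here-doc md5 manifest checked with
  `md5sum -c`. The template is frozen in a golden-file test; the manifest's
  byte total must equal the selection summary's.
* **nf-core/eager sheets** use the 2.x input contract column order
  (`Sample_Name`…`BAM`). PAIRED layouts take R1/R2 from the first two URLs;
  SINGLE gets `R2 = NA`. `unknown` pretreatment maps to `none` *with a
  warning*: the conservative direction, since wrongly assuming UDG
  treatment would trim real damage signal, while the cost of `none` is a
  reviewable over-caution. Unknown strandedness/polymerase pass through for
  the user to resolve. Colour chemistry comes from an ordered, extendable
  regex lookup (NextSeq/NovaSeq → 2; HiSeq/MiSeq/Genome Analyzer → 4);
  an unmatched instrument is an error suggesting a rule extension rather
  than a silent guess. Lanes are numbered sequentially per sample in
  library order because archives do not expose lane structure. Generated
  sheets are templates for review, never guaranteed runnable.
* **Bibliographies** emit one `@misc` entry per distinct DOI, keyed by a
  sanitised DOI, sorted by key; online enrichment via DOI content
  negotiation degrades to the minimal entry with a warning.
* **Merging** is append-only with identical headers and refuses key
  clashes outright — the reviewing workflow wants a rejected pull request,
  not a silent de-duplication.

## ENA autofill

The `filereport` endpoint, `result=read_run`, and the field list are
configuration (`ena_endpoint()`), as is the field→column mapping. The
archive can fill project/sample/run accessions, library name, instrument,
layout, strategy, read counts and the FASTQ url/md5/bytes triplets; it can
never know construction method, polymerase, or pretreatment, so drafts carry
`"unknown"` there and the function returns the unfilled column list
explicitly. Multi-file fields split on the archive's `;` separator and the
three lists must stay parallel. Drafts de-duplicate on run accession in
deterministic order (input accession order, then archive row order). The
recorded transport is a directory of `<accession>.tsv` files byte-identical
to live responses; live mode retries three times with exponential backoff.

## Release retrieval

Release assets follow `<dir_name>_<table_type>_<tag>.tsv` with tags
`v<YY>.<MM>[.<patch>]`. The canonical directory name of the single-genome
category is not externally fixed, so the shipped default
(`ancientsinglegenome-hostassociated`) is configuration like the other two
and can be overridden via the schema directory layout. Remote retrieval
defaults to the archived release store and distinguishes release-not-found
from transport failures; the offline test suite exercises the local-mirror
path, and the release-census check that needs the real archive runs only
where that download is possible.

## Problem sizes and runtime

The suite runs on desk-scale fixtures chosen to finish in seconds while
still exercising every code path: oracle-closure over 20 seeds at 12
samples × ~2 libraries, filtering oracles on 200-row tables, one 300-sample
validation pass, conversion checks on 10–40 sample bundles. The acceptance
script re-derives its quantities at the same scales from a caller-supplied
seed.

## Known limitations

* Validation reports the first problem per cell; a cell that is both the
  wrong type and a disallowed missing token surfaces one message.
* DOI checking is syntactic by default; online resolution is best-effort.
* The eager converter targets the 2.x sheet contract only; other pipeline
  converters are an extension point, not implemented.
* No spreadsheet import, no schema inference, no radiocarbon-date
  standardisation; ages are opaque integers to the schema.
* The sample→library join assumes archive accessions are curated correctly;
  it will not repair linkage through file-name heuristics.
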