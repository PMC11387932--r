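test_that("download scripts fetch and verify each FASTQ file exactly once", {
  b <- test_bundle(10, 1, seed = 21)
  script <- make_download_script(b$libraries, "curl")
  flat_urls <- unlist(strsplit(b$libraries$cells[, "download_links"], ";", fixed = TRUE))
  expect_equal(sum(grepl("^curl -L -o", script$lines)), length(flat_urls))
  expect_equal(nrow(script$manifest), length(flat_urls))
  expect_identical(script$manifest$url, unname(flat_urls))
  expect_identical(script$manifest$filename, basename(unname(flat_urls)))
  # every file appears exactly once in the verification manifest
  md5_lines <- grep("^[0-9a-f]{32}  ", script$lines, value = TRUE)
  expect_identical(sub("^[0-9a-f]{32}  ", "", md5_lines), script$manifest$filename)
  expect_identical(script$lines[1:2], c("#!/usr/bin/env bash", "set -euo pipefail"))

  wget <- make_download_script(b$libraries, "wget")
  expect_equal(sum(grepl("^wget -O", wget$lines)), length(flat_urls))

  # manifest byte conservation against the selection summary
  expect_equal(sum(script$manifest$bytes), summarize_selection(b$libraries)$total_bytes)

  empty <- b$libraries
  empty$cells <- empty$cells[0, , drop = FALSE]
  s0 <- make_download_script(empty, "curl")
  expect_equal(nrow(s0$manifest), 0L)
  expect_false(any(grepl("^curl", s0$lines)))

  bad <- b$libraries
  bad$cells[2, "download_md5s"] <- strsplit(bad$cells[2, "download_md5s"], ";")[[1]][1]
  bad$cells[2, "download_links"] <- paste(rep("ftp://x/a.fq.gz", 2), collapse = ";")
  if (bad$cells[2, "library_layout"] == "SINGLE") {
    bad$cells[2, "download_sizes"] <- "1;2"
  }
  expect_error(make_download_script(bad, "curl"), class = "amdir_conversion_error")
})

test_that("download script text is frozen for a fixed two-file library", {
  schema <- amdir_schema("host_associated_metagenome", "libraries")
  lib <- test_bundle(1, 1)$libraries
  lib$cells[1, "download_links"] <-
    "ftp://ftp.sra.example.org/vol1/fastq/ERR000001/ERR000001_1.fastq.gz;ftp://ftp.sra.example.org/vol1/fastq/ERR000001/ERR000001_2.fastq.gz"
  lib$cells[1, "download_md5s"] <-
    paste0(strrep("a", 32), ";", strrep("b", 32))
  lib$cells[1, "download_sizes"] <- "100;200"
  got <- write_download_script(make_download_script(lib, "curl"))
  expect_identical(got, paste0(
    "#!/usr/bin/env bash\n",
    "set -euo pipefail\n",
    "\n",
    "# Fetch all selected FASTQ files\n",
    "curl -L -o 'ERR000001_1.fastq.gz' 'ftp://ftp.sra.example.org/vol1/fastq/ERR000001/ERR000001_1.fastq.gz'\n",
    "curl -L -o 'ERR000001_2.fastq.gz' 'ftp://ftp.sra.example.org/vol1/fastq/ERR000001/ERR000001_2.fastq.gz'\n",
    "\n",
    "# Verify md5 checksums\n",
    "cat <<'EOF' > AncientMetagenomeDir_md5sums.txt\n",
    strrep("a", 32), "  ERR000001_1.fastq.gz\n",
    strrep("b", 32), "  ERR000001_2.fastq.gz\n",
    "EOF\n",
    "md5sum -c AncientMetagenomeDir_md5sums.txt\n"
  ))
})

test_that("eager sheets map layout, pretreatment and chemistry correctly", {
  b <- test_bundle(8, 2, seed = 31)
  lib <- b$libraries
  lib$cells[1, c("library_layout", "download_links", "download_md5s", "download_sizes")] <-
    c("SINGLE", "ftp://x/solo.fastq.gz", strrep("c", 32), "10")
  lib$cells[1, "library_treatment"] <- "half"
  lib$cells[1, "instrument_model"] <- "NextSeq 500"
  lib$cells[2, "instrument_model"] <- "Illumina HiSeq 4000"
  lib$cells[2, "library_treatment"] <- "full"
  lib$cells[, "library_treatment"][lib$cells[, "library_treatment"] == "unknown"] <- "none"

  sheet <- read_amdir_table(make_eager_sheet(b$samples, lib))
  expect_identical(sheet$header,
                   c("Sample_Name", "Library_ID", "Lane", "Colour_Chemistry",
                     "SeqType", "Organism", "Strandedness", "UDG_Treatment",
                     "R1", "R2", "BAM"))
  expect_equal(n_rows(sheet), n_rows(lib))

  expect_identical(unname(sheet$cells[1, c("SeqType", "R2", "UDG_Treatment", "Colour_Chemistry")]),
                   c("SE", "NA", "half", "2"))
  expect_identical(unname(sheet$cells[2, c("UDG_Treatment", "Colour_Chemistry")]),
                   c("full", "4"))

  # invariants across all rows
  for (i in seq_len(n_rows(sheet))) {
    row <- sheet$cells[i, ]
    expect_true(row[["Colour_Chemistry"]] %in% c("2", "4"))
    expect_identical(row[["SeqType"]] == "PE", row[["R2"]] != "NA")
    expect_true(row[["UDG_Treatment"]] %in% c("none", "half", "full"))
    expect_true(row[["Strandedness"]] %in% c("double", "single"))
    expect_identical(row[["BAM"]], "NA")
    expect_true(as.integer(row[["Lane"]]) >= 1L)
  }

  # unknown pretreatment: conservative 'none' plus a warning
  lib$cells[3, "library_treatment"] <- "unknown"
  expect_warning(sheet2 <- make_eager_sheet(b$samples, lib), "pretreatment")
  expect_identical(unname(read_amdir_table(sheet2)$cells[3, "UDG_Treatment"]), "none")

  # unmapped instrument suggests extending the rules
  lib$cells[4, "instrument_model"] <- "PacBio Sequel"
  expect_error(suppressWarnings(make_eager_sheet(b$samples, lib)),
               class = "amdir_conversion_error")
  expect_equal(instrument_chemistry("Illumina NovaSeq 6000"), 2L)
  expect_equal(instrument_chemistry("Illumina Genome Analyzer II"), 4L)
})

test_that("bibliographies carry one sorted entry per distinct DOI", {
  b <- test_bundle(20, 1, seed = 51)
  s <- b$samples
  s$cells[1:3, "publication_doi"] <- "10.99999/shared.1"
  bib <- make_bibliography(s)
  keys <- regmatches(bib, gregexpr("@misc\\{[^,]+", bib))[[1]]
  dois <- unique(s$cells[, "publication_doi"])
  expect_length(keys, length(dois))
  expect_false(anyDuplicated(keys) > 0)
  expect_identical(keys, sort(keys))

  empty <- s
  empty$cells <- empty$cells[0, , drop = FALSE]
  expect_identical(make_bibliography(empty), "")
})

test_that("export writes the canonical artefact set deterministically", {
  b <- test_bundle(6, 2, seed = 61)
  lib <- b$libraries
  lib$cells[, "library_treatment"][lib$cells[, "library_treatment"] == "unknown"] <- "none"
  out1 <- withr::local_tempdir()
  out2 <- withr::local_tempdir()
  paths <- export_tables(b$samples, lib, out1)
  expect_setequal(basename(unname(paths)), c(
    "AncientMetagenomeDir_curl_download_script.sh",
    "AncientMetagenomeDir_nf_core_eager_input_table.tsv",
    "AncientMetagenomeDir_bibliography.bib",
    "AncientMetagenomeDir_filtered_libraries.tsv"
  ))
  expect_length(list.files(out1), 4L)
  export_tables(b$samples, lib, out2)
  for (f in list.files(out1)) {
    expect_identical(readBin(file.path(out1, f), "raw", file.size(file.path(out1, f))),
                     readBin(file.path(out2, f), "raw", file.size(file.path(out2, f))),
                     label = sprintf("deterministic bytes of %s", f))
  }
})

test_that("merging appends disjoint rows and rejects key clashes", {
  b <- test_bundle(10, 1, seed = 71)
  schema <- b$samples$schema
  a <- b$samples; a$cells <- a$cells[1:3, , drop = FALSE]
  d <- b$samples; d$cells <- d$cells[4:5, , drop = FALSE]
  merged <- merge_tables(a, d)
  expect_equal(n_rows(merged), 5L)
  expect_identical(merged$cells[1:3, ], a$cells)
  expect_true(check_duplicates(bind_schema(merged, schema))$passed)

  clash <- b$samples; clash$cells <- clash$cells[3:4, , drop = FALSE]
  expect_error(merge_tables(a, clash), class = "amdir_merge_error")
  expect_error(merge_tables(a, clash), "sample_003")

  wrong <- as_amdir_table(a$cells[, rev(seq_len(ncol(a$cells)))])
  expect_error(merge_tables(a, wrong), class = "amdir_merge_error")

  # set-union oracle on random disjoint splits
  for (seed in 1:3) {
    set.seed(seed)
    idx <- sample(10, 6)
    x <- b$samples; x$cells <- x$cells[idx[1:3], , drop = FALSE]
    y <- b$samples; y$cells <- y$cells[idx[4:6], , drop = FALSE]
    m <- merge_tables(x, y)
    expect_setequal(m$cells[, "sample_name"],
                    union(x$cells[, "sample_name"], y$cells[, "sample_name"]))
  }
})
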