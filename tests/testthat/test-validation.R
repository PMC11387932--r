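test_that("per-cell schema validation pinpoints seeded violations", {
  b <- test_bundle()
  expect_true(validate_schema(b$libraries)$passed)

  lib <- b$libraries
  lib$cells[3, "library_treatment"] <- "halfish"
  r <- validate_schema(lib)
  expect_false(r$passed)
  expect_equal(nrow(r$errors), 1L)
  expect_identical(r$errors$error_type, "enum_violation")
  expect_equal(r$errors$line, 4L)  # header is line 1
  expect_identical(r$errors$column, "library_treatment")
  expect_match(r$errors$suggestion, "none, half, full")

  # one error per cell, first failing check only
  lib$cells[5, "read_count"] <- "many"
  lib$cells[6, "download_md5s"] <- "zzz"
  r <- validate_schema(lib)
  expect_equal(nrow(r$errors), 3L)
  expect_setequal(r$errors$error_type, c("enum_violation", "schema_violation"))
})

test_that("missing token is honoured only where the column allows it", {
  b <- test_bundle()
  s <- b$samples
  s$cells[2, "latitude"] <- "unknown"    # flagged missing_token_allowed
  expect_true(validate_schema(s)$passed)
  s$cells[3, "publication_year"] <- "unknown"  # integer, not allowed
  r <- validate_schema(s)
  expect_equal(nrow(r$errors), 1L)
  expect_identical(r$errors$error_type, "schema_violation")
  expect_equal(r$errors$line, 4L)
})

test_that("duplicate-key detection matches a quadratic-scan oracle", {
  b <- test_bundle()
  s <- b$samples
  # trivial case: rows A, B, A
  s$cells <- s$cells[c(1, 2, 1), , drop = FALSE]
  r <- check_duplicates(s)
  expect_equal(nrow(r$errors), 1L)
  expect_identical(r$errors$error_type, "duplicate_row")
  expect_equal(r$errors$line, 4L)

  expect_true(check_duplicates(b$samples)$passed)

  # randomized: inject duplicates and compare against brute force
  for (seed in 1:5) {
    set.seed(seed)
    s <- b$samples
    n <- nrow(s$cells)
    picks <- sample(n, 3)
    targets <- sample(setdiff(seq_len(n), picks), 3)
    keys <- s$schema$key_columns
    s$cells[targets, keys] <- s$cells[picks, keys]
    got <- check_duplicates(s)$errors$line
    # oracle: pairwise comparison of key tuples
    tup <- apply(s$cells[, keys, drop = FALSE], 1, paste, collapse = "|")
    want <- sort(which(vapply(seq_len(n), function(i) {
      any(tup[seq_len(i - 1L)] == tup[i])
    }, logical(1))) + 1L)
    expect_identical(sort(got), want)
  }
})

test_that("DOI syntax classification matches the regex oracle", {
  schema <- amdir_schema("host_associated_metagenome", "samples")
  b <- test_bundle()
  s <- b$samples

  s$cells[1, "publication_doi"] <- "10.12688/f1000research.134798.2"
  expect_true(check_doi(s)$passed)
  s$cells[1, "publication_doi"] <- "doi:not-a-doi"
  expect_false(check_doi(s)$passed)

  set.seed(99)
  alphabet <- c(letters, LETTERS, 0:9, ".", "/", "-", ":", "_")
  strings <- c(
    vapply(1:80, function(i) paste(sample(alphabet, sample(5:25, 1), TRUE), collapse = ""),
           character(1)),
    sprintf("10.%d/%s", sample(1000:99999, 20),
            vapply(1:20, function(i) paste(sample(c(letters, 0:9, "."), 8, TRUE), collapse = ""),
                   character(1)))
  )
  pattern <- "^10\\.[0-9]{4,9}/[^[:space:]]+$"  # oracle applied directly
  for (str in strings) {
    s$cells[1, "publication_doi"] <- str
    expect_identical(!check_doi(s)$passed, !grepl(pattern, str, ignore.case = TRUE),
                     label = sprintf("DOI classification of '%s'", str))
  }
})

test_that("cross-table accession checks catch mismatches, duplicates and orphans", {
  b <- test_bundle()
  expect_true(check_accessions(b$samples, b$libraries)$passed)

  lib <- b$libraries
  lib$cells[2, "archive_project"] <- "PRJEB999"
  r <- check_accessions(b$samples, lib)
  expect_identical(r$errors$error_type, "accession_project_mismatch")
  expect_equal(r$errors$line, 3L)

  lib <- b$libraries
  lib$cells[4, "archive_data_accession"] <- lib$cells[1, "archive_data_accession"]
  r <- check_accessions(b$samples, lib)
  expect_identical(r$errors$error_type, "duplicate_accession")
  expect_equal(r$errors$line, 5L)

  # per-library unique sample accessions leave orphaned library rows
  lib <- b$libraries
  lib$cells[c(2, 3), "archive_sample_accession"] <- c("SAMEA0111111", "SAMEA0222222")
  r <- check_accessions(b$samples, lib)
  expect_identical(r$errors$error_type, rep("orphan_library", 2))
  expect_equal(r$errors$line, c(3L, 4L))

  lib <- b$libraries
  lib$cells[1, "archive_data_accession"] <- "NOT_A_RUN"
  r <- check_accessions(b$samples, lib)
  expect_identical(r$errors$error_type, "invalid_accession")
})

test_that("validate_dataset reports exactly the corruption manifest", {
  for (seed in c(3, 17)) {
    b <- test_bundle(seed = seed)
    cd <- corrupt_dataset(b, k_per_kind = 1, seed = seed + 1)
    r <- validate_dataset(cd$bundle$samples, cd$bundle$libraries)
    expect_equal(nrow(r$errors), 8L)
    expect_identical(error_key(r$errors), error_key(cd$manifest))
    expect_setequal(unique(r$errors$error_type),
                    c("schema_violation", "enum_violation", "duplicate_row",
                      "duplicate_accession", "invalid_doi", "invalid_accession",
                      "accession_project_mismatch", "orphan_library"))
  }
})

test_that("validation is deterministic and renders the required report fields", {
  b <- test_bundle()
  cd <- corrupt_dataset(b, k_per_kind = 2, seed = 5)
  r1 <- validate_dataset(cd$bundle$samples, cd$bundle$libraries)
  r2 <- validate_dataset(cd$bundle$samples, cd$bundle$libraries)
  expect_identical(report_to_tsv(r1), report_to_tsv(r2))

  rendered <- read_amdir_table(report_to_tsv(r1))
  expect_true(all(c("error_type", "table_name", "line", "column",
                    "message", "suggestion") %in% rendered$header))
  expect_true(all(nzchar(rendered$cells[, "message"])))
  expect_true(all(nzchar(rendered$cells[, "suggestion"])))
  expect_true(all(as.integer(r1$errors$line) >= 2L))

  # canonical ordering: table, then line, then column position
  e <- r1$errors
  expect_false(is.unsorted(e$table_name))
  for (tab in unique(e$table_name)) {
    expect_false(is.unsorted(e$line[e$table_name == tab]))
  }
})

test_that("pristine fixture pairs pass across all dataset categories", {
  for (id in dataset_kinds()$identifier) {
    b <- test_bundle(8, c(1, 2), kind = id, seed = 11)
    expect_true(validate_dataset(b$samples, b$libraries)$passed)
  }
})
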