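test_that("shipped schemas satisfy the dialect's structural contract", {
  kinds <- dataset_kinds()
  expect_equal(nrow(kinds), 3L)
  expect_false(anyDuplicated(kinds$dir_name) > 0)
  expect_true("ancientmetagenome-hostassociated" %in% kinds$dir_name)

  for (id in kinds$identifier) {
    for (tt in c("samples", "libraries")) {
      schema <- amdir_schema(id, tt)
      expect_identical(schema$columns$position, seq_len(nrow(schema$columns)))
      expect_true(all(xor(schema$columns$value_kind == "enum",
                          !nzchar(schema$columns$enum_ref))))
    }
  }

  # positions downstream filters rely on (awk-style $2 / $7 on samples)
  s <- amdir_schema("host_associated_metagenome", "samples")
  expect_identical(s$columns$name[2], "publication_year")
  expect_identical(s$columns$name[7], "geo_loc_name")

  l <- amdir_schema("host_associated_metagenome", "libraries")
  expect_true(all(c("library_name", "strand_type", "library_polymerase",
                    "library_treatment", "instrument_model", "library_layout",
                    "library_strategy", "read_count", "download_links",
                    "download_md5s", "download_sizes") %in% l$columns$name))
  expect_setequal(l$enums$library_treatment, c("none", "half", "full", "unknown"))
  expect_true(all(c("double", "single") %in% l$enums$strand_type))
})

test_that("load_schema resolves enums and rejects inconsistent documents", {
  doc <- '{"dataset": "ancientmetagenome-hostassociated", "table_type": "samples",
           "columns": [{"name": "a", "value_kind": "enum", "enum": "vocab"}]}'
  schema <- load_schema(doc, enums = list(vocab = c("x", "y")))
  expect_identical(schema$enums$vocab, c("x", "y"))

  expect_error(
    load_schema('{"dataset": "ancientmetagenome-hostassociated", "table_type": "samples", "columns": []}'),
    class = "amdir_schema_error"
  )
  expect_error(load_schema(doc, enums = list()), class = "amdir_schema_error")
  expect_error(load_schema("{not json"), class = "amdir_parse_error")
})

test_that("column positions reproduce document order for random permutations", {
  names <- sprintf("col_%02d", 1:8)
  for (s in 1:5) {
    set.seed(s)
    perm <- sample(names)
    doc <- jsonlite::toJSON(list(
      dataset = "ancientmetagenome-environmental", table_type = "samples",
      columns = lapply(perm, function(nm) list(name = nm, value_kind = "free_text"))
    ), auto_unbox = TRUE)
    schema <- load_schema(doc)
    # oracle: direct index enumeration of the document's column list
    expect_identical(schema$columns$name, perm)
    expect_identical(schema$columns$position[match(perm, schema$columns$name)],
                     seq_along(perm))
  }
})

test_that("TSV reading enforces the dialect and round trips byte-identically", {
  txt <- "a\tb\nx\ty\n1\t\n"
  tbl <- read_amdir_table(txt)
  expect_equal(n_rows(tbl), 2L)
  expect_identical(tbl$cells[2, ], c(a = "1", b = ""))
  expect_identical(write_amdir_table(tbl), txt)

  expect_error(read_amdir_table("a\tb\nonly-one-field\n"),
               class = "amdir_structural_error")
  expect_error(read_amdir_table("a\tb\nx\ty\tz\n"),
               class = "amdir_structural_error")

  b <- test_bundle()
  for (t in list(b$samples, b$libraries)) {
    txt <- write_amdir_table(t)
    expect_identical(write_amdir_table(read_amdir_table(txt)), txt)
  }
})

test_that("serialization rejects cells the dialect cannot represent", {
  tbl <- as_amdir_table(data.frame(a = "x\ty", b = "ok"))
  expect_error(write_amdir_table(tbl), class = "amdir_serialization_error")
  empty <- as_amdir_table(matrix(character(), 0, 2, dimnames = list(NULL, c("a", "b"))))
  expect_identical(write_amdir_table(empty), "a\tb\n")
})

test_that("schema binding is order-sensitive", {
  b <- test_bundle()
  schema <- amdir_schema("host_associated_metagenome", "samples")
  cells <- b$samples$cells
  swapped <- cells[, c(2, 1, 3:ncol(cells)), drop = FALSE]
  tbl <- as_amdir_table(swapped)
  expect_error(bind_schema(tbl, schema), class = "amdir_schema_error")
  expect_silent(bind_schema(as_amdir_table(cells), schema))
})

test_that("release tables resolve from a local release layout", {
  b <- test_bundle(5, 1)
  dir <- withr::local_tempdir()
  write_amdir_table(b$samples,
                    file.path(dir, "ancientmetagenome-hostassociated_samples_v24.03.0.tsv"))
  tbl <- resolve_release_table("host_associated_metagenome", "samples", "v24.03.0",
                               source = "local_dir", dir = dir)
  expect_equal(n_rows(tbl), 5L)
  expect_match(tbl$provenance, "v24\\.03\\.0")

  expect_error(
    resolve_release_table("host_associated_metagenome", "samples", "v19.01.0",
                          source = "local_dir", dir = dir),
    class = "amdir_release_not_found"
  )
  expect_error(parse_release_tag("24.03"), class = "amdir_usage_error")
  expect_equal(parse_release_tag("v24.03.0")$month, 3L)
})
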