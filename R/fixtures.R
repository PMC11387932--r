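# Synthetic datasets. The generator emits schema-valid sample/library pairs
# plus matching per-project read_run report fixtures; the corruption engine
# seeds exactly-located errors mirroring mistakes observed in public archive
# uploads (wrong platform metadata, per-library sample accessions, duplicated
# runs, malformed DOIs/accessions, ...), and its manifest is the ground truth
# the validator is tested against.

geo_pool <- c("Germany", "Mexico", "United Kingdom", "Denmark",
              "Sweden", "Argentina", "Egypt", "Italy")

random_hex <- function(n_chars) {
  paste(sample(c(0:9, letters[1:6]), n_chars, replace = TRUE), collapse = "")
}

#' Generate a schema-valid synthetic dataset
#'
#' Emulates one release directory of a dataset category: a samples table, a
#' libraries table whose rows link back to the samples via archive
#' accessions, and one recorded read_run report per project consistent with
#' the library rows. Everything is drawn from a single seeded stream, so a
#' given `(arguments, seed)` pair is byte-reproducible.
#'
#' Sample sites span a small country pool; a configurable fraction of
#' samples is placed in Spain and publication years span `year_range`, so
#' the year/geography filtering workflow can be exercised on generated data.
#'
#' @param n_samples Number of sample rows (>= 1).
#' @param libs_per_sample Either a single integer (exact libraries per
#'   sample) or a length-2 integer range sampled uniformly per sample.
#' @param kind Dataset category (identifier or directory name).
#' @param seed Integer seed.
#' @param spain_fraction Expected fraction of samples with
#'   `geo_loc_name = "Spain"`.
#' @param year_range Inclusive publication-year range.
#' @return An `amdir_bundle`: list with `samples`, `libraries` (schema-bound
#'   `amdir_table`s), `run_reports` (named character vector of TSV texts,
#'   one per project accession), `kind`, `seed`.
#' @export
generate_dataset <- function(n_samples, libs_per_sample = c(1L, 3L),
                             kind = "host_associated_metagenome", seed = 1L,
                             spain_fraction = 0.25, year_range = c(2015L, 2024L)) {
  if (!is.numeric(n_samples) || n_samples < 1L) stop_usage("n_samples must be >= 1")
  if (!length(libs_per_sample) %in% c(1L, 2L) || any(libs_per_sample < 1L)) {
    stop_usage("libs_per_sample must be a positive integer or a length-2 range")
  }
  kind <- dataset_kind(kind)
  s_schema <- amdir_schema(kind$identifier, "samples")
  l_schema <- amdir_schema(kind$identifier, "libraries")
  n_samples <- as.integer(n_samples)

  with_seed(seed, {
    n_projects <- ceiling(n_samples / 3)
    project_idx <- rep(seq_len(n_projects), each = 3L)[seq_len(n_samples)]
    project_acc <- sprintf("PRJEB%d", 100000L + sample.int(899999L, n_projects))
    project_doi <- sprintf("10.99999/amd.%04d", sample(1000:9999, n_projects))
    project_year <- sample(seq(year_range[1], year_range[2]), n_projects, replace = TRUE)
    project_name <- sprintf("study_%03d", seq_len(n_projects))

    spain <- stats::runif(n_samples) < spain_fraction
    geo <- ifelse(spain, "Spain", sample(geo_pool, n_samples, replace = TRUE))
    sample_name <- sprintf("sample_%03d", seq_len(n_samples))
    sample_acc <- sprintf("SAMEA%d", 1000000L + sample.int(8999999L, n_samples))
    material <- switch(kind$identifier,
      host_associated_metagenome = sample(c("dental calculus", "palaeofaeces", "gut content"),
                                          n_samples, replace = TRUE),
      host_associated_singlegenome = sample(c("tooth", "petrous bone", "dental calculus"),
                                            n_samples, replace = TRUE),
      environmental_metagenome = sample(c("lake sediment", "cave sediment", "permafrost"),
                                        n_samples, replace = TRUE)
    )

    samples_df <- data.frame(
      project_name = project_name[project_idx],
      publication_year = as.character(project_year[project_idx]),
      publication_doi = project_doi[project_idx],
      site_name = sprintf("site_%02d", sample(1:30, n_samples, replace = TRUE)),
      latitude = sprintf("%.4f", stats::runif(n_samples, -60, 70)),
      longitude = sprintf("%.4f", stats::runif(n_samples, -120, 120)),
      geo_loc_name = geo,
      sample_name = sample_name,
      stringsAsFactors = FALSE
    )
    if (kind$identifier != "environmental_metagenome") {
      samples_df$sample_host <- sample(c("Homo sapiens", "Ursus arctos", "Canis lupus"),
                                       n_samples, replace = TRUE, prob = c(0.8, 0.1, 0.1))
    }
    samples_df$sample_age <- as.character(sample(100:10000, n_samples, replace = TRUE))
    samples_df$material <- material
    samples_df$archive <- "ENA"
    samples_df$archive_project <- project_acc[project_idx]
    samples_df$archive_accession <- sample_acc

    nlibs <- if (length(libs_per_sample) == 1L) {
      rep(as.integer(libs_per_sample), n_samples)
    } else {
      sample(seq(libs_per_sample[1], libs_per_sample[2]), n_samples, replace = TRUE)
    }
    total <- sum(nlibs)
    run_acc <- sprintf("ERR%d", 1000000L + sample.int(8999999L, total))
    owner <- rep(seq_len(n_samples), nlibs)
    lib_no <- unlist(lapply(nlibs, seq_len), use.names = FALSE)

    layout <- sample(c("SINGLE", "PAIRED"), total, replace = TRUE, prob = c(0.3, 0.7))
    files_per_lib <- ifelse(layout == "PAIRED", 2L, 1L)
    urls <- md5s <- sizes <- character(total)
    for (i in seq_len(total)) {
      suffix <- if (layout[i] == "PAIRED") sprintf("%s_%d", run_acc[i], 1:2) else run_acc[i]
      urls[i] <- paste(sprintf("ftp://ftp.sra.example.org/vol1/fastq/%s/%s.fastq.gz",
                               run_acc[i], suffix), collapse = ";")
      md5s[i] <- paste(vapply(seq_len(files_per_lib[i]), function(k) random_hex(32), character(1)),
                       collapse = ";")
      sizes[i] <- paste(999999L + sample.int(999000000L, files_per_lib[i]), collapse = ";")
    }

    libraries_df <- data.frame(
      project_name = samples_df$project_name[owner],
      publication_year = samples_df$publication_year[owner],
      data_publication_doi = samples_df$publication_doi[owner],
      sample_name = samples_df$sample_name[owner],
      archive = "ENA",
      archive_project = samples_df$archive_project[owner],
      archive_sample_accession = samples_df$archive_accession[owner],
      library_name = sprintf("%s_L%d", samples_df$sample_name[owner], lib_no),
      strand_type = sample(c("double", "single"), total, replace = TRUE, prob = c(0.8, 0.2)),
      library_polymerase = sample(c("proofreading", "non-proofreading"), total, replace = TRUE),
      library_treatment = sample(c("none", "half", "full", "unknown"), total,
                                 replace = TRUE, prob = c(0.4, 0.3, 0.2, 0.1)),
      instrument_model = sample(c("Illumina HiSeq 4000", "NextSeq 500", "Illumina NovaSeq 6000",
                                  "Illumina MiSeq", "Illumina HiSeq 2500"), total, replace = TRUE),
      library_layout = layout,
      library_strategy = sample(c("WGS", "Target-Capture"), total, replace = TRUE, prob = c(0.9, 0.1)),
      read_count = as.character(99999L + sample.int(49900001L, total, replace = TRUE)),
      archive_data_accession = run_acc,
      download_links = urls,
      download_md5s = md5s,
      download_sizes = sizes,
      stringsAsFactors = FALSE
    )

    samples_tbl <- as_amdir_table(samples_df, provenance = "samples", schema = s_schema)
    libraries_tbl <- as_amdir_table(libraries_df, provenance = "libraries", schema = l_schema)

    run_reports <- vapply(unique(samples_df$archive_project), function(prj) {
      idx <- which(libraries_df$archive_project == prj)
      rpt <- data.frame(
        study_accession = libraries_df$archive_project[idx],
        sample_accession = libraries_df$archive_sample_accession[idx],
        run_accession = libraries_df$archive_data_accession[idx],
        library_name = libraries_df$library_name[idx],
        instrument_model = libraries_df$instrument_model[idx],
        library_layout = libraries_df$library_layout[idx],
        library_strategy = libraries_df$library_strategy[idx],
        read_count = libraries_df$read_count[idx],
        fastq_ftp = libraries_df$download_links[idx],
        fastq_md5 = libraries_df$download_md5s[idx],
        fastq_bytes = libraries_df$download_sizes[idx],
        stringsAsFactors = FALSE
      )
      write_amdir_table(as_amdir_table(rpt, provenance = prj))
    }, character(1))

    structure(
      list(samples = samples_tbl, libraries = libraries_tbl,
           run_reports = run_reports, kind = kind, seed = as.integer(seed)),
      class = "amdir_bundle"
    )
  })
}

#' @export
print.amdir_bundle <- function(x, ...) {
  cat(sprintf(
    "<amdir_bundle> %s: %d samples, %d libraries, %d project run reports (seed %d)\n",
    x$kind$dir_name, nrow(x$samples$cells), nrow(x$libraries$cells),
    length(x$run_reports), x$seed
  ))
  invisible(x)
}

corruptible_kinds <- c(
  "schema_violation", "enum_violation", "duplicate_row", "duplicate_accession",
  "invalid_doi", "invalid_accession", "accession_project_mismatch", "orphan_library"
)

#' Seed known corruptions into a valid dataset
#'
#' Applies each requested error kind exactly `k_per_kind` times, at distinct
#' locations that never overlap, and records every mutation in a manifest.
#' [validate_dataset()] on the corrupted bundle is expected to report
#' exactly the manifest — the closure that anchors the validation tests.
#'
#' The corruption repertoire mirrors errors observed in real archive
#' uploads: `enum_violation` alternates between an impossible library
#' treatment and a sequencing platform outside the controlled vocabulary
#' (the publication/archive platform discrepancy), and `orphan_library`
#' rewrites a library's sample accession to a fresh one, emulating uploads
#' where every library received its own sample accession.
#'
#' @param bundle A valid `amdir_bundle`.
#' @param error_kinds Subset of the eight row/cell error types.
#' @param k_per_kind Occurrences per kind (>= 1).
#' @param seed Integer seed for target selection.
#' @return List with `bundle` (corrupted copy) and `manifest` (data frame:
#'   error_type, table_name, line, column, description).
#' @export
corrupt_dataset <- function(bundle, error_kinds = corruptible_kinds,
                            k_per_kind = 1L, seed = 1L) {
  stopifnot(inherits(bundle, "amdir_bundle"))
  bad <- setdiff(error_kinds, corruptible_kinds)
  if (length(bad)) {
    stop_usage(sprintf("unknown error kind(s): %s", paste(bad, collapse = ", ")))
  }
  if (k_per_kind < 1L) stop_usage("k_per_kind must be >= 1")
  k <- as.integer(k_per_kind)

  sample_kinds <- intersect(error_kinds, c("schema_violation", "invalid_doi", "duplicate_row"))
  library_kinds <- intersect(error_kinds, c("enum_violation", "invalid_accession",
                                            "accession_project_mismatch", "orphan_library",
                                            "duplicate_accession"))
  need_s <- k * (length(sample_kinds) + ("duplicate_row" %in% sample_kinds))
  need_l <- k * (length(library_kinds) + ("duplicate_accession" %in% library_kinds))
  n_s <- nrow(bundle$samples$cells)
  n_l <- nrow(bundle$libraries$cells)
  if (need_s > n_s || need_l > n_l) {
    stop_capacity(sprintf(
      "bundle too small for requested corruptions: need %d sample and %d library rows, have %d and %d",
      need_s, need_l, n_s, n_l
    ))
  }

  with_seed(seed, {
    s_pool <- sample(n_s)
    l_pool <- sample(n_l)
    take_s <- function(m) { out <- s_pool[seq_len(m)]; s_pool <<- s_pool[-seq_len(m)]; out }
    take_l <- function(m) { out <- l_pool[seq_len(m)]; l_pool <<- l_pool[-seq_len(m)]; out }

    samples <- bundle$samples
    libraries <- bundle$libraries
    manifest <- list()
    note <- function(error_type, table_name, row, column, description) {
      manifest[[length(manifest) + 1L]] <<- data.frame(
        error_type = error_type, table_name = table_name, line = row + 1L,
        column = column, description = description, stringsAsFactors = FALSE
      )
    }
    counter <- 0L

    for (kind in error_kinds) {
      for (occ in seq_len(k)) {
        counter <- counter + 1L
        switch(kind,
          schema_violation = {
            r <- take_s(1L)
            samples$cells[r, "latitude"] <- "ninety-two"
            note(kind, "samples", r, "latitude", "latitude replaced by a non-numeric string")
          },
          invalid_doi = {
            r <- take_s(1L)
            samples$cells[r, "publication_doi"] <- sprintf("doi:not-a-valid-doi-%d", counter)
            note(kind, "samples", r, "publication_doi", "DOI replaced by a malformed string")
          },
          duplicate_row = {
            rr <- sort(take_s(2L))
            keys <- samples$schema$key_columns
            samples$cells[rr[2], keys] <- samples$cells[rr[1], keys]
            note(kind, "samples", rr[2], "",
                 sprintf("key columns copied from data row %d", rr[1]))
          },
          enum_violation = {
            r <- take_l(1L)
            if (occ %% 2L == 1L) {
              libraries$cells[r, "library_treatment"] <- "halfish"
              note(kind, "libraries", r, "library_treatment",
                   "treatment token outside the controlled vocabulary")
            } else {
              libraries$cells[r, "instrument_model"] <- "Illumina SuperSeq 9000"
              note(kind, "libraries", r, "instrument_model",
                   "sequencing platform outside the controlled vocabulary")
            }
          },
          invalid_accession = {
            r <- take_l(1L)
            libraries$cells[r, "archive_data_accession"] <- sprintf("RUNX%04d", counter)
            note(kind, "libraries", r, "archive_data_accession",
                 "run accession replaced by a non-INSDC token")
          },
          accession_project_mismatch = {
            r <- take_l(1L)
            libraries$cells[r, "archive_project"] <- sprintf("PRJEB%06d", counter)
            note(kind, "libraries", r, "archive_project",
                 "library project accession diverged from its sample's")
          },
          orphan_library = {
            r <- take_l(1L)
            libraries$cells[r, "archive_sample_accession"] <- sprintf("SAMEA0%06d", counter)
            note(kind, "libraries", r, "archive_sample_accession",
                 "library given its own fresh sample accession")
          },
          duplicate_accession = {
            rr <- sort(take_l(2L))
            libraries$cells[rr[2], "archive_data_accession"] <-
              libraries$cells[rr[1], "archive_data_accession"]
            note(kind, "libraries", rr[2], "archive_data_accession",
                 sprintf("run accession copied from data row %d", rr[1]))
          }
        )
      }
    }

    out <- bundle
    out$samples <- samples
    out$libraries <- libraries
    manifest <- do.call(rbind, manifest)
    rownames(manifest) <- NULL
    list(bundle = out, manifest = manifest)
  })
}

#' Write a fixture bundle to disk
#'
#' Writes `samples.tsv`, `libraries.tsv`, and one recorded read_run report
#' per project under `run_reports/` — the directory layout the recorded
#' transport of [fetch_run_report()] replays.
#'
#' @param bundle An `amdir_bundle`.
#' @param outdir Output directory (created if needed).
#' @return Invisibly, the named vector of written paths.
#' @export
write_fixture_bundle <- function(bundle, outdir) {
  stopifnot(inherits(bundle, "amdir_bundle"))
  dir.create(file.path(outdir, "run_reports"), recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    samples = file.path(outdir, "samples.tsv"),
    libraries = file.path(outdir, "libraries.tsv")
  )
  write_amdir_table(bundle$samples, paths[["samples"]])
  write_amdir_table(bundle$libraries, paths[["libraries"]])
  for (prj in names(bundle$run_reports)) {
    p <- file.path(outdir, "run_reports", paste0(prj, ".tsv"))
    con <- file(p, open = "wb")
    writeChar(bundle$run_reports[[prj]], con, eos = NULL, useBytes = TRUE)
    close(con)
    paths[[prj]] <- p
  }
  invisible(paths)
}
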