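# Patterns are configuration: INSDC accession namespaces evolve, so callers
# can swap them without touching the checkers.

#' Default syntax patterns for DOIs and INSDC accessions
#'
#' @return Named list of case-sensitive regular expressions (the DOI pattern
#'   is applied case-insensitively): `doi`, `project`, `biosample`, `run`.
#' @export
amdir_patterns <- function() {
  list(
    doi = "^10\\.[0-9]{4,9}/[^[:space:]]+$",
    project = "^PRJ[EDN][A-Z][0-9]+$",
    biosample = "^SAM(EA|N|D)[A-Z]?[0-9]+$",
    run = "^[EDS]RR[0-9]{6,}$"
  )
}

new_report <- function(errors = NULL) {
  if (is.null(errors) || nrow(errors) == 0L) {
    errors <- data.frame(
      error_type = character(), table_name = character(), line = integer(),
      column = character(), message = character(), suggestion = character(),
      stringsAsFactors = FALSE
    )
  }
  structure(list(errors = errors, passed = nrow(errors) == 0L), class = "amdir_report")
}

one_error <- function(error_type, table_name, line, column, message, suggestion) {
  data.frame(
    error_type = error_type, table_name = table_name, line = as.integer(line),
    column = column, message = message, suggestion = suggestion,
    stringsAsFactors = FALSE
  )
}

combine_reports <- function(..., order_with = NULL) {
  errs <- do.call(rbind, lapply(list(...), function(r) r$errors))
  r <- new_report(errs)
  if (!is.null(order_with)) r <- sort_report(r, order_with)
  r
}

# Canonical ordering: table name, then line, then the column's schema
# position (errors without a column sort first within a line).
sort_report <- function(report, schemas) {
  e <- report$errors
  if (nrow(e) == 0L) return(report)
  pos <- mapply(function(tab, col) {
    if (!nzchar(col) || is.null(schemas[[tab]])) return(0L)
    p <- match(col, schemas[[tab]]$columns$name)
    if (is.na(p)) 0L else p
  }, e$table_name, e$column)
  e <- e[order(e$table_name, e$line, pos, e$error_type), , drop = FALSE]
  rownames(e) <- NULL
  new_report(e)
}

table_label <- function(table, default = "table") {
  if (!is.null(table$provenance) && nzchar(table$provenance)) table$provenance else default
}

#' @export
print.amdir_report <- function(x, ...) {
  if (x$passed) {
    cat("<amdir_report> PASSED (0 errors)\n")
  } else {
    cat(sprintf("<amdir_report> FAILED (%d error%s)\n", nrow(x$errors),
                if (nrow(x$errors) == 1L) "" else "s"))
    print(x$errors[, c("error_type", "table_name", "line", "column", "message")])
  }
  invisible(x)
}

#' Render a validation report as TSV
#'
#' One row per error with the fields `error_type`, `table_name`, `line`,
#' `column`, `message`, `suggestion` — the tabular form the review workflow
#' consumes.
#'
#' @param report An `amdir_report`.
#' @param path Optional output file.
#' @return TSV text (invisibly when written to `path`).
#' @export
report_to_tsv <- function(report, path = NULL) {
  e <- report$errors
  e$line <- as.character(e$line)
  tbl <- new_amdir_table(names(e), as.matrix(e), provenance = "report")
  write_amdir_table(tbl, path = path)
}

cell_at <- function(table, row, column) table$cells[row, column]

required_schema <- function(table, what) {
  if (is.null(table$schema)) {
    stop_usage(sprintf("%s requires a schema-bound table (see bind_schema())", what))
  }
  table$schema
}

#' Validate every cell of a table against its schema
#'
#' Each cell violating its column specification (type, enum membership,
#' list-token patterns, or a disallowed missing token) yields exactly one
#' error — the first failing check in the order required/missing/type.
#' DOI and accession syntax are deliberately not checked here: those columns
#' are owned by [check_doi()] and [check_accessions()], so a single bad cell
#' is never reported twice by [validate_dataset()].
#'
#' @param table Schema-bound `amdir_table` (or pass `schema`).
#' @param schema Optional schema overriding the bound one.
#' @param table_name Label used in the report; defaults to provenance.
#' @return An `amdir_report`.
#' @export
validate_schema <- function(table, schema = NULL, table_name = NULL) {
  schema <- schema %||% required_schema(table, "validate_schema()")
  if (is.null(table$schema)) table <- bind_schema(table, schema)
  table_name <- table_name %||% table_label(table)
  spec <- schema$columns
  errs <- list()
  for (j in seq_len(nrow(spec))) {
    col <- spec$name[j]
    kind <- spec$value_kind[j]
    vocab <- if (nzchar(spec$enum_ref[j])) schema$enums[[spec$enum_ref[j]]] else NULL
    for (i in seq_len(nrow(table$cells))) {
      cell <- unname(table$cells[i, j])
      line <- i + 1L
      err <- check_cell(cell, kind, vocab,
                        required = spec$required[j],
                        missing_ok = spec$missing_token_allowed[j])
      if (!is.null(err)) {
        errs[[length(errs) + 1L]] <-
          one_error(err$type, table_name, line, col, err$message, err$suggestion)
      }
    }
  }
  sort_report(new_report(if (length(errs)) do.call(rbind, errs)),
              stats::setNames(list(schema), table_name))
}

check_cell <- function(cell, kind, vocab, required, missing_ok) {
  if (!nzchar(cell)) {
    if (required) {
      return(list(type = "schema_violation", message = "required cell is empty",
                  suggestion = sprintf("fill in a value or use the missing token '%s' where permitted", missing_token)))
    }
    return(NULL)
  }
  if (identical(cell, missing_token)) {
    if (missing_ok || (kind == "enum" && missing_token %in% vocab)) return(NULL)
    return(list(type = "schema_violation",
                message = sprintf("missing token '%s' is not permitted in this column", missing_token),
                suggestion = "provide a concrete value"))
  }
  switch(kind,
    free_text = NULL,
    doi = NULL,            # owned by check_doi()
    accession_list = NULL, # owned by check_accessions()
    integer = if (!grepl("^-?[0-9]+$", cell)) {
      list(type = "schema_violation", message = sprintf("'%s' is not an integer", cell),
           suggestion = "use digits only, e.g. 2020")
    },
    number = if (!grepl("^-?[0-9]+(\\.[0-9]+)?$", cell)) {
      list(type = "schema_violation", message = sprintf("'%s' is not a decimal number", cell),
           suggestion = "use a plain decimal, e.g. 41.6488")
    },
    enum = if (!cell %in% vocab) {
      list(type = "enum_violation",
           message = sprintf("'%s' is not in the controlled vocabulary", cell),
           suggestion = sprintf("use one of: %s", paste(vocab, collapse = ", ")))
    },
    url_list = check_tokens(cell, ";", "^(https?|ftp)://[^[:space:]]+$",
                            "is not a URL", "use http(s)/ftp URLs separated by ';'"),
    md5_list = check_tokens(cell, ";", "^[0-9a-f]{32}$",
                            "is not an md5 checksum", "use 32 lowercase hex characters per file, ';'-separated"),
    byte_size_list = check_tokens(cell, ";", "^[0-9]+$",
                                  "is not a byte count", "use plain integers per file, ';'-separated"),
    NULL
  )
}

check_tokens <- function(cell, sep, pattern, what, suggestion) {
  tokens <- strsplit(cell, sep, fixed = TRUE)[[1]]
  bad <- tokens[!grepl(pattern, tokens)]
  if (length(bad)) {
    list(type = "schema_violation",
         message = sprintf("token '%s' %s", bad[1], what),
         suggestion = suggestion)
  }
}

#' Flag rows that repeat an earlier row's key
#'
#' A row whose key tuple (the schema's `key_columns`) equals that of an
#' earlier row yields one `duplicate_row` error on the later line.
#'
#' @inheritParams validate_schema
#' @return An `amdir_report`.
#' @export
check_duplicates <- function(table, schema = NULL, table_name = NULL) {
  schema <- schema %||% required_schema(table, "check_duplicates()")
  table_name <- table_name %||% table_label(table)
  keys <- schema$key_columns
  if (!length(keys)) return(new_report())
  if (!all(keys %in% table$header)) {
    stop_usage(sprintf("key column(s) missing from header: %s",
                       paste(setdiff(keys, table$header), collapse = ", ")))
  }
  if (nrow(table$cells) == 0L) return(new_report())
  tuples <- apply(table$cells[, keys, drop = FALSE], 1L, paste, collapse = "\x1f")
  dup <- duplicated(tuples)
  errs <- lapply(which(dup), function(i) {
    first <- which(tuples == tuples[i])[1]
    one_error("duplicate_row", table_name, i + 1L, "",
              sprintf("row repeats the key (%s) of line %d",
                      paste(sprintf("%s='%s'", keys, table$cells[i, keys]), collapse = ", "),
                      first + 1L),
              "remove the duplicate row or correct its key columns")
  })
  new_report(if (length(errs)) do.call(rbind, errs))
}

#' Check DOI syntax (and optionally resolution)
#'
#' Offline mode (the default, fully deterministic) checks each DOI cell
#' against the configured pattern. Online mode additionally treats a
#' non-success HTTP resolution of `https://doi.org/<doi>` as invalid; a
#' network failure there is a warning, never an `invalid_doi`.
#'
#' @param table `amdir_table` with a DOI column.
#' @param online Resolve DOIs over the network as well.
#' @param column DOI column name; defaults to the schema's first `doi`-kind
#'   column, else `"publication_doi"`.
#' @param patterns See [amdir_patterns()].
#' @param table_name Report label.
#' @return An `amdir_report`.
#' @export
check_doi <- function(table, online = FALSE, column = NULL,
                      patterns = amdir_patterns(), table_name = NULL) {
  table_name <- table_name %||% table_label(table)
  if (is.null(column)) {
    column <- if (!is.null(table$schema)) {
      cand <- table$schema$columns$name[table$schema$columns$value_kind == "doi"]
      if (length(cand)) cand[1] else "publication_doi"
    } else {
      "publication_doi"
    }
  }
  if (!column %in% table$header) {
    stop_usage(sprintf("table has no DOI column '%s'", column))
  }
  errs <- list()
  for (i in seq_len(nrow(table$cells))) {
    doi <- unname(table$cells[i, column])
    if (!nzchar(doi) || identical(doi, missing_token)) next
    if (!grepl(patterns$doi, doi, ignore.case = TRUE)) {
      errs[[length(errs) + 1L]] <- one_error(
        "invalid_doi", table_name, i + 1L, column,
        sprintf("'%s' is not a syntactically valid DOI", doi),
        "use the bare DOI, e.g. 10.12688/f1000research.134798.2"
      )
    } else if (online) {
      status <- tryCatch(doi_resolves(doi), error = function(e) NA)
      if (is.na(status)) {
        warning(sprintf("could not resolve DOI %s (network failure); skipping online check", doi),
                call. = FALSE)
      } else if (!status) {
        errs[[length(errs) + 1L]] <- one_error(
          "invalid_doi", table_name, i + 1L, column,
          sprintf("'%s' does not resolve at doi.org", doi),
          "check the DOI against the publisher's landing page"
        )
      }
    }
  }
  new_report(if (length(errs)) do.call(rbind, errs))
}

doi_resolves <- function(doi) {
  con <- url(paste0("https://doi.org/", doi), method = "libcurl")
  on.exit(try(close(con), silent = TRUE))
  ok <- tryCatch({ suppressWarnings(open(con, "r")); TRUE }, error = function(e) FALSE)
  ok
}

# Sample/library linkage: by archive sample accession when the library table
# carries one (samples may list several, comma-separated), else by exact
# sample_name. Returns the matching sample row index per library row (NA when
# orphaned).
link_libraries_to_samples <- function(samples, libraries) {
  n <- nrow(libraries$cells)
  if ("archive_sample_accession" %in% libraries$header &&
      "archive_accession" %in% samples$header) {
    sample_acc <- strsplit(samples$cells[, "archive_accession"], ",", fixed = TRUE)
    lut <- new.env(parent = emptyenv())
    for (i in seq_along(sample_acc)) {
      for (a in trimws(sample_acc[[i]])) {
        if (nzchar(a) && !exists(a, envir = lut, inherits = FALSE)) assign(a, i, envir = lut)
      }
    }
    vapply(seq_len(n), function(i) {
      a <- trimws(libraries$cells[i, "archive_sample_accession"])
      if (exists(a, envir = lut, inherits = FALSE)) get(a, envir = lut) else NA_integer_
    }, integer(1))
  } else if ("sample_name" %in% libraries$header && "sample_name" %in% samples$header) {
    match(libraries$cells[, "sample_name"], samples$cells[, "sample_name"])
  } else {
    stop_usage("no usable linkage columns between samples and libraries")
  }
}

#' Cross-table accession checks
#'
#' Emits `invalid_accession` for tokens failing the INSDC syntax patterns
#' (projects, biosamples, runs) in either table; `duplicate_accession` when a
#' run accession appears on more than one library row; `orphan_library` when
#' a library row links to no sample row; and `accession_project_mismatch`
#' when a linked library's project accession differs from its sample's.
#'
#' @param samples,libraries Schema-bound `amdir_table`s of one dataset
#'   category.
#' @param patterns See [amdir_patterns()].
#' @param sample_name,library_name Report labels.
#' @return An `amdir_report`.
#' @export
check_accessions <- function(samples, libraries, patterns = amdir_patterns(),
                             sample_name = NULL, library_name = NULL) {
  sample_name <- sample_name %||% table_label(samples, "samples")
  library_name <- library_name %||% table_label(libraries, "libraries")
  errs <- list()
  push <- function(e) errs[[length(errs) + 1L]] <<- e

  check_col <- function(table, tname, column, pattern, what, sep = ",") {
    if (!column %in% table$header) return()
    for (i in seq_len(nrow(table$cells))) {
      cell <- unname(table$cells[i, column])
      if (!nzchar(cell) || identical(cell, missing_token)) next
      tokens <- trimws(strsplit(cell, sep, fixed = TRUE)[[1]])
      bad <- tokens[!grepl(pattern, tokens)]
      if (length(bad)) {
        push(one_error("invalid_accession", tname, i + 1L, column,
                       sprintf("'%s' is not a valid %s accession", bad[1], what),
                       sprintf("use the INSDC %s accession format", what)))
      }
    }
  }
  check_col(samples, sample_name, "archive_project", patterns$project, "project")
  check_col(samples, sample_name, "archive_accession", patterns$biosample, "sample")
  check_col(libraries, library_name, "archive_project", patterns$project, "project")
  check_col(libraries, library_name, "archive_sample_accession", patterns$biosample, "sample")
  check_col(libraries, library_name, "archive_data_accession", patterns$run, "run")

  if ("archive_data_accession" %in% libraries$header && nrow(libraries$cells)) {
    runs <- libraries$cells[, "archive_data_accession"]
    for (i in which(duplicated(runs))) {
      first <- which(runs == runs[i])[1]
      push(one_error("duplicate_accession", library_name, i + 1L, "archive_data_accession",
                     sprintf("run accession '%s' already used on line %d", runs[i], first + 1L),
                     "each sequencing run belongs to exactly one library row"))
    }
  }

  link <- link_libraries_to_samples(samples, libraries)
  for (i in seq_len(nrow(libraries$cells))) {
    if (is.na(link[i])) {
      col <- if ("archive_sample_accession" %in% libraries$header) "archive_sample_accession" else "sample_name"
      push(one_error("orphan_library", library_name, i + 1L, col,
                     sprintf("'%s' matches no row of the samples table", libraries$cells[i, col]),
                     "add the sample row, or correct the sample accession/name on this library"))
    } else if ("archive_project" %in% libraries$header && "archive_project" %in% samples$header) {
      lp <- unname(libraries$cells[i, "archive_project"])
      sp <- unname(samples$cells[link[i], "archive_project"])
      if (nzchar(lp) && nzchar(sp) && !identical(lp, sp)) {
        push(one_error("accession_project_mismatch", library_name, i + 1L, "archive_project",
                       sprintf("library project '%s' differs from its sample's project '%s' (samples line %d)",
                               lp, sp, link[i] + 1L),
                       "align the project accession with the sample row"))
      }
    }
  }
  new_report(if (length(errs)) do.call(rbind, errs))
}

#' Validate a sample/library dataset pair
#'
#' Runs, in canonical order: per-cell schema validation on both tables,
#' duplicate-key checks on both, DOI syntax on the samples table, and the
#' cross-table accession checks. `passed` is true iff every sub-report
#' passed. Identical inputs always produce an identical (byte-stable) report.
#'
#' @param samples,libraries `amdir_table`s; bound schemas are used unless
#'   `schemas` overrides them.
#' @param schemas Optional list with elements `samples` and `libraries`.
#' @param online Forwarded to [check_doi()].
#' @param patterns See [amdir_patterns()].
#' @return An `amdir_report` sorted by (table, line, column position).
#' @export
validate_dataset <- function(samples, libraries, schemas = NULL, online = FALSE,
                             patterns = amdir_patterns()) {
  s_schema <- (schemas$samples %||% samples$schema)
  l_schema <- (schemas$libraries %||% libraries$schema)
  if (is.null(s_schema) || is.null(l_schema)) {
    stop_usage("validate_dataset() needs schemas for both tables")
  }
  samples <- bind_schema(samples, s_schema)
  libraries <- bind_schema(libraries, l_schema)
  s_name <- table_label(samples, "samples")
  l_name <- table_label(libraries, "libraries")
  order_with <- stats::setNames(list(s_schema, l_schema), c(s_name, l_name))
  combine_reports(
    validate_schema(samples, table_name = s_name),
    validate_schema(libraries, table_name = l_name),
    check_duplicates(samples, table_name = s_name),
    check_duplicates(libraries, table_name = l_name),
    check_doi(samples, online = online, patterns = patterns, table_name = s_name),
    check_accessions(samples, libraries, patterns = patterns,
                     sample_name = s_name, library_name = l_name),
    order_with = order_with
  )
}
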