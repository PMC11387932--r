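# ENA portal API client for read_run reports, with a recorded transport so
# everything downstream of the HTTP boundary is replayable offline.

#' ENA filereport endpoint configuration
#'
#' The field list mirrors what a library draft needs; both endpoint and
#' fields are configuration, not hard-coded into the client.
#' @return List with `endpoint` and `fields` (character vector).
#' @export
ena_endpoint <- function() {
  list(
    endpoint = "https://www.ebi.ac.uk/ena/portal/api/filereport",
    fields = c("study_accession", "sample_accession", "run_accession",
               "library_name", "instrument_model", "library_layout",
               "library_strategy", "read_count", "fastq_ftp", "fastq_md5",
               "fastq_bytes")
  )
}

#' Construct a transport for archive queries
#'
#' `recorded` transports replay per-accession TSV files from `fixture_store`
#' and never open a network connection; `live` transports query the ENA
#' portal API with retries (3 attempts, exponential backoff on failure).
#'
#' @param mode `"recorded"` or `"live"`.
#' @param fixture_store Directory of `<accession>.tsv` files (recorded mode).
#' @return An `amdir_transport`.
#' @export
ena_transport <- function(mode = c("recorded", "live"), fixture_store = NULL) {
  mode <- match.arg(mode)
  if (mode == "recorded") {
    if (is.null(fixture_store)) stop_usage("recorded transport requires `fixture_store`")
    if (!dir.exists(fixture_store)) {
      stop_usage(sprintf("fixture store does not exist: %s", fixture_store))
    }
  }
  structure(list(mode = mode, fixture_store = fixture_store), class = "amdir_transport")
}

transport_get <- function(transport, accession) {
  if (transport$mode == "recorded") {
    path <- file.path(transport$fixture_store, paste0(accession, ".tsv"))
    if (!file.exists(path)) {
      stop_transport(sprintf("no recorded response for accession '%s' (%s)", accession, path))
    }
    txt <- readChar(path, file.size(path), useBytes = TRUE)
    Encoding(txt) <- "UTF-8"
    return(txt)
  }
  cfg <- ena_endpoint()
  u <- sprintf("%s?accession=%s&result=read_run&fields=%s&format=tsv&limit=0",
               cfg$endpoint, utils::URLencode(accession, reserved = TRUE),
               paste(cfg$fields, collapse = ","))
  last <- NULL
  for (attempt in 1:3) {
    out <- tryCatch({
      con <- url(u, method = "libcurl")
      on.exit(try(close(con), silent = TRUE), add = TRUE)
      paste(readLines(con, warn = FALSE), collapse = "\n")
    }, error = function(e) e, warning = function(w) w)
    if (is.character(out)) return(out)
    last <- out
    Sys.sleep(2^(attempt - 1))
  }
  stop_transport(sprintf("ENA query for '%s' failed after 3 attempts: %s",
                         accession, conditionMessage(last)))
}

#' Fetch the read_run report for one accession
#'
#' Returns one record per sequencing run, with the archive's
#' semicolon-separated multi-file fields (`fastq_ftp`, `fastq_md5`,
#' `fastq_bytes`) split into parallel lists. An empty report is an empty
#' result, not an error.
#'
#' @param accession INSDC project or sample accession.
#' @param transport An `amdir_transport` (see [ena_transport()]).
#' @param patterns See [amdir_patterns()].
#' @return A list of run records; each is a list with scalar fields
#'   (`study_accession`, `sample_accession`, `run_accession`,
#'   `library_name`, `instrument_model`, `library_layout`,
#'   `library_strategy`, `read_count`) and parallel character/numeric
#'   vectors `fastq_urls`, `fastq_md5`, `fastq_bytes`.
#' @export
fetch_run_report <- function(accession, transport, patterns = amdir_patterns()) {
  if (!grepl(patterns$project, accession) && !grepl(patterns$biosample, accession)) {
    stop_usage(sprintf("'%s' is not an INSDC project or sample accession", accession))
  }
  txt <- transport_get(transport, accession)
  if (!nzchar(trimws(txt))) return(list())
  tbl <- read_amdir_table(txt, provenance = sprintf("read_run:%s", accession))
  need <- ena_endpoint()$fields
  if (!all(need %in% tbl$header)) {
    stop_parse(sprintf("read_run report for '%s' lacks field(s): %s",
                       accession, paste(setdiff(need, tbl$header), collapse = ", ")))
  }
  lapply(seq_len(nrow(tbl$cells)), function(i) {
    row <- tbl$cells[i, ]
    split3 <- function(field) {
      v <- row[[field]]
      if (!nzchar(v)) character() else strsplit(v, ";", fixed = TRUE)[[1]]
    }
    rec <- list(
      study_accession = row[["study_accession"]],
      sample_accession = row[["sample_accession"]],
      run_accession = row[["run_accession"]],
      library_name = row[["library_name"]],
      instrument_model = row[["instrument_model"]],
      library_layout = row[["library_layout"]],
      library_strategy = row[["library_strategy"]],
      read_count = row[["read_count"]],
      fastq_urls = split3("fastq_ftp"),
      fastq_md5 = split3("fastq_md5"),
      fastq_bytes = split3("fastq_bytes")
    )
    lens <- lengths(rec[c("fastq_urls", "fastq_md5", "fastq_bytes")])
    if (length(unique(lens)) != 1L) {
      stop_parse(sprintf(
        "read_run report for '%s', row %d (%s): fastq url/md5/bytes lists have lengths %s",
        accession, i, rec$run_accession, paste(lens, collapse = "/")
      ))
    }
    if (length(rec$fastq_md5) && any(!grepl("^[0-9a-f]{32}$", rec$fastq_md5))) {
      stop_parse(sprintf("read_run report for '%s', row %d: malformed md5", accession, i))
    }
    rec
  })
}

# Which library-table columns the archive can fill, and from which record
# field. Everything else is ancient-DNA-specific and must come from the
# original publication.
ena_column_mapping <- function() {
  c(
    archive_project = "study_accession",
    archive_sample_accession = "sample_accession",
    archive_data_accession = "run_accession",
    library_name = "library_name",
    instrument_model = "instrument_model",
    library_layout = "library_layout",
    library_strategy = "library_strategy",
    read_count = "read_count"
  )
}

#' Map run records onto a draft library table
#'
#' Archive-derivable columns are populated from the records; columns the
#' archive cannot know — library construction method, indexing polymerase,
#' damage pretreatment, publication metadata — are set to the missing token
#' `"unknown"` and returned in `unfilled` for the submitter to complete.
#'
#' @param records List of run records from [fetch_run_report()].
#' @param kind Dataset category.
#' @return List with `draft` (schema-bound `amdir_table`, one row per
#'   record, in record order) and `unfilled` (column names left at
#'   `"unknown"`).
#' @export
map_run_to_library_draft <- function(records, kind) {
  if (!length(records)) stop_usage("no run records to map")
  schema <- amdir_schema(kind, "libraries")
  mapping <- ena_column_mapping()
  cols <- schema$columns$name
  cells <- matrix(missing_token, nrow = length(records), ncol = length(cols),
                  dimnames = list(NULL, cols))
  for (i in seq_along(records)) {
    rec <- records[[i]]
    for (col in names(mapping)) cells[i, col] <- rec[[mapping[[col]]]]
    cells[i, "archive"] <- "ENA"
    cells[i, "download_links"] <- paste(rec$fastq_urls, collapse = ";")
    cells[i, "download_md5s"] <- paste(rec$fastq_md5, collapse = ";")
    cells[i, "download_sizes"] <- paste(rec$fastq_bytes, collapse = ";")
    if (!nzchar(cells[i, "library_name"])) cells[i, "library_name"] <- rec$run_accession
  }
  filled <- c(names(mapping), "archive", "download_links", "download_md5s", "download_sizes")
  draft <- bind_schema(
    new_amdir_table(cols, cells, provenance = "ena-draft"),
    schema
  )
  list(draft = draft, unfilled = setdiff(cols, filled))
}

#' Autofill a draft library table from archive accessions
#'
#' Fetches the read_run report for every accession, maps the union of
#' records to a draft library table, and de-duplicates on run accession.
#' Order is deterministic: input accession order, then archive row order.
#' Any accession whose fetch fails aborts with a transport error naming it.
#'
#' @param accessions Character vector of project/sample accessions (>= 1).
#' @param kind Dataset category.
#' @param transport An `amdir_transport`.
#' @return List with `draft` and `unfilled`, as in
#'   [map_run_to_library_draft()].
#' @export
autofill_libraries <- function(accessions, kind, transport) {
  if (!length(accessions)) stop_usage("at least one accession is required")
  records <- list()
  for (acc in accessions) {
    recs <- tryCatch(
      fetch_run_report(acc, transport),
      amdir_transport_error = function(e) {
        stop_transport(sprintf("autofill aborted: %s", conditionMessage(e)))
      }
    )
    records <- c(records, recs)
  }
  if (!length(records)) stop_usage("no runs found for the given accession(s)")
  runs <- vapply(records, `[[`, character(1), "run_accession")
  records <- records[!duplicated(runs)]
  map_run_to_library_draft(records, kind)
}
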