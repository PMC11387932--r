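# Deterministic converters from a library selection to the artefacts a user
# actually runs: a POSIX download script with an md5 manifest, an
# nf-core/eager (2.x) input sheet, a BibTeX file, and the filtered table
# itself. Identical input bytes always give identical output bytes.

canonical_output_names <- c(
  curl = "AncientMetagenomeDir_curl_download_script.sh",
  wget = "AncientMetagenomeDir_wget_download_script.sh",
  eager = "AncientMetagenomeDir_nf_core_eager_input_table.tsv",
  bibliography = "AncientMetagenomeDir_bibliography.bib",
  librarymetadata = "AncientMetagenomeDir_filtered_libraries.tsv"
)

parse_file_lists <- function(libraries, row) {
  fields <- c("download_links", "download_md5s", "download_sizes")
  vals <- lapply(fields, function(f) {
    cell <- libraries$cells[row, f]
    if (!nzchar(cell)) character() else strsplit(cell, ";", fixed = TRUE)[[1]]
  })
  names(vals) <- fields
  if (length(unique(lengths(vals))) != 1L) {
    stop_conversion(sprintf(
      "data line %d: download_links/md5s/sizes have lengths %s; they must be parallel",
      row + 1L, paste(lengths(vals), collapse = "/")
    ))
  }
  vals
}

#' Generate a FASTQ download script
#'
#' One fetch command per FASTQ file of every library row (row order, then
#' position within the row's URL list), followed by an md5 verification
#' block that checks every downloaded file exactly once. Local file names
#' are the URL basenames. The script is plain POSIX-compatible shell.
#'
#' @param libraries Libraries `amdir_table` (needs the download columns).
#' @param tool `"curl"` or `"wget"`.
#' @return An `amdir_download_script`: list with `tool`, `lines` (the
#'   script, one element per line), and `manifest` (data frame: filename,
#'   url, md5, bytes).
#' @export
make_download_script <- function(libraries, tool = c("curl", "wget")) {
  tool <- match.arg(tool)
  stopifnot(inherits(libraries, "amdir_table"))
  need <- c("download_links", "download_md5s", "download_sizes")
  if (!all(need %in% libraries$header)) {
    stop_usage(sprintf("libraries table lacks column(s): %s",
                       paste(setdiff(need, libraries$header), collapse = ", ")))
  }
  manifest <- list()
  for (i in seq_len(nrow(libraries$cells))) {
    lists <- parse_file_lists(libraries, i)
    if (!length(lists$download_links)) next
    manifest[[length(manifest) + 1L]] <- data.frame(
      filename = basename(lists$download_links),
      url = lists$download_links,
      md5 = lists$download_md5s,
      bytes = as.numeric(lists$download_sizes),
      stringsAsFactors = FALSE
    )
  }
  manifest <- if (length(manifest)) do.call(rbind, manifest) else {
    data.frame(filename = character(), url = character(), md5 = character(),
               bytes = numeric(), stringsAsFactors = FALSE)
  }
  rownames(manifest) <- NULL

  fetch <- if (tool == "curl") {
    sprintf("curl -L -o '%s' '%s'", manifest$filename, manifest$url)
  } else {
    sprintf("wget -O '%s' '%s'", manifest$filename, manifest$url)
  }
  lines <- c(
    "#!/usr/bin/env bash",
    "set -euo pipefail",
    "",
    "# Fetch all selected FASTQ files",
    fetch,
    "",
    "# Verify md5 checksums",
    "cat <<'EOF' > AncientMetagenomeDir_md5sums.txt",
    sprintf("%s  %s", manifest$md5, manifest$filename),
    "EOF",
    "md5sum -c AncientMetagenomeDir_md5sums.txt"
  )
  structure(list(tool = tool, lines = lines, manifest = manifest),
            class = "amdir_download_script")
}

#' @export
print.amdir_download_script <- function(x, ...) {
  cat(sprintf("<download script> %s, %d files, %.2f GB\n",
              x$tool, nrow(x$manifest), sum(x$manifest$bytes) / 1e9))
  invisible(x)
}

#' Render a download script as text
#' @param script An `amdir_download_script`.
#' @param path Optional output file (written byte-stable with LF endings).
#' @return Script text (invisibly when written).
#' @export
write_download_script <- function(script, path = NULL) {
  txt <- paste0(paste(script$lines, collapse = "\n"), "\n")
  if (is.null(path)) return(txt)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeChar(txt, con, eos = NULL, useBytes = TRUE)
  invisible(txt)
}

#' Instrument model to Illumina colour chemistry
#'
#' Two-colour platforms (NextSeq/NovaSeq families) call G as 'no signal'
#' and therefore produce spurious poly-G tails on inserts shorter than the
#' read length — exactly the regime of degraded ancient DNA — so downstream
#' pipelines must know the chemistry to decide on poly-G trimming.
#'
#' @param model Instrument model string.
#' @param rules Ordered named list mapping regular expressions to chemistry
#'   (2 or 4); user-extendable for new platforms.
#' @return Integer 2 or 4.
#' @export
instrument_chemistry <- function(model, rules = chemistry_rules()) {
  for (pat in names(rules)) {
    if (grepl(pat, model, ignore.case = TRUE)) return(rules[[pat]])
  }
  stop_conversion(sprintf(
    "no colour-chemistry rule matches instrument '%s'; extend `rules` (see chemistry_rules())",
    model
  ))
}

#' Default colour-chemistry rules
#' @return Named list of regex -> chemistry.
#' @export
chemistry_rules <- function() {
  list("NextSeq" = 2L, "NovaSeq" = 2L, "HiSeq" = 4L, "MiSeq" = 4L,
       "Genome Analyzer" = 4L)
}

eager_columns <- c("Sample_Name", "Library_ID", "Lane", "Colour_Chemistry",
                   "SeqType", "Organism", "Strandedness", "UDG_Treatment",
                   "R1", "R2", "BAM")

#' Generate an nf-core/eager input sheet
#'
#' One row per library of the samples' selection, in the column order of
#' the nf-core/eager 2.x input contract. Paired-end libraries take R1/R2
#' from the first two FASTQ URLs; single-end libraries get `R2 = NA`.
#' Damage pretreatment maps directly onto `UDG_Treatment`
#' (none/half/full); an `unknown` pretreatment is conservatively written as
#' `none` — never silently trimming possible damage — with a warning.
#' Lanes are numbered sequentially per sample in library order (archives do
#' not expose lanes). The sheet is a template: it must be reviewed against
#' the pipeline's expectations before use.
#'
#' @param samples Samples `amdir_table` (source of the organism column).
#' @param libraries Libraries `amdir_table`, joinable to `samples`.
#' @param rules Colour-chemistry rules, see [chemistry_rules()].
#' @param local_paths Use local basenames for R1/R2 (pairing with the
#'   download script) instead of the remote URLs.
#' @return The sheet as TSV text.
#' @export
make_eager_sheet <- function(samples, libraries, rules = chemistry_rules(),
                             local_paths = FALSE) {
  stopifnot(inherits(samples, "amdir_table"), inherits(libraries, "amdir_table"))
  link <- link_libraries_to_samples(samples, libraries)
  lanes <- if (nrow(libraries$cells)) {
    stats::ave(seq_len(nrow(libraries$cells)),
               libraries$cells[, "sample_name"], FUN = seq_along)
  } else {
    integer()
  }
  warned_udg <- FALSE
  rows <- lapply(seq_len(nrow(libraries$cells)), function(i) {
    lib <- libraries$cells[i, ]
    lists <- parse_file_lists(libraries, i)
    urls <- if (local_paths) basename(lists$download_links) else lists$download_links
    paired <- identical(lib[["library_layout"]], "PAIRED")
    if (paired && length(urls) < 2L) {
      stop_conversion(sprintf("data line %d: PAIRED layout but fewer than two FASTQ URLs", i + 1L))
    }
    udg <- lib[["library_treatment"]]
    if (identical(udg, missing_token)) {
      if (!warned_udg) {
        warning("unknown library pretreatment mapped to UDG_Treatment 'none'; review before trimming damage",
                call. = FALSE)
        warned_udg <<- TRUE
      }
      udg <- "none"
    }
    organism <- if (!is.na(link[i]) && "sample_host" %in% samples$header) {
      samples$cells[link[i], "sample_host"]
    } else {
      "NA"
    }
    c(
      Sample_Name = lib[["sample_name"]],
      Library_ID = lib[["library_name"]],
      Lane = as.character(lanes[i]),
      Colour_Chemistry = as.character(instrument_chemistry(lib[["instrument_model"]], rules)),
      SeqType = if (paired) "PE" else "SE",
      Organism = organism,
      Strandedness = lib[["strand_type"]],
      UDG_Treatment = udg,
      R1 = if (length(urls)) urls[1] else "NA",
      R2 = if (paired) urls[2] else "NA",
      BAM = "NA"
    )
  })
  cells <- if (length(rows)) do.call(rbind, rows) else {
    matrix(character(), 0L, length(eager_columns), dimnames = list(NULL, eager_columns))
  }
  write_amdir_table(new_amdir_table(eager_columns, cells, provenance = "eager-sheet"))
}

doi_to_bibkey <- function(doi) {
  paste0("ref_", gsub("[^A-Za-z0-9]+", "_", doi))
}

#' Generate a BibTeX bibliography for a sample selection
#'
#' One entry per distinct publication DOI, sorted by citation key. Offline
#' mode (the default) emits minimal entries (key, doi, url); online mode
#' fills bibliographic fields via DOI content negotiation and degrades to
#' the offline entry, with a warning, when resolution fails.
#'
#' @param samples_subset Samples `amdir_table` with a `publication_doi`
#'   column.
#' @param mode `"offline"` or `"online"`.
#' @return BibTeX text ("" for an empty selection).
#' @export
make_bibliography <- function(samples_subset, mode = c("offline", "online")) {
  mode <- match.arg(mode)
  stopifnot(inherits(samples_subset, "amdir_table"))
  if (!"publication_doi" %in% samples_subset$header) {
    stop_usage("samples table has no 'publication_doi' column")
  }
  dois <- samples_subset$cells[, "publication_doi"]
  dois <- unique(dois[nzchar(dois) & dois != missing_token])
  if (!length(dois)) return("")
  entries <- vapply(dois, function(doi) {
    fetched <- NULL
    if (mode == "online") {
      fetched <- tryCatch(fetch_bibtex(doi), error = function(e) {
        warning(sprintf("could not resolve '%s' online; writing minimal entry", doi), call. = FALSE)
        NULL
      })
    }
    fetched %||% paste0(
      "@misc{", doi_to_bibkey(doi), ",\n",
      "  doi = {", doi, "},\n",
      "  url = {https://doi.org/", doi, "}\n",
      "}"
    )
  }, character(1))
  keys <- vapply(dois, doi_to_bibkey, character(1))
  paste0(paste(entries[order(keys)], collapse = "\n\n"), "\n")
}

fetch_bibtex <- function(doi) {
  con <- url(paste0("https://doi.org/", doi),
             headers = c(Accept = "application/x-bibtex"))
  on.exit(try(close(con), silent = TRUE))
  paste(readLines(con, warn = FALSE), collapse = "\n")
}

#' Write the conversion artefacts for a selection
#'
#' Writes, under their canonical file names, any of: the download script
#' (`curl`/`wget`), the nf-core/eager input sheet (`eager`), the BibTeX
#' file (`bibliography`), and the filtered libraries table
#' (`librarymetadata`). Reruns on identical input produce byte-identical
#' files.
#'
#' @param samples,libraries `amdir_table`s (the selection).
#' @param outdir Output directory (created if needed).
#' @param what Subset of `c("curl", "wget", "eager", "bibliography",
#'   "librarymetadata")`.
#' @param bib_mode Forwarded to [make_bibliography()].
#' @return Invisibly, the written paths.
#' @export
export_tables <- function(samples, libraries, outdir,
                          what = c("curl", "eager", "bibliography", "librarymetadata"),
                          bib_mode = "offline") {
  bad <- setdiff(what, names(canonical_output_names))
  if (length(bad)) stop_usage(sprintf("unknown artefact(s): %s", paste(bad, collapse = ", ")))
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  if (!dir.exists(outdir)) stop_usage(sprintf("cannot create output directory %s", outdir))
  write_bytes <- function(txt, path) {
    con <- file(path, open = "wb")
    on.exit(close(con))
    writeChar(txt, con, eos = NULL, useBytes = TRUE)
  }
  paths <- character()
  for (w in what) {
    path <- file.path(outdir, canonical_output_names[[w]])
    switch(w,
      curl = write_download_script(make_download_script(libraries, "curl"), path),
      wget = write_download_script(make_download_script(libraries, "wget"), path),
      eager = write_bytes(make_eager_sheet(samples, libraries), path),
      bibliography = write_bytes(make_bibliography(samples, mode = bib_mode), path),
      librarymetadata = write_amdir_table(libraries, path)
    )
    paths[w] <- path
  }
  invisible(paths)
}

#' Merge a new table into an existing one
#'
#' Appends the rows of `new` after `existing`. Headers must be identical;
#' any row of `new` whose key tuple already exists is a merge error naming
#' the offending keys (nothing is merged in that case).
#'
#' @param existing,new `amdir_table`s with identical headers.
#' @param schema Schema providing the key columns; defaults to the bound
#'   schema of `existing`.
#' @return The merged `amdir_table`.
#' @export
merge_tables <- function(existing, new, schema = NULL) {
  stopifnot(inherits(existing, "amdir_table"), inherits(new, "amdir_table"))
  schema <- schema %||% existing$schema
  if (is.null(schema)) stop_usage("merge_tables() needs a schema for the key columns")
  if (!identical(existing$header, new$header)) {
    stop_merge("header mismatch between existing and new tables")
  }
  keys <- schema$key_columns
  if (length(keys) && nrow(new$cells) && nrow(existing$cells)) {
    old_keys <- apply(existing$cells[, keys, drop = FALSE], 1L, paste, collapse = "\x1f")
    new_keys <- apply(new$cells[, keys, drop = FALSE], 1L, paste, collapse = "\x1f")
    clash <- new_keys %in% old_keys
    if (any(clash)) {
      shown <- apply(new$cells[clash, keys, drop = FALSE], 1L, paste, collapse = "/")
      stop_merge(sprintf("new rows duplicate existing key(s): %s",
                         paste(utils::head(shown, 10L), collapse = ", ")))
    }
  }
  out <- existing
  out$cells <- rbind(existing$cells, new$cells)
  out$provenance <- sprintf("merge(%s + %s)", table_label(existing), table_label(new))
  out
}
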