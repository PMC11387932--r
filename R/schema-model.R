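#' Dataset categories of the AncientMetagenomeDir dialect
#'
#' The directory tracks three categories of ancient datasets, each stored in
#' its own top-level directory of a release: host-associated shotgun
#' metagenomes, host-associated microbial single genomes, and environmental
#' (sediment) metagenomes.
#'
#' @return A data frame with columns `identifier` and `dir_name`, one row per
#'   dataset category.
#' @examples
#' dataset_kinds()
#' @export
dataset_kinds <- function() {
  data.frame(
    identifier = c(
      "host_associated_metagenome",
      "host_associated_singlegenome",
      "environmental_metagenome"
    ),
    dir_name = c(
      "ancientmetagenome-hostassociated",
      "ancientsinglegenome-hostassociated",
      "ancientmetagenome-environmental"
    ),
    stringsAsFactors = FALSE
  )
}

#' Resolve a dataset category
#'
#' Accepts either the short identifier (e.g. `"host_associated_metagenome"`)
#' or the canonical directory name (e.g. `"ancientmetagenome-hostassociated"`).
#'
#' @param x Identifier or directory name.
#' @return A list with `identifier` and `dir_name`.
#' @export
dataset_kind <- function(x) {
  kinds <- dataset_kinds()
  i <- match(x, kinds$identifier)
  if (is.na(i)) i <- match(x, kinds$dir_name)
  if (is.na(i)) {
    stop_usage(sprintf(
      "unknown dataset kind '%s'; expected one of: %s",
      x, paste(c(kinds$identifier, kinds$dir_name), collapse = ", ")
    ))
  }
  list(identifier = kinds$identifier[i], dir_name = kinds$dir_name[i])
}

#' Parse a release tag
#'
#' Release tags follow `v<YY>.<MM>[.<patch>]`, e.g. `"v24.03.0"`.
#'
#' @param tag Release tag string.
#' @return A list with `tag`, `year`, `month`, `patch` (patch `NA` when absent).
#' @export
parse_release_tag <- function(tag) {
  m <- regmatches(tag, regexec("^v([0-9]{2})\\.([0-9]{2})(?:\\.([0-9]+))?$", tag))[[1]]
  if (length(m) == 0L) {
    stop_usage(sprintf("malformed release tag '%s'; expected v<YY>.<MM>[.<patch>]", tag))
  }
  list(
    tag = tag,
    year = as.integer(m[2]),
    month = as.integer(m[3]),
    patch = if (m[4] == "") NA_integer_ else as.integer(m[4])
  )
}

valid_value_kinds <- c(
  "free_text", "integer", "number", "doi", "accession_list",
  "url_list", "md5_list", "byte_size_list", "enum"
)

#' Load a table schema from JSON documents
#'
#' A schema document declares the table type, dataset category, and ordered
#' column definitions; controlled vocabularies are supplied as separate JSON
#' enum documents and resolved by name. Schemas are data, not code: the
#' package ships its own under `system.file("extdata", "schemas", ...)` but
#' any conforming documents can be loaded.
#'
#' @param schema_json Path to, or literal text of, a schema JSON document.
#' @param enums Named list of enum vocabularies. Each element is either a
#'   character vector of allowed tokens, or a path to / text of a JSON array.
#' @return An object of class `amdir_schema`: a list with `dataset_kind`,
#'   `table_type`, `columns` (data frame: name, position, required,
#'   value_kind, enum_ref, missing_token_allowed), `key_columns`, `enums`.
#' @export
load_schema <- function(schema_json, enums = list()) {
  doc <- parse_json_document(schema_json, what = "schema document")
  for (field in c("dataset", "table_type", "columns")) {
    if (is.null(doc[[field]])) {
      stop_schema(sprintf("schema document lacks required field '%s'", field))
    }
  }
  if (!doc$table_type %in% c("samples", "libraries")) {
    stop_schema(sprintf("table_type must be 'samples' or 'libraries', got '%s'", doc$table_type))
  }
  kind <- dataset_kind(doc$dataset)
  cols <- doc$columns
  if (is.data.frame(cols)) {
    cols <- lapply(seq_len(nrow(cols)), function(i) as.list(cols[i, , drop = FALSE]))
  }
  if (length(cols) == 0L) stop_schema("schema document declares zero columns")

  vocab <- lapply(enums, function(e) {
    if (is.character(e) && length(e) == 1L && (file.exists(e) || grepl("^\\s*\\[", e))) {
      e <- parse_json_document(e, what = "enum document")
    }
    vals <- as.character(unlist(e, use.names = FALSE))
    if (anyDuplicated(vals) || any(!nzchar(vals))) {
      stop_schema("enum vocabulary values must be unique non-empty strings")
    }
    vals
  })

  spec <- data.frame(
    name = vapply(cols, function(cc) as.character(cc$name %||% NA_character_), character(1)),
    position = seq_along(cols),
    required = vapply(cols, function(cc) isTRUE(cc$required %||% TRUE), logical(1)),
    value_kind = vapply(cols, function(cc) as.character(cc$value_kind %||% "free_text"), character(1)),
    enum_ref = vapply(cols, function(cc) as.character(cc$enum %||% ""), character(1)),
    missing_token_allowed = vapply(
      cols, function(cc) isTRUE(cc$missing_token_allowed %||% FALSE), logical(1)
    ),
    stringsAsFactors = FALSE
  )
  if (anyNA(spec$name) || any(!nzchar(spec$name))) {
    stop_schema("every column definition needs a non-empty 'name'")
  }
  if (anyDuplicated(spec$name)) {
    stop_schema(sprintf("duplicated column name(s): %s",
                        paste(unique(spec$name[duplicated(spec$name)]), collapse = ", ")))
  }
  bad_kind <- setdiff(spec$value_kind, valid_value_kinds)
  if (length(bad_kind)) {
    stop_schema(sprintf("unknown value_kind(s): %s", paste(bad_kind, collapse = ", ")))
  }
  mismatch <- xor(spec$value_kind == "enum", nzchar(spec$enum_ref))
  if (any(mismatch)) {
    stop_schema(sprintf(
      "column(s) %s: 'enum' reference must be present iff value_kind is 'enum'",
      paste(spec$name[mismatch], collapse = ", ")
    ))
  }
  dangling <- setdiff(spec$enum_ref[nzchar(spec$enum_ref)], names(vocab))
  if (length(dangling)) {
    stop_schema(sprintf("unresolved enum reference(s): %s", paste(dangling, collapse = ", ")))
  }
  # Enum columns always admit the canonical missing token when the vocabulary
  # itself carries it; numeric/text columns need the explicit flag.
  key_columns <- as.character(doc$key_columns %||% character())
  if (length(key_columns) && !all(key_columns %in% spec$name)) {
    stop_schema("key_columns must be a subset of the declared column names")
  }

  structure(
    list(
      dataset_kind = kind,
      table_type = doc$table_type,
      columns = spec,
      key_columns = key_columns,
      enums = vocab[unique(spec$enum_ref[nzchar(spec$enum_ref)])]
    ),
    class = "amdir_schema"
  )
}

parse_json_document <- function(x, what = "JSON document") {
  label <- if (is.character(x) && length(x) == 1L && file.exists(x)) x else sprintf("inline %s", what)
  out <- tryCatch(
    jsonlite::fromJSON(x, simplifyDataFrame = FALSE),
    error = function(e) stop_parse(sprintf("malformed JSON in %s: %s", label, conditionMessage(e)))
  )
  out
}

#' @export
print.amdir_schema <- function(x, ...) {
  cat(sprintf(
    "<amdir_schema> %s / %s: %d columns (keys: %s)\n",
    x$dataset_kind$dir_name, x$table_type, nrow(x$columns),
    if (length(x$key_columns)) paste(x$key_columns, collapse = ", ") else "none"
  ))
  invisible(x)
}

#' Load a shipped AncientMetagenomeDir schema
#'
#' Convenience wrapper over [load_schema()] for the schema documents bundled
#' with the package.
#'
#' @param kind Dataset category (identifier or directory name).
#' @param table_type `"samples"` or `"libraries"`.
#' @param schema_dir Optional override directory laid out like the shipped
#'   `extdata/schemas` tree (per-category subdirectories plus a shared
#'   `enums/` directory).
#' @return An `amdir_schema`.
#' @export
amdir_schema <- function(kind, table_type = c("samples", "libraries"), schema_dir = NULL) {
  table_type <- match.arg(table_type)
  kind <- dataset_kind(kind)
  root <- schema_dir %||% system.file("extdata", "schemas", package = "amdirtools")
  path <- file.path(root, kind$dir_name, paste0(table_type, ".json"))
  if (!file.exists(path)) {
    stop_usage(sprintf("no schema document at %s", path))
  }
  load_schema(path, enums = load_enum_dir(file.path(root, "enums")))
}

load_enum_dir <- function(dir) {
  if (!dir.exists(dir)) return(list())
  files <- list.files(dir, pattern = "\\.json$", full.names = TRUE)
  vocab <- lapply(files, function(f) parse_json_document(f, "enum document"))
  names(vocab) <- tools::file_path_sans_ext(basename(files))
  vocab
}

# ---- tables -----------------------------------------------------------------

missing_token <- "unknown"

new_amdir_table <- function(header, cells, provenance = "in-memory", schema = NULL) {
  if (is.null(dim(cells))) {
    cells <- matrix(cells, ncol = length(header), byrow = TRUE)
  }
  colnames(cells) <- header
  structure(
    list(header = header, cells = cells, provenance = provenance, schema = schema),
    class = "amdir_table"
  )
}

#' Construct a metadata table from a data frame or character matrix
#'
#' All cells are carried as strings: the dialect is typed by the schema, not
#' by the container.
#'
#' @param x Data frame or character matrix with column names.
#' @param provenance Free-text source label.
#' @param schema Optional `amdir_schema` to bind (header must match).
#' @return An `amdir_table`.
#' @export
as_amdir_table <- function(x, provenance = "in-memory", schema = NULL) {
  if (is.data.frame(x)) {
    x <- vapply(x, as.character, character(nrow(x)))
    if (is.null(dim(x))) x <- matrix(x, nrow = 1L, dimnames = list(NULL, names(x) %||% colnames(x)))
  }
  if (!is.matrix(x) || is.null(colnames(x))) {
    stop_usage("as_amdir_table() needs a data frame or a character matrix with column names")
  }
  storage.mode(x) <- "character"
  x[is.na(x)] <- ""
  tbl <- new_amdir_table(colnames(x), x, provenance = provenance)
  if (!is.null(schema)) tbl <- bind_schema(tbl, schema) else tbl
}

#' Number of data rows in a metadata table
#' @param table An `amdir_table`.
#' @return Integer row count (header excluded).
#' @export
n_rows <- function(table) nrow(table$cells)

#' Bind a schema to a metadata table
#'
#' Binding is order-sensitive: the table header must equal the schema's
#' column names in order, otherwise a schema-binding error lists the missing,
#' extra, and misplaced columns.
#'
#' @param table An `amdir_table`.
#' @param schema An `amdir_schema`.
#' @return The table with `$schema` set.
#' @export
bind_schema <- function(table, schema) {
  stopifnot(inherits(table, "amdir_table"), inherits(schema, "amdir_schema"))
  want <- schema$columns$name
  have <- table$header
  if (!identical(have, want)) {
    missing <- setdiff(want, have)
    extra <- setdiff(have, want)
    moved <- intersect(want, have)
    moved <- moved[match(moved, want) != match(moved, have)]
    stop_schema(sprintf(
      "header does not match schema '%s/%s': missing [%s]; extra [%s]; out of order [%s]",
      schema$dataset_kind$dir_name, schema$table_type,
      paste(missing, collapse = ", "), paste(extra, collapse = ", "),
      paste(moved, collapse = ", ")
    ))
  }
  table$schema <- schema
  table
}

#' Read a metadata table in the AncientMetagenomeDir TSV dialect
#'
#' The dialect is deliberately rigid for byte-stable diffs: UTF-8, LF line
#' endings, tab separator, no quoting or escaping, mandatory header row,
#' trailing newline. Ragged rows are structural errors reported with their
#' 1-based line number (the header is line 1).
#'
#' @param x Path to a file, or literal TSV text (anything containing a
#'   newline is treated as text).
#' @param schema Optional `amdir_schema` to bind after reading.
#' @param provenance Source label; defaults to the path for files.
#' @return An `amdir_table`.
#' @export
read_amdir_table <- function(x, schema = NULL, provenance = NULL) {
  if (length(x) == 1L && !grepl("\n", x, fixed = TRUE)) {
    if (!file.exists(x)) stop_usage(sprintf("no such file: %s", x))
    txt <- readChar(x, file.size(x), useBytes = TRUE)
    Encoding(txt) <- "UTF-8"
    if (!validUTF8(txt)) stop_structural(sprintf("%s is not valid UTF-8", x))
    provenance <- provenance %||% x
  } else {
    txt <- paste(x, collapse = "\n")
    provenance <- provenance %||% "text"
  }
  txt <- gsub("\r\n", "\n", txt, fixed = TRUE)
  lines <- strsplit(txt, "\n", fixed = TRUE)[[1]]
  # A trailing newline yields no phantom row; interior empty lines are skipped
  # but tracked so error line numbers still match the file.
  if (length(lines) == 0L || !nzchar(lines[1])) {
    stop_structural(sprintf("%s: missing header row", provenance))
  }
  split_tsv <- function(line) {
    # strsplit drops trailing empty fields; the sentinel keeps them.
    parts <- strsplit(paste0(line, "\x01"), "\t", fixed = TRUE)[[1]]
    parts[length(parts)] <- sub("\x01$", "", parts[length(parts)])
    parts
  }
  header <- split_tsv(lines[1])
  body_idx <- which(seq_along(lines) > 1L & nzchar(lines))
  rows <- lapply(body_idx, function(i) {
    cells <- split_tsv(lines[i])
    if (length(cells) != length(header)) {
      stop_structural(sprintf(
        "%s: line %d has %d fields, expected %d", provenance, i, length(cells), length(header)
      ))
    }
    cells
  })
  cells <- if (length(rows)) do.call(rbind, rows) else matrix(character(), 0L, length(header))
  tbl <- new_amdir_table(header, cells, provenance = provenance)
  if (!is.null(schema)) bind_schema(tbl, schema) else tbl
}

#' Serialize a metadata table to the TSV dialect
#'
#' Inverse of [read_amdir_table()]: the round trip is byte-identical for any
#' table in the dialect. Cells containing tabs or newlines cannot be
#' represented and raise a serialization error naming the offending cell.
#'
#' @param table An `amdir_table`.
#' @param path Optional output file; when `NULL` the TSV text is returned.
#' @return The TSV text (invisibly when written to `path`).
#' @export
write_amdir_table <- function(table, path = NULL) {
  stopifnot(inherits(table, "amdir_table"))
  bad <- which(grepl("[\t\n]", table$cells), arr.ind = TRUE)
  if (nrow(table$cells) && length(bad)) {
    bad <- which(matrix(grepl("[\t\n]", table$cells), nrow(table$cells)), arr.ind = TRUE)
    stop_serialization(sprintf(
      "cell at data row %d, column '%s' contains a tab or newline",
      bad[1, 1], table$header[bad[1, 2]]
    ))
  }
  if (any(grepl("[\t\n]", table$header))) {
    stop_serialization("header names may not contain tabs or newlines")
  }
  body <- if (nrow(table$cells)) {
    apply(table$cells, 1L, paste, collapse = "\t")
  } else {
    character()
  }
  txt <- paste0(paste(c(paste(table$header, collapse = "\t"), body), collapse = "\n"), "\n")
  if (is.null(path)) return(txt)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeChar(txt, con, eos = NULL, useBytes = TRUE)
  invisible(txt)
}

#' @export
print.amdir_table <- function(x, ...) {
  cat(sprintf(
    "<amdir_table> %d columns x %d rows (%s)%s\n",
    length(x$header), nrow(x$cells), x$provenance,
    if (!is.null(x$schema)) {
      sprintf(" [schema: %s/%s]", x$schema$dataset_kind$dir_name, x$schema$table_type)
    } else {
      ""
    }
  ))
  if (nrow(x$cells)) {
    show <- utils::head(as.data.frame(x$cells[, seq_len(min(5L, length(x$header))), drop = FALSE],
                                      stringsAsFactors = FALSE), 5L)
    print(show)
    if (nrow(x$cells) > 5L || length(x$header) > 5L) cat("...\n")
  }
  invisible(x)
}

release_asset_name <- function(kind, table_type, tag) {
  sprintf("%s_%s_%s.tsv", kind$dir_name, table_type, tag)
}

#' Fetch a released metadata table
#'
#' Resolves the `<dir_name>_<table_type>_<tag>.tsv` asset of a tagged
#' release, either from a local directory mirroring the release layout or
#' over HTTPS from the release archive.
#'
#' @param kind Dataset category (identifier or directory name).
#' @param table_type `"samples"` or `"libraries"`.
#' @param release Release tag, e.g. `"v24.03.0"`.
#' @param source `"local_dir"` or `"remote"`.
#' @param dir Directory holding release assets (for `source = "local_dir"`).
#' @param base_url Base URL of the release store (for `source = "remote"`);
#'   the asset name is appended.
#' @param schema Optional schema to bind to the parsed table.
#' @return An `amdir_table` with provenance recording the resolved source.
#' @export
resolve_release_table <- function(kind, table_type = c("samples", "libraries"),
                                  release, source = c("local_dir", "remote"),
                                  dir = NULL, base_url = amdir_release_base_url(),
                                  schema = NULL) {
  table_type <- match.arg(table_type)
  source <- match.arg(source)
  kind <- dataset_kind(kind)
  tag <- parse_release_tag(release)$tag
  asset <- release_asset_name(kind, table_type, tag)
  if (source == "local_dir") {
    if (is.null(dir)) stop_usage("source = 'local_dir' requires `dir`")
    path <- file.path(dir, asset)
    if (!file.exists(path)) {
      stop_release(sprintf("release asset not found: %s (unknown tag '%s'?)", path, tag))
    }
    return(read_amdir_table(path, schema = schema))
  }
  url <- paste0(sub("/$", "", base_url), "/", asset)
  dest <- tempfile(fileext = ".tsv")
  ok <- tryCatch(
    utils::download.file(url, dest, quiet = TRUE, mode = "wb"),
    error = function(e) stop_transport(sprintf("failed to fetch %s: %s", url, conditionMessage(e))),
    warning = function(w) stop_transport(sprintf("failed to fetch %s: %s", url, conditionMessage(w)))
  )
  if (!identical(ok, 0L)) stop_transport(sprintf("failed to fetch %s (status %s)", url, ok))
  read_amdir_table(dest, schema = schema, provenance = url)
}

#' Default remote release store
#'
#' The released datasets are archived on Zenodo; the default points at the
#' pinned v24.03 ("Monticello") record. Override per call for other releases
#' or mirrors.
#' @return Base URL string.
#' @export
amdir_release_base_url <- function() {
  "https://zenodo.org/records/10942606/files"
}
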