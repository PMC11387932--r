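# Headless filtering with the semantics of the interactive table viewer:
# per-column clause chains combined left-to-right with explicit AND/OR,
# and the per-column results combined with AND across columns.

filter_ops <- c("eq", "ne", "lt", "le", "gt", "ge", "contains", "in_set")

#' Build a filter predicate
#'
#' @param column Column name.
#' @param op One of `eq`, `ne`, `lt`, `le`, `gt`, `ge`, `contains`,
#'   `in_set`. The ordered comparisons are numeric; `contains` is a
#'   case-sensitive substring test; `in_set` takes a character vector.
#' @param operand Comparison value (character vector for `in_set`).
#' @param connective `"AND"` or `"OR"`, linking this clause to the previous
#'   clause *of the same column* (ignored for a column's first clause).
#' @return An `amdir_predicate`.
#' @export
predicate <- function(column, op, operand, connective = "AND") {
  if (!op %in% filter_ops) {
    stop_usage(sprintf("unknown operator '%s'; expected one of: %s",
                       op, paste(filter_ops, collapse = ", ")))
  }
  if (!connective %in% c("AND", "OR")) stop_usage("connective must be 'AND' or 'OR'")
  structure(list(column = column, op = op, operand = operand, connective = connective),
            class = "amdir_predicate")
}

#' Parse a compact filter-expression string
#'
#' Grammar: clauses separated by `&` (AND) or `|` (OR); each clause is
#' `column OP value` with `OP` one of `>=`, `<=`, `!=`, `==`, `=`, `>`,
#' `<`, `~` (contains). The connective written before a clause binds it to
#' the previous clause of the same column. Example:
#' `"publication_year>=2020 & geo_loc_name=Spain"`.
#'
#' @param text Expression string ("" selects all rows).
#' @return A list of `amdir_predicate`s (an `amdir_filter`).
#' @export
parse_filter_expression <- function(text) {
  text <- trimws(text)
  if (!nzchar(text)) return(structure(list(), class = "amdir_filter"))
  # manual scan so each clause keeps the connective written before it
  parts <- list()
  buf <- ""
  conns <- character()
  conn <- "AND"
  for (ch in strsplit(text, "")[[1]]) {
    if (ch %in% c("&", "|")) {
      parts[[length(parts) + 1L]] <- buf
      conns[length(parts)] <- conn
      conn <- if (ch == "&") "AND" else "OR"
      buf <- ""
    } else {
      buf <- paste0(buf, ch)
    }
  }
  parts[[length(parts) + 1L]] <- buf
  conns[length(parts)] <- conn

  op_map <- c(">=" = "ge", "<=" = "le", "!=" = "ne", "==" = "eq",
              "~" = "contains", ">" = "gt", "<" = "lt", "=" = "eq")
  preds <- lapply(seq_along(parts), function(i) {
    clause <- trimws(parts[[i]])
    m <- regmatches(clause, regexec("^([A-Za-z0-9_]+)\\s*(>=|<=|!=|==|~|>|<|=)\\s*(.*)$", clause))[[1]]
    if (length(m) == 0L) stop_usage(sprintf("cannot parse filter clause '%s'", clause))
    predicate(m[2], op_map[[m[3]]], trimws(m[4]), connective = conns[i])
  })
  structure(preds, class = "amdir_filter")
}

eval_predicate <- function(pred, cells) {
  x <- cells[, pred$column]
  switch(pred$op,
    eq = x == pred$operand,
    ne = x != pred$operand,
    contains = grepl(pred$operand, x, fixed = TRUE),
    in_set = x %in% pred$operand,
    {
      # ordered numeric comparisons; unparseable cells and the missing token
      # never satisfy a numeric predicate
      xv <- suppressWarnings(as.numeric(x))
      ov <- suppressWarnings(as.numeric(pred$operand))
      if (is.na(ov)) stop_usage(sprintf("operand '%s' of a numeric comparison is not a number", pred$operand))
      xv[x == missing_token] <- NA
      res <- switch(pred$op, lt = xv < ov, le = xv <= ov, gt = xv > ov, ge = xv >= ov)
      res & !is.na(res)
    }
  )
}

#' Filter a metadata table
#'
#' Keeps rows for which the expression evaluates true; header and original
#' row order are preserved, and the empty expression selects all rows.
#'
#' @param table An `amdir_table`.
#' @param expr An `amdir_filter`, a list of `amdir_predicate`s, or a string
#'   for [parse_filter_expression()].
#' @return The filtered `amdir_table`.
#' @export
filter_table <- function(table, expr) {
  stopifnot(inherits(table, "amdir_table"))
  if (is.character(expr)) expr <- parse_filter_expression(expr)
  if (inherits(expr, "amdir_predicate")) expr <- list(expr)
  unknown <- setdiff(unique(vapply(expr, `[[`, character(1), "column")), table$header)
  if (length(unknown)) {
    stop_usage(sprintf("unknown column(s) %s; available: %s",
                       paste(unknown, collapse = ", "), paste(table$header, collapse = ", ")))
  }
  if (!length(expr) || nrow(table$cells) == 0L) {
    keep <- rep(TRUE, nrow(table$cells))
  } else {
    cols <- vapply(expr, `[[`, character(1), "column")
    keep <- rep(TRUE, nrow(table$cells))
    for (col in unique(cols)) {
      idx <- which(cols == col)
      acc <- eval_predicate(expr[[idx[1]]], table$cells)
      for (i in idx[-1]) {
        v <- eval_predicate(expr[[i]], table$cells)
        acc <- if (expr[[i]]$connective == "AND") acc & v else acc | v
      }
      keep <- keep & acc
    }
  }
  out <- table
  out$cells <- table$cells[keep, , drop = FALSE]
  out
}

#' Select the library rows of retained samples
#'
#' Applies the standard sample/library linkage (archive sample accession
#' when available, else exact sample name) and returns exactly the library
#' rows whose linkage key matches a sample in `samples_subset`, in original
#' library order.
#'
#' @param samples_subset Filtered samples `amdir_table`.
#' @param libraries Libraries `amdir_table` of the same dataset category.
#' @return The filtered libraries `amdir_table`.
#' @export
join_libraries <- function(samples_subset, libraries) {
  stopifnot(inherits(samples_subset, "amdir_table"), inherits(libraries, "amdir_table"))
  link <- link_libraries_to_samples(samples_subset, libraries)
  out <- libraries
  out$cells <- libraries$cells[!is.na(link), , drop = FALSE]
  out
}

#' Summarise a library selection
#'
#' Reports how many library rows and distinct sequencing runs are selected
#' and the total download footprint in bytes (the sum over every file of
#' every selected row).
#'
#' @param libraries Libraries `amdir_table`.
#' @return List with `n_rows`, `n_runs`, `total_bytes` (class
#'   `amdir_selection_summary`).
#' @export
summarize_selection <- function(libraries) {
  stopifnot(inherits(libraries, "amdir_table"))
  if (!"download_sizes" %in% libraries$header) {
    stop_usage("libraries table has no 'download_sizes' column")
  }
  total <- 0
  for (i in seq_len(nrow(libraries$cells))) {
    cell <- libraries$cells[i, "download_sizes"]
    if (!nzchar(cell)) next
    tokens <- strsplit(cell, ";", fixed = TRUE)[[1]]
    vals <- suppressWarnings(as.numeric(tokens))
    if (anyNA(vals)) {
      stop_usage(sprintf("unparseable download size '%s' at data line %d", cell, i + 1L))
    }
    total <- total + sum(vals)
  }
  n_runs <- if ("archive_data_accession" %in% libraries$header && nrow(libraries$cells)) {
    length(unique(libraries$cells[, "archive_data_accession"]))
  } else {
    nrow(libraries$cells)
  }
  structure(
    list(n_rows = nrow(libraries$cells), n_runs = n_runs, total_bytes = total),
    class = "amdir_selection_summary"
  )
}

#' @export
print.amdir_selection_summary <- function(x, ...) {
  cat(sprintf("<selection> %d library rows, %d runs, %.2f GB to download\n",
              x$n_rows, x$n_runs, x$total_bytes / 1e9))
  invisible(x)
}
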