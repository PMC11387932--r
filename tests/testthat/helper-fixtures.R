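# Shared fixtures, built in code. Bundles are cached per (n, kind, seed) so
# repeated tests do not regenerate them.

.bundle_cache <- new.env(parent = emptyenv())

test_bundle <- function(n_samples = 12, libs = c(1, 3),
                        kind = "host_associated_metagenome", seed = 42) {
  key <- paste(n_samples, paste(libs, collapse = "-"), kind, seed, sep = "_")
  if (!exists(key, envir = .bundle_cache)) {
    assign(key, generate_dataset(n_samples, libs, kind = kind, seed = seed),
           envir = .bundle_cache)
  }
  get(key, envir = .bundle_cache)
}

# Three-row sample table for the year/geography worked example.
worked_example_samples <- function() {
  schema <- amdir_schema("host_associated_metagenome", "samples")
  base <- test_bundle(3, 1)$samples$cells[, , drop = FALSE]
  base[, "publication_year"] <- c("2019", "2021", "2021")
  base[, "geo_loc_name"] <- c("Spain", "Spain", "Germany")
  tbl <- as_amdir_table(base, provenance = "worked-example")
  bind_schema(tbl, schema)
}

# Independent row-scan evaluator used as the filtering oracle.
naive_filter_rows <- function(cells, preds) {
  vapply(seq_len(nrow(cells)), function(i) {
    by_col <- split(seq_along(preds), vapply(preds, `[[`, character(1), "column"))
    all(vapply(by_col, function(idx) {
      idx <- sort(idx)
      acc <- NULL
      for (k in idx) {
        p <- preds[[k]]
        cell <- unname(cells[i, p$column])
        v <- switch(p$op,
          eq = cell == p$operand,
          ne = cell != p$operand,
          contains = grepl(p$operand, cell, fixed = TRUE),
          in_set = cell %in% p$operand,
          {
            num <- suppressWarnings(as.numeric(cell))
            if (cell == "unknown" || is.na(num)) FALSE
            else switch(p$op,
                        lt = num < as.numeric(p$operand), le = num <= as.numeric(p$operand),
                        gt = num > as.numeric(p$operand), ge = num >= as.numeric(p$operand))
          }
        )
        acc <- if (is.null(acc)) v else if (p$connective == "AND") acc && v else acc || v
      }
      acc
    }, logical(1)))
  }, logical(1))
}

error_key <- function(d) {
  sort(do.call(paste, c(d[, c("error_type", "table_name", "line", "column")], sep = "|")))
}
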