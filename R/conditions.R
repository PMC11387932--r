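# Typed conditions so callers (and the CLI) can map failures to exit codes:
# usage -> 2, transport -> 3, everything parse/structural -> 2 at the CLI.

amdir_error <- function(msg, class, call = sys.call(-1)) {
  stop(structure(
    class = c(class, "amdir_error", "error", "condition"),
    list(message = msg, call = call)
  ))
}

stop_usage <- function(msg) amdir_error(msg, "amdir_usage_error")
stop_parse <- function(msg) amdir_error(msg, "amdir_parse_error")
stop_structural <- function(msg) amdir_error(msg, "amdir_structural_error")
stop_schema <- function(msg) amdir_error(msg, "amdir_schema_error")
stop_transport <- function(msg) amdir_error(msg, "amdir_transport_error")
stop_release <- function(msg) amdir_error(msg, c("amdir_release_not_found", "amdir_transport_error"))
stop_serialization <- function(msg) amdir_error(msg, "amdir_serialization_error")
stop_conversion <- function(msg) amdir_error(msg, "amdir_conversion_error")
stop_merge <- function(msg) amdir_error(msg, "amdir_merge_error")
stop_capacity <- function(msg) amdir_error(msg, "amdir_capacity_error")

# Seeded evaluation that never leaks into (or depends on) the caller's RNG
# stream; all generator/corruption determinism hangs off this.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop_usage("`seed` must be a single non-missing integer")
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
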