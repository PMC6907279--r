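#' @importFrom rlang abort warn %||% .data
NULL

# Condition helpers: every user-facing failure carries a hetpath_* class so
# callers (and tests) can distinguish identifier, schema, and config errors.
abort_identifier <- function(msg, ...) abort(msg, class = "hetpath_identifier_error", ...)
abort_schema     <- function(msg, ...) abort(msg, class = "hetpath_schema_error", ...)
abort_integrity  <- function(msg, ...) abort(msg, class = "hetpath_integrity_error", ...)
abort_config     <- function(msg, ...) abort(msg, class = "hetpath_config_error", ...)
abort_empty      <- function(msg, ...) abort(msg, class = "hetpath_empty_network_error", ...)
abort_sampling   <- function(msg, ...) abort(msg, class = "hetpath_sampling_error", ...)
abort_budget     <- function(msg, ...) abort(msg, class = "hetpath_budget_error", ...)
abort_metric     <- function(msg, ...) abort(msg, class = "hetpath_metric_error", ...)

# Run `expr` under a local RNG seeded with `seed`, restoring the caller's RNG
# state afterwards so package functions never perturb user-level randomness.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      get(".Random.seed", globalenv())
    }
    on.exit({
      if (is.null(old)) {
        suppressWarnings(rm(".Random.seed", envir = globalenv()))
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Stable string sort independent of the session locale.
sort_c <- function(x) {
  if (length(x) == 0) return(character())
  sort(x, method = "radix")
}

order_c <- function(...) order(..., method = "radix")

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
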