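#' @keywords internal
"_PACKAGE"

# Structured conditions used across the package. Every user-facing failure
# is one of these classes so callers (and the CLI) can branch on them.

ht_error <- function(message, class, call. = FALSE, ...) {
  stop(errorCondition(message, ..., class = c(class, "habtile_error")))
}

#' @noRd
ht_validation_error <- function(message, field = NULL) {
  if (!is.null(field)) message <- sprintf("%s [field: %s]", message, field)
  ht_error(message, "habtile_validation_error", field = field)
}

#' @noRd
ht_infeasible_error <- function(message, diagnostics = NULL) {
  ht_error(message, "habtile_infeasible_error", diagnostics = diagnostics)
}

#' @noRd
ht_constraint_error <- function(message, violations = NULL) {
  ht_error(message, "habtile_constraint_error", violations = violations)
}

#' @noRd
ht_not_found_error <- function(message) {
  ht_error(message, "habtile_not_found_error")
}

#' @noRd
ht_unsupported_comparison_error <- function(message) {
  ht_error(message, "habtile_unsupported_comparison_error")
}

# Evaluate expr with the RNG seeded to `seed`, restoring the caller's RNG
# state afterwards so library calls never perturb a user's simulation.
with_tile_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  expr
}

ht_stopifnot_number <- function(x, what, positive = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    ht_validation_error(sprintf("%s must be a single finite number", what), what)
  }
  if (positive && x <= 0) {
    ht_validation_error(sprintf("%s must be > 0", what), what)
  }
  invisible(x)
}
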