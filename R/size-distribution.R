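#' Size distributions for object dimensions
#'
#' A size distribution describes how one dimension of an object type
#' (footprint or depth) varies across a tile. Three kinds are supported:
#'
#' * `"fixed"`: every realisation equals `min` (`min == max`).
#' * `"discrete-uniform"`: values are drawn uniformly from the finite lattice
#'   \{`min`, `min + by`, ..., `max`\}; `max - min` must be an integer
#'   multiple of `by`. Only this kind yields a finite level count, which is
#'   what makes cross-tile complexity comparisons legitimate.
#' * `"continuous-uniform"`: values are drawn from U(`min`, `max`). Such
#'   ranges can be realised and fabricated, but they have no finite level
#'   count, so complexity comparisons involving them are refused (see
#'   [size_level_count()]).
#'
#' All lengths are dimensionless user units; tiles are scale-free and a units
#' label travels only in export metadata.
#'
#' @param min Minimum value (> 0).
#' @param max Maximum value; defaults to `min` (a fixed distribution).
#' @param by Lattice increment for a discrete-uniform distribution. Leave
#'   `NULL` for fixed (when `min == max`) or continuous (when `min < max`)
#'   distributions.
#' @param kind Optional explicit kind; inferred from the other arguments when
#'   omitted.
#'
#' @return An object of class `size_dist`.
#' @examples
#' size_dist(10)                  # fixed at 10
#' size_dist(8, 56, by = 8)       # lattice 8, 16, ..., 56
#' size_dist(8, 56)               # continuous range
#' @export
size_dist <- function(min, max = min, by = NULL, kind = NULL) {
  ht_stopifnot_number(min, "min")
  ht_stopifnot_number(max, "max")
  if (min > max) {
    ht_validation_error("min must not exceed max", "min")
  }
  if (is.null(kind)) {
    kind <- if (!is.null(by)) "discrete-uniform"
            else if (min == max) "fixed"
            else "continuous-uniform"
  }
  kind <- match.arg(kind, c("fixed", "discrete-uniform", "continuous-uniform"))
  if (kind == "fixed") {
    if (min != max) ht_validation_error("a fixed distribution needs min == max", "max")
    by <- NULL
  } else if (kind == "discrete-uniform") {
    if (is.null(by)) ht_validation_error("a discrete-uniform distribution needs an increment", "by")
    ht_stopifnot_number(by, "by")
    steps <- (max - min) / by
    if (abs(steps - round(steps)) > 1e-9 * base::max(1, steps)) {
      ht_validation_error("max - min must be an integer multiple of the increment", "by")
    }
  } else {
    if (!is.null(by)) ht_validation_error("a continuous-uniform distribution takes no increment", "by")
    if (min == max) ht_validation_error("a continuous-uniform distribution needs min < max", "max")
  }
  structure(list(kind = kind, min = as.numeric(min), max = as.numeric(max),
                 by = if (is.null(by)) NULL else as.numeric(by)),
            class = "size_dist")
}

#' @export
print.size_dist <- function(x, ...) {
  if (x$kind == "fixed") {
    cat(sprintf("<size_dist> fixed at %g\n", x$min))
  } else if (x$kind == "discrete-uniform") {
    cat(sprintf("<size_dist> discrete-uniform on {%g, %g, ..., %g} (%d levels)\n",
                x$min, x$min + x$by, x$max, size_level_count(x)))
  } else {
    cat(sprintf("<size_dist> continuous-uniform on [%g, %g]\n", x$min, x$max))
  }
  invisible(x)
}

is_size_dist <- function(x) inherits(x, "size_dist")

#' Number of distinct size levels of a distribution
#'
#' The level count is the size of the finite set a dimension is sampled
#' from: 1 for a fixed value, `(max - min)/by + 1` for a discrete-uniform
#' lattice. Smaller increments over the same range give more levels, hence
#' more informational complexity. Continuous ranges have no finite level
#' count: the probability of any particular value is zero, which makes
#' complexity comparisons between tiles meaningless, so they are refused
#' with an error rather than answered with infinity.
#'
#' @param dist A [size_dist()].
#' @return Integer count of levels (>= 1).
#' @examples
#' size_level_count(size_dist(8, 56, by = 8))  # 7
#' @export
size_level_count <- function(dist) {
  if (!is_size_dist(dist)) ht_validation_error("dist must be a size_dist", "dist")
  switch(dist$kind,
    "fixed" = 1L,
    "discrete-uniform" = as.integer(round((dist$max - dist$min) / dist$by)) + 1L,
    "continuous-uniform" = ht_unsupported_comparison_error(
      "continuous size ranges have no finite level count; complexity comparisons with them are unsupported"
    )
  )
}

#' The lattice of values a discrete distribution can realise
#' @param dist A [size_dist()].
#' @return Numeric vector of admissible values.
#' @export
size_levels <- function(dist) {
  if (!is_size_dist(dist)) ht_validation_error("dist must be a size_dist", "dist")
  n <- size_level_count(dist)
  if (n == 1L) dist$min else dist$min + (seq_len(n) - 1L) * dist$by
}

#' Sample realised sizes from a distribution
#'
#' Draws `count` independent values from the current RNG stream: the
#' constant for a fixed distribution, uniform over the lattice for a
#' discrete-uniform one, and U(min, max) for a continuous range.
#'
#' @param dist A [size_dist()].
#' @param count Number of draws (>= 0).
#' @return Numeric vector of length `count`; for discrete distributions
#'   every value is a lattice member.
#' @export
sample_sizes <- function(dist, count) {
  if (!is_size_dist(dist)) ht_validation_error("dist must be a size_dist", "dist")
  if (!is.numeric(count) || length(count) != 1L || count < 0 ||
      abs(count - round(count)) > 0) {
    ht_validation_error("count must be a non-negative integer", "count")
  }
  count <- as.integer(count)
  if (count == 0L) return(numeric(0))
  switch(dist$kind,
    "fixed" = rep(dist$min, count),
    "discrete-uniform" = {
      lv <- size_levels(dist)
      lv[sample.int(length(lv), count, replace = TRUE)]
    },
    "continuous-uniform" = stats::runif(count, dist$min, dist$max)
  )
}
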