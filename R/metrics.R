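#' Shannon entropy of a probability vector, in bits
#'
#' For a random variable with distribution p1, ..., pk the entropy
#' H = -sum(p_i * log2(p_i)) quantifies the uncertainty in predicting which
#' object type occupies a randomly chosen component of the tile surface.
#' It is zero for a single certain outcome and maximal, log2(k), when all k
#' types are equally abundant. Zero-probability entries contribute nothing
#' (the 0 * log 0 := 0 convention), so a type can be zeroed out without
#' error. Base 2 is used throughout the package, so entropies are in bits.
#'
#' @param p Non-empty numeric probability vector; entries >= 0, summing to 1
#'   within 1e-9.
#' @return Entropy in bits, in `[0, log2(length(p))]`.
#' @examples
#' shannon_entropy(c(0.5, 0.5))        # 1 bit
#' shannon_entropy(c(0.5, 0.25, 0.25)) # 1.5 bits
#' @export
shannon_entropy <- function(p) {
  validate_probability_vector(p, "p")
  pos <- p[p > 0]
  -sum(pos * log2(pos)) + 0  # + 0 normalises IEEE -0 from a certain outcome
}

#' Possible combinations of components and descriptors
#'
#' The number of distinguishable configurations grows as
#' components^descriptors: heterogeneity (the number of descriptors, a
#' higher-order factor) dominates density (the number of components). Two
#' components described by five descriptors admit 2^5 = 32 combinations,
#' while five components with only two descriptors admit just 5^2 = 25.
#'
#' @param components Positive integer (object/density count).
#' @param descriptors Positive integer (number of varying attributes).
#' @return `components ^ descriptors` as an exact integer-valued number.
#' @examples
#' combination_count(2, 5)  # 32
#' combination_count(5, 2)  # 25
#' @export
combination_count <- function(components, descriptors) {
  for (nm in c("components", "descriptors")) {
    x <- get(nm)
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x) ||
        x < 1 || abs(x - round(x)) > 0) {
      ht_validation_error(sprintf("%s must be an integer >= 1", nm), nm)
    }
  }
  out <- as.numeric(components)^as.numeric(descriptors)
  if (out <= .Machine$integer.max) as.integer(out) else out
}

#' Total surface area of a tile design
#'
#' Pits are modelled as vertical-walled recesses: a pit's floor replaces the
#' area of its opening, so the planar contribution is unchanged and each pit
#' adds only its wall area. A square pit of side w and depth d adds 4*w*d; a
#' circular pit of diameter w adds pi*w*d. The total is the planar tile area
#' plus the summed wall areas, in user units squared. This is the quantity
#' held constant when designing simple and complex tiles of equal surface
#' area so that complexity is isolated from area as an experimental
#' variable.
#'
#' @param design A [tile_design] from [generate_tile()].
#' @return Surface area in user units squared.
#' @export
surface_area <- function(design) {
  design <- as_tile_design(design)
  obj <- design$objects
  planar <- design$spec$width * design$spec$length
  if (nrow(obj) == 0L) return(planar)
  wall <- ifelse(obj$shape == "square",
                 4 * obj$footprint_size * obj$depth,
                 pi * obj$footprint_size * obj$depth)
  planar + sum(wall)
}

# Canonical comparability key: entropy values are only meaningful between
# tiles generated under the same rules (same arrangement, same kinds of
# size distribution, no manual edits).
comparable_key <- function(spec, edited = FALSE) {
  kinds <- sort(unique(unlist(lapply(spec$types, function(t)
    c(t$footprint$kind, t$depth$kind)))))
  key <- paste0("arrangement=", spec$arrangement,
                "|dists=", paste(kinds, collapse = ","))
  if (edited) key <- paste0(key, "|edited")
  key
}

#' Informational-complexity report for a tile design
#'
#' Assembles the package's complexity metrics for one design:
#'
#' * `type_entropy`: Shannon entropy (bits) of the type-abundance vector.
#' * `size_levels`: per type and per dimension, the number of discrete size
#'   levels and the corresponding size entropy `log2(levels)` in bits
#'   (uniform sampling over the lattice is assumed). Reported separately
#'   from the type entropy rather than folded into one number.
#' * `combination_count`: `density ^ descriptors`, where `descriptors`
#'   defaults to the number of varying attributes on the tile — every size
#'   dimension with more than one level, plus type identity itself when
#'   there is more than one type. Because the attribute list behind a
#'   "descriptor" is ultimately a modelling choice, it can be overridden.
#' * `comparable_key`: a canonical string of the tile's rules (arrangement
#'   and distribution kinds); entropy comparisons are only meaningful
#'   between reports whose keys match (see [is_comparable()]).
#'
#' @param design A [tile_design].
#' @param descriptors Optional positive integer overriding the descriptor
#'   count used for `combination_count`.
#' @return An object of class `complexity_report`.
#' @export
complexity_report <- function(design, descriptors = NULL) {
  design <- as_tile_design(design)
  spec <- design$spec
  k <- length(spec$types)

  lvl <- do.call(rbind, lapply(spec$types, function(t) {
    counts <- vapply(c(footprint = "footprint", depth = "depth"), function(dim)
      size_level_count(t[[dim]]), integer(1))
    data.frame(type_id = t$type_id,
               dimension = c("footprint", "depth"),
               levels = as.integer(counts),
               entropy_bits = log2(counts),
               row.names = NULL)
  }))

  if (is.null(descriptors)) {
    descriptors <- sum(lvl$levels > 1L) + (k > 1L)
  } else if (!is.numeric(descriptors) || length(descriptors) != 1L ||
             descriptors < 1 || abs(descriptors - round(descriptors)) > 0) {
    ht_validation_error("descriptors must be a positive integer", "descriptors")
  }

  combos <- if (spec$n >= 1L && descriptors >= 1L) {
    combination_count(spec$n, as.integer(descriptors))
  } else 1L

  structure(list(
    type_entropy = shannon_entropy(spec$abundances),
    entropy_base = "log2 (bits)",
    size_levels = lvl,
    combination_count = combos,
    descriptors = as.integer(descriptors),
    density = spec$n,
    arrangement_rule = spec$arrangement,
    comparable_key = comparable_key(spec, edited = isTRUE(design$edited))
  ), class = "complexity_report")
}

#' Are two complexity reports comparable?
#'
#' Entropy values are only meaningful between tiles generated under the same
#' rules: the same spatial arrangement (ordered layouts encode information
#' in their pattern that the entropy of the inputs does not see) and the
#' same kinds of size distribution (a continuous range makes the selection
#' probability of any value zero). Manually edited designs are never
#' comparable, as hand placement breaks the sampling rules. Returns `FALSE`
#' rather than erroring so callers can gate comparisons.
#'
#' @param a,b Two [complexity_report()] objects.
#' @return `TRUE` iff the reports' comparability keys match.
#' @export
is_comparable <- function(a, b) {
  if (!inherits(a, "complexity_report") || !inherits(b, "complexity_report")) {
    ht_validation_error("both arguments must be complexity_report objects")
  }
  identical(a$comparable_key, b$comparable_key)
}

#' @export
print.complexity_report <- function(x, ...) {
  cat("<complexity_report>\n")
  cat(sprintf("  type entropy      : %.6g bits (%s arrangement, density %d)\n",
              x$type_entropy, x$arrangement_rule, x$density))
  cat(sprintf("  combination count : %s (%d components ^ %d descriptors)\n",
              format(x$combination_count, big.mark = ","), x$density, x$descriptors))
  cat("  size levels:\n")
  for (i in seq_len(nrow(x$size_levels))) {
    r <- x$size_levels[i, ]
    cat(sprintf("    %-12s %-9s %2d level(s)  %.4g bits\n",
                r$type_id, r$dimension, r$levels, r$entropy_bits))
  }
  cat(sprintf("  comparable key    : %s\n", x$comparable_key))
  invisible(x)
}
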