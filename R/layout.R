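#' Apportion a total object count over type abundances
#'
#' Deterministic largest-remainder apportionment of `n * p`: each type first
#' receives `floor(n * p_i)` objects and the remaining objects go to the
#' types with the largest fractional parts. The RNG is consulted only to
#' break exact remainder ties (e.g. three types at p = 1/3 with n = 10), so
#' a spec with untied remainders is apportioned identically on every run.
#'
#' @param n Total object count (>= 0).
#' @param p Probability vector over types.
#' @return Integer vector of per-type counts summing exactly to `n`, each
#'   within 1 of `n * p_i`.
#' @examples
#' assign_types(10, c(0.5, 0.5))  # 5 5
#' @export
assign_types <- function(n, p) {
  validate_probability_vector(p, "p")
  if (!is.numeric(n) || length(n) != 1L || n < 0 || abs(n - round(n)) > 0) {
    ht_validation_error("n must be a non-negative integer", "n")
  }
  n <- as.integer(n)
  k <- length(p)
  quota <- n * p
  base <- floor(quota + 1e-9)
  frac <- pmax(quota - base, 0)
  base <- as.integer(base)
  r <- n - sum(base)
  if (r > 0L) {
    ord <- order(frac, decreasing = TRUE)
    cutoff <- frac[ord[r]]
    tol <- 1e-9
    sure <- which(frac > cutoff + tol)
    tied <- setdiff(which(frac >= cutoff - tol), sure)
    need <- r - length(sure)
    extra <- if (need == length(tied)) tied else sort(sample(tied, need))
    base[c(sure, extra)] <- base[c(sure, extra)] + 1L
  }
  base
}

#' Draw a random abundance vector
#'
#' Relative abundances may be randomised with each tile generation. The
#' vector is drawn uniformly from the probability simplex (a flat
#' Dirichlet, via normalised exponential spacings), so every composition of
#' k types is equally likely.
#'
#' @param k Number of object types (>= 1).
#' @return Probability vector of length `k` summing to 1.
#' @export
randomize_abundances <- function(k) {
  if (!is.numeric(k) || length(k) != 1L || k < 1 || abs(k - round(k)) > 0) {
    ht_validation_error("k must be a positive integer", "k")
  }
  k <- as.integer(k)
  if (k == 1L) return(1)
  e <- -log(stats::runif(k))
  e / sum(e)
}

# Edge-to-edge gap between two axis-aligned objects. Circles use centre
# distance minus radii; squares use the Chebyshev analogue; a circle-square
# pair measures from the circle centre to the square's boundary (clamped
# point) minus the radius.
pair_gap <- function(x1, y1, s1, shape1, x2, y2, s2, shape2) {
  if (shape1 == "circle" && shape2 == "circle") {
    sqrt((x1 - x2)^2 + (y1 - y2)^2) - (s1 + s2) / 2
  } else if (shape1 == "square" && shape2 == "square") {
    max(abs(x1 - x2), abs(y1 - y2)) - (s1 + s2) / 2
  } else {
    if (shape1 == "square") { # make object 1 the circle
      tmp <- c(x1, y1, s1); x1 <- x2; y1 <- y2; s1 <- s2
      x2 <- tmp[1]; y2 <- tmp[2]; s2 <- tmp[3]
    }
    h <- s2 / 2
    dx <- max(abs(x1 - x2) - h, 0)
    dy <- max(abs(y1 - y2) - h, 0)
    sqrt(dx^2 + dy^2) - s1 / 2
  }
}

new_tile_design <- function(spec, objects, seed, edited = FALSE,
                            warnings = character(0)) {
  rownames(objects) <- NULL
  structure(list(spec = spec, objects = objects,
                 provenance = list(
                   seed = seed,
                   generator = paste0("habtile ",
                                      as.character(utils::packageVersion("habtile")))),
                 edited = edited, warnings = warnings),
            class = "tile_design")
}

empty_objects <- function() {
  data.frame(object_id = integer(0), type_id = character(0),
             shape = character(0), centre_x = numeric(0),
             centre_y = numeric(0), footprint_size = numeric(0),
             depth = numeric(0), stringsAsFactors = FALSE)
}

as_tile_design <- function(x) {
  if (!inherits(x, "tile_design")) {
    ht_validation_error("expected a tile_design object", "design")
  }
  x
}

# Realise the typed + sized object table for a spec: counts from
# assign_types, then footprint and depth sampled per type in spec order.
realize_objects <- function(spec, abundances = spec$abundances) {
  counts <- assign_types(spec$n, abundances)
  rows <- lapply(seq_along(spec$types), function(i) {
    t <- spec$types[[i]]
    m <- counts[i]
    data.frame(type_id = rep(t$type_id, m), shape = rep(t$shape, m),
               footprint_size = sample_sizes(t$footprint, m),
               depth = sample_sizes(t$depth, m), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Place sized objects by buffered random sequential adsorption
#'
#' Random sequential adsorption (dart throwing): object centres are proposed
#' uniformly over the admissible region and rejected whenever the footprint
#' would leave the tile or come closer than `buffer` (edge to edge) to an
#' already-placed object. Every accepted configuration satisfies all
#' constraints exactly; the same RNG state yields the identical design.
#' Objects are placed in table order with up to `max_attempts` proposals
#' each; exhaustion raises an infeasible-density error carrying placement
#' diagnostics (attempts used, rejection counts, objects achieved).
#'
#' @param spec A [tile_spec()] with `arrangement = "random"`.
#' @param sized_objects Data frame with columns `type_id`, `shape`,
#'   `footprint_size`, `depth` (as produced internally by
#'   [generate_tile()]).
#' @param max_attempts Proposal cap per object (default 10000).
#' @return A `tile_design`.
#' @export
place_random <- function(spec, sized_objects, max_attempts = 10000L) {
  if (!is_tile_spec(spec)) ht_validation_error("spec must be a tile_spec", "spec")
  m <- nrow(sized_objects)
  xs <- ys <- numeric(m)
  rejected_overlap <- rejected_bounds <- 0L
  attempts_total <- 0L
  for (i in seq_len(m)) {
    half <- sized_objects$footprint_size[i] / 2
    lo_x <- half; hi_x <- spec$width - half
    lo_y <- half; hi_y <- spec$length - half
    placed <- FALSE
    if (hi_x >= lo_x && hi_y >= lo_y) {
      for (att in seq_len(max_attempts)) {
        attempts_total <- attempts_total + 1L
        cx <- stats::runif(1, lo_x, hi_x)
        cy <- stats::runif(1, lo_y, hi_y)
        ok <- TRUE
        if (i > 1L) {
          for (j in seq_len(i - 1L)) {
            g <- pair_gap(cx, cy, sized_objects$footprint_size[i],
                          sized_objects$shape[i],
                          xs[j], ys[j], sized_objects$footprint_size[j],
                          sized_objects$shape[j])
            if (g < spec$buffer) { ok <- FALSE; break }
          }
        }
        if (ok) { xs[i] <- cx; ys[i] <- cy; placed <- TRUE; break }
        rejected_overlap <- rejected_overlap + 1L
      }
    } else {
      rejected_bounds <- rejected_bounds + 1L
    }
    if (!placed) {
      diag <- list(attempts_used = attempts_total,
                   rejected_overlap = rejected_overlap,
                   rejected_bounds = rejected_bounds,
                   achieved_count = i - 1L)
      ht_infeasible_error(sprintf(
        "could not place object %d of %d after %d attempts (tile %g x %g, buffer %g)",
        i, m, max_attempts, spec$width, spec$length, spec$buffer),
        diagnostics = diag)
    }
  }
  obj <- cbind(data.frame(object_id = seq_len(m)),
               sized_objects[, c("type_id", "shape")],
               data.frame(centre_x = xs, centre_y = ys),
               sized_objects[, c("footprint_size", "depth")])
  if (m == 0L) obj <- empty_objects()
  new_tile_design(spec, obj, spec$seed)
}

#' Place sized objects on a deterministic ordered grid
#'
#' Objects are laid out row-major (bottom row first, origin at the tile's
#' lower-left corner) at the cell midpoints of an even `r x c` partition of
#' the tile, with `r = ceiling(sqrt(n))` rows and `c = ceiling(n / r)`
#' columns. No randomness is consumed, so ordered designs are invariant
#' under regeneration. Containment and buffer constraints are re-validated
#' on the result; a grid too tight for the footprints plus buffer raises an
#' infeasible-density error.
#'
#' @inheritParams place_random
#' @return A `tile_design`.
#' @export
place_ordered <- function(spec, sized_objects) {
  if (!is_tile_spec(spec)) ht_validation_error("spec must be a tile_spec", "spec")
  m <- nrow(sized_objects)
  if (m == 0L) return(new_tile_design(spec, empty_objects(), spec$seed))
  r <- ceiling(sqrt(m))
  cc <- ceiling(m / r)
  cw <- spec$width / cc
  ch <- spec$length / r
  idx <- seq_len(m) - 1L
  col <- idx %% cc
  row <- idx %/% cc
  xs <- (col + 0.5) * cw
  ys <- (row + 0.5) * ch
  obj <- cbind(data.frame(object_id = seq_len(m)),
               sized_objects[, c("type_id", "shape")],
               data.frame(centre_x = xs, centre_y = ys),
               sized_objects[, c("footprint_size", "depth")])
  design <- new_tile_design(spec, obj, spec$seed)
  viol <- validate_design(design)
  if (nrow(viol) > 0L) {
    diag <- list(attempts_used = m, rejected_overlap = sum(viol$kind == "buffer"),
                 rejected_bounds = sum(viol$kind == "containment"),
                 achieved_count = m - length(unique(c(viol$object_id, viol$other_id))))
    ht_infeasible_error(sprintf(
      "ordered grid cells (%g x %g) are too small for the footprints plus buffer %g",
      cw, ch, spec$buffer), diagnostics = diag)
  }
  design
}

#' Generate a tile design from a specification
#'
#' Realises a [tile_spec()] into a concrete `tile_design`: the RNG is seeded
#' once from the spec's seed (or the `seed` argument), then sub-operations
#' draw from it in a fixed, documented order — abundance randomisation (if
#' requested), type apportionment, size sampling per type in spec order,
#' then placement. A (spec, seed) pair therefore reproduces the identical
#' design byte for byte. The caller's global RNG state is left untouched.
#'
#' @param spec A [tile_spec()].
#' @param seed Optional seed overriding `spec$seed`.
#' @param randomize_abundances If `TRUE`, draw the abundance vector uniformly
#'   from the simplex instead of using `spec$abundances`.
#' @param max_attempts Proposal cap per object for random placement.
#' @return A `tile_design`: the spec, the placed-object table
#'   (`object_id, type_id, shape, centre_x, centre_y, footprint_size,
#'   depth`) and provenance (seed, generator version).
#' @examples
#' spec <- tile_spec(100, 100,
#'   types = object_type("pit", size_dist(8, 24, by = 8), size_dist(10)),
#'   n = 6, arrangement = "random", buffer = 2, seed = 1)
#' design <- generate_tile(spec)
#' surface_area(design)
#' @export
generate_tile <- function(spec, seed = NULL, randomize_abundances = FALSE,
                          max_attempts = 10000L) {
  if (!is_tile_spec(spec)) ht_validation_error("spec must be a tile_spec", "spec")
  if (!is.null(seed)) {
    spec$seed <- as.integer(seed)
  }
  with_tile_seed(spec$seed, {
    ab <- if (randomize_abundances) {
      habtile::randomize_abundances(length(spec$types))
    } else spec$abundances
    spec$abundances <- ab
    sized <- realize_objects(spec, ab)
    design <- if (spec$arrangement == "ordered") {
      place_ordered(spec, sized)
    } else {
      place_random(spec, sized, max_attempts = max_attempts)
    }
    design
  })
}

#' @export
print.tile_design <- function(x, ...) {
  cat(sprintf("<tile_design> %g x %g %s tile, %d object(s), %s arrangement (seed %d)\n",
              x$spec$width, x$spec$length, x$spec$units, nrow(x$objects),
              x$spec$arrangement, x$provenance$seed))
  if (isTRUE(x$edited)) cat("  manually edited (not comparable)\n")
  if (length(x$warnings)) cat("  warnings:", paste(x$warnings, collapse = "; "), "\n")
  invisible(x)
}

#' @export
summary.tile_design <- function(object, ...) {
  rep <- complexity_report(object)
  cat(sprintf("Tile design: %g x %g (%s), surface area %.6g\n",
              object$spec$width, object$spec$length, object$spec$units,
              surface_area(object)))
  tab <- table(factor(object$objects$type_id, levels = type_ids(object$spec)))
  cat("Objects per type:\n")
  print(tab)
  print(rep)
  invisible(rep)
}

#' Plot a tile design
#'
#' Draws the tile outline and every placed object (circles and squares,
#' coloured by type) in tile coordinates, one plot unit per user unit.
#'
#' @param x A `tile_design`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.tile_design <- function(x, ...) {
  spec <- x$spec
  graphics::plot(NA, xlim = c(0, spec$width), ylim = c(0, spec$length),
                 asp = 1, xlab = spec$units, ylab = spec$units,
                 main = sprintf("%s tile, n = %d", spec$arrangement, nrow(x$objects)),
                 ...)
  graphics::rect(0, 0, spec$width, spec$length, border = "black")
  cols <- design_colour_map(x)
  obj <- x$objects
  for (i in seq_len(nrow(obj))) {
    col <- cols[[obj$type_id[i]]]
    h <- obj$footprint_size[i] / 2
    if (obj$shape[i] == "circle") {
      th <- seq(0, 2 * pi, length.out = 72)
      graphics::polygon(obj$centre_x[i] + h * cos(th),
                        obj$centre_y[i] + h * sin(th), col = col, border = NA)
    } else {
      graphics::rect(obj$centre_x[i] - h, obj$centre_y[i] - h,
                     obj$centre_x[i] + h, obj$centre_y[i] + h,
                     col = col, border = NA)
    }
  }
  invisible(x)
}

design_colour_map <- function(design, colour_map = NULL) {
  ids <- type_ids(design$spec)
  if (is.null(colour_map)) {
    declared <- lapply(design$spec$types, function(t) t$colour)
    fallback <- grDevices::hcl.colors(max(length(ids), 3L), "Dark 3")
    colour_map <- stats::setNames(
      mapply(function(cl, i) if (is.null(cl)) fallback[i] else cl,
             declared, seq_along(declared)),
      ids)
  }
  missing <- setdiff(ids, names(colour_map))
  if (length(missing)) {
    ht_validation_error(sprintf("colour_map is missing type_id(s): %s",
                                paste(missing, collapse = ", ")), "colour_map")
  }
  as.list(colour_map)
}
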