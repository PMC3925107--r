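#' Declare an object type
#'
#' An object type is one class of surface feature (a pit in a moulded tile),
#' identified by a short label and a display colour, with independent size
#' distributions for its footprint (diameter of a circle, side of a square)
#' and its depth. The number of object types on a tile is the first of the
#' five complexity variables.
#'
#' @param type_id Short unique label, e.g. `"pit_a"`.
#' @param footprint A [size_dist()] for the footprint dimension.
#' @param depth A [size_dist()] for the pit depth.
#' @param shape `"circle"` or `"square"` (axis-aligned).
#' @param colour Display colour used in SVG output and plots.
#' @return An object of class `object_type`.
#' @examples
#' object_type("pit", size_dist(8, 56, by = 8), size_dist(24))
#' @export
object_type <- function(type_id, footprint, depth,
                        shape = c("circle", "square"), colour = NULL) {
  if (!is.character(type_id) || length(type_id) != 1L || !nzchar(type_id)) {
    ht_validation_error("type_id must be a non-empty string", "type_id")
  }
  if (grepl("[,\n\"]", type_id)) {
    ht_validation_error("type_id must not contain commas, quotes or newlines", "type_id")
  }
  if (!is_size_dist(footprint)) ht_validation_error("footprint must be a size_dist", "footprint")
  if (!is_size_dist(depth)) ht_validation_error("depth must be a size_dist", "depth")
  shape <- match.arg(shape)
  structure(list(type_id = type_id, footprint = footprint, depth = depth,
                 shape = shape, colour = colour),
            class = "object_type")
}

#' @export
print.object_type <- function(x, ...) {
  cat(sprintf("<object_type> '%s' (%s%s)\n", x$type_id, x$shape,
              if (is.null(x$colour)) "" else paste0(", ", x$colour)))
  cat("  footprint: "); print(x$footprint)
  cat("  depth:     "); print(x$depth)
  invisible(x)
}

#' Specify a habitat tile
#'
#' A tile specification carries the five controllable variables of
#' informational complexity — object types (with their size variability),
#' relative abundances, object density, and spatial arrangement — together
#' with the tile geometry, the minimum edge-to-edge buffer between objects,
#' and the RNG seed that makes a generated design reproducible.
#'
#' @param width,length Tile dimensions in user units (scale-free).
#' @param types A single [object_type()] or a list of them; `type_id`s must
#'   be unique.
#' @param n Total object count on the tile (density variable).
#' @param abundances Probability vector over the types (must sum to 1);
#'   defaults to equal abundances.
#' @param arrangement `"random"` (buffered random sequential adsorption) or
#'   `"ordered"` (deterministic grid).
#' @param buffer Minimum edge-to-edge spacing enforced between any two
#'   objects (>= 0).
#' @param seed Non-negative integer seed used by [generate_tile()].
#' @param thickness Tile thickness; metadata only, carried into exports.
#' @param units Free-text units label for export metadata (default "mm").
#' @return An object of class `tile_spec`.
#' @examples
#' tile_spec(400, 400,
#'   types = object_type("pit", size_dist(32), size_dist(24), "square"),
#'   n = 36, arrangement = "ordered")
#' @export
tile_spec <- function(width, length, types, n,
                      abundances = NULL,
                      arrangement = c("random", "ordered"),
                      buffer = 0, seed = 0L, thickness = NULL,
                      units = "mm") {
  ht_stopifnot_number(width, "width")
  ht_stopifnot_number(length, "length")
  if (!is.null(thickness)) ht_stopifnot_number(thickness, "thickness")
  if (is_object_type(types)) types <- list(types)
  if (!is.list(types) || base::length(types) < 1L ||
      !all(vapply(types, is_object_type, logical(1)))) {
    ht_validation_error("types must be one object_type or a non-empty list of them", "types")
  }
  ids <- vapply(types, function(t) t$type_id, character(1))
  if (anyDuplicated(ids)) {
    ht_validation_error(sprintf("duplicate type_id: %s", ids[duplicated(ids)][1]), "types")
  }
  k <- base::length(types)
  if (is.null(abundances)) abundances <- rep(1 / k, k)
  validate_probability_vector(abundances, "abundances")
  if (base::length(abundances) != k) {
    ht_validation_error("abundances must have one entry per object type", "abundances")
  }
  if (!is.numeric(n) || length(n) != 1L || n < 0 || abs(n - round(n)) > 0) {
    ht_validation_error("n must be a non-negative integer", "n")
  }
  arrangement <- match.arg(arrangement)
  if (!is.numeric(buffer) || length(buffer) != 1L || buffer < 0) {
    ht_validation_error("buffer must be a non-negative length", "buffer")
  }
  if (!is.numeric(seed) || length(seed) != 1L || seed < 0 ||
      abs(seed - round(seed)) > 0) {
    ht_validation_error("seed must be a non-negative integer", "seed")
  }
  structure(list(width = as.numeric(width), length = as.numeric(length),
                 thickness = if (is.null(thickness)) NULL else as.numeric(thickness),
                 types = types, abundances = as.numeric(abundances),
                 n = as.integer(n), arrangement = arrangement,
                 buffer = as.numeric(buffer), seed = as.integer(seed),
                 units = units),
            class = "tile_spec")
}

is_object_type <- function(x) inherits(x, "object_type")
is_tile_spec <- function(x) inherits(x, "tile_spec")

validate_probability_vector <- function(p, field = "p") {
  if (!is.numeric(p) || length(p) == 0L) {
    ht_validation_error("probability vector must be non-empty numeric", field)
  }
  neg <- which(p < 0)
  if (length(neg)) {
    ht_validation_error(sprintf("probability entry %d is negative (%g)", neg[1], p[neg[1]]),
                        field)
  }
  if (abs(sum(p) - 1) > 1e-9) {
    ht_validation_error(sprintf("probabilities sum to %.12g, not 1", sum(p)), field)
  }
  invisible(p)
}

type_ids <- function(spec) vapply(spec$types, function(t) t$type_id, character(1))

spec_type <- function(spec, type_id) {
  i <- match(type_id, type_ids(spec))
  if (is.na(i)) ht_not_found_error(sprintf("no such object type: %s", type_id))
  spec$types[[i]]
}

#' @export
print.tile_spec <- function(x, ...) {
  cat(sprintf("<tile_spec> %g x %g %s tile, %d objects, %s arrangement, buffer %g\n",
              x$width, x$length, x$units, x$n, x$arrangement, x$buffer))
  cat(sprintf("  %d object type(s): %s\n", base::length(x$types),
              paste(type_ids(x), collapse = ", ")))
  cat(sprintf("  abundances: %s | seed %d\n",
              paste(signif(x$abundances, 4), collapse = ", "), x$seed))
  invisible(x)
}
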