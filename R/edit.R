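#' Independently validate a tile design
#'
#' Checks every placed object for containment in the tile rectangle and
#' every object pair for the minimum edge-to-edge buffer, using a vectorised
#' all-pairs computation written separately from the placement engine so it
#' can serve as the single source of truth for design feasibility.
#'
#' @param design A `tile_design`.
#' @return Data frame of violations, one row each, with columns `kind`
#'   (`"containment"` or `"buffer"`), `object_id`, `other_id` (`NA` for
#'   containment), `measured_gap` and `required_gap`. Zero rows iff the
#'   design is valid.
#' @export
validate_design <- function(design) {
  design <- as_tile_design(design)
  spec <- design$spec
  obj <- design$objects
  out <- data.frame(kind = character(0), object_id = integer(0),
                    other_id = integer(0), measured_gap = numeric(0),
                    required_gap = numeric(0), stringsAsFactors = FALSE)
  m <- nrow(obj)
  if (m == 0L) return(out)

  h <- obj$footprint_size / 2
  margin <- pmin(obj$centre_x - h, spec$width - obj$centre_x - h,
                 obj$centre_y - h, spec$length - obj$centre_y - h)
  bad <- which(margin < -1e-9)
  if (length(bad)) {
    out <- rbind(out, data.frame(kind = "containment",
                                 object_id = obj$object_id[bad],
                                 other_id = NA_integer_,
                                 measured_gap = margin[bad],
                                 required_gap = 0))
  }

  if (m >= 2L) {
    pairs <- utils::combn(m, 2)
    i <- pairs[1, ]; j <- pairs[2, ]
    dx <- abs(obj$centre_x[i] - obj$centre_x[j])
    dy <- abs(obj$centre_y[i] - obj$centre_y[j])
    both_circle <- obj$shape[i] == "circle" & obj$shape[j] == "circle"
    both_square <- obj$shape[i] == "square" & obj$shape[j] == "square"
    gap <- numeric(length(i))
    gap[both_circle] <- sqrt(dx[both_circle]^2 + dy[both_circle]^2) -
      (h[i[both_circle]] + h[j[both_circle]])
    gap[both_square] <- pmax(dx[both_square], dy[both_square]) -
      (h[i[both_square]] + h[j[both_square]])
    mixed <- which(!(both_circle | both_square))
    for (q in mixed) {
      ci <- if (obj$shape[i[q]] == "circle") i[q] else j[q]
      sq <- if (ci == i[q]) j[q] else i[q]
      ddx <- max(abs(obj$centre_x[ci] - obj$centre_x[sq]) - h[sq], 0)
      ddy <- max(abs(obj$centre_y[ci] - obj$centre_y[sq]) - h[sq], 0)
      gap[q] <- sqrt(ddx^2 + ddy^2) - h[ci]
    }
    badp <- which(gap < spec$buffer - 1e-9)
    if (length(badp)) {
      out <- rbind(out, data.frame(kind = "buffer",
                                   object_id = obj$object_id[i[badp]],
                                   other_id = obj$object_id[j[badp]],
                                   measured_gap = gap[badp],
                                   required_gap = spec$buffer))
    }
  }
  rownames(out) <- NULL
  out
}

#' Edit commands for advanced-mode design editing
#'
#' Constructors for the three per-object edits a realised design supports:
#' moving an object to a new centre, resizing its footprint and/or depth,
#' and deleting it. Apply with [apply_edit()].
#'
#' @param object_id Integer id of the target object.
#' @param x,y New centre coordinates (tile origin at lower-left).
#' @param footprint_size,depth New dimensions; at least one must be given to
#'   `edit_resize()`.
#' @return An object of class `edit_command`.
#' @name edit_command
NULL

new_edit_command <- function(kind, object_id, new_centre = NULL,
                             new_footprint_size = NULL, new_depth = NULL) {
  if (!is.numeric(object_id) || length(object_id) != 1L ||
      abs(object_id - round(object_id)) > 0) {
    ht_validation_error("object_id must be a single integer", "object_id")
  }
  structure(list(kind = kind, object_id = as.integer(object_id),
                 new_centre = new_centre,
                 new_footprint_size = new_footprint_size,
                 new_depth = new_depth),
            class = "edit_command")
}

#' @rdname edit_command
#' @export
edit_move <- function(object_id, x, y) {
  ht_stopifnot_number(x, "x", positive = FALSE)
  ht_stopifnot_number(y, "y", positive = FALSE)
  new_edit_command("move", object_id, new_centre = c(x, y))
}

#' @rdname edit_command
#' @export
edit_resize <- function(object_id, footprint_size = NULL, depth = NULL) {
  if (is.null(footprint_size) && is.null(depth)) {
    ht_validation_error("resize needs a new footprint_size and/or depth", "footprint_size")
  }
  if (!is.null(footprint_size)) ht_stopifnot_number(footprint_size, "footprint_size")
  if (!is.null(depth)) ht_stopifnot_number(depth, "depth")
  new_edit_command("resize", object_id, new_footprint_size = footprint_size,
                   new_depth = depth)
}

#' @rdname edit_command
#' @export
edit_delete <- function(object_id) {
  new_edit_command("delete", object_id)
}

#' @export
print.edit_command <- function(x, ...) {
  detail <- switch(x$kind,
    move = sprintf(" to (%g, %g)", x$new_centre[1], x$new_centre[2]),
    resize = paste0(
      if (!is.null(x$new_footprint_size)) sprintf(" footprint -> %g", x$new_footprint_size) else "",
      if (!is.null(x$new_depth)) sprintf(" depth -> %g", x$new_depth) else ""),
    delete = "")
  cat(sprintf("<edit_command> %s object %d%s\n", x$kind, x$object_id, detail))
  invisible(x)
}

#' Apply a manual edit to a tile design
#'
#' Returns a new design with the edit applied; the input design is never
#' modified. Under `strict = TRUE` (the default) the edited design must
#' still satisfy the containment and buffer invariants, otherwise a
#' constraint error names the offending object pairs and the edit is
#' refused. Under permissive mode any violations are attached to the
#' returned design as warnings instead. Either way the design is marked as
#' edited: manual placement breaks the sampling rules, so its complexity
#' report is no longer comparable to generated tiles (and resized
#' dimensions may leave the discrete lattice).
#'
#' @param design A `tile_design`.
#' @param cmd An [edit_command] from [edit_move()], [edit_resize()] or
#'   [edit_delete()].
#' @param strict Refuse constraint-violating edits? Default `TRUE`.
#' @return The edited `tile_design`.
#' @export
apply_edit <- function(design, cmd, strict = TRUE) {
  design <- as_tile_design(design)
  if (!inherits(cmd, "edit_command")) {
    ht_validation_error("cmd must be an edit_command", "cmd")
  }
  obj <- design$objects
  i <- match(cmd$object_id, obj$object_id)
  if (is.na(i)) {
    ht_not_found_error(sprintf("no object with id %d in this design", cmd$object_id))
  }
  if (cmd$kind == "delete") {
    obj <- obj[-i, , drop = FALSE]
    new <- design
    new$objects <- obj
    rownames(new$objects) <- NULL
    new$spec$n <- nrow(obj)
    new$edited <- TRUE
    return(new)
  }
  if (cmd$kind == "move") {
    obj$centre_x[i] <- cmd$new_centre[1]
    obj$centre_y[i] <- cmd$new_centre[2]
  } else { # resize
    if (!is.null(cmd$new_footprint_size)) obj$footprint_size[i] <- cmd$new_footprint_size
    if (!is.null(cmd$new_depth)) obj$depth[i] <- cmd$new_depth
  }
  new <- design
  new$objects <- obj
  new$edited <- TRUE
  viol <- validate_design(new)
  if (nrow(viol) > 0L) {
    msgs <- apply(viol, 1, function(r) {
      if (r[["kind"]] == "containment") {
        sprintf("object %s breaches the tile boundary by %g",
                r[["object_id"]], -as.numeric(r[["measured_gap"]]))
      } else {
        sprintf("objects %s and %s have gap %g < required %g",
                r[["object_id"]], r[["other_id"]],
                as.numeric(r[["measured_gap"]]), as.numeric(r[["required_gap"]]))
      }
    })
    if (strict) {
      ht_constraint_error(paste0("edit refused: ", paste(msgs, collapse = "; ")),
                          violations = viol)
    }
    new$warnings <- c(new$warnings, msgs)
  }
  new
}
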