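# Readers and writers: YAML tile specs, spreadsheet CSV, CAD DXF (R12
# ASCII dialect), and SVG renderings. All writers are deterministic
# functions of their inputs and use "." as the decimal separator
# regardless of locale. Numeric fields are printed with %.17g so a
# write-read cycle reproduces every double exactly.

fmt_num <- function(x) sprintf("%.17g", x)

dist_to_list <- function(d) {
  out <- list(kind = d$kind, min = d$min, max = d$max)
  if (!is.null(d$by)) out$by <- d$by
  out
}

dist_from_list <- function(x, path) {
  if (!is.list(x) || is.null(x$min)) {
    ht_validation_error(sprintf("missing or malformed size distribution at %s", path), path)
  }
  tryCatch(
    size_dist(min = x$min, max = if (is.null(x$max)) x$min else x$max,
              by = x$by, kind = x$kind),
    habtile_validation_error = function(e) {
      ht_validation_error(sprintf("%s at %s", conditionMessage(e), path), path)
    })
}

#' Write a tile specification to a YAML file
#'
#' The on-disk schema is a small YAML document with `tile` (width, length,
#' thickness, units), `arrangement`, `buffer`, `seed`, `density`, `abundances`
#' and an `object_types` list, each type carrying `type_id`, `shape`,
#' `colour` and `footprint` / `depth` distributions (`kind`, `min`, `max`,
#' `by`). [read_spec()] inverts this exactly.
#'
#' @param spec A [tile_spec()].
#' @param path Output file path.
#' @export
write_spec <- function(spec, path) {
  if (!is_tile_spec(spec)) ht_validation_error("spec must be a tile_spec", "spec")
  doc <- list(
    tile = c(list(width = spec$width, length = spec$length),
             if (!is.null(spec$thickness)) list(thickness = spec$thickness),
             list(units = spec$units)),
    arrangement = spec$arrangement,
    buffer = spec$buffer,
    seed = spec$seed,
    density = spec$n,
    abundances = as.list(spec$abundances),
    object_types = lapply(spec$types, function(t) {
      c(list(type_id = t$type_id, shape = t$shape),
        if (!is.null(t$colour)) list(colour = t$colour),
        list(footprint = dist_to_list(t$footprint),
             depth = dist_to_list(t$depth)))
    })
  )
  yaml::write_yaml(doc, path, precision = 17)
  invisible(path)
}

#' Read a tile specification from a YAML file
#'
#' @param path Path to a YAML file in the schema written by [write_spec()].
#' @return A validated [tile_spec()]; any validation failure names the
#'   offending field path.
#' @export
read_spec <- function(path) {
  if (!file.exists(path)) ht_validation_error(sprintf("no such file: %s", path), "path")
  doc <- tryCatch(yaml::read_yaml(path), error = function(e) {
    ht_validation_error(sprintf("cannot parse %s as YAML: %s", path, conditionMessage(e)),
                        "path")
  })
  need <- function(x, field) {
    if (is.null(x)) ht_validation_error(sprintf("missing field '%s'", field), field)
    x
  }
  tile <- need(doc$tile, "tile")
  raw_types <- need(doc$object_types, "object_types")
  types <- lapply(seq_along(raw_types), function(i) {
    rt <- raw_types[[i]]
    at <- function(f) sprintf("object_types[%d].%s", i, f)
    object_type(
      type_id = need(rt$type_id, at("type_id")),
      footprint = dist_from_list(need(rt$footprint, at("footprint")), at("footprint")),
      depth = dist_from_list(need(rt$depth, at("depth")), at("depth")),
      shape = need(rt$shape, at("shape")),
      colour = rt$colour)
  })
  tile_spec(width = need(tile$width, "tile.width"),
            length = need(tile$length, "tile.length"),
            types = types,
            n = need(doc$density, "density"),
            abundances = if (is.null(doc$abundances)) NULL else unlist(doc$abundances),
            arrangement = need(doc$arrangement, "arrangement"),
            buffer = if (is.null(doc$buffer)) 0 else doc$buffer,
            seed = if (is.null(doc$seed)) 0L else doc$seed,
            thickness = tile$thickness,
            units = if (is.null(tile$units)) "mm" else tile$units)
}

design_csv_header <- c("object_id", "type_id", "shape", "centre_x",
                       "centre_y", "footprint_size", "depth")

#' Write a tile design as spreadsheet-ready CSV
#'
#' One row per placed object in `object_id` order, with header
#' `object_id,type_id,shape,centre_x,centre_y,footprint_size,depth`. Plain
#' comma-separated UTF-8 with a decimal point (never a comma) and full
#' numeric precision, so the file is both Excel-openable and a lossless
#' serialisation. With `include_report = TRUE` a companion file at
#' `<path>.report.csv` carries the [complexity_report()] as key-value rows.
#'
#' @param design A `tile_design`.
#' @param path Output file path.
#' @param include_report Also write the complexity report CSV?
#' @export
write_design_csv <- function(design, path, include_report = FALSE) {
  design <- as_tile_design(design)
  obj <- design$objects[order(design$objects$object_id), , drop = FALSE]
  lines <- paste(design_csv_header, collapse = ",")
  if (nrow(obj) > 0L) {
    body <- vapply(seq_len(nrow(obj)), function(i) {
      paste(c(obj$object_id[i], obj$type_id[i], obj$shape[i],
              fmt_num(obj$centre_x[i]), fmt_num(obj$centre_y[i]),
              fmt_num(obj$footprint_size[i]), fmt_num(obj$depth[i])),
            collapse = ",")
    }, character(1))
    lines <- c(lines, body)
  }
  writeLines(lines, path, useBytes = TRUE)
  if (include_report) {
    rep <- complexity_report(design)
    rl <- c("key,value",
            sprintf("type_entropy_bits,%s", fmt_num(rep$type_entropy)),
            sprintf("combination_count,%s", fmt_num(as.numeric(rep$combination_count))),
            sprintf("descriptors,%d", rep$descriptors),
            sprintf("density,%d", rep$density),
            sprintf("arrangement_rule,%s", rep$arrangement_rule),
            sprintf("comparable_key,%s", rep$comparable_key),
            sprintf("size_entropy_bits[%s.%s],%s", rep$size_levels$type_id,
                    rep$size_levels$dimension, fmt_num(rep$size_levels$entropy_bits)))
    writeLines(rl, paste0(path, ".report.csv"), useBytes = TRUE)
  }
  invisible(path)
}

#' Read a design CSV back into a tile design
#'
#' Inverts [write_design_csv()]. The CSV stores only the realised objects,
#' so the tile geometry and rules must be supplied as the spec the design
#' was generated from.
#'
#' @param path Path to a design CSV.
#' @param spec The [tile_spec()] the design belongs to.
#' @return A `tile_design`.
#' @export
read_design_csv <- function(path, spec) {
  if (!file.exists(path)) ht_validation_error(sprintf("no such file: %s", path), "path")
  if (!is_tile_spec(spec)) ht_validation_error("spec must be a tile_spec", "spec")
  df <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = c(
    object_id = "integer", type_id = "character", shape = "character",
    centre_x = "numeric", centre_y = "numeric",
    footprint_size = "numeric", depth = "numeric"))
  if (!identical(names(df), design_csv_header)) {
    ht_validation_error(sprintf("unexpected CSV columns in %s", path), "path")
  }
  spec$n <- nrow(df)
  if (nrow(df) == 0L) df <- empty_objects()
  new_tile_design(spec, df, spec$seed)
}

# --- DXF -------------------------------------------------------------------

dxf_pair <- function(code, value) c(as.character(code), as.character(value))

dxf_closed_polyline <- function(layer, xs, ys, thickness = NULL) {
  out <- c(dxf_pair(0, "POLYLINE"), dxf_pair(8, layer),
           if (!is.null(thickness)) dxf_pair(39, fmt_num(thickness)),
           dxf_pair(66, 1), dxf_pair(70, 1))
  for (i in seq_along(xs)) {
    out <- c(out, dxf_pair(0, "VERTEX"), dxf_pair(8, layer),
             dxf_pair(10, fmt_num(xs[i])), dxf_pair(20, fmt_num(ys[i])),
             dxf_pair(30, "0.0"))
  }
  c(out, dxf_pair(0, "SEQEND"), dxf_pair(8, layer))
}

#' Write a tile design as CAD-ready DXF
#'
#' Emits a minimal R12-compatible ASCII DXF: the tile boundary as a closed
#' polyline on layer `TILE`, each circular pit as a `CIRCLE` entity and
#' each square pit as a closed polyline, both on a layer named after the
#' object's `type_id`. Pit depth is written into each entity's thickness
#' attribute (group code 39) — DXF has no standard notion of pit depth —
#' and mirrored in a `999` comment (`object_id=... depth=...`) preceding
#' the entity. Coordinates are in user units at full precision.
#'
#' @param design A `tile_design`.
#' @param path Output file path.
#' @export
write_design_dxf <- function(design, path) {
  design <- as_tile_design(design)
  spec <- design$spec
  lines <- c(dxf_pair(999, sprintf("habtile design, units=%s, seed=%d",
                                   spec$units, design$provenance$seed)),
             dxf_pair(0, "SECTION"), dxf_pair(2, "HEADER"),
             dxf_pair(9, "$ACADVER"), dxf_pair(1, "AC1009"),
             dxf_pair(0, "ENDSEC"),
             dxf_pair(0, "SECTION"), dxf_pair(2, "ENTITIES"),
             dxf_closed_polyline("TILE",
                                 c(0, spec$width, spec$width, 0),
                                 c(0, 0, spec$length, spec$length)))
  obj <- design$objects[order(design$objects$object_id), , drop = FALSE]
  for (i in seq_len(nrow(obj))) {
    lines <- c(lines, dxf_pair(999, sprintf("object_id=%d depth=%s",
                                            obj$object_id[i], fmt_num(obj$depth[i]))))
    if (obj$shape[i] == "circle") {
      lines <- c(lines,
                 dxf_pair(0, "CIRCLE"), dxf_pair(8, obj$type_id[i]),
                 dxf_pair(39, fmt_num(obj$depth[i])),
                 dxf_pair(10, fmt_num(obj$centre_x[i])),
                 dxf_pair(20, fmt_num(obj$centre_y[i])),
                 dxf_pair(30, "0.0"),
                 dxf_pair(40, fmt_num(obj$footprint_size[i] / 2)))
    } else {
      h <- obj$footprint_size[i] / 2
      lines <- c(lines, dxf_closed_polyline(
        obj$type_id[i],
        obj$centre_x[i] + c(-h, h, h, -h),
        obj$centre_y[i] + c(-h, -h, h, h),
        thickness = obj$depth[i]))
    }
  }
  lines <- c(lines, dxf_pair(0, "ENDSEC"), dxf_pair(0, "EOF"))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

# --- SVG -------------------------------------------------------------------

#' Render a tile design as SVG
#'
#' Draws the tile as a rectangle and every object as a filled shape
#' coloured by type, at 1 user unit per SVG unit. The SVG y axis points
#' down, so tile coordinates (origin lower-left) are flipped on output.
#' Output is byte-deterministic for a given design and colour map.
#'
#' @param design A `tile_design`.
#' @param path Output file path.
#' @param colour_map Named character vector or list mapping every `type_id`
#'   to a fill colour; defaults to the types' declared colours (with an
#'   automatic palette for types that declare none).
#' @export
render_svg <- function(design, path, colour_map = NULL) {
  design <- as_tile_design(design)
  spec <- design$spec
  cols <- design_colour_map(design, colour_map)
  w <- spec$width; l <- spec$length
  lines <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    sprintf('<svg xmlns="http://www.w3.org/2000/svg" version="1.1" width="%s" height="%s" viewBox="0 0 %s %s">',
            fmt_num(w), fmt_num(l), fmt_num(w), fmt_num(l)),
    sprintf('<rect x="0" y="0" width="%s" height="%s" fill="white" stroke="black" stroke-width="%s"/>',
            fmt_num(w), fmt_num(l), fmt_num(max(w, l) / 400)))
  obj <- design$objects[order(design$objects$object_id), , drop = FALSE]
  for (i in seq_len(nrow(obj))) {
    fill <- cols[[obj$type_id[i]]]
    cy <- l - obj$centre_y[i]   # flip to SVG's downward y axis
    if (obj$shape[i] == "circle") {
      lines <- c(lines, sprintf('<circle cx="%s" cy="%s" r="%s" fill="%s"/>',
                                fmt_num(obj$centre_x[i]), fmt_num(cy),
                                fmt_num(obj$footprint_size[i] / 2), fill))
    } else {
      h <- obj$footprint_size[i] / 2
      lines <- c(lines, sprintf('<rect x="%s" y="%s" width="%s" height="%s" fill="%s"/>',
                                fmt_num(obj$centre_x[i] - h), fmt_num(cy - h),
                                fmt_num(obj$footprint_size[i]),
                                fmt_num(obj$footprint_size[i]), fill))
    }
  }
  lines <- c(lines, "</svg>")
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Export a design in one or more formats
#'
#' Convenience wrapper writing `<stem>.csv`, `<stem>.dxf` and/or
#' `<stem>.svg` into a directory.
#'
#' @param design A `tile_design`.
#' @param dir Output directory (created if missing).
#' @param stem File name stem (default `"tile"`).
#' @param formats Subset of `c("csv", "dxf", "svg")`; at least one.
#' @param colour_map Passed to [render_svg()].
#' @param include_report Passed to [write_design_csv()].
#' @return Invisibly, the written file paths.
#' @export
export_design <- function(design, dir, stem = "tile",
                          formats = c("csv", "dxf", "svg"),
                          colour_map = NULL, include_report = FALSE) {
  formats <- unique(match.arg(formats, c("csv", "dxf", "svg"), several.ok = TRUE))
  if (length(formats) == 0L) ht_validation_error("select at least one format", "formats")
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  for (f in formats) {
    p <- file.path(dir, paste0(stem, ".", f))
    switch(f,
      csv = write_design_csv(design, p, include_report = include_report),
      dxf = write_design_dxf(design, p),
      svg = render_svg(design, p, colour_map = colour_map))
    paths <- c(paths, p)
  }
  invisible(paths)
}
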