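# Independent oracles used across the suite. These are deliberately naive
# implementations, separate from the package's code paths.

# Entropy by literal hand-summation over the terms.
oracle_entropy <- function(p) {
  h <- 0
  for (pi in p) if (pi > 0) h <- h - pi * log(pi) / log(2)
  h
}

# Count configurations by materialising the full Cartesian product.
oracle_combinations <- function(components, descriptors) {
  nrow(expand.grid(rep(list(seq_len(components)), descriptors)))
}

# Surface area by polygonal approximation of each pit wall: perimeter of a
# fine inscribed polygon (circles) or the exact rectangle perimeter, times
# depth, plus the planar tile area.
oracle_surface_area <- function(design, segments = 20000) {
  obj <- design$objects
  area <- design$spec$width * design$spec$length
  for (i in seq_len(nrow(obj))) {
    w <- obj$footprint_size[i]
    if (obj$shape[i] == "circle") {
      th <- 2 * pi / segments
      perim <- segments * w * sin(th / 2) # chord length sums
    } else {
      perim <- 4 * w
    }
    area <- area + perim * obj$depth[i]
  }
  area
}

# Naive all-pairs edge-to-edge gap, double loop, no shared code with the
# package's validator or placement engine.
oracle_min_gap <- function(design) {
  obj <- design$objects
  m <- nrow(obj)
  if (m < 2) return(Inf)
  gaps <- c()
  for (i in 1:(m - 1)) for (j in (i + 1):m) {
    xi <- obj$centre_x[i]; yi <- obj$centre_y[i]; hi <- obj$footprint_size[i] / 2
    xj <- obj$centre_x[j]; yj <- obj$centre_y[j]; hj <- obj$footprint_size[j] / 2
    si <- obj$shape[i]; sj <- obj$shape[j]
    g <- if (si == "circle" && sj == "circle") {
      sqrt((xi - xj)^2 + (yi - yj)^2) - hi - hj
    } else if (si == "square" && sj == "square") {
      max(abs(xi - xj), abs(yi - yj)) - hi - hj
    } else {
      if (si == "square") { # swap so i is the circle
        tmp <- c(xi, yi, hi); xi <- xj; yi <- yj; hi <- hj
        xj <- tmp[1]; yj <- tmp[2]; hj <- tmp[3]
      }
      dx <- max(abs(xi - xj) - hj, 0); dy <- max(abs(yi - yj) - hj, 0)
      sqrt(dx^2 + dy^2) - hi
    }
    gaps <- c(gaps, g)
  }
  min(gaps)
}

oracle_containment_ok <- function(design) {
  obj <- design$objects
  h <- obj$footprint_size / 2
  all(obj$centre_x - h >= -1e-9, obj$centre_x + h <= design$spec$width + 1e-9,
      obj$centre_y - h >= -1e-9, obj$centre_y + h <= design$spec$length + 1e-9)
}

# Minimal DXF reader: group-code/value pairs -> list of entities with their
# attributes. Independent of the package's writer.
oracle_read_dxf <- function(path) {
  lines <- readLines(path)
  codes <- lines[seq(1, length(lines), by = 2)]
  values <- lines[seq(2, length(lines), by = 2)]
  entities <- list()
  cur <- NULL
  in_entities <- FALSE
  for (i in seq_along(codes)) {
    code <- as.integer(codes[i]); val <- values[i]
    if (code == 2 && val == "ENTITIES") in_entities <- TRUE
    if (!in_entities) next
    if (code == 0) {
      if (!is.null(cur)) entities[[length(entities) + 1]] <- cur
      cur <- if (val %in% c("ENDSEC", "EOF")) NULL else list(type = val)
      if (val == "ENDSEC") break
    } else if (!is.null(cur)) {
      key <- as.character(code)
      cur[[key]] <- c(cur[[key]], val)
    }
  }
  entities
}

# Collapse a parsed DXF into one object row per CIRCLE / closed POLYLINE
# (excluding the TILE boundary), for comparison with the CSV export.
oracle_dxf_objects <- function(path) {
  ents <- oracle_read_dxf(path)
  out <- list()
  i <- 1
  while (i <= length(ents)) {
    e <- ents[[i]]
    if (e$type == "CIRCLE") {
      out[[length(out) + 1]] <- data.frame(
        layer = e[["8"]], shape = "circle",
        centre_x = as.numeric(e[["10"]]), centre_y = as.numeric(e[["20"]]),
        footprint_size = 2 * as.numeric(e[["40"]]),
        depth = as.numeric(e[["39"]]), stringsAsFactors = FALSE)
      i <- i + 1
    } else if (e$type == "POLYLINE" && e[["8"]] != "TILE") {
      xs <- c(); ys <- c()
      j <- i + 1
      while (j <= length(ents) && ents[[j]]$type == "VERTEX") {
        xs <- c(xs, as.numeric(ents[[j]][["10"]]))
        ys <- c(ys, as.numeric(ents[[j]][["20"]]))
        j <- j + 1
      }
      out[[length(out) + 1]] <- data.frame(
        layer = e[["8"]], shape = "square",
        centre_x = mean(range(xs)), centre_y = mean(range(ys)),
        footprint_size = diff(range(xs)),
        depth = as.numeric(e[["39"]]), stringsAsFactors = FALSE)
      i <- j
    } else {
      i <- i + 1
    }
  }
  do.call(rbind, out)
}

# Small spec factories -------------------------------------------------------

one_type_spec <- function(n = 4, arrangement = "random", buffer = 2,
                          seed = 1, width = 100, length = 100,
                          footprint = size_dist(8, 24, by = 8),
                          depth = size_dist(10), shape = "circle") {
  tile_spec(width, length,
            types = object_type("pit", footprint, depth, shape = shape),
            n = n, arrangement = arrangement, buffer = buffer, seed = seed)
}

two_type_spec <- function(n = 6, arrangement = "random", buffer = 2, seed = 1) {
  tile_spec(120, 120,
            types = list(
              object_type("disc", size_dist(8, 16, by = 4), size_dist(6), "circle"),
              object_type("pit", size_dist(10), size_dist(4, 12, by = 4), "square")),
            abundances = c(0.5, 0.5),
            n = n, arrangement = arrangement, buffer = buffer, seed = seed)
}

random_spec <- function(seed) {
  # A varied but always-feasible spec family for bulk property tests.
  set.seed(seed)
  k <- sample(1:3, 1)
  shapes <- sample(c("circle", "square"), k, replace = TRUE)
  types <- lapply(seq_len(k), function(i)
    object_type(paste0("t", i),
                footprint = size_dist(6, 18, by = 6),
                depth = size_dist(4, 12, by = 4),
                shape = shapes[i]))
  p <- as.numeric(stats::rmultinom(1, 20, rep(1 / k, k))) / 20
  if (any(p == 0)) p <- rep(1 / k, k)
  tile_spec(150, 150, types = types, abundances = p,
            n = sample(4:10, 1),
            arrangement = sample(c("random", "ordered"), 1),
            buffer = sample(c(0, 2, 5), 1), seed = seed)
}
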