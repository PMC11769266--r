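#' @title Thiessen polygons and zonal statistics
#' @description
#' Builds the Voronoi (Thiessen) footprint polygon of every harvester
#' yield point, clipped to the field boundary; computes shape metrics;
#' filters irregular and edge polygons; and extracts per-polygon zonal
#' means from rasters. The Voronoi cells are computed exactly by
#' successive half-plane clipping of the (convex) boundary, visiting
#' neighbors in order of distance with the standard 2x-max-radius cutoff.
#' @name harvest_geometry
NULL

# Clip a convex polygon (n x 2 matrix) to the half-plane a*x + b*y <= c.
clip_halfplane <- function(poly, a, b, c) {
  n <- nrow(poly)
  if (n == 0L) return(poly)
  d <- a * poly[, 1] + b * poly[, 2] - c
  inside <- d <= 1e-12
  if (all(inside)) return(poly)
  if (!any(inside)) return(poly[0, , drop = FALSE])
  out <- matrix(numeric(0), 0, 2)
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    if (inside[i]) out <- rbind(out, poly[i, ])
    if (inside[i] != inside[j]) {
      t <- d[i] / (d[i] - d[j])
      out <- rbind(out, poly[i, ] + t * (poly[j, ] - poly[i, ]))
    }
  }
  out
}

ensure_ccw <- function(poly) {
  n <- nrow(poly)
  a2 <- sum(poly[, 1] * poly[c(2:n, 1), 2] - poly[c(2:n, 1), 1] * poly[, 2])
  if (a2 < 0) poly[n:1, , drop = FALSE] else poly
}

point_segment_distance <- function(px, py, x1, y1, x2, y2) {
  dx <- x2 - x1; dy <- y2 - y1
  len2 <- dx^2 + dy^2
  t <- if (len2 == 0) 0 else pmin(1, pmax(0, ((px - x1) * dx + (py - y1) * dy) / len2))
  sqrt((px - (x1 + t * dx))^2 + (py - (y1 + t * dy))^2)
}

touches_ring <- function(poly, boundary, tol = 1e-7) {
  nb <- nrow(boundary)
  for (k in seq_len(nb)) {
    k2 <- if (k == nb) 1L else k + 1L
    d <- point_segment_distance(poly[, 1], poly[, 2],
                                boundary[k, 1], boundary[k, 2],
                                boundary[k2, 1], boundary[k2, 2])
    if (any(d < tol)) return(TRUE)
  }
  FALSE
}

#' Thiessen (Voronoi) polygons of harvest points
#'
#' @param points A `harvest_point_set` or data frame with `point_id`, `x`,
#'   `y` columns; at least 2 distinct points.
#' @param boundary Convex boundary polygon as an `n x 2` vertex matrix
#'   (defaults to the `boundary` attribute of `points`).
#' @return A list of `field_polygon` objects (class `field_polygon_set`),
#'   each with `polygon_id` (the generating `point_id`), `vertices`,
#'   `area` (m^2), `perimeter` (m), `roundness` (isoperimetric ratio,
#'   1 for a circle) and `is_edge` (touches the boundary ring).
#' @export
thiessen_polygons <- function(points, boundary = attr(points, "boundary")) {
  if (is.null(boundary)) stop("boundary polygon required")
  pts <- as.data.frame(points)
  dup <- duplicated(round(pts[, c("x", "y")], 9)) |
    duplicated(round(pts[, c("x", "y")], 9), fromLast = TRUE)
  if (any(dup)) {
    stop(sprintf("duplicate-point: coincident points for ids %s",
                 paste(pts$point_id[dup], collapse = ", ")), call. = FALSE)
  }
  if (nrow(pts) < 2L) stop("need at least 2 distinct points", call. = FALSE)
  boundary <- ensure_ccw(as.matrix(boundary))
  n <- nrow(pts)
  px <- pts$x; py <- pts$y
  polys <- vector("list", n)
  for (i in seq_len(n)) {
    d2 <- (px - px[i])^2 + (py - py[i])^2
    ord <- order(d2)[-1]
    cell <- boundary
    max_r2 <- max((cell[, 1] - px[i])^2 + (cell[, 2] - py[i])^2)
    for (j in ord) {
      if (d2[j] > 4 * max_r2) break
      a <- 2 * (px[j] - px[i]); b <- 2 * (py[j] - py[i])
      c <- px[j]^2 + py[j]^2 - px[i]^2 - py[i]^2
      cell <- clip_halfplane(cell, a, b, c)
      if (nrow(cell) < 3L) break
      max_r2 <- max((cell[, 1] - px[i])^2 + (cell[, 2] - py[i])^2)
    }
    m <- shape_metrics(list(vertices = cell))
    polys[[i]] <- structure(
      list(polygon_id = pts$point_id[i], vertices = cell,
           area = m$area, perimeter = m$perimeter, roundness = m$roundness,
           is_edge = touches_ring(cell, boundary)),
      class = "field_polygon")
  }
  structure(polys, class = "field_polygon_set")
}

#' Shape metrics of a simple polygon
#'
#' Area by the shoelace formula, perimeter as the closed vertex-chain
#' length, and roundness as the isoperimetric ratio `P^2 / (4 pi A)` —
#' exactly 1 for a circle, larger for less round shapes.
#'
#' @param polygon A `field_polygon` or list with a `vertices` matrix
#'   (>= 3 vertices).
#' @return List with `area`, `perimeter`, `roundness`.
#' @export
shape_metrics <- function(polygon) {
  v <- polygon$vertices
  if (is.null(v) || nrow(v) < 3L) {
    stop("invalid-polygon: need at least 3 vertices", call. = FALSE)
  }
  nxt <- c(2:nrow(v), 1)
  area <- abs(sum(v[, 1] * v[nxt, 2] - v[nxt, 1] * v[, 2])) / 2
  perimeter <- sum(sqrt((v[nxt, 1] - v[, 1])^2 + (v[nxt, 2] - v[, 2])^2))
  list(area = area, perimeter = perimeter,
       roundness = perimeter^2 / (4 * pi * area))
}

#' Filter polygons by area, roundness and edge contact
#'
#' @param polys A `field_polygon_set`.
#' @param area_bounds Length-2 numeric `(min, max)` in m^2.
#' @param roundness_max Maximum isoperimetric roundness retained
#'   (default 3).
#' @param drop_edges Drop polygons touching the boundary ring
#'   (default TRUE).
#' @return The retained subset, order preserved, as a
#'   `field_polygon_set`; counts of removals attached as attribute
#'   `dropped`.
#' @export
filter_polygons <- function(polys, area_bounds = c(0, Inf),
                            roundness_max = 3, drop_edges = TRUE) {
  if (length(area_bounds) != 2L || area_bounds[1] > area_bounds[2]) {
    stop("invalid-config: area_bounds must be (min, max) with min <= max",
         call. = FALSE)
  }
  area <- vapply(polys, `[[`, 0, "area")
  rnd <- vapply(polys, `[[`, 0, "roundness")
  edge <- vapply(polys, `[[`, TRUE, "is_edge")
  keep <- area >= area_bounds[1] & area <= area_bounds[2] &
    rnd <= roundness_max & (!drop_edges | !edge)
  out <- structure(polys[keep], class = "field_polygon_set")
  attr(out, "dropped") <- c(
    area = sum(area < area_bounds[1] | area > area_bounds[2]),
    roundness = sum(rnd > roundness_max),
    edge = if (drop_edges) sum(edge) else 0L
  )
  out
}

# Vectorized even-odd (ray casting) point-in-polygon test.
points_in_polygon <- function(px, py, v) {
  n <- nrow(v)
  inside <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    crosses <- ((v[i, 2] > py) != (v[j, 2] > py)) &
      (px < (v[j, 1] - v[i, 1]) * (py - v[i, 2]) /
         (v[j, 2] - v[i, 2]) + v[i, 1])
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

#' Zonal mean of a raster over field polygons
#'
#' The mean of all pixels whose centers fall inside each polygon
#' (pixel-center containment rule), ignoring nodata pixels. Polygons with
#' no valid pixel get an `NA` mean and are flagged, not dropped.
#'
#' @param r A [field_raster()].
#' @param polys A `field_polygon_set`.
#' @return Data frame with `polygon_id`, `mean`, `n_valid_pixels`,
#'   `empty`.
#' @export
zonal_mean <- function(r, polys) {
  g <- raster_grid(r)
  vals <- unclass(r)
  ctr <- pixel_centers(g)
  out <- lapply(polys, function(p) {
    v <- p$vertices
    if (nrow(v) < 3L) {
      return(data.frame(polygon_id = p$polygon_id, mean = NA_real_,
                        n_valid_pixels = 0L, empty = TRUE))
    }
    cols <- which(ctr$x >= min(v[, 1]) & ctr$x <= max(v[, 1]))
    rows <- which(ctr$y >= min(v[, 2]) & ctr$y <= max(v[, 2]))
    if (length(cols) == 0L || length(rows) == 0L) {
      return(data.frame(polygon_id = p$polygon_id, mean = NA_real_,
                        n_valid_pixels = 0L, empty = TRUE))
    }
    xx <- rep(ctr$x[cols], each = length(rows))
    yy <- rep(ctr$y[rows], times = length(cols))
    inside <- points_in_polygon(xx, yy, v)
    if (!any(inside)) {
      return(data.frame(polygon_id = p$polygon_id, mean = NA_real_,
                        n_valid_pixels = 0L, empty = TRUE))
    }
    sub <- vals[rows, cols, drop = FALSE][matrix(inside, length(rows))]
    nv <- sum(!is.na(sub))
    data.frame(polygon_id = p$polygon_id,
               mean = if (nv > 0) mean(sub, na.rm = TRUE) else NA_real_,
               n_valid_pixels = nv, empty = nv == 0L)
  })
  do.call(rbind, out)
}

#' Write polygons as a GeoJSON FeatureCollection
#'
#' @param polys A `field_polygon_set`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_polygons_geojson <- function(polys, path) {
  features <- lapply(polys, function(p) {
    ring <- rbind(p$vertices, p$vertices[1, , drop = FALSE])
    list(type = "Feature",
         geometry = list(type = "Polygon",
                         coordinates = list(lapply(seq_len(nrow(ring)),
                           function(i) as.numeric(ring[i, ])))),
         properties = list(polygon_id = p$polygon_id, area = p$area,
                           perimeter = p$perimeter, roundness = p$roundness,
                           is_edge = p$is_edge))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = features),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
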