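#' Grid specification for a field raster
#'
#' Describes the georeferencing of a raster: dimensions, pixel size and the
#' coordinate of the top-left corner in a projected, metric coordinate
#' system. Rasters are stored row-major with row 1 at the top (largest y);
#' a pixel's value refers to its full square footprint (area convention).
#'
#' @param n_rows,n_cols Grid dimensions (>= 1).
#' @param pixel_size Pixel edge length in meters (> 0).
#' @param origin_x,origin_y Coordinates (m) of the top-left corner of the
#'   top-left pixel.
#' @param crs_label Free-text label of the projected CRS; informational only.
#' @return An object of class `grid_spec`.
#' @export
grid_spec <- function(n_rows, n_cols, pixel_size = 1,
                      origin_x = 0, origin_y = n_rows * pixel_size,
                      crs_label = "local-metric") {
  if (length(n_rows) != 1L || length(n_cols) != 1L ||
      is.na(n_rows) || is.na(n_cols) || n_rows < 1 || n_cols < 1) {
    stop("invalid-config: grid dimensions must be >= 1", call. = FALSE)
  }
  if (!is.numeric(pixel_size) || pixel_size <= 0) {
    stop("invalid-grid: pixel_size must be > 0", call. = FALSE)
  }
  structure(
    list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
         pixel_size = as.numeric(pixel_size),
         origin_x = as.numeric(origin_x), origin_y = as.numeric(origin_y),
         crs_label = crs_label),
    class = "grid_spec"
  )
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %d x %d @ %g m, origin (%g, %g), %s\n",
              x$n_rows, x$n_cols, x$pixel_size, x$origin_x, x$origin_y,
              x$crs_label))
  invisible(x)
}

same_grid <- function(a, b, tol = 1e-9) {
  a$n_rows == b$n_rows && a$n_cols == b$n_cols &&
    abs(a$pixel_size - b$pixel_size) < tol &&
    abs(a$origin_x - b$origin_x) < tol &&
    abs(a$origin_y - b$origin_y) < tol
}

stop_if_grid_mismatch <- function(a, b) {
  if (!same_grid(a, b)) stop("grid-mismatch: rasters are not co-registered",
                             call. = FALSE)
  invisible(TRUE)
}

#' Construct a field raster
#'
#' A field raster is a numeric matrix carrying a [grid_spec()]. Missing or
#' masked pixels are `NA` in memory; the nodata sentinel (-9999) appears
#' only in files.
#'
#' @param values Numeric matrix, `n_rows x n_cols`.
#' @param grid A [grid_spec()] matching `dim(values)`.
#' @return An object of class `field_raster` (a matrix with a `grid`
#'   attribute).
#' @export
field_raster <- function(values, grid) {
  values <- as.matrix(values)
  if (!inherits(grid, "grid_spec")) stop("grid must be a grid_spec")
  if (nrow(values) != grid$n_rows || ncol(values) != grid$n_cols) {
    stop("grid-mismatch: matrix dimensions do not match grid_spec",
         call. = FALSE)
  }
  structure(values, grid = grid, class = c("field_raster", "matrix", "array"))
}

#' @export
print.field_raster <- function(x, ...) {
  g <- attr(x, "grid")
  v <- as.vector(x)
  cat(sprintf("<field_raster> %d x %d @ %g m | range [%g, %g] | %d NA\n",
              g$n_rows, g$n_cols, g$pixel_size,
              suppressWarnings(min(v, na.rm = TRUE)),
              suppressWarnings(max(v, na.rm = TRUE)), sum(is.na(v))))
  invisible(x)
}

raster_grid <- function(r) attr(r, "grid")

#' Pixel-center coordinates of a grid
#'
#' @param grid A [grid_spec()].
#' @return List with vectors `x` (length `n_cols`) and `y` (length
#'   `n_rows`, decreasing: row 1 is the northernmost row).
#' @export
pixel_centers <- function(grid) {
  list(
    x = grid$origin_x + (seq_len(grid$n_cols) - 0.5) * grid$pixel_size,
    y = grid$origin_y - (seq_len(grid$n_rows) - 0.5) * grid$pixel_size
  )
}

#' Write / read a raster as ESRI ASCII grid
#'
#' Plain-text georeferenced raster exchange format (`.asc`). `NA` pixels are
#' written as the nodata sentinel -9999.
#'
#' @param r A [field_raster()].
#' @param path Output file path.
#' @return `write_ascii_grid()` returns `path` invisibly; `read_ascii_grid()`
#'   returns a [field_raster()].
#' @export
write_ascii_grid <- function(r, path) {
  g <- raster_grid(r)
  header <- c(
    sprintf("ncols %d", g$n_cols),
    sprintf("nrows %d", g$n_rows),
    sprintf("xllcorner %.10g", g$origin_x),
    sprintf("yllcorner %.10g", g$origin_y - g$n_rows * g$pixel_size),
    sprintf("cellsize %.10g", g$pixel_size),
    "NODATA_value -9999"
  )
  m <- unclass(r)
  m[is.na(m)] <- -9999
  lines <- apply(m, 1L, function(row) paste(format(row, trim = TRUE,
                                                   digits = 10),
                                            collapse = " "))
  writeLines(c(header, lines), path)
  invisible(path)
}

#' @rdname write_ascii_grid
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path)
  hdr <- lines[1:6]
  kv <- do.call(rbind, strsplit(trimws(hdr), "\\s+"))
  h <- stats::setNames(as.numeric(kv[, 2]), tolower(kv[, 1]))
  m <- do.call(rbind, lapply(lines[-(1:6)], function(l) {
    as.numeric(strsplit(trimws(l), "\\s+")[[1]])
  }))
  m[m == h[["nodata_value"]]] <- NA_real_
  g <- grid_spec(h[["nrows"]], h[["ncols"]], h[["cellsize"]],
                 origin_x = h[["xllcorner"]],
                 origin_y = h[["yllcorner"]] + h[["nrows"]] * h[["cellsize"]])
  field_raster(m, g)
}

# Run code with a fixed RNG state, restoring the caller's state afterwards.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed %% 2147483647L))
  force(code)
}
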