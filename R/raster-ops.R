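#' @title Grid-level raster operations
#' @description Bare-ground masking by red-edge NDVI, mask application,
#'   nearest-neighbor resampling and slope derivation from a DEM.
#' @name raster_ops
NULL

#' Otsu threshold of a numeric sample
#'
#' Histogram-based threshold maximizing between-class variance over 256
#' equal-width bins spanning the finite data range. Used to automate the
#' canopy/soil cut on red-edge NDVI when no manual per-flight threshold is
#' supplied.
#'
#' @param x Numeric vector; `NA`s ignored.
#' @param n_bins Number of histogram bins (default 256).
#' @return The threshold (a bin boundary) as a single numeric value.
#' @export
otsu_threshold <- function(x, n_bins = 256) {
  x <- x[is.finite(x)]
  if (length(x) < 2L || diff(range(x)) == 0) {
    stop("invalid-config: cannot threshold a constant or empty sample",
         call. = FALSE)
  }
  edges <- seq(min(x), max(x), length.out = n_bins + 1L)
  counts <- tabulate(findInterval(x, edges, rightmost.closed = TRUE),
                     nbins = n_bins)
  p <- counts / sum(counts)
  mids <- (edges[-1] + edges[-(n_bins + 1L)]) / 2
  w0 <- cumsum(p)
  mu0 <- cumsum(p * mids)
  mu_t <- mu0[n_bins]
  # between-class variance for cut after bin k
  bcv <- (mu_t * w0 - mu0)^2 / (w0 * (1 - w0))
  bcv[!is.finite(bcv)] <- -Inf
  k <- which.max(bcv[-n_bins])
  edges[k + 1L]
}

#' Binary vegetation mask from red-edge NDVI
#'
#' Computes `NDVIre = (rededge - red) / (rededge + red)` per pixel and
#' classifies pixels as vegetation (1) when `NDVIre >= threshold`, soil (0)
#' otherwise. Nodata pixels classify as 0. With `threshold = "auto"` the
#' cut is chosen by [otsu_threshold()] on the finite NDVIre values.
#'
#' @param rededge,red Co-registered [field_raster()]s of reflectance.
#' @param threshold Numeric threshold, or `"auto"`.
#' @return A [field_raster()] of 0/1 values with attributes
#'   `threshold_used` (numeric) and class `binary_mask`.
#' @export
ndvire_mask <- function(rededge, red, threshold = "auto") {
  stop_if_grid_mismatch(raster_grid(rededge), raster_grid(red))
  ndvire <- safe_div(unclass(rededge) - unclass(red),
                     unclass(rededge) + unclass(red))
  thr <- if (identical(threshold, "auto")) {
    otsu_threshold(as.vector(ndvire))
  } else as.numeric(threshold)
  m <- ifelse(!is.na(ndvire) & ndvire >= thr, 1, 0)
  out <- field_raster(m, raster_grid(rededge))
  attr(out, "threshold_used") <- thr
  class(out) <- c("binary_mask", class(out))
  out
}

#' Apply a binary mask to a reflectance stack
#'
#' Masked-out pixels (mask 0) become nodata (`NA`) in every band; they are
#' never set to literal 0 reflectance, so zonal means later average
#' vegetation pixels only. Idempotent.
#'
#' @param stack A `reflectance_stack` (see [make_reflectance_series()]) or a
#'   named list of co-registered [field_raster()]s.
#' @param mask A `binary_mask` from [ndvire_mask()].
#' @return The stack with masked pixels set to `NA`.
#' @export
apply_mask <- function(stack, mask) {
  bands <- intersect(names(stack), c("blue", "green", "red", "rededge", "nir"))
  drop <- unclass(mask) == 0
  for (nm in bands) {
    stop_if_grid_mismatch(raster_grid(stack[[nm]]), raster_grid(mask))
    v <- unclass(stack[[nm]])
    v[drop] <- NA_real_
    stack[[nm]] <- field_raster(v, raster_grid(mask))
  }
  stack
}

#' Nearest-neighbor resampling onto a target grid
#'
#' Each target pixel takes the value of the source pixel containing its
#' center, so no new values are introduced (the closure-of-values property;
#' e.g. sand+silt+clay percentages that sum to 100 still do after
#' resampling). Target centers outside the source extent become `NA`.
#'
#' @param r Source [field_raster()].
#' @param target A [grid_spec()] overlapping the source extent.
#' @return A [field_raster()] on `target`.
#' @export
resample_nearest <- function(r, target) {
  g <- raster_grid(r)
  ctr <- pixel_centers(target)
  col <- floor((ctr$x - g$origin_x) / g$pixel_size) + 1L
  row <- floor((g$origin_y - ctr$y) / g$pixel_size) + 1L
  ok_col <- col >= 1L & col <= g$n_cols
  ok_row <- row >= 1L & row <= g$n_rows
  if (!any(ok_col) || !any(ok_row)) {
    stop("empty-output: target grid does not overlap the source extent",
         call. = FALSE)
  }
  col[!ok_col] <- NA_integer_
  row[!ok_row] <- NA_integer_
  idx <- outer(row, col, function(i, j) i + (j - 1L) * g$n_rows)
  vals <- unclass(r)[idx]
  field_raster(matrix(vals, target$n_rows, target$n_cols), target)
}

#' Slope in degrees from a DEM by Horn's method
#'
#' 3x3 finite-difference stencil of Horn (1981), the algorithm behind the
#' standard GIS 'Slope' tool: `slope = atan(sqrt(gx^2 + gy^2))` with
#' weighted east-west and north-south gradients over 8 neighbors. Edge
#' pixels use edge-replication padding.
#'
#' @param dem A [field_raster()] of elevations (m) on a metric grid.
#' @return A [field_raster()] of slope in degrees (>= 0).
#' @export
slope_from_dem <- function(dem) {
  g <- raster_grid(dem)
  if (g$pixel_size <= 0) stop("invalid-grid: pixel_size must be > 0",
                              call. = FALSE)
  z <- unclass(dem)
  nr <- nrow(z); nc <- ncol(z)
  pad <- rbind(z[1, , drop = FALSE], z, z[nr, , drop = FALSE])
  pad <- cbind(pad[, 1, drop = FALSE], pad, pad[, nc, drop = FALSE])
  sh <- function(dr, dc) pad[(1 + dr):(nr + dr), (1 + dc):(nc + dc)]
  # Horn weights: corners 1, edge-neighbors 2
  gx <- ((sh(0, 2) + 2 * sh(1, 2) + sh(2, 2)) -
         (sh(0, 0) + 2 * sh(1, 0) + sh(2, 0))) / (8 * g$pixel_size)
  gy <- ((sh(2, 0) + 2 * sh(2, 1) + sh(2, 2)) -
         (sh(0, 0) + 2 * sh(0, 1) + sh(0, 2))) / (8 * g$pixel_size)
  field_raster(atan(sqrt(gx^2 + gy^2)) * 180 / pi, g)
}
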