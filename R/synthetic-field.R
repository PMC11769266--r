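#' @title Synthetic field generator
#' @description
#' Seed-reproducible generator of a rain-fed corn field with the
#' statistical structure the downstream analysis assumes: two smoothly
#' interlocking soil bodies (a heavy smectitic clay and a silty carbonatic
#' clay), a gently ridged DEM with configurable total relief, a latent crop
#' vigor field driven by soil and slope, per-growth-stage canopy
#' reflectance from a two-endmember mixing model over dilating planting
#' rows, and harvester yield points on parallel transects whose yield is a
#' known (stored) function of vigor, soil and slope. Every generated
#' object exposes its ground truth (vigor, canopy masks, generating
#' coefficients) so recovery tests can interrogate the pipeline.
#' @name synthetic_field
NULL

# Growth-stage labels and days-after-planting of the emulated flight
# campaign (4-leaf through tasseling).
STAGE_TABLE <- data.frame(
  stage_label = c("V4", "V5", "V6", "V7", "V9", "V12", "V14/VT"),
  dap = c(20L, 27L, 43L, 55L, 64L, 78L, 83L),
  stringsAsFactors = FALSE
)

#' Scenario configuration for the synthetic field
#'
#' @param seed Integer master seed; identical seed + config give
#'   bit-identical output.
#' @param grid A [grid_spec()]; default 300 x 300 at 1 m.
#' @param soil_effect_weight,slope_effect_weight Non-negative weights of
#'   the soil score and (negated) slope in the latent vigor field, and of
#'   the direct soil/slope terms in the yield response.
#' @param vigor_noise_sd Standard deviation of the spatially smooth vigor
#'   noise component (on the standardized scale).
#' @param yield_mean Field mean yield, Mg/ha.
#' @param yield_cv Coefficient of variation of yield (fraction in `[0, 1)`).
#' @param nonlinearity `"linear"` or `"threshold-interaction"` (adds a
#'   clay-by-slope interaction and a low-vigor threshold penalty to the
#'   yield response).
#' @param n_stages Number of growth stages (flights), 1-7.
#' @param canopy_cover_by_stage Canopy cover fraction per stage,
#'   non-decreasing; default interpolates 0.10 to 0.75.
#' @param transect_spacing Harvester transect spacing, m (combine header
#'   width; default 4.6 m, six 0.76-m rows).
#' @param point_spacing Along-transect spacing of yield records, m
#'   (default 3.7 m, giving ~17 m^2 per record).
#' @param relief_m Total DEM relief (max - min), m.
#' @param yield_floor Lower clip for yield, Mg/ha (avoids non-physical
#'   values in the far noise tail).
#' @param reflectance_noise_sd Per-pixel, per-band reflectance noise sd.
#' @param row_spacing Planting-row spacing used for the canopy growth
#'   pattern, m. At the default 1 m grid real 0.76-m corn rows are
#'   sub-pixel, so the default (1 = one pixel) gives spatially uniform
#'   canopy fill; set larger than `pixel_size` to emulate resolved rows
#'   at finer ground sampling distances. A resolved row pattern whose
#'   period beats against the harvest-record spacing makes the
#'   spectral measurement quality vary systematically with position.
#' @param boundary_margin Inset of the harvested boundary from the raster
#'   edge, m.
#' @param planting_date Planting date (used for flight dates).
#' @return A validated list of class `scenario_config`.
#' @export
scenario_config <- function(seed = 1L,
                            grid = grid_spec(300, 300, 1),
                            soil_effect_weight = 1,
                            slope_effect_weight = 0.6,
                            vigor_noise_sd = 0.6,
                            yield_mean = 10.19,
                            yield_cv = 0.1211,
                            nonlinearity = c("linear", "threshold-interaction"),
                            n_stages = 7L,
                            canopy_cover_by_stage = NULL,
                            transect_spacing = 4.6,
                            point_spacing = 3.7,
                            relief_m = 8,
                            yield_floor = 1.5,
                            reflectance_noise_sd = 0.004,
                            row_spacing = 1,
                            boundary_margin = 4,
                            planting_date = as.Date("2023-02-28")) {
  nonlinearity <- match.arg(nonlinearity)
  if (!inherits(grid, "grid_spec")) stop("invalid-config: grid must be a grid_spec")
  if (yield_mean <= 0) stop("invalid-config: yield_mean must be > 0")
  if (yield_cv < 0 || yield_cv >= 1) stop("invalid-config: yield_cv must be in [0, 1)")
  if (soil_effect_weight < 0 || slope_effect_weight < 0) {
    stop("invalid-config: effect weights must be >= 0")
  }
  n_stages <- as.integer(n_stages)
  if (n_stages < 1L || n_stages > nrow(STAGE_TABLE)) {
    stop("invalid-config: n_stages must be between 1 and 7")
  }
  if (is.null(canopy_cover_by_stage)) {
    canopy_cover_by_stage <- if (n_stages == 1L) 0.5 else
      seq(0.10, 0.75, length.out = n_stages)
  }
  if (length(canopy_cover_by_stage) != n_stages ||
      any(canopy_cover_by_stage < 0 | canopy_cover_by_stage > 1) ||
      is.unsorted(canopy_cover_by_stage)) {
    stop("invalid-config: canopy_cover_by_stage must be a non-decreasing fraction vector of length n_stages")
  }
  structure(list(
    seed = as.integer(seed), grid = grid,
    soil_effect_weight = soil_effect_weight,
    slope_effect_weight = slope_effect_weight,
    vigor_noise_sd = vigor_noise_sd,
    yield_mean = yield_mean, yield_cv = yield_cv,
    nonlinearity = nonlinearity, n_stages = n_stages,
    canopy_cover_by_stage = canopy_cover_by_stage,
    transect_spacing = transect_spacing, point_spacing = point_spacing,
    relief_m = relief_m, yield_floor = yield_floor,
    reflectance_noise_sd = reflectance_noise_sd,
    row_spacing = row_spacing, boundary_margin = boundary_margin,
    planting_date = as.Date(planting_date)
  ), class = "scenario_config")
}

# Stationary Gaussian random field: white noise smoothed by a periodic
# Gaussian kernel via FFT, standardized to mean 0 / sd 1. Deterministic
# given the RNG state.
smooth_gaussian_field <- function(n_rows, n_cols, range_px) {
  w <- matrix(stats::rnorm(n_rows * n_cols), n_rows, n_cols)
  ix <- 0:(n_cols - 1); ix <- pmin(ix, n_cols - ix)
  iy <- 0:(n_rows - 1); iy <- pmin(iy, n_rows - iy)
  k <- exp(-outer(iy^2, ix^2, "+") / (2 * range_px^2))
  k <- k / sum(k)
  f <- Re(stats::fft(stats::fft(w) * stats::fft(k), inverse = TRUE)) /
    (n_rows * n_cols)
  (f - mean(f)) / stats::sd(f)
}

zscale <- function(m) {
  v <- as.vector(m)
  (m - mean(v, na.rm = TRUE)) / stats::sd(v, na.rm = TRUE)
}

#' Generate soil-property and terrain rasters
#'
#' Sand/silt/clay are drawn per soil zone (two smoothly interlocking
#' bodies from a thresholded smoothed random field: a heavy-clay body and
#' a siltier carbonatic body), perturbed by smooth noise and closed
#' (renormalized to sum exactly 100). OM, BD and AWC are smooth fields
#' with realistic means; the DEM is a gentle diagonal ridge (highest along
#' the NW-SE diagonal, falling toward the NE and SW corners) plus smooth
#' noise, rescaled so max - min equals `config$relief_m` exactly. Slope is
#' derived with [slope_from_dem()].
#'
#' @param config A [scenario_config()].
#' @return A `soil_terrain_stack`: list of [field_raster()]s `sand`,
#'   `silt`, `clay` (percent), `om` (percent), `bd` (g/cm^3), `awc`
#'   (fraction), `dem` (m), `slope` (degrees), plus `grid`; the soil-zone
#'   indicator is attached as attribute `zone`.
#' @export
make_soil_terrain <- function(config) {
  g <- config$grid
  if (g$n_rows < 1 || g$n_cols < 1) stop("invalid-config: non-positive grid")
  nr <- g$n_rows; nc <- g$n_cols
  rng <- max(4, 0.12 * min(nr, nc))
  with_seed(config$seed, {
    zone <- smooth_gaussian_field(nr, nc, rng) > 0  # TRUE = heavy clay body
    f1 <- smooth_gaussian_field(nr, nc, rng / 2)
    f2 <- smooth_gaussian_field(nr, nc, rng / 2)
    f3 <- smooth_gaussian_field(nr, nc, rng / 2)
    f4 <- smooth_gaussian_field(nr, nc, rng / 2)
    f5 <- smooth_gaussian_field(nr, nc, rng / 2)
    f6 <- smooth_gaussian_field(nr, nc, rng / 2)
    dem_noise <- smooth_gaussian_field(nr, nc, rng)

    clip <- function(m, lo, hi) { m[m < lo] <- lo; m[m > hi] <- hi; m }
    sand <- clip(ifelse(zone, 14, 9) + 3 * f1, 1, Inf)
    silt <- clip(ifelse(zone, 30, 50) + 4 * f2, 1, Inf)
    clay <- clip(ifelse(zone, 56, 41) + 4 * f3, 1, Inf)
    tot <- sand + silt + clay
    sand <- 100 * sand / tot; silt <- 100 * silt / tot
    clay <- 100 - sand - silt  # exact closure

    om <- clip(3 + 0.4 * zone + 0.6 * f4, 0.5, 8)
    bd <- clip(1.35 + 0.06 * f5, 1.0, 1.8)
    awc <- clip(0.13 + 0.025 * f6, 0.02, 0.35)

    ctr <- pixel_centers(g)
    cx <- mean(range(ctr$x)); cy <- mean(range(ctr$y))
    # signed distance from the NW-SE diagonal ridge line (positive toward NE)
    p <- outer(ctr$y - cy, ctr$x - cx, function(y, x) (x + y) / sqrt(2))
    half_span <- max(abs(p))
    raw <- -(p / half_span)^2 + 0.18 * dem_noise
    dem <- 192 + config$relief_m * (raw - min(raw)) / (max(raw) - min(raw))

    fr <- function(m) field_raster(m, g)
    dem_r <- fr(dem)
    out <- list(sand = fr(sand), silt = fr(silt), clay = fr(clay),
                om = fr(om), bd = fr(bd), awc = fr(awc),
                dem = dem_r, slope = slope_from_dem(dem_r), grid = g)
    attr(out, "zone") <- zone
    class(out) <- "soil_terrain_stack"
    out
  })
}

#' Latent crop-vigor field
#'
#' `vigor = standardize(w_soil * soil_score + w_slope * (-z(slope)) +
#' noise)`, where the soil score is the documented linear blend
#' `0.5 z(OM) + 0.3 z(AWC) - 0.2 z(clay)` of standardized rasters and the
#' noise is a spatially smooth random field with sd
#' `config$vigor_noise_sd`. Deterministic given `config$seed`.
#'
#' @param soil A `soil_terrain_stack` on `config$grid`.
#' @param config A [scenario_config()].
#' @return A standardized [field_raster()] with the soil-score raster
#'   attached as attribute `soil_score`.
#' @export
latent_vigor <- function(soil, config) {
  stop_if_grid_mismatch(soil$grid, config$grid)
  g <- soil$grid
  soil_score <- 0.5 * zscale(unclass(soil$om)) +
    0.3 * zscale(unclass(soil$awc)) - 0.2 * zscale(unclass(soil$clay))
  soil_score <- zscale(soil_score)
  slope_z <- zscale(unclass(soil$slope))
  # vigor noise is plant-scale variability: near-white (1-pixel range), so
  # it neither masquerades as a field-scale soil pattern nor correlates
  # between neighboring harvest footprints
  noise <- with_seed(config$seed + 11L, {
    smooth_gaussian_field(g$n_rows, g$n_cols, 0.5)
  })
  raw <- config$soil_effect_weight * soil_score -
    config$slope_effect_weight * slope_z + config$vigor_noise_sd * noise
  out <- field_raster(zscale(raw), g)
  attr(out, "soil_score") <- field_raster(soil_score, g)
  out
}

load_endmembers <- function() {
  path <- system.file("extdata", "endmembers.yml", package = "canopyield")
  em <- yaml::read_yaml(path)
  lapply(em, function(e) unlist(e)[c("blue", "green", "red", "rededge", "nir")])
}

#' Mix two endmember spectra
#'
#' @param w Mixing weight(s) in `[0, 1]`; 1 returns `em1` exactly.
#' @param em1,em2 Named 5-band reflectance vectors.
#' @return Matrix with one row per weight, one column per band.
#' @export
mix_spectra <- function(w, em1, em2) {
  outer(w, em1) + outer(1 - w, em2)
}

# Perpendicular pixel distance (in pixels) to the nearest planting row
# line; rows run east-west every `row_spacing` meters.
row_distance <- function(grid, row_spacing) {
  row_px <- max(1L, round(row_spacing / grid$pixel_size))
  d <- (seq_len(grid$n_rows) - 1L) %% row_px
  d <- pmin(d, row_px - d)
  matrix(d, grid$n_rows, grid$n_cols)
}

#' Generate the per-stage reflectance series
#'
#' For each growth stage a canopy mask covering exactly
#' `canopy_cover_by_stage[i]` of the field is grown outward from
#' east-west planting rows (pixels join in order of distance to the
#' nearest row, so later stages nest earlier ones). Canopy pixels get a
#' two-endmember mixture of the healthy and stressed canopy spectra with
#' weight `pnorm(vigor)`; bare pixels get the soil endmember; all bands
#' receive independent Gaussian noise (`reflectance_noise_sd`) and are
#' clipped to `[0, 1]`.
#'
#' @param soil A `soil_terrain_stack` on `config$grid`.
#' @param config A [scenario_config()].
#' @return List of `reflectance_stack` objects (one per stage), each a
#'   list of [field_raster()]s `blue`, `green`, `red`, `rededge`, `nir`
#'   plus `stage_label`, `dap`, `flight_date`, `grid`; ground truth is
#'   attached as attributes `truth_canopy` (logical matrix) and `vigor`.
#' @export
make_reflectance_series <- function(soil, config) {
  stop_if_grid_mismatch(soil$grid, config$grid)
  g <- config$grid
  em <- load_endmembers()
  vigor <- latent_vigor(soil, config)
  w <- stats::pnorm(as.vector(unclass(vigor)))
  dist <- as.vector(row_distance(g, config$row_spacing))
  # ties at equal row distance fill in a seeded spatially-uniform order, so
  # a partially filled row ring spreads over the whole field
  tie <- with_seed(config$seed + 50L, sample.int(length(dist)))
  ord <- order(dist, tie)
  npix <- length(dist)
  stage_idx <- if (config$n_stages == nrow(STAGE_TABLE)) {
    seq_len(nrow(STAGE_TABLE))
  } else round(seq(1, nrow(STAGE_TABLE), length.out = config$n_stages))
  bands <- c("blue", "green", "red", "rededge", "nir")

  lapply(seq_len(config$n_stages), function(i) {
    cover <- config$canopy_cover_by_stage[i]
    n_canopy <- round(cover * npix)
    canopy <- logical(npix)
    if (n_canopy > 0) canopy[ord[seq_len(n_canopy)]] <- TRUE
    canopy_mix <- mix_spectra(w, em$healthy_canopy, em$stressed_canopy)
    stack <- with_seed(config$seed + 100L + i, {
      out <- lapply(seq_along(bands), function(bi) {
        v <- ifelse(canopy, canopy_mix[, bi], em$bare_soil[[bands[bi]]])
        if (config$reflectance_noise_sd > 0) {
          v <- v + stats::rnorm(npix, 0, config$reflectance_noise_sd)
        }
        field_raster(matrix(pmin(1, pmax(0, v)), g$n_rows, g$n_cols), g)
      })
      names(out) <- bands
      out
    })
    stack$stage_label <- STAGE_TABLE$stage_label[stage_idx[i]]
    stack$dap <- STAGE_TABLE$dap[stage_idx[i]]
    stack$flight_date <- config$planting_date + stack$dap
    stack$grid <- g
    attr(stack, "truth_canopy") <- matrix(canopy, g$n_rows, g$n_cols)
    attr(stack, "vigor") <- vigor
    class(stack) <- "reflectance_stack"
    stack
  })
}

field_boundary <- function(config) {
  g <- config$grid
  m <- config$boundary_margin
  xmin <- g$origin_x + m; xmax <- g$origin_x + g$n_cols * g$pixel_size - m
  ymax <- g$origin_y - m; ymin <- g$origin_y - g$n_rows * g$pixel_size + m
  cbind(x = c(xmin, xmax, xmax, xmin), y = c(ymin, ymin, ymax, ymax))
}

sample_raster_at <- function(r, x, y) {
  g <- raster_grid(r)
  col <- pmin(g$n_cols, pmax(1L, floor((x - g$origin_x) / g$pixel_size) + 1L))
  row <- pmin(g$n_rows, pmax(1L, floor((g$origin_y - y) / g$pixel_size) + 1L))
  unclass(r)[cbind(row, col)]
}

# Mean of the raster over the rectangular harvested footprint (wx by wy
# meters) centered on each point: the combine integrates grain over the
# whole footprint, not the GPS centroid pixel.
sample_footprint_mean <- function(r, x, y, wx, wy) {
  g <- raster_grid(r)
  v <- unclass(r)
  px <- g$pixel_size
  # pixels whose CENTERS fall in the window, so the windows of adjacent
  # points partition the pixels (no double-counted boundary pixels)
  c1 <- pmax(1L, ceiling((x - wx / 2 - g$origin_x) / px + 0.5))
  c2 <- pmin(g$n_cols, ceiling((x + wx / 2 - g$origin_x) / px + 0.5) - 1L)
  r1 <- pmax(1L, ceiling((g$origin_y - (y + wy / 2)) / px + 0.5))
  r2 <- pmin(g$n_rows, ceiling((g$origin_y - (y - wy / 2)) / px + 0.5) - 1L)
  c2 <- pmax(c2, c1); r2 <- pmax(r2, r1)
  vapply(seq_along(x), function(i) {
    mean(v[r1[i]:r2[i], c1[i]:c2[i]])
  }, 0)
}

#' Generate harvester yield points on parallel transects
#'
#' Points are laid on east-west transects spaced `transect_spacing` m
#' apart, every `point_spacing` m, strictly inside the field boundary
#' (the raster extent inset by `boundary_margin`). Yield is
#' `yield_mean * (1 + yield_cv * response)` clipped below at
#' `yield_floor`, where the standardized response is linear in vigor, the
#' soil score and the slope benefit (`-z(slope)`) under
#' `nonlinearity = "linear"`, and additionally carries a clay-by-slope
#' interaction and a low-vigor threshold penalty under
#' `"threshold-interaction"`. The realized generating coefficients (on
#' the standardized covariates, in Mg/ha per SD) are stored in the
#' `truth` attribute for recovery tests.
#'
#' @param soil A `soil_terrain_stack`.
#' @param vigor_final The standardized vigor [field_raster()]
#'   (from [latent_vigor()]).
#' @param config A [scenario_config()].
#' @return A `harvest_point_set`: data frame with `point_id`, `x`, `y`,
#'   `yield_mg_ha`; attributes `harvested_area_per_point`, `boundary`
#'   (polygon vertex matrix) and `truth` (generating coefficients,
#'   covariates, noise sd).
#' @export
make_harvest_points <- function(soil, vigor_final, config) {
  stop_if_grid_mismatch(soil$grid, raster_grid(vigor_final))
  bnd <- field_boundary(config)
  xmin <- min(bnd[, 1]); xmax <- max(bnd[, 1])
  ymin <- min(bnd[, 2]); ymax <- max(bnd[, 2])
  if (ymin + config$transect_spacing / 2 >= ymax ||
      xmin + config$point_spacing / 2 >= xmax) {
    stop("empty-output: transect or point spacing exceeds the field extent",
         call. = FALSE)
  }
  ys <- seq(ymin + config$transect_spacing / 2, ymax,
            by = config$transect_spacing)
  ys <- ys[ys < ymax]
  xs <- seq(xmin + config$point_spacing / 2, xmax, by = config$point_spacing)
  xs <- xs[xs < xmax]
  pts <- expand.grid(x = xs, y = ys, KEEP.OUT.ATTRS = FALSE)
  n <- nrow(pts)

  soil_score <- attr(vigor_final, "soil_score")
  zslope_r <- field_raster(zscale(unclass(soil$slope)), soil$grid)
  zclay_r <- field_raster(zscale(unclass(soil$clay)), soil$grid)
  # every covariate is integrated over the harvested footprint, as the
  # combine does; footprint means are then standardized over points
  wx <- config$point_spacing; wy <- config$transect_spacing
  zv <- zscale(sample_footprint_mean(vigor_final, pts$x, pts$y, wx, wy))
  zs <- zscale(sample_footprint_mean(soil_score, pts$x, pts$y, wx, wy))
  zslope <- zscale(sample_footprint_mean(zslope_r, pts$x, pts$y, wx, wy))
  zclay <- zscale(sample_footprint_mean(zclay_r, pts$x, pts$y, wx, wy))
  zp <- -zslope  # slope benefit: flatter ground yields more

  b <- c(vigor = 0.8, soil = 0.5 * config$soil_effect_weight,
         slope = 0.5 * config$slope_effect_weight)
  noise_sd <- 0.5
  raw <- b["vigor"] * zv + b["soil"] * zs + b["slope"] * zp
  if (config$nonlinearity == "threshold-interaction") {
    # the nonlinear structure carries weight comparable to the linear part:
    # a clay-by-slope interaction (waterlogging on heavy flat clay vs
    # droughty steep clay) plus a low-vigor threshold penalty
    raw <- raw + 0.8 * config$soil_effect_weight * zclay * zslope -
      1.0 * pmax(-0.2 - zv, 0)
  }
  eps <- with_seed(config$seed + 2000L, stats::rnorm(n, 0, noise_sd))
  raw <- raw + eps
  s <- if (config$yield_cv > 0) stats::sd(raw) else 1
  yield <- pmax(config$yield_floor,
                config$yield_mean * (1 + config$yield_cv * raw / s))

  out <- data.frame(point_id = seq_len(n), x = pts$x, y = pts$y,
                    yield_mg_ha = yield)
  attr(out, "harvested_area_per_point") <-
    config$transect_spacing * config$point_spacing
  attr(out, "boundary") <- bnd
  scale_f <- config$yield_mean * config$yield_cv / s
  attr(out, "truth") <- list(
    coefficients = c(intercept = config$yield_mean,
                     vigor = unname(b["vigor"]) * scale_f,
                     soil = unname(b["soil"]) * scale_f,
                     slope_benefit = unname(b["slope"]) * scale_f),
    covariates = data.frame(zv = zv, zs = zs, zp = zp,
                            zclay = zclay, zslope = zslope),
    noise_sd = noise_sd * scale_f,
    response_sd = s,
    nonlinearity = config$nonlinearity
  )
  class(out) <- c("harvest_point_set", "data.frame")
  out
}

#' Write harvest points to CSV / GeoJSON
#'
#' @param points A `harvest_point_set`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_points_csv <- function(points, path) {
  utils::write.csv(as.data.frame(points)[, c("point_id", "x", "y",
                                             "yield_mg_ha")],
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_points_csv
#' @export
write_points_geojson <- function(points, path) {
  features <- lapply(seq_len(nrow(points)), function(i) {
    list(type = "Feature",
         geometry = list(type = "Point",
                         coordinates = c(points$x[i], points$y[i])),
         properties = list(point_id = points$point_id[i],
                           yield_mg_ha = points$yield_mg_ha[i]))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = features),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Save / load a scenario configuration
#'
#' Flat key-value config file (YAML).
#' @param config A [scenario_config()].
#' @param path File path.
#' @return `read_scenario_config()` returns a [scenario_config()].
#' @export
write_scenario_config <- function(config, path) {
  x <- unclass(config)
  x$grid <- unclass(x$grid)
  x$planting_date <- as.character(x$planting_date)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_scenario_config
#' @export
read_scenario_config <- function(path) {
  x <- yaml::read_yaml(path)
  g <- x$grid
  do.call(scenario_config, c(
    list(grid = grid_spec(g$n_rows, g$n_cols, g$pixel_size, g$origin_x,
                          g$origin_y, g$crs_label)),
    x[setdiff(names(x), "grid")]
  ))
}
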