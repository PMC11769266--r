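small_cfg <- function(seed = 1, ...) {
  scenario_config(seed = seed, grid = grid_spec(60, 60, 1), n_stages = 3,
                  canopy_cover_by_stage = c(0.2, 0.5, 0.75), ...)
}

test_that("soil/terrain generation is seed-deterministic and validated", {
  cfg <- small_cfg()
  a <- make_soil_terrain(cfg)
  b <- make_soil_terrain(cfg)
  expect_identical(unclass(a$sand), unclass(b$sand))
  expect_identical(unclass(a$dem), unclass(b$dem))
  c2 <- make_soil_terrain(small_cfg(seed = 2))
  expect_false(identical(unclass(a$sand), unclass(c2$sand)))
  expect_error(scenario_config(grid = grid_spec(0, 10)), "invalid")
  expect_error(scenario_config(yield_cv = 1.2), "invalid-config")
  expect_error(scenario_config(n_stages = 3,
                               canopy_cover_by_stage = c(0.5, 0.4, 0.6)),
               "non-decreasing")
})

test_that("soil textures close to 100 percent and ranges are physical", {
  soil <- make_soil_terrain(small_cfg())
  total <- unclass(soil$sand) + unclass(soil$silt) + unclass(soil$clay)
  expect_lt(max(abs(total - 100)), 1e-6)
  for (nm in c("sand", "silt", "clay", "om")) {
    v <- as.vector(unclass(soil[[nm]]))
    expect_true(all(v >= 0 & v <= 100), info = nm)
  }
  expect_true(all(unclass(soil$slope) >= 0))
})

test_that("DEM relief hits the configured target exactly", {
  soil <- make_soil_terrain(small_cfg())
  expect_equal(max(unclass(soil$dem)) - min(unclass(soil$dem)), 8,
               tolerance = 0.01)
  soil5 <- make_soil_terrain(small_cfg(relief_m = 5))
  expect_equal(max(unclass(soil5$dem)) - min(unclass(soil5$dem)), 5,
               tolerance = 0.01)
})

test_that("reflectance series honors cover fractions, mixing and nodata rules", {
  cfg <- small_cfg()
  soil <- make_soil_terrain(cfg)
  stacks <- make_reflectance_series(soil, cfg)
  expect_length(stacks, 3)
  em <- canopyield:::load_endmembers()
  for (i in seq_along(stacks)) {
    truth <- attr(stacks[[i]], "truth_canopy")
    expect_equal(mean(truth), cfg$canopy_cover_by_stage[i], tolerance = 1e-3)
    for (b in c("blue", "green", "red", "rededge", "nir")) {
      v <- as.vector(unclass(stacks[[i]][[b]]))
      expect_true(all(v >= 0 & v <= 1))
    }
  }
  # canopy masks nest across stages (canopy only grows)
  expect_true(all(attr(stacks[[2]], "truth_canopy") |
                    !attr(stacks[[1]], "truth_canopy")))

  # zero cover limit: all pixels carry the soil endmember spectrum
  cfg0 <- scenario_config(seed = 1, grid = grid_spec(30, 30, 1), n_stages = 1,
                          canopy_cover_by_stage = 0, reflectance_noise_sd = 0)
  soil0 <- make_soil_terrain(cfg0)
  s0 <- make_reflectance_series(soil0, cfg0)[[1]]
  expect_true(all(unclass(s0$red) == em$bare_soil[["red"]]))
  expect_true(all(unclass(s0$nir) == em$bare_soil[["nir"]]))

  # mixing identity: weight 1 reproduces the healthy endmember's NDVIre
  mixed <- mix_spectra(1, em$healthy_canopy, em$stressed_canopy)
  nd <- (mixed[, "rededge"] - mixed[, "red"]) /
    (mixed[, "rededge"] + mixed[, "red"])
  nd_healthy <- (em$healthy_canopy[["rededge"]] - em$healthy_canopy[["red"]]) /
    (em$healthy_canopy[["rededge"]] + em$healthy_canopy[["red"]])
  expect_equal(unname(nd), nd_healthy)
})

test_that("auto NDVIre threshold recovers the stored canopy mask at half cover", {
  cfg <- scenario_config(seed = 3, grid = grid_spec(100, 100, 1), n_stages = 1,
                         canopy_cover_by_stage = 0.5)
  soil <- make_soil_terrain(cfg)
  stack <- make_reflectance_series(soil, cfg)[[1]]
  mask <- ndvire_mask(stack$rededge, stack$red, "auto")
  truth <- attr(stack, "truth_canopy")
  thr <- attr(mask, "threshold_used")
  ndvire <- (unclass(stack$rededge) - unclass(stack$red)) /
    (unclass(stack$rededge) + unclass(stack$red))
  # the two populations are separated: threshold sits in the gap
  expect_gt(thr, max(ndvire[!truth]) - 0.05)
  expect_lt(thr, min(ndvire[truth]) + 0.05)
  agreement <- mean((unclass(mask) == 1) == truth)
  expect_gte(agreement, 0.99)
})

test_that("harvest points: moments, degenerate noise, boundary containment", {
  # n >= 5000 points for the sampling check on the configured CV
  cfg <- scenario_config(seed = 5, grid = grid_spec(320, 320, 1), n_stages = 1,
                         transect_spacing = 4.6, point_spacing = 3.7)
  soil <- make_soil_terrain(cfg)
  vig <- latent_vigor(soil, cfg)
  pts <- make_harvest_points(soil, vig, cfg)
  expect_gte(nrow(pts), 5000)
  cv <- sd(pts$yield_mg_ha) / mean(pts$yield_mg_ha)
  expect_lt(abs(cv - cfg$yield_cv) / cfg$yield_cv, 0.2)
  expect_equal(mean(pts$yield_mg_ha), cfg$yield_mean, tolerance = 0.05)
  bnd <- attr(pts, "boundary")
  expect_true(all(pts$x > min(bnd[, 1]) & pts$x < max(bnd[, 1])))
  expect_true(all(pts$y > min(bnd[, 2]) & pts$y < max(bnd[, 2])))
  expect_false(any(duplicated(pts$point_id)))
  expect_true(all(pts$yield_mg_ha > 0))

  cfg0 <- small_cfg(yield_cv = 0)
  soil0 <- make_soil_terrain(cfg0)
  pts0 <- make_harvest_points(soil0, latent_vigor(soil0, cfg0), cfg0)
  expect_true(all(pts0$yield_mg_ha == cfg0$yield_mean))

  cfg_big <- small_cfg(transect_spacing = 500)
  expect_error(make_harvest_points(soil0, latent_vigor(soil0, cfg0), cfg_big),
               "empty-output")
})

test_that("vigor decouples from soil when the soil weight is zero", {
  cfg <- scenario_config(seed = 8, grid = grid_spec(120, 120, 1), n_stages = 1,
                         soil_effect_weight = 0, slope_effect_weight = 0)
  soil <- make_soil_terrain(cfg)
  vig <- latent_vigor(soil, cfg)
  pts <- make_harvest_points(soil, vig, cfg)
  tr <- attr(pts, "truth")
  expect_equal(unname(tr$coefficients[c("soil", "slope_benefit")]), c(0, 0))
  # partial correlation of yield with the soil score given vigor ~ 0
  res_y <- resid(lm(pts$yield_mg_ha ~ tr$covariates$zv))
  res_s <- resid(lm(tr$covariates$zs ~ tr$covariates$zv))
  expect_lt(abs(cor(res_y, res_s)), 3 / sqrt(nrow(pts)) + 0.05)
})

test_that("point sets and configs survive their file formats", {
  cfg <- small_cfg()
  soil <- make_soil_terrain(cfg)
  pts <- make_harvest_points(soil, latent_vigor(soil, cfg), cfg)
  csv <- tempfile(fileext = ".csv"); gj <- tempfile(fileext = ".geojson")
  write_points_csv(pts, csv)
  back <- utils::read.csv(csv)
  expect_equal(back$yield_mg_ha, pts$yield_mg_ha)
  write_points_geojson(pts, gj)
  parsed <- jsonlite::read_json(gj)
  expect_equal(parsed$type, "FeatureCollection")
  expect_length(parsed$features, nrow(pts))
  yml <- tempfile(fileext = ".yml")
  write_scenario_config(cfg, yml)
  cfg2 <- read_scenario_config(yml)
  expect_equal(cfg2$yield_mean, cfg$yield_mean)
  expect_equal(cfg2$canopy_cover_by_stage, cfg$canopy_cover_by_stage)
  expect_true(canopyield:::same_grid(cfg2$grid, cfg$grid))
  unlink(c(csv, gj, yml))
})
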