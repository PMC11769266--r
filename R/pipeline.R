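#' @title End-to-end pipeline
#' @description
#' Orchestration from rasters + harvest points to per-stage feature
#' tables, fitted models, accuracy metrics and comparison statistics,
#' with a fully synthetic entry point for validation studies.
#' @name pipeline
NULL

# The five non-spectral predictors whose joint contribution the
# soil-inclusion t-test measures.
SOIL_SLOPE_PREDICTORS <- c("sand", "silt", "clay", "om", "slope")

#' Assemble the per-polygon feature table for one growth stage
#'
#' Masks bare ground on the stage's reflectance stack
#' ([ndvire_mask()] + [apply_mask()]), extracts the zonal mean of each
#' band over vegetation pixels, computes every registered spectral index
#' from those zonal band means, extracts zonal means of the soil and
#' slope rasters (unmasked), and joins the observed yield by polygon id.
#' Rows with any missing predictor (e.g. fully-masked polygons) are
#' dropped; the number dropped is attached as attribute `n_dropped`.
#'
#' @param stack A `reflectance_stack`.
#' @param soil A `soil_terrain_stack` on the same grid.
#' @param polys A (filtered) `field_polygon_set`.
#' @param points The `harvest_point_set` supplying yields.
#' @param mask_threshold Numeric NDVIre threshold or `"auto"` (Otsu).
#' @return Feature table: one row per retained polygon with `polygon_id`,
#'   `stage_label`, `dap`, band / index / soil / slope predictors and
#'   `yield_mg_ha`.
#' @export
build_feature_table <- function(stack, soil, polys, points,
                                mask_threshold = "auto") {
  mask <- ndvire_mask(stack$rededge, stack$red, mask_threshold)
  masked <- apply_mask(stack, mask)
  bands <- c("blue", "green", "red", "rededge", "nir")
  band_means <- lapply(bands, function(b) zonal_mean(masked[[b]], polys)$mean)
  names(band_means) <- bands
  tab <- data.frame(polygon_id = vapply(polys, `[[`, 0, "polygon_id"))
  for (b in bands) tab[[b]] <- band_means[[b]]
  tab <- cbind(tab, compute_indices(band_means))
  for (s in c("sand", "silt", "clay", "om", "bd", "awc", "slope")) {
    tab[[s]] <- zonal_mean(soil[[s]], polys)$mean
  }
  tab <- merge(tab, as.data.frame(points)[, c("point_id", "yield_mg_ha")],
               by.x = "polygon_id", by.y = "point_id", sort = TRUE)
  tab$stage_label <- stack$stage_label
  tab$dap <- stack$dap
  keep <- stats::complete.cases(tab)
  out <- tab[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_dropped") <- sum(!keep)
  attr(out, "mask_threshold") <- attr(mask, "threshold_used")
  out
}

#' Generate a synthetic scenario end to end
#'
#' Runs the synthetic generator and the geometric feature extraction:
#' soil/terrain, reflectance series, harvest points, Thiessen polygons
#' (filtered by area, roundness and edge contact) and one feature table
#' per growth stage.
#'
#' @param config A [scenario_config()].
#' @param mask_threshold Per-stage NDVIre threshold(s) or `"auto"`.
#' @param area_bounds,roundness_max,drop_edges Polygon filter settings
#'   (defaults: 0.5x-2x the nominal per-point area, 3, TRUE).
#' @return List with `soil`, `vigor`, `stacks`, `points`, `polygons`
#'   (filtered) and `tables` (list of per-stage feature tables).
#' @export
run_scenario <- function(config, mask_threshold = "auto",
                         area_bounds = NULL, roundness_max = 3,
                         drop_edges = TRUE) {
  soil <- make_soil_terrain(config)
  vigor <- latent_vigor(soil, config)
  stacks <- make_reflectance_series(soil, config)
  points <- make_harvest_points(soil, vigor, config)
  if (is.null(area_bounds)) {
    nominal <- attr(points, "harvested_area_per_point")
    area_bounds <- c(0.5, 2) * nominal
  }
  polys <- thiessen_polygons(points)
  polys <- filter_polygons(polys, area_bounds, roundness_max, drop_edges)
  thr <- rep_len(if (identical(mask_threshold, "auto")) list("auto") else
    as.list(mask_threshold), length(stacks))
  tables <- lapply(seq_along(stacks), function(i) {
    build_feature_table(stacks[[i]], soil, polys, points, thr[[i]])
  })
  names(tables) <- vapply(stacks, `[[`, "", "stage_label")
  list(soil = soil, vigor = vigor, stacks = stacks, points = points,
       polygons = polys, tables = tables)
}

#' Fit and evaluate the regression methods across growth stages
#'
#' Splits each stage's feature table 80:20 (or `split_ratio`), fits every
#' requested method and evaluates on the held-out rows; optionally refits
#' without the soil/slope predictor block (`sand, silt, clay, om, slope`)
#' for the soil-inclusion comparison.
#'
#' @param tables Named list of per-stage feature tables.
#' @param model_kinds Subset of `c("MLR","RF","GBR","XGB")`.
#' @param split_ratio Training fraction (default 0.8).
#' @param seed Seed for splits and stochastic learners.
#' @param with_reduced Also fit models without soil/slope predictors.
#' @return Data frame with `method`, `stage_label`, `dap`, `predictors`
#'   (`"full"` / `"reduced"`), `rmse`, `r2`, `n_train`, `n_test`.
#' @export
evaluate_stage_models <- function(tables,
                                  model_kinds = c("MLR", "RF", "GBR", "XGB"),
                                  split_ratio = 0.8, seed = 1L,
                                  with_reduced = FALSE) {
  rows <- list()
  for (stage in names(tables)) {
    tab <- tables[[stage]]
    # each stage's dataset gets its own random partition (salted by its
    # position), so stages provide independent replicates downstream
    stage_seed <- seed + 1000L * match(stage, names(tables))
    sp <- split_train_test(tab, split_ratio, stage_seed)
    variants <- list(full = tab)
    if (with_reduced) {
      keep <- setdiff(names(tab), SOIL_SLOPE_PREDICTORS)
      variants$reduced <- tab[, keep, drop = FALSE]
    }
    for (variant in names(variants)) {
      cols <- names(variants[[variant]])
      for (kind in model_kinds) {
        if (variant == "reduced" && kind == "MLR") next
        fit <- fit_model(model_config(kind, seed = seed),
                         sp$train[, cols, drop = FALSE])
        met <- evaluate(fit, sp$test[, cols, drop = FALSE])
        rows[[length(rows) + 1L]] <- data.frame(
          method = kind, stage_label = stage, dap = tab$dap[1],
          predictors = variant, rmse = met$rmse, r2 = met$r2,
          n_train = nrow(sp$train), n_test = nrow(sp$test),
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

#' Method-by-stage RMSE matrix from evaluation results
#'
#' @param metrics Output of [evaluate_stage_models()].
#' @param predictors Which variant to tabulate (default `"full"`).
#' @return Numeric matrix, methods in rows, stages in columns.
#' @export
rmse_matrix <- function(metrics, predictors = "full") {
  m <- metrics[metrics$predictors == predictors, ]
  stats::xtabs(rmse ~ method + stage_label, data = m)[, unique(m$stage_label),
                                                      drop = FALSE] |>
    unclass()
}

#' Run the full pipeline from a single configuration
#'
#' Executes generate -> mask -> polygons -> zonal -> feature tables ->
#' split -> per-stage fits -> metrics -> method comparison ->
#' soil-inclusion test, and writes per-stage feature-table CSVs, a
#' metrics JSON, comparison statistics and a MANIFEST to `output_dir`.
#' Reruns with an identical configuration produce identical outputs.
#'
#' @param config A [scenario_config()].
#' @param output_dir Output directory (created if absent).
#' @param model_kinds Methods to fit.
#' @param split_ratio Training fraction.
#' @param mask_threshold NDVIre threshold(s) or `"auto"`.
#' @param run_selection Also run [iterative_feature_selection()] (RF) on
#'   the final stage (default TRUE).
#' @param quiet Suppress stage-by-stage progress messages.
#' @return Invisibly, a list with `metrics`, `comparison`,
#'   `soil_inclusion_p`, `selection` and `manifest`.
#' @export
run_pipeline <- function(config, output_dir,
                         model_kinds = c("MLR", "RF", "GBR", "XGB"),
                         split_ratio = 0.8, mask_threshold = "auto",
                         run_selection = TRUE, quiet = FALSE) {
  say <- function(...) if (!quiet) message(sprintf(...))
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  emit <- function(name) { files <<- c(files, name); file.path(output_dir, name) }

  say("simulate: %d x %d grid, %d stages, seed %d", config$grid$n_rows,
      config$grid$n_cols, config$n_stages, config$seed)
  sc <- run_scenario(config, mask_threshold = mask_threshold)
  say("points: %d harvest records; polygons retained: %d (dropped: %s)",
      nrow(sc$points), length(sc$polygons),
      paste(names(attr(sc$polygons, "dropped")),
            attr(sc$polygons, "dropped"), sep = "=", collapse = ", "))

  for (stage in names(sc$tables)) {
    tab <- sc$tables[[stage]]
    say("stage %s (DAP %d): %d rows, %d dropped, mask threshold %.3f",
        stage, tab$dap[1], nrow(tab), attr(tab, "n_dropped"),
        attr(tab, "mask_threshold"))
    fn <- sprintf("features_%s.csv", gsub("[^A-Za-z0-9]", "_", stage))
    utils::write.csv(tab, emit(fn), row.names = FALSE)
  }
  schema <- list(columns = names(sc$tables[[1]]),
                 target = "yield_mg_ha", meta = META_COLUMNS)
  jsonlite::write_json(schema, emit("feature_schema.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  metrics <- evaluate_stage_models(sc$tables, model_kinds, split_ratio,
                                   config$seed, with_reduced = TRUE)
  utils::write.csv(metrics, emit("metrics.csv"), row.names = FALSE)

  comparison <- NULL; soil_p <- NA_real_
  if (length(model_kinds) >= 2L && config$n_stages >= 2L) {
    comparison <- compare_methods(rmse_matrix(metrics, "full"))
    full_ens <- metrics[metrics$predictors == "full" &
                          metrics$method != "MLR", ]
    red_ens <- metrics[metrics$predictors == "reduced", ]
    key <- function(d) order(d$method, d$stage_label)
    soil_p <- soil_inclusion_test(full_ens$rmse[key(full_ens)],
                                  red_ens$rmse[key(red_ens)])
  }
  selection <- NULL
  if (run_selection) {
    final <- sc$tables[[length(sc$tables)]]
    selection <- iterative_feature_selection(
      final, model_config("RF", seed = config$seed))
    say("selection (final stage): %d predictors retained",
        length(selection$selected))
  }
  report <- list(
    metrics = metrics,
    anova_p = comparison$anova_p,
    lsd_letters = as.list(comparison$letters),
    method_mean_rmse = as.list(comparison$means),
    soil_inclusion_p = soil_p,
    selected_features = selection$selected
  )
  jsonlite::write_json(report, emit("report.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, na = "null")
  if (!is.null(selection)) {
    utils::write.csv(selection$history, emit("selection_history.csv"),
                     row.names = FALSE)
  }
  write_points_csv(sc$points, emit("harvest_points.csv"))
  write_polygons_geojson(sc$polygons, emit("polygons.geojson"))
  write_scenario_config(config, emit("scenario_config.yml"))

  manifest <- list(
    package = "canopyield",
    version = as.character(utils::packageVersion("canopyield")),
    seed = config$seed,
    files = sort(c(files, "MANIFEST.json"))
  )
  jsonlite::write_json(manifest, file.path(output_dir, "MANIFEST.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(metrics = metrics, comparison = comparison,
                 soil_inclusion_p = soil_p, selection = selection,
                 manifest = manifest))
}

#' Replicate the scenario study over several seeds
#'
#' Generates one synthetic scenario per seed, runs the full feature
#' pipeline and evaluates the requested methods per stage (optionally
#' also without the soil/slope predictors), stacking all metrics with a
#' `seed` column. This is the workhorse behind the method-ranking and
#' soil-inclusion validation studies.
#'
#' @param seeds Integer vector of scenario seeds.
#' @param grid,n_stages,canopy_cover_by_stage,nonlinearity,soil_effect_weight,slope_effect_weight
#'   Passed to [scenario_config()]; defaults are the desk-scale study
#'   conditions (100 x 100 m at 1 m, five stages at 15-75 % cover).
#'   Five stages keep the (method, stage) cells of the comparison
#'   statistics reasonably replicated; with very few stages the paired
#'   tests lean on too few independent partitions.
#' @param model_kinds,split_ratio,with_reduced Passed to
#'   [evaluate_stage_models()].
#' @return Data frame of per-seed, per-stage, per-method metrics.
#' @export
run_replicated_study <- function(seeds,
                                 grid = grid_spec(100, 100, 1),
                                 n_stages = 5,
                                 canopy_cover_by_stage = seq(0.15, 0.75,
                                                             length.out = 5),
                                 nonlinearity = "threshold-interaction",
                                 soil_effect_weight = 1,
                                 slope_effect_weight = 0.6,
                                 model_kinds = c("MLR", "RF", "GBR", "XGB"),
                                 split_ratio = 0.8,
                                 with_reduced = TRUE) {
  do.call(rbind, lapply(seeds, function(s) {
    cfg <- scenario_config(
      seed = s, grid = grid, n_stages = n_stages,
      canopy_cover_by_stage = canopy_cover_by_stage,
      nonlinearity = nonlinearity,
      soil_effect_weight = soil_effect_weight,
      slope_effect_weight = slope_effect_weight)
    sc <- run_scenario(cfg)
    m <- evaluate_stage_models(sc$tables, model_kinds, split_ratio,
                               seed = s, with_reduced = with_reduced)
    m$seed <- s
    m
  }))
}

#' Pair full and reduced RMSEs for the soil-inclusion comparison
#'
#' @param metrics Output of [run_replicated_study()] (with reduced fits).
#' @return Data frame with one row per (seed, method, stage) pair and
#'   columns `full` and `reduced`.
#' @export
soil_inclusion_pairs <- function(metrics) {
  red <- metrics[metrics$predictors == "reduced", ]
  full <- metrics[metrics$predictors == "full" &
                    metrics$method %in% unique(red$method), ]
  key <- function(d) paste(d$seed, d$method, d$stage_label)
  stopifnot(setequal(key(full), key(red)))
  red <- red[match(key(full), key(red)), ]
  data.frame(seed = full$seed, method = full$method,
             stage_label = full$stage_label,
             full = full$rmse, reduced = red$rmse)
}
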