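#!/usr/bin/env Rscript
# Simulate the study field: soil bodies, terrain, per-stage canopy
# reflectance and harvester yield points, and write the raw layers.
# Downstream scripts (02-04) re-derive everything from the same seed, so
# this script's outputs are for inspection and external tooling.

suppressMessages(library(canopyield))

out <- "results/01_simulate"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cfg <- scenario_config(seed = 1, grid = grid_spec(150, 150, 1), n_stages = 3,
                       canopy_cover_by_stage = c(0.2, 0.5, 0.75))
write_scenario_config(cfg, file.path(out, "scenario_config.yml"))

soil <- make_soil_terrain(cfg)
for (nm in c("sand", "silt", "clay", "om", "bd", "awc", "dem", "slope")) {
  write_ascii_grid(soil[[nm]], file.path(out, paste0(nm, ".asc")))
}
message(sprintf("soil/terrain written: relief %.2f m, clay %.0f-%.0f %%",
                max(unclass(soil$dem)) - min(unclass(soil$dem)),
                min(unclass(soil$clay)), max(unclass(soil$clay))))

vigor <- latent_vigor(soil, cfg)
write_ascii_grid(vigor, file.path(out, "vigor.asc"))

stacks <- make_reflectance_series(soil, cfg)
for (s in stacks) {
  tag <- gsub("[^A-Za-z0-9]", "_", s$stage_label)
  for (b in c("blue", "green", "red", "rededge", "nir")) {
    write_ascii_grid(s[[b]], file.path(out, sprintf("refl_%s_%s.asc", tag, b)))
  }
  message(sprintf("stage %s (DAP %d): canopy cover %.0f %%", s$stage_label,
                  s$dap, 100 * mean(attr(s, "truth_canopy"))))
}

pts <- make_harvest_points(soil, vigor, cfg)
write_points_csv(pts, file.path(out, "harvest_points.csv"))
write_points_geojson(pts, file.path(out, "harvest_points.geojson"))
message(sprintf(
  "harvest points: %d records, mean %.2f Mg/ha, CV %.1f %% (%.1f m2 each)",
  nrow(pts), mean(pts$yield_mg_ha),
  100 * sd(pts$yield_mg_ha) / mean(pts$yield_mg_ha),
  attr(pts, "harvested_area_per_point")))
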