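#!/usr/bin/env Rscript
# Model fitting and evaluation: 80:20 split per stage, the four
# regression methods, accuracy metrics, and the iterative
# collinearity/importance feature-selection loop on the final stage.

suppressMessages(library(canopyield))

out <- "results/03_models"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cfg <- read_scenario_config("results/01_simulate/scenario_config.yml")
sc <- run_scenario(cfg)

metrics <- suppressWarnings(
  evaluate_stage_models(sc$tables, split_ratio = 0.8, seed = cfg$seed,
                        with_reduced = TRUE))
utils::write.csv(metrics, file.path(out, "metrics.csv"), row.names = FALSE)

full <- metrics[metrics$predictors == "full", ]
for (stage in unique(full$stage_label)) {
  d <- full[full$stage_label == stage, ]
  message(sprintf("stage %s: %s", stage,
                  paste(sprintf("%s RMSE %.3f (R2 %.2f)", d$method, d$rmse,
                                d$r2), collapse = ", ")))
}

final <- sc$tables[[length(sc$tables)]]
sel <- suppressWarnings(
  iterative_feature_selection(final, model_config("RF", seed = cfg$seed)))
message(sprintf("feature selection (final stage): %d -> %d predictors",
                47, length(sel$selected)))
message("top 10 by importance: ",
        paste(utils::head(sel$selected, 10), collapse = ", "))
utils::write.csv(sel$history, file.path(out, "selection_history.csv"),
                 row.names = FALSE)
jsonlite::write_json(list(selected = sel$selected),
                     file.path(out, "selected_features.json"),
                     auto_unbox = TRUE, pretty = TRUE)
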