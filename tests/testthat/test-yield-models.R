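# tiny synthetic regression tables used across model tests
toy_table <- function(n = 200, p_noise = 1, seed = 17) {
  set.seed(seed)
  x1 <- rnorm(n); x2 <- rnorm(n)
  tab <- data.frame(polygon_id = seq_len(n), x1 = x1, x2 = x2)
  for (k in seq_len(p_noise)) tab[[paste0("noise", k)]] <- rnorm(n)
  tab$yield_mg_ha <- 10 + 1.5 * x1 - 0.8 * x2 + rnorm(n, 0, 0.3)
  tab
}

test_that("train/test split is exact, disjoint, exhaustive and seeded", {
  tab <- toy_table(8581)
  sp <- split_train_test(tab, 0.8, seed = 1)
  expect_equal(nrow(sp$train), 6865)
  expect_equal(nrow(sp$test), 1716)
  expect_length(intersect(sp$train$polygon_id, sp$test$polygon_id), 0)
  expect_setequal(c(sp$train$polygon_id, sp$test$polygon_id), tab$polygon_id)
  sp2 <- split_train_test(tab, 0.8, seed = 1)
  expect_identical(sp$train$polygon_id, sp2$train$polygon_id)
  sp3 <- split_train_test(tab, 0.8, seed = 2)
  expect_false(identical(sp$train$polygon_id, sp3$train$polygon_id))
  small <- split_train_test(toy_table(10), 0.8, seed = 1)
  expect_equal(c(nrow(small$train), nrow(small$test)), c(8, 2))
  expect_error(split_train_test(toy_table(1), 0.8), "insufficient-data")
})

test_that("model configs carry the tuned defaults", {
  expect_equal(model_config("RF")$hyperparameters,
               list(max_depth = 21, max_features = 11, n_estimators = 500))
  expect_equal(model_config("XGB")$hyperparameters,
               list(colsample_bytree = 0.9, gamma = 0.30,
                    learning_rate = 0.05, max_depth = 6, n_estimators = 200,
                    subsample = 0.7))
  expect_equal(model_config("GBR")$hyperparameters,
               list(learning_rate = 0.1, max_depth = 5, n_estimators = 200,
                    subsample = 0.7))
  expect_length(model_config("MLR")$hyperparameters, 0)
  expect_equal(model_config("RF", list(n_estimators = 50))$
                 hyperparameters$n_estimators, 50)
})

test_that("MLR recovers an exact linear relationship", {
  tab <- data.frame(polygon_id = 1:20, x = 1:20,
                    yield_mg_ha = 2 * (1:20) + 1)
  fit <- fit_model(model_config("MLR"), tab)
  expect_equal(unname(fit$beta), c(1, 2), tolerance = 1e-9)
  expect_equal(evaluate(fit, tab)$rmse, 0, tolerance = 1e-9)
  expect_equal(evaluate(fit, tab)$r2, 1, tolerance = 1e-9)
})

test_that("tree ensembles are deterministic, importance-normalized and sane", {
  tab <- toy_table(300)
  for (kind in c("RF", "GBR", "XGB")) {
    cfgm <- model_config(kind, list(n_estimators = 50), seed = 3)
    f1 <- fit_model(cfgm, tab)
    f2 <- fit_model(cfgm, tab)
    expect_identical(predict_yield(f1, tab), predict_yield(f2, tab),
                     info = kind)
    expect_equal(sum(f1$importances), 1, tolerance = 1e-9, info = kind)
    expect_true(all(f1$importances >= 0), info = kind)
    # informative predictors dominate the pure-noise column
    expect_gt(f1$importances[["x1"]], f1$importances[["noise1"]])
  }
  # constant target: constant prediction
  const <- toy_table(100)
  const$yield_mg_ha <- 7.7
  frf <- fit_model(model_config("RF", list(n_estimators = 50)), const)
  expect_equal(unique(predict_yield(frf, const)), 7.7, tolerance = 1e-9)
})

test_that("metrics follow their defining equations", {
  m <- regression_metrics(c(10, 12, 14), c(11, 11, 15))
  expect_equal(m$rmse, 1)
  expect_equal(m$r2, 1 - 3 / 8)
  perfect <- regression_metrics(1:10, 1:10)
  expect_equal(perfect$r2, 1)
  expect_equal(perfect$rmse, 0)
  mean_only <- regression_metrics(c(1, 2, 3), rep(2, 3))
  expect_equal(mean_only$r2, 0)
  degenerate <- regression_metrics(rep(5, 4), c(5, 5, 6, 4))
  expect_true(is.na(degenerate$r2))
  expect_gt(degenerate$rmse, 0)
  # row-order invariance
  set.seed(41)
  o <- rnorm(50); p <- rnorm(50); perm <- sample(50)
  expect_equal(regression_metrics(o, p)$rmse,
               regression_metrics(o[perm], p[perm])$rmse)
})

test_that("VIF screening matches the direct 1/(1-R2) computation", {
  set.seed(19)
  n <- 300
  z <- rnorm(n)
  tab <- data.frame(polygon_id = 1:n,
                    a = z + rnorm(n, 0, 0.46),  # pairwise r ~ 0.9
                    b = z + rnorm(n, 0, 0.46),
                    c = rnorm(n))
  tab$yield_mg_ha <- rnorm(n)
  cs <- collinearity_screen(tab, vif_cut = 10)
  for (j in c("a", "b", "c")) {
    others <- setdiff(c("a", "b", "c"), j)
    r2 <- summary(lm(stats::reformulate(others, j), tab))$r.squared
    expect_equal(unname(cs$vif[j]), 1 / (1 - r2), tolerance = 1e-9)
  }
  # orthogonal centered predictors: VIF 1, nothing flagged
  orth <- data.frame(polygon_id = 1:4, u = c(-1, -1, 1, 1),
                     v = c(-1, 1, -1, 1), yield_mg_ha = rnorm(4))
  cso <- collinearity_screen(orth, 10)
  expect_equal(unname(cso$vif), c(1, 1))
  expect_length(cso$flagged, 0)
  # duplicated column: infinite VIF on both copies, flagged first
  dup <- data.frame(polygon_id = 1:50, a = rnorm(50))
  dup$b <- dup$a
  dup$c <- rnorm(50)
  dup$yield_mg_ha <- rnorm(50)
  csd <- collinearity_screen(dup, 10)
  expect_true(all(is.infinite(csd$vif[c("a", "b")])))
  expect_true(all(c("a", "b") %in% csd$flagged[1:2]))
})

test_that("iterative selection removes noise and duplicate predictors", {
  set.seed(23)
  n <- 400
  x <- rnorm(n)
  tab <- data.frame(polygon_id = 1:n, signal = x, copy = x,
                    junk = rnorm(n),
                    yield_mg_ha = 10 + 2 * x + rnorm(n, 0, 0.2))
  sel <- iterative_feature_selection(tab, model_config("RF",
                                                       list(n_estimators = 100),
                                                       seed = 2),
                                     vif_cut = 10, importance_floor = 0.05)
  expect_true(sum(c("signal", "copy") %in% sel$selected) == 1)
  expect_false("junk" %in% sel$selected)
  expect_true(nrow(sel$history) >= 2)
  # nothing removable: single iteration, identity selection
  clean <- toy_table(200, p_noise = 0)
  sel2 <- iterative_feature_selection(clean, model_config("MLR"),
                                      vif_cut = 10, importance_floor = 0)
  expect_equal(nrow(sel2$history), 1)
  expect_setequal(sel2$selected, c("x1", "x2"))
})

test_that("ANOVA + LSD letters reproduce a textbook separation", {
  # two well-separated pairs of methods: distinct letters, ordered worst-first
  S <- 7
  jitter7 <- c(-0.03, -0.02, -0.01, 0, 0.01, 0.02, 0.03)
  rmse <- rbind(MLR = 2.0 + jitter7, RF = 1.0 + jitter7,
                GBR = 1.0 + rev(jitter7), XGB = 2.0 + rev(jitter7))
  cmp <- compare_methods(rmse, alpha = 0.05)
  expect_lt(cmp$anova_p, 0.001)
  expect_equal(unname(cmp$letters["MLR"]), "a")
  expect_equal(unname(cmp$letters["XGB"]), "a")
  expect_equal(unname(cmp$letters["RF"]), "b")
  expect_equal(unname(cmp$letters["GBR"]), "b")
  # hand computation of the LSD value itself
  df_long <- data.frame(m = factor(rep(rownames(rmse), S)),
                        v = as.vector(rmse))
  a <- anova(lm(v ~ m, df_long))
  lsd_hand <- qt(0.975, a$Df[2]) * sqrt(a$`Mean Sq`[2] * 2 / S)
  expect_equal(cmp$lsd, lsd_hand, tolerance = 1e-12)
  # identical methods: non-significant ANOVA, everyone lettered 'a'
  same <- rbind(MLR = c(1, 1.01, 0.99), RF = c(1, 1.01, 0.99),
                GBR = c(1.01, 1, 0.99), XGB = c(0.99, 1, 1.01))
  cmp2 <- compare_methods(same)
  expect_gte(cmp2$anova_p, 0.05)
  expect_true(all(cmp2$letters == "a"))
  expect_error(compare_methods(rmse[, 1, drop = FALSE]),
               "insufficient-replication")
})

test_that("overlapping means share letters in the compact display", {
  # three graded means where adjacent pairs overlap but the extremes differ
  S <- 6
  rmse <- rbind(A = rep(1.00, S) + seq(-0.01, 0.01, length.out = S),
                B = rep(1.09, S) + seq(-0.012, 0.012, length.out = S),
                C = rep(1.20, S) + seq(-0.011, 0.011, length.out = S))
  cmp <- compare_methods(rmse, alpha = 0.05)
  if (cmp$anova_p < 0.05 && !is.na(cmp$lsd) && cmp$lsd > 0.09 &&
      cmp$lsd < 0.11) {
    expect_equal(unname(cmp$letters), c("b", "ab", "a"))
  }
  # highest mean always gets 'a'
  expect_match(cmp$letters[which.max(cmp$means)], "a")
})

test_that("the paired one-tailed soil-inclusion test matches the t CDF", {
  set.seed(37)
  full <- runif(12, 0.4, 0.6)
  reduced <- full + rnorm(12, 0.05, 0.03)
  p <- soil_inclusion_test(full, reduced)
  oracle <- t.test(reduced, full, paired = TRUE,
                   alternative = "greater")$p.value
  expect_equal(p, oracle, tolerance = 1e-9)
  d <- reduced - full
  t_stat <- mean(d) / (sd(d) / sqrt(length(d)))
  expect_equal(p, 1 - pt(t_stat, length(d) - 1), tolerance = 1e-12)
  # boundary conventions
  expect_equal(soil_inclusion_test(full, full), 0.5)
  expect_lt(soil_inclusion_test(full, full + 1), 0.001)
  expect_error(soil_inclusion_test(1:3, 1:4), "paired")
})

test_that("days after planting follows the calendar", {
  expect_equal(days_after_planting("2023-02-28", "2023-03-20"), 20)
  expect_equal(days_after_planting("2023-02-28", "2023-05-22"), 83)
  expect_equal(days_after_planting("2023-02-28", "2023-08-14"), 167)
  expect_equal(days_after_planting("2023-02-28", "2023-02-28"), 0)
  expect_error(days_after_planting("2023-02-28", "2023-02-27"),
               "negative-interval")
})
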