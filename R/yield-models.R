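#' @title Yield regression models and comparison statistics
#' @description
#' Train/test splitting, the four regression methods (multiple linear
#' regression and the random-forest, gradient-boosting and XGBoost
#' ensembles), accuracy metrics, collinearity screening, the iterative
#' feature-selection loop, and the statistics used to compare methods
#' (one-way ANOVA with Fisher's LSD letters, and the paired one-tailed
#' t-test for the contribution of soil and slope predictors).
#' @name yield_models
NULL

# Columns of a feature table that are never predictors.
META_COLUMNS <- c("polygon_id", "stage_label", "dap", "yield_mg_ha")

predictor_columns <- function(table) setdiff(names(table), META_COLUMNS)

#' Random train/test split
#'
#' Uniform sampling without replacement; the training set has
#' `round(ratio * n)` rows; the two sets are disjoint and exhaustive and
#' the partition is reproducible from `seed`.
#'
#' @param table A feature table (data frame).
#' @param ratio Training fraction in (0, 1); default 0.8.
#' @param seed Integer seed.
#' @return List with `train` and `test` data frames.
#' @export
split_train_test <- function(table, ratio = 0.8, seed = 1L) {
  n <- nrow(table)
  if (n < 2L) stop("insufficient-data: need at least 2 rows", call. = FALSE)
  if (ratio <= 0 || ratio >= 1) stop("invalid-config: ratio must be in (0,1)",
                                     call. = FALSE)
  n_train <- round(ratio * n)
  idx <- with_seed(seed, sample.int(n, n_train))
  list(train = table[sort(idx), , drop = FALSE],
       test = table[setdiff(seq_len(n), idx), , drop = FALSE])
}

#' Model configuration with the tuned default hyperparameters
#'
#' Defaults are the grid-search winners used throughout:
#' RF `max_depth 21, max_features 11, n_estimators 500`;
#' XGB `colsample_bytree 0.9, gamma 0.30, learning_rate 0.05, max_depth 6,
#' n_estimators 200, subsample 0.7`;
#' GBR `learning_rate 0.1, max_depth 5, n_estimators 200, subsample 0.7`;
#' MLR has none.
#'
#' @param kind One of `"MLR"`, `"RF"`, `"GBR"`, `"XGB"`.
#' @param hyperparameters Named list of overrides.
#' @param seed Integer seed for the stochastic learners.
#' @return List of class `model_config`.
#' @export
model_config <- function(kind = c("MLR", "RF", "GBR", "XGB"),
                         hyperparameters = list(), seed = 1L) {
  kind <- match.arg(kind)
  defaults <- switch(kind,
    MLR = list(),
    RF  = list(max_depth = 21, max_features = 11, n_estimators = 500),
    XGB = list(colsample_bytree = 0.9, gamma = 0.30, learning_rate = 0.05,
               max_depth = 6, n_estimators = 200, subsample = 0.7),
    GBR = list(learning_rate = 0.1, max_depth = 5, n_estimators = 200,
               subsample = 0.7))
  hp <- utils::modifyList(defaults, hyperparameters)
  structure(list(kind = kind, hyperparameters = hp, seed = as.integer(seed)),
            class = "model_config")
}

#' Fit a yield model
#'
#' MLR is fit by ordinary least squares (aliased coefficients from a
#' rank-deficient design are set to zero with a warning, the minimum-norm
#' solution on the reduced basis). RF is fit with `ranger`; GBR and XGB
#' with `xgboost` — GBR as plain gradient boosting (regularization terms
#' zeroed, exact greedy splits), XGB with its regularized objective.
#' Feature importances are impurity/gain based for the tree ensembles
#' (non-negative, summing to 1) and absolute standardized coefficients
#' (also normalized to 1) for MLR, so the selection loop treats all kinds
#' uniformly. Results are deterministic given `config$seed`.
#'
#' @param config A [model_config()].
#' @param train Feature table with a `yield_mg_ha` column; all
#'   non-metadata columns are predictors.
#' @return A `fit_result`: list with `config`, `features`, `importances`,
#'   `train_ids` and the fitted backend model.
#' @export
fit_model <- function(config, train) {
  if (nrow(train) == 0L) stop("insufficient-data: empty training set",
                              call. = FALSE)
  features <- predictor_columns(train)
  x <- as.matrix(train[, features, drop = FALSE])
  y <- train$yield_mg_ha
  hp <- config$hyperparameters
  fit <- switch(config$kind,
    MLR = {
      df <- as.data.frame(x); df$.y <- y
      m <- stats::lm(.y ~ ., data = df)
      beta <- stats::coef(m)
      if (anyNA(beta)) {
        warning("rank-deficient design: aliased coefficients set to zero")
        beta[is.na(beta)] <- 0
      }
      sx <- apply(x, 2, stats::sd)
      sy <- stats::sd(y)
      imp <- abs(beta[make.names(features)] * sx) / if (sy > 0) sy else 1
      imp[!is.finite(imp)] <- 0
      names(imp) <- features
      list(model = m, beta = beta, importances = norm1(imp))
    },
    RF = {
      m <- with_seed(config$seed, ranger::ranger(
        x = as.data.frame(x), y = y,
        num.trees = hp$n_estimators,
        mtry = min(hp$max_features, ncol(x)),
        max.depth = hp$max_depth,
        importance = "impurity", seed = config$seed, num.threads = 1))
      list(model = m, importances = norm1(m$variable.importance))
    },
    XGB = xgb_fit(x, y, config, params = list(
      eta = hp$learning_rate, max_depth = hp$max_depth, gamma = hp$gamma,
      subsample = hp$subsample, colsample_bytree = hp$colsample_bytree,
      nthread = 1), nrounds = hp$n_estimators),
    GBR = xgb_fit(x, y, config, params = list(
      eta = hp$learning_rate, max_depth = hp$max_depth, gamma = 0,
      subsample = hp$subsample, colsample_bytree = 1, lambda = 0, alpha = 0,
      tree_method = "exact", nthread = 1), nrounds = hp$n_estimators)
  )
  structure(c(fit, list(config = config, features = features,
                        train_ids = train$polygon_id)),
            class = "fit_result")
}

norm1 <- function(v) {
  v <- pmax(v, 0)
  s <- sum(v)
  if (s > 0) v / s else v
}

xgb_fit <- function(x, y, config, params, nrounds) {
  m <- with_seed(config$seed, {
    d <- xgboost::xgb.DMatrix(x, label = y)
    xgboost::xgb.train(params = params, data = d, nrounds = nrounds,
                       verbose = 0)
  })
  it <- xgboost::xgb.importance(model = m)
  imp <- stats::setNames(rep(0, ncol(x)), colnames(x))
  imp[it$Feature] <- it$Gain
  list(model = m, importances = norm1(imp))
}

#' Predict yield from a fitted model
#'
#' @param fit A `fit_result`.
#' @param newdata Feature table containing the fit's feature columns.
#' @return Numeric vector of predicted yields (Mg/ha).
#' @export
predict_yield <- function(fit, newdata) {
  x <- as.matrix(newdata[, fit$features, drop = FALSE])
  switch(fit$config$kind,
    MLR = {
      b <- fit$beta
      xn <- x
      colnames(xn) <- make.names(fit$features)
      as.numeric(b[1] + xn[, names(b)[-1], drop = FALSE] %*% b[-1])
    },
    RF = stats::predict(fit$model, data = as.data.frame(x),
                        num.threads = 1)$predictions,
    stats::predict(fit$model, xgboost::xgb.DMatrix(x))
  )
}

#' Regression accuracy metrics
#'
#' `R^2 = 1 - SS_res / SS_tot` about the evaluation-set mean and
#' `RMSE = sqrt(mean((obs - pred)^2))`. A zero-variance observed vector
#' leaves R^2 undefined (`NA`); RMSE is always returned.
#'
#' @param obs,pred Numeric vectors of observed and predicted yield.
#' @return List with `r2`, `rmse`, `n`.
#' @export
regression_metrics <- function(obs, pred) {
  n <- length(obs)
  ss_res <- sum((obs - pred)^2)
  ss_tot <- sum((obs - mean(obs))^2)
  list(r2 = if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_,
       rmse = sqrt(ss_res / n), n = n)
}

#' Evaluate a fitted model on a test set
#'
#' @param fit A `fit_result`.
#' @param test Feature table with observed `yield_mg_ha`.
#' @return List with `r2`, `rmse`, `n` (see [regression_metrics()]).
#' @export
evaluate <- function(fit, test) {
  if (nrow(test) == 0L) stop("insufficient-data: empty test set",
                             call. = FALSE)
  regression_metrics(test$yield_mg_ha, predict_yield(fit, test))
}

#' Variance-inflation-factor collinearity screen
#'
#' `VIF_j = 1 / (1 - R^2_j)` from regressing predictor j on all the
#' others. Perfectly collinear predictors report `Inf` and are flagged
#' first.
#'
#' @param table Feature table (>= 2 predictors).
#' @param vif_cut Flagging threshold (default 10).
#' @return List with `vif` (named vector, all predictors) and `flagged`
#'   (character vector of predictors with VIF > `vif_cut`, worst first).
#' @export
collinearity_screen <- function(table, vif_cut = 10) {
  features <- predictor_columns(table)
  if (length(features) < 2L) stop("need at least 2 predictors", call. = FALSE)
  x <- as.matrix(table[, features, drop = FALSE])
  vif <- vapply(seq_along(features), function(j) {
    yj <- x[, j]
    ss_tot <- sum((yj - mean(yj))^2)
    if (ss_tot == 0) return(Inf)
    fit <- stats::lm.fit(cbind(1, x[, -j, drop = FALSE]), yj)
    r2 <- 1 - sum(fit$residuals^2) / ss_tot
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, 0)
  names(vif) <- features
  flagged <- names(sort(vif[vif > vif_cut], decreasing = TRUE))
  list(vif = vif, flagged = flagged)
}

#' Iterative feature selection by collinearity and importance
#'
#' Repeatedly fits the model on the training rows and evaluates on the
#' test rows; each round removes the single worst VIF offender above
#' `vif_cut` plus every predictor whose importance falls below
#' `importance_floor` (ties broken alphabetically), then refits. The loop
#' stops when nothing is removable or when the test RMSE has risen more
#' than `rmse_rise_tol` above the best iteration. The selected set is the
#' predictor set of the best iteration (lowest RMSE, then fewest
#' predictors), ordered by that iteration's importances.
#'
#' Selection on the test RMSE follows the workflow being reproduced, but
#' note it optimistically biases the reported RMSE; hold out a third
#' validation split if an unbiased error estimate is needed.
#'
#' @param table Feature table.
#' @param config A [model_config()].
#' @param vif_cut VIF threshold (default 10).
#' @param importance_floor Minimum retained importance (default 0.005).
#' @param split_ratio Train fraction (default 0.8); the split is fixed by
#'   `config$seed` before the loop.
#' @param rmse_rise_tol Relative RMSE rise that stops the loop
#'   (default 0.01).
#' @return List with `selected` (ordered character vector) and `history`
#'   (one data-frame row per iteration).
#' @export
iterative_feature_selection <- function(table, config, vif_cut = 10,
                                        importance_floor = 0.005,
                                        split_ratio = 0.8,
                                        rmse_rise_tol = 0.01) {
  sp <- split_train_test(table, split_ratio, config$seed)
  preds <- sort(predictor_columns(table))
  best <- NULL
  history <- list()
  iter <- 0L
  repeat {
    iter <- iter + 1L
    cols <- c(intersect(names(table), META_COLUMNS), preds)
    fit <- fit_model(config, sp$train[, cols, drop = FALSE])
    met <- evaluate(fit, sp$test[, cols, drop = FALSE])
    imp <- fit$importances[order(-fit$importances, names(fit$importances))]
    if (is.null(best) || met$rmse < best$rmse ||
        (met$rmse == best$rmse && length(preds) < length(best$preds))) {
      best <- list(rmse = met$rmse, preds = preds, imp = imp)
    }
    drop <- character(0)
    if (length(preds) > 1L) {
      cs <- collinearity_screen(sp$train[, cols, drop = FALSE], vif_cut)
      if (length(cs$flagged) > 0L) {
        worst <- cs$vif[cs$flagged]
        drop <- sort(names(worst)[worst == max(worst)])[1]
      }
      drop <- union(drop, sort(names(imp)[imp < importance_floor]))
      drop <- setdiff(drop, character(0))
      if (length(drop) >= length(preds)) drop <- drop[seq_len(length(preds) - 1L)]
    }
    history[[iter]] <- data.frame(
      iteration = iter, n_predictors = length(preds), rmse = met$rmse,
      r2 = met$r2, dropped = paste(drop, collapse = ";"),
      stringsAsFactors = FALSE)
    if (length(drop) == 0L) break
    if (met$rmse > best$rmse * (1 + rmse_rise_tol)) break
    preds <- setdiff(preds, drop)
    if (length(preds) == 0L) {
      warning("empty predictor set reached; returning best previous iteration")
      break
    }
  }
  sel_imp <- best$imp[names(best$imp) %in% best$preds]
  list(selected = names(sel_imp)[order(-sel_imp, names(sel_imp))],
       history = do.call(rbind, history))
}

#' Compare regression methods by ANOVA and Fisher's LSD letters
#'
#' Treats the per-stage RMSE values of each method as replicates in a
#' one-way ANOVA; if the method effect is significant at `alpha`,
#' pairwise mean separation uses the least significant difference
#' `LSD = t(1 - alpha/2, df_E) * sqrt(2 MSE / S)` and a compact letter
#' display is built ('a' = highest mean, following the usual plot-caption
#' convention). A non-significant ANOVA letters every method 'a'.
#'
#' @param rmse Numeric matrix, methods in rows (rownames required),
#'   stages/replicates in columns (>= 2).
#' @param alpha Significance level (default 0.05).
#' @return List with `anova_p`, `lsd` (the LSD value or `NA`), `means`
#'   and `letters` (named character vector, method order preserved).
#' @export
compare_methods <- function(rmse, alpha = 0.05) {
  rmse <- as.matrix(rmse)
  if (is.null(rownames(rmse))) stop("rmse matrix needs method rownames")
  S <- ncol(rmse)
  if (S < 2L || anyNA(rmse)) {
    stop("insufficient-replication: each method needs >= 2 RMSE values",
         call. = FALSE)
  }
  methods <- rownames(rmse)
  df <- data.frame(method = factor(rep(methods, S)), value = as.vector(rmse))
  fit <- stats::aov(value ~ method, data = df)
  tab <- summary(fit)[[1]]
  p <- tab[["Pr(>F)"]][1]
  means <- rowMeans(rmse)
  if (is.na(p) || p >= alpha) {
    return(list(anova_p = ifelse(is.na(p), 1, p), lsd = NA_real_,
                means = means,
                letters = stats::setNames(rep("a", length(methods)), methods)))
  }
  mse <- tab[["Mean Sq"]][2]
  df_e <- tab[["Df"]][2]
  lsd <- stats::qt(1 - alpha / 2, df_e) * sqrt(2 * mse / S)
  ord <- order(-means)
  sorted <- means[ord]
  k <- length(sorted)
  # maximal runs of mutually non-separated (by LSD) methods on the sorted
  # means are intervals; one letter per maximal interval
  ends <- vapply(seq_len(k), function(i) {
    max(which(sorted[i] - sorted <= lsd + 1e-12))
  }, 0L)
  intervals <- list()
  for (i in seq_len(k)) {
    iv <- c(i, ends[i])
    if (length(intervals) == 0L ||
        !(iv[1] >= intervals[[length(intervals)]][1] &&
          iv[2] <= intervals[[length(intervals)]][2])) {
      intervals[[length(intervals) + 1L]] <- iv
    }
  }
  lets <- stats::setNames(rep("", k), names(sorted))
  for (g in seq_along(intervals)) {
    iv <- intervals[[g]]
    idx <- iv[1]:iv[2]
    lets[idx] <- paste0(lets[idx], letters[g])
  }
  list(anova_p = p, lsd = lsd, means = means,
       letters = lets[methods])
}

#' Paired one-tailed t-test for the value of soil and slope predictors
#'
#' Tests whether models without the soil/slope predictors have higher
#' error: H1 `mean(reduced - full) > 0` over paired (method, stage)
#' RMSEs. With zero-variance differences the p-value is 0 for a positive
#' mean difference, 1 for a negative one, and 0.5 at exactly zero
#' (boundary convention).
#'
#' @param full_rmses,reduced_rmses Paired numeric vectors (same length,
#'   >= 2): test RMSEs of the full and soil/slope-free models.
#' @return One-tailed p-value.
#' @export
soil_inclusion_test <- function(full_rmses, reduced_rmses) {
  if (length(full_rmses) != length(reduced_rmses) || length(full_rmses) < 2L) {
    stop("paired lists of equal length >= 2 required", call. = FALSE)
  }
  d <- reduced_rmses - full_rmses
  sdd <- stats::sd(d)
  if (sdd == 0) {
    m <- mean(d)
    return(if (m > 0) 0 else if (m < 0) 1 else 0.5)
  }
  t_stat <- mean(d) / (sdd / sqrt(length(d)))
  1 - stats::pt(t_stat, df = length(d) - 1L)
}

#' Days after planting
#'
#' @param planting,flight Dates (or strings coercible to Date); `flight`
#'   must not precede `planting`.
#' @return Integer calendar-day difference.
#' @export
#' @examples
#' days_after_planting("2023-02-28", "2023-03-20")  # 20
days_after_planting <- function(planting, flight) {
  d <- as.integer(as.Date(flight) - as.Date(planting))
  if (any(d < 0)) stop("negative-interval: flight precedes planting",
                       call. = FALSE)
  d
}
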