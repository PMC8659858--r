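#' Accuracy metrics
#'
#' MAE, RMSE and the coefficient of determination
#' `R2 = 1 - sum((O-P)^2) / sum((O - mean(O))^2)` of predictions against
#' observations.
#'
#' @param observed,predicted equal-length finite numeric vectors.
#' @return named list `mae`, `rmse`, `r2`.
#' @export
metrics <- function(observed, predicted) {
  stopifnot(length(observed) == length(predicted),
            all(is.finite(observed)), all(is.finite(predicted)))
  ss_tot <- sum((observed - mean(observed))^2)
  if (ss_tot == 0) stop("metrics: zero variance in observations, R2 undefined")
  err <- observed - predicted
  list(mae = mean(abs(err)), rmse = sqrt(mean(err^2)),
       r2 = 1 - sum(err^2) / ss_tot)
}

#' RMSE improvement of a hybrid over its base model
#'
#' `(rmse_base - rmse_hybrid) / rmse_base * 100`, rounded to 2 decimal
#' places (the percentage-point convention of the accuracy-improvement
#' statistic).
#'
#' @param rmse_base base-model RMSE, > 0.
#' @param rmse_hybrid hybrid-model RMSE.
#' @return improvement in percent, 2 dp.
#' @export
improvement <- function(rmse_base, rmse_hybrid) {
  stopifnot(rmse_base > 0)
  round((rmse_base - rmse_hybrid) / rmse_base * 100, 2)
}

#' Leave-one-out cross-validation of base and hybrid volume models
#'
#' For each plot in turn, the remaining n-1 plots are used to (optionally)
#' re-screen predictors, refit each base learner, refit the residual
#' variogram of each hybrid, and predict the held-out plot. Pooled MAE,
#' RMSE and R2 are computed over the n held-out predictions (the pooled
#' form is the standard leave-one-out convention: per-fold R2 is undefined
#' with a single observation per fold). The held-out plot never
#' contributes to screening, fitting, residuals or variograms in its own
#' fold. Variogram failures in a fold fall back to the base prediction
#' and are counted.
#'
#' @param table data.frame with the response column plus predictors.
#' @param locations n x 2 plot coordinates (same units as variogram range;
#'   the pipeline passes kilometres).
#' @param learners character subset of `c("rf", "svr", "ann")`.
#' @param hybrids logical: also evaluate the kriging hybrids.
#' @param response response column name.
#' @param screen logical: re-screen predictors inside each fold.
#' @param threshold,alpha screening parameters (see [screen_features()]).
#' @param n_bins,max_lag variogram estimation parameters.
#' @param seed base seed; each fold uses a seed derived from it.
#' @return list of class `vk_cv`: `summary` (data.frame model, mae, rmse,
#'   r2, plus `delta_r2` and `improvement_pct` for hybrids), `predictions`
#'   (plots x models), `observed`, `vario_failures`.
#' @export
loo_cv <- function(table, locations, learners = c("rf", "svr", "ann"),
                   hybrids = TRUE, response = "M", screen = TRUE,
                   threshold = 0.4, alpha = 0.05, n_bins = 12,
                   max_lag = NULL, seed = 1L) {
  n <- nrow(table)
  stopifnot(n >= 10, nrow(locations) == n)
  locations <- as.matrix(locations)
  learners <- match.arg(learners, several.ok = TRUE)
  obs <- table[[response]]
  models <- c(learners, if (hybrids) paste0(learners, "k"))
  preds <- matrix(NA_real_, n, length(models),
                  dimnames = list(NULL, models))
  failures <- stats::setNames(integer(length(learners)), learners)

  for (i in seq_len(n)) {
    train <- table[-i, , drop = FALSE]
    if (screen) {
      sc <- suppressMessages(screen_features(train, response = response,
                                             threshold = threshold,
                                             alpha = alpha))
      train <- sc$table
    }
    feat_cols <- setdiff(names(train), response)
    test_feat <- table[i, feat_cols, drop = FALSE]
    for (lrn in learners) {
      cfg <- learner_config(lrn, seed = child_seed(seed, i))
      fit <- suppressWarnings(
        fit_learner(cfg, train[, feat_cols, drop = FALSE], train[[response]]))
      preds[i, lrn] <- predict_learner(fit, test_feat)
      if (hybrids) {
        hyb <- tryCatch(
          hybrid_fit(fit, train[, feat_cols, drop = FALSE],
                     train[[response]], locations[-i, , drop = FALSE],
                     n_bins = n_bins, max_lag = max_lag),
          error = function(e) NULL)
        if (is.null(hyb)) {
          failures[lrn] <- failures[lrn] + 1L
          preds[i, paste0(lrn, "k")] <- preds[i, lrn]
        } else {
          preds[i, paste0(lrn, "k")] <-
            hybrid_predict(hyb, test_feat, locations[i, , drop = FALSE])
        }
      }
    }
  }

  summ <- do.call(rbind, lapply(models, function(mn) {
    m <- metrics(obs, preds[, mn])
    data.frame(model = mn, mae = m$mae, rmse = m$rmse, r2 = m$r2)
  }))
  summ$delta_r2 <- NA_real_
  summ$improvement_pct <- NA_real_
  if (hybrids) {
    for (lrn in learners) {
      b <- summ$model == lrn; h <- summ$model == paste0(lrn, "k")
      summ$delta_r2[h] <- summ$r2[h] - summ$r2[b]
      summ$improvement_pct[h] <- improvement(summ$rmse[b], summ$rmse[h])
    }
  }
  structure(list(summary = summ, predictions = preds, observed = obs,
                 vario_failures = failures), class = "vk_cv")
}

#' Write a cross-validation report
#'
#' Writes the model summary (one row per model: MAE, RMSE, R2, delta R2
#' and RMSE improvement for hybrids) as CSV and JSON, the per-plot
#' observed-vs-predicted values as CSV (scatter-plot data), and, when a
#' fitted rf learner is supplied, the feature importance ranking.
#'
#' @param cv a [loo_cv()] result.
#' @param path output directory.
#' @param rf_model optional fitted rf learner for the importance ranking.
#' @return character vector of written file paths, invisibly.
#' @export
write_cv_report <- function(cv, path, rf_model = NULL) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  files <- c(cv_csv = file.path(path, "cv_summary.csv"),
             cv_json = file.path(path, "cv_summary.json"),
             scatter = file.path(path, "observed_predicted.csv"))
  utils::write.csv(cv$summary, files["cv_csv"], row.names = FALSE,
                   quote = FALSE)
  jsonlite::write_json(cv$summary, files["cv_json"], auto_unbox = TRUE,
                       digits = NA, dataframe = "rows")
  utils::write.csv(cbind(data.frame(observed = cv$observed),
                         as.data.frame(cv$predictions)),
                   files["scatter"], row.names = FALSE, quote = FALSE)
  if (!is.null(rf_model)) {
    imp <- feature_importance(rf_model)
    fi <- file.path(path, "rf_importance.csv")
    utils::write.csv(data.frame(feature = names(imp), score = unname(imp)),
                     fi, row.names = FALSE, quote = FALSE)
    files <- c(files, importance = fi)
  }
  invisible(files)
}
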