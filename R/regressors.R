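#' Learner configuration
#'
#' Bundles the hyperparameters of the three base learners used for stand
#' volume regression. Defaults are the package's reference configuration:
#'
#' * random forest (`rf`): 500 trees, up to 58 candidate features per
#'   split (clamped to the number of available predictors), minimum node
#'   size 5 for splitting, maximum depth 8, bootstrap resampling;
#' * support vector regression (`svr`): RBF kernel, `C = 150`,
#'   `gamma = 0.001`, fitted on standardized features;
#' * neural network (`ann`): two 50-unit relu hidden layers and one relu
#'   output unit, Adam with learning rate 0.01, at most 1000 epochs, early
#'   stopping with patience 20 on a 10% validation split, fitted on
#'   standardized features.
#'
#' @param kind `"rf"`, `"svr"` or `"ann"`.
#' @param seed integer seed controlling all stochastic parts of the fit.
#' @param ... overrides for individual hyperparameters (see Details).
#' @return a list of class `vk_learner_config`.
#' @export
learner_config <- function(kind = c("rf", "svr", "ann"), seed = 1L, ...) {
  kind <- match.arg(kind)
  defaults <- switch(kind,
    rf = list(n_trees = 500L, max_features = 58L, min_split = 5L,
              min_leaf = 2L, max_depth = 8L, bootstrap = TRUE),
    svr = list(kernel = "radial", C = 150, gamma = 0.001, epsilon = 0.1),
    ann = list(hidden = c(50L, 50L), activation = "relu",
               learning_rate = 0.01, max_epochs = 1000L, patience = 20L,
               val_frac = 0.1))
  over <- list(...)
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown) > 0)
    stop("learner_config: unknown parameter(s) for ", kind, ": ",
         paste(unknown, collapse = ", "))
  defaults[names(over)] <- over
  structure(c(list(kind = kind, seed = as.integer(seed)), defaults),
            class = "vk_learner_config")
}

#' Standardize feature columns
#'
#' Centres and scales each numeric column to mean 0 and sd 1 using either
#' statistics computed from the table itself (training) or supplied
#' statistics (test-time reuse). Columns with zero sd are passed through
#' unchanged with a warning.
#'
#' @param table data.frame of numeric columns.
#' @param stats optional statistics from a previous call (`$mean`, `$sd`).
#' @return list with `table` (standardized) and `stats`.
#' @export
standardize <- function(table, stats = NULL) {
  stopifnot(is.data.frame(table))
  if (is.null(stats)) {
    mu <- vapply(table, mean, numeric(1))
    sdv <- vapply(table, stats::sd, numeric(1))
    if (any(sdv == 0)) {
      warning("standardize: constant column(s) passed through: ",
              paste(names(table)[sdv == 0], collapse = ", "))
    }
    stats <- list(mean = mu, sd = sdv)
  } else {
    stopifnot(identical(names(stats$mean), names(table)))
  }
  out <- as.data.frame(mapply(function(col, m, s)
    if (s == 0) col else (col - m) / s,
    table, stats$mean, stats$sd, SIMPLIFY = FALSE))
  names(out) <- names(table)
  list(table = out, stats = stats)
}

#' Fit a base learner
#'
#' Fits the configured learner to a numeric feature table and response
#' under a uniform contract: the returned object predicts with
#' [predict_learner()] on a table with the same column names in the same
#' order. SVR and the neural network are fitted on standardized features
#' (statistics stored for test-time reuse); SVR additionally
#' standardizes the response, libsvm-style, so `C` and `epsilon` act on
#' a unit-variance scale (predictions are transformed back). The random
#' forest uses raw features. Fits are deterministic given `config$seed`.
#'
#' @param config a [learner_config()].
#' @param features data.frame of numeric predictors (n >= 5 rows).
#' @param response numeric response (m3/ha in the pipeline).
#' @return object of class `vk_learner`.
#' @export
fit_learner <- function(config, features, response) {
  stopifnot(inherits(config, "vk_learner_config"),
            is.data.frame(features), nrow(features) >= 5,
            length(response) == nrow(features))
  bad <- names(features)[!vapply(features, function(c) all(is.finite(c)),
                                 logical(1))]
  if (length(bad) > 0)
    stop("fit_learner: non-finite values in column(s): ",
         paste(bad, collapse = ", "))
  if (!all(is.finite(response))) stop("fit_learner: non-finite response")

  model <- list(config = config, feature_names = names(features),
                train_range = range(response))
  if (config$kind == "rf") {
    mtry <- config$max_features
    if (mtry > ncol(features)) {
      warning("fit_learner: max_features ", mtry, " exceeds ",
              ncol(features), " predictors; clamped")
      mtry <- ncol(features)
    }
    dat <- cbind(features, .response = response)
    model$fit <- ranger::ranger(
      dependent.variable.name = ".response", data = dat,
      num.trees = config$n_trees, mtry = mtry,
      min.node.size = config$min_split, max.depth = config$max_depth,
      replace = config$bootstrap, importance = "impurity",
      seed = config$seed, num.threads = 1)
  } else {
    std <- standardize(features)
    model$stats <- std$stats
    if (config$kind == "svr") {
      # libsvm-style full normalization: the response is standardized too,
      # so C and epsilon act on a unit-variance scale
      model$y_center <- mean(response)
      model$y_scale <- stats::sd(response)
      if (model$y_scale == 0) {
        # constant response: libsvm has no support vectors to fit
        model$y_scale <- 1
        model$const <- model$y_center
      } else {
        model$fit <- e1071::svm(
          x = as.matrix(std$table),
          y = (response - model$y_center) / model$y_scale,
          type = "eps-regression",
          kernel = config$kernel, cost = config$C, gamma = config$gamma,
          epsilon = config$epsilon, scale = FALSE)
      }
    } else {
      model$fit <- mlp_fit(
        as.matrix(std$table), response, hidden = config$hidden,
        learning_rate = config$learning_rate,
        max_epochs = config$max_epochs, patience = config$patience,
        val_frac = config$val_frac, seed = config$seed)
    }
  }
  structure(model, class = "vk_learner")
}

#' Predict from a fitted learner
#'
#' @param model a [fit_learner()] result.
#' @param features data.frame whose column names and order match training.
#' @return numeric predictions, one per row.
#' @export
predict_learner <- function(model, features) {
  stopifnot(inherits(model, "vk_learner"))
  if (!identical(names(features), model$feature_names))
    stop("predict_learner: feature names/order differ from training")
  kind <- model$config$kind
  if (kind == "rf") {
    stats::predict(model$fit, data = features, num.threads = 1)$predictions
  } else {
    std <- standardize(features, model$stats)
    if (kind == "svr") {
      if (!is.null(model$const)) return(rep(model$const, nrow(features)))
      as.numeric(stats::predict(model$fit, as.matrix(std$table))) *
        model$y_scale + model$y_center
    } else {
      mlp_predict(model$fit, as.matrix(std$table))
    }
  }
}

#' Random-forest feature importance
#'
#' Impurity-based importance scores, normalized to sum to one and sorted
#' in decreasing order.
#'
#' @param model a fitted `rf` learner.
#' @return named numeric vector of scores summing to 1.
#' @export
feature_importance <- function(model) {
  stopifnot(inherits(model, "vk_learner"))
  if (model$config$kind != "rf")
    stop("feature_importance: only supported for rf models")
  imp <- ranger::importance(model$fit)
  imp <- pmax(imp, 0)
  sort(imp / sum(imp), decreasing = TRUE)
}
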