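#' Variogram model
#'
#' Constructs a bounded semivariogram model of the spherical or Gaussian
#' family, parameterized by nugget, partial sill and range. The sill is
#' `nugget + psill` and the sill effect (nugget/sill) measures the share of
#' unstructured variance: the smaller it is, the stronger the spatial
#' autocorrelation. Distances are unit-agnostic; `range` is in whatever
#' units the coordinates later supplied to [model_gamma()]/[ok_predict()]
#' are in (the pipeline uses kilometres).
#'
#' For the Gaussian family `range` is the effective range at which the
#' model reaches 95% of its sill (exponent factor 3); for the spherical
#' family the sill is reached exactly at `range`.
#'
#' @param family `"spherical"` or `"gaussian"`.
#' @param nugget nugget variance, >= 0.
#' @param psill partial sill (sill minus nugget), >= 0.
#' @param range range parameter, > 0.
#' @return object of class `vk_variogram` with fields `family`, `nugget`,
#'   `psill`, `range`, `sill`, `sill_effect`.
#' @export
variogram_model <- function(family = c("spherical", "gaussian"),
                            nugget, psill, range) {
  family <- match.arg(family)
  stopifnot(nugget >= 0, psill >= 0, range > 0)
  sill <- nugget + psill
  structure(list(family = family, nugget = nugget, psill = psill,
                 range = range, sill = sill,
                 sill_effect = if (sill > 0) nugget / sill else NA_real_),
            class = "vk_variogram")
}

#' @export
print.vk_variogram <- function(x, ...) {
  cat(sprintf("<variogram %s: nugget %.4g, partial sill %.4g, range %.4g, sill effect %s>\n",
              x$family, x$nugget, x$psill, x$range,
              if (is.na(x$sill_effect)) "NA" else sprintf("%.3f", x$sill_effect)))
  invisible(x)
}

#' Model semivariance
#'
#' Evaluates the theoretical semivariogram gamma(h). Both families follow
#' the exact-interpolation convention gamma(0) = 0: the nugget appears only
#' as the discontinuity for h > 0, so ordinary kriging honours observed
#' values at data locations.
#'
#' @param model a [variogram_model()].
#' @param h distances, >= 0 (vectorized).
#' @return semivariances, same length as `h`.
#' @export
model_gamma <- function(model, h) {
  if (any(h < 0)) stop("model_gamma: negative distance")
  a <- model$range
  g <- if (model$family == "spherical") {
    u <- pmin(h / a, 1)
    model$nugget + model$psill * (1.5 * u - 0.5 * u^3)
  } else {
    model$nugget + model$psill * (1 - exp(-3 * h^2 / a^2))
  }
  g[h == 0] <- 0
  g
}

#' Sill effect (nugget-to-sill ratio)
#'
#' nugget / (nugget + partial sill); 0 for a nugget-free model, 1 for pure
#' nugget. Lower values indicate stronger spatial autocorrelation.
#'
#' @param model a [variogram_model()].
#' @return the ratio in `[0, 1]`.
#' @export
sill_effect <- function(model) {
  if (model$sill <= 0) stop("sill_effect: undefined for zero sill")
  model$nugget / model$sill
}

#' Empirical semivariogram
#'
#' Method-of-moments estimator: for each equal-width lag bin,
#' `gamma = sum (z_i - z_j)^2 / (2 N(h))` over point pairs whose separation
#' falls in the bin. Empty bins are dropped.
#'
#' @param locations n x 2 matrix of coordinates.
#' @param values numeric vector of length n.
#' @param n_bins number of equal-width lag bins.
#' @param max_lag maximum lag; defaults to half the maximum pairwise
#'   distance (a standard rule: larger lags have few, unstable pairs).
#' @return object of class `vk_emp_variogram`: data.frame with columns
#'   `h` (bin centre), `gamma`, `n_pairs`.
#' @export
empirical_semivariogram <- function(locations, values, n_bins = 12,
                                    max_lag = NULL) {
  locations <- as.matrix(locations)
  n <- nrow(locations)
  stopifnot(n >= 3, length(values) == n)
  d <- as.vector(stats::dist(locations))
  if (max(d) == 0) stop("empirical_semivariogram: all points coincident")
  if (is.null(max_lag)) max_lag <- max(d) / 2
  sq <- as.vector(stats::dist(values))^2
  keep <- d > 0 & d <= max_lag
  if (!any(keep)) stop("empirical_semivariogram: no pairs within max_lag")
  width <- max_lag / n_bins
  bin <- pmin(floor(d[keep] / width), n_bins - 1)
  np <- tabulate(bin + 1L, nbins = n_bins)
  ssq <- vapply(seq_len(n_bins) - 1L,
                function(b) sum(sq[keep][bin == b]), numeric(1))
  nonempty <- np > 0
  out <- data.frame(h = (which(nonempty) - 0.5) * width,
                    gamma = ssq[nonempty] / (2 * np[nonempty]),
                    n_pairs = np[nonempty])
  structure(out, class = c("vk_emp_variogram", "data.frame"))
}

#' Fit a variogram model to an empirical semivariogram
#'
#' Weighted least squares with the classical weights N(h)/h^2 (pairs per
#' bin over squared lag, emphasizing short, well-estimated lags), solved by
#' box-constrained quasi-Newton optimization from a grid of data-driven
#' starting points. Each candidate family is fitted and the one with the
#' lowest weighted SSE is returned.
#'
#' @param emp an [empirical_semivariogram()] result (>= 4 populated bins).
#' @param families families to try.
#' @return the best-fitting [variogram_model()], with attributes `wsse`
#'   (weighted SSE) and `fits` (per-family parameter table).
#' @export
fit_variogram <- function(emp, families = c("spherical", "gaussian")) {
  stopifnot(nrow(emp) >= 4)
  h <- emp$h; g <- emp$gamma; w <- emp$n_pairs / pmax(h, 1e-12)^2
  gmax <- max(g); hmax <- max(h)
  obj <- function(par, fam) {
    m <- variogram_model(fam, par[1], par[2], par[3])
    sum(w * (g - model_gamma(m, h))^2)
  }
  starts <- expand.grid(nugget = c(0, 0.3) * gmax,
                        psill = c(0.6, 1.1) * gmax,
                        range = c(0.3, 0.7) * hmax)
  best <- NULL; rows <- list()
  for (fam in families) {
    fbest <- NULL
    for (k in seq_len(nrow(starts))) {
      fit <- tryCatch(
        stats::optim(as.numeric(starts[k, ]), obj, fam = fam,
                     method = "L-BFGS-B",
                     lower = c(0, 0, hmax * 1e-3),
                     upper = c(2 * gmax, 5 * gmax, 10 * hmax)),
        error = function(e) NULL)
      if (!is.null(fit) && (is.null(fbest) || fit$value < fbest$value))
        fbest <- fit
    }
    if (is.null(fbest)) next
    rows[[fam]] <- data.frame(family = fam, nugget = fbest$par[1],
                              psill = fbest$par[2], range = fbest$par[3],
                              wsse = fbest$value)
    if (is.null(best) || fbest$value < best$value) {
      best <- fbest; best$family <- fam
    }
  }
  if (is.null(best))
    stop("fit_variogram: optimizer failed for all starting points and families")
  m <- variogram_model(best$family, best$par[1], best$par[2], best$par[3])
  attr(m, "wsse") <- best$value
  attr(m, "fits") <- do.call(rbind, rows)
  m
}

#' Ordinary kriging prediction
#'
#' Solves the ordinary kriging system for each target: the n x n matrix of
#' model semivariances between observations, augmented with the
#' unbiasedness row/column of ones and a Lagrange multiplier; the
#' right-hand side holds semivariances between observations and the
#' target. Weights sum to one and, with gamma(0) = 0, the predictor
#' interpolates exactly at observation locations. The full (global)
#' neighbourhood is used.
#'
#' @param model a [variogram_model()] (range in the coordinate units).
#' @param obs_locations n x 2 matrix of observation coordinates.
#' @param obs_values numeric vector of length n.
#' @param targets m x 2 matrix of prediction coordinates.
#' @return list with `predictions` (length m) and `weights` (m x n matrix,
#'   rows summing to 1).
#' @export
ok_predict <- function(model, obs_locations, obs_values, targets) {
  obs_locations <- as.matrix(obs_locations)
  targets <- matrix(as.numeric(targets), ncol = 2)
  n <- nrow(obs_locations)
  stopifnot(n >= 2, length(obs_values) == n)
  D <- as.matrix(stats::dist(obs_locations))
  dup <- which(D == 0 & upper.tri(D), arr.ind = TRUE)
  if (nrow(dup) > 0)
    stop("ok_predict: duplicate observation locations at rows ",
         paste(apply(dup, 1, paste, collapse = "/"), collapse = ", "))
  A <- rbind(cbind(apply(D, 2, function(col) model_gamma(model, col)),
                   rep(1, n)),
             c(rep(1, n), 0))
  dx <- outer(obs_locations[, 1], targets[, 1], "-")
  dy <- outer(obs_locations[, 2], targets[, 2], "-")
  G0 <- matrix(model_gamma(model, as.vector(sqrt(dx^2 + dy^2))), nrow = n)
  B <- rbind(G0, rep(1, ncol(G0)))
  sol <- solve(A, B)
  lambda <- t(sol[seq_len(n), , drop = FALSE])   # m x n
  list(predictions = as.vector(lambda %*% obs_values), weights = lambda)
}

#' Simulate a Gaussian random field with a given variogram
#'
#' Draws one realization of a zero-mean Gaussian field at the supplied
#' locations whose variogram is the given model, by Cholesky factorization
#' of the covariance matrix C(h) = sill - gamma(h) (full sill on the
#' diagonal, nugget contributing independent noise). Exact for the small n
#' used here. A model with zero sill returns zeros.
#'
#' @param model a [variogram_model()].
#' @param locations n x 2 coordinate matrix (units of the model range).
#' @return numeric vector of length n. Uses the current RNG state.
#' @export
simulate_variogram_field <- function(model, locations) {
  locations <- as.matrix(locations)
  n <- nrow(locations)
  if (model$sill <= 0) return(rep(0, n))
  D <- as.matrix(stats::dist(locations))
  C <- model$sill - apply(D, 2, function(col) model_gamma(model, col))
  diag(C) <- model$sill
  # tiny jitter guards against numerically semi-definite matrices
  L <- chol(C + diag(1e-10 * model$sill, n))
  as.vector(t(L) %*% stats::rnorm(n))
}

#' Fit a regression-kriging hybrid
#'
#' Combines a fitted base learner with ordinary kriging of its training
#' residuals: the hybrid prediction is base prediction + kriged residual.
#' Residuals are observed minus the base learner's in-sample predictions at
#' the training plots, so that (with the exact-interpolation kriging
#' convention) the hybrid reproduces observed values at training plots.
#'
#' @param base a fitted learner from [fit_learner()].
#' @param features training feature data.frame (same columns as fit).
#' @param response observed response at the training plots.
#' @param locations n x 2 training coordinates (units define the fitted
#'   range's units; the pipeline passes kilometres).
#' @param n_bins,max_lag passed to [empirical_semivariogram()].
#' @return object of class `vk_hybrid` with the base model, training
#'   locations, residuals, and the fitted residual [variogram_model()].
#' @export
hybrid_fit <- function(base, features, response, locations,
                       n_bins = 12, max_lag = NULL) {
  base_pred <- predict_learner(base, features)
  resid <- response - base_pred
  if (stats::sd(resid) == 0) {
    # degenerate: constant residual field, the hybrid adds it verbatim
    return(structure(list(base = base, locations = as.matrix(locations),
                          residuals = resid, variogram = NULL,
                          empirical = NULL, const_residual = resid[1]),
                     class = "vk_hybrid"))
  }
  emp <- empirical_semivariogram(locations, resid, n_bins = n_bins,
                                 max_lag = max_lag)
  vario <- fit_variogram(emp)
  structure(list(base = base, locations = as.matrix(locations),
                 residuals = resid, variogram = vario, empirical = emp),
            class = "vk_hybrid")
}

#' Predict from a regression-kriging hybrid
#'
#' Base-learner prediction plus ordinary-kriging interpolation of the
#' training residuals at the target locations, elementwise. At a training
#' plot the kriged residual reproduces the training residual exactly, so
#' the hybrid returns the observed value there.
#'
#' @param hybrid a [hybrid_fit()] result.
#' @param features feature data.frame for the targets.
#' @param locations target coordinates, aligned with `features` rows.
#' @return numeric predictions.
#' @export
hybrid_predict <- function(hybrid, features, locations) {
  locations <- matrix(as.numeric(locations), ncol = 2)
  stopifnot(nrow(features) == nrow(locations))
  base_pred <- predict_learner(hybrid$base, features)
  if (!is.null(hybrid$const_residual))
    return(base_pred + hybrid$const_residual)
  ok <- ok_predict(hybrid$variogram, hybrid$locations, hybrid$residuals,
                   locations)
  base_pred + ok$predictions
}
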