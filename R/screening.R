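#' Pearson correlation with significance test
#'
#' Sample Pearson correlation between two vectors with the two-sided
#' p-value from the t statistic `r * sqrt((n-2) / (1-r^2))` on n-2 degrees
#' of freedom (via [stats::cor.test()]).
#'
#' @param x,y numeric vectors of equal length, n >= 3, both non-constant.
#' @return list with `r` and `p`.
#' @export
pearson_r_p <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("pearson_r_p: constant vector, correlation undefined")
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value)
}

#' Correlation screening of candidate predictors
#'
#' Keeps predictors whose absolute Pearson correlation with the response
#' is at least `threshold` and whose correlation test is significant at
#' `alpha`. Constant predictors are excluded with a warning (their
#' correlation is undefined). Column order is preserved.
#'
#' The significance direction is `p < alpha` by default; `direction =
#' "greater"` inverts it for sensitivity analysis.
#'
#' @param table data.frame containing the response column and candidate
#'   predictor columns (numeric).
#' @param response name of the response column (default `"M"`).
#' @param threshold minimum absolute correlation (default 0.4).
#' @param alpha significance level (default 0.05).
#' @param direction `"less"` keeps p < alpha (default), `"greater"` keeps
#'   p > alpha.
#' @return list with `result` (data.frame `predictor`, `r`, `p`,
#'   `selected`) and `table` (response + surviving predictors).
#' @export
screen_features <- function(table, response = "M", threshold = 0.4,
                            alpha = 0.05, direction = c("less", "greater")) {
  direction <- match.arg(direction)
  stopifnot(response %in% names(table))
  y <- table[[response]]
  preds <- setdiff(names(table), response)
  res <- lapply(preds, function(nm) {
    x <- table[[nm]]
    if (stats::sd(x) == 0) {
      warning("screen_features: constant predictor excluded: ", nm)
      return(data.frame(predictor = nm, r = NA_real_, p = NA_real_,
                        selected = FALSE))
    }
    rp <- pearson_r_p(x, y)
    sig <- if (direction == "less") rp$p < alpha else rp$p > alpha
    data.frame(predictor = nm, r = rp$r, p = rp$p,
               selected = abs(rp$r) >= threshold && sig)
  })
  res <- do.call(rbind, res)
  keep <- res$predictor[res$selected]
  if (length(keep) == 0)
    stop("screen_features: no predictors survive |r| >= ", threshold,
         " at alpha ", alpha, "; lower the threshold")
  message(sprintf("screen_features: %d of %d predictors kept (|r| >= %g, p %s %g)",
                  length(keep), length(preds), threshold,
                  if (direction == "less") "<" else ">", alpha))
  list(result = res, table = table[, c(response, keep), drop = FALSE])
}
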