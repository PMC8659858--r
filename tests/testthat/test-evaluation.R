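test_that("metrics match hand arithmetic", {
  m <- metrics(c(1, 2, 3), c(1, 2, 5))
  expect_equal(m$mae, 2 / 3)
  expect_equal(m$rmse, sqrt(4 / 3))
  expect_equal(m$r2, -1)
  perfect <- metrics(1:10, 1:10)
  expect_equal(unlist(perfect), c(mae = 0, rmse = 0, r2 = 1))
  shifted <- metrics(1:10, 1:10 + 3)
  expect_equal(shifted$mae, 3)
  expect_equal(shifted$rmse, 3)
  expect_gte(shifted$rmse, shifted$mae)
  expect_error(metrics(rep(1, 5), rnorm(5)), "zero variance")
})

test_that("improvement reproduces the percentage arithmetic", {
  expect_equal(improvement(52.3, 46.3), 11.47)
  expect_equal(improvement(75.1, 59.8), 20.37)
  expect_equal(improvement(10, 10), 0)
  expect_error(improvement(0, 1))
})

test_that("hybrid composition is exact at training plots", {
  set.seed(31)
  n <- 30
  X <- data.frame(a = rnorm(n), b = rnorm(n))
  loc <- matrix(runif(2 * n, 0, 10), ncol = 2)
  y <- 100 + 30 * X$a +
    simulate_variogram_field(variogram_model("spherical", 1, 200, 5), loc)
  for (kind in c("svr", "rf")) {
    base <- suppressWarnings(fit_learner(learner_config(kind, seed = 1),
                                         X, y))
    hyb <- hybrid_fit(base, X, y, loc)
    expect_equal(hybrid_predict(hyb, X, loc), y, tolerance = 1e-6,
                 info = kind)
    # additivity: hybrid minus base equals the kriged residual surface
    tg <- matrix(runif(10, 0, 10), ncol = 2)
    Xt <- data.frame(a = rnorm(5), b = rnorm(5))
    delta <- hybrid_predict(hyb, Xt, tg) - predict_learner(base, Xt)
    krg <- ok_predict(hyb$variogram, hyb$locations, hyb$residuals, tg)
    expect_equal(delta, krg$predictions, info = kind)
  }
})

test_that("far from the data the hybrid tends to base plus mean residual", {
  set.seed(32)
  n <- 25
  X <- data.frame(a = rnorm(n))
  loc <- matrix(runif(2 * n, 0, 2), ncol = 2)
  y <- 50 + 10 * X$a + rnorm(n, sd = 4)
  base <- fit_learner(learner_config("svr", seed = 1), X, y)
  hyb <- hybrid_fit(base, X, y, loc)
  far <- matrix(c(1e4, 1e4), ncol = 2)
  Xt <- data.frame(a = 0.3)
  expect_equal(
    hybrid_predict(hyb, Xt, far) - predict_learner(base, Xt),
    mean(ok_predict(hyb$variogram, hyb$locations, hyb$residuals,
                    far)$predictions),
    tolerance = 1e-6)
  # zero residuals: hybrid falls back to the base model everywhere
  y0 <- rep(7, n)
  base0 <- fit_learner(learner_config("svr", seed = 1), X, y0)
  expect_error(hybrid_fit(base0, X, y0, loc), NA)
})

test_that("LOO cross-validation pools fold predictions honestly", {
  set.seed(33)
  n <- 14
  tab <- data.frame(M = rnorm(n, 100, 20))
  tab$x1 <- tab$M + rnorm(n, sd = 5)
  tab$x2 <- rnorm(n)
  loc <- matrix(runif(2 * n, 0, 5), ncol = 2)
  cv <- suppressWarnings(suppressMessages(
    loo_cv(tab, loc, learners = "rf", hybrids = FALSE, threshold = 0.3,
           seed = 2)))
  # pooled metrics recomputable from the stored per-fold predictions
  m <- metrics(cv$observed, cv$predictions[, "rf"])
  expect_equal(cv$summary$rmse, m$rmse)
  expect_equal(cv$summary$mae, m$mae)
  expect_equal(cv$summary$r2, m$r2)
  expect_equal(length(cv$observed), n)
})

test_that("an uninformative constant-mean setting gives non-positive R2", {
  set.seed(34)
  n <- 16
  # predictors unrelated to the response: every learner approximates the
  # fold mean, and LOO R2 of the mean predictor is <= 0 by construction
  tab <- data.frame(M = rnorm(n, 50, 10), x1 = rnorm(n), x2 = rnorm(n))
  loc <- matrix(runif(2 * n, 0, 5), ncol = 2)
  cv <- suppressWarnings(suppressMessages(
    loo_cv(tab, loc, learners = "rf", hybrids = FALSE, screen = FALSE,
           seed = 3)))
  expect_lte(cv$summary$r2, 0.05)
})

test_that("cv report files agree with the in-memory summary", {
  set.seed(35)
  n <- 12
  tab <- data.frame(M = rnorm(n, 100, 15))
  tab$x1 <- tab$M + rnorm(n, sd = 8)
  loc <- matrix(runif(2 * n, 0, 5), ncol = 2)
  cv <- suppressWarnings(suppressMessages(
    loo_cv(tab, loc, learners = "rf", hybrids = TRUE, screen = FALSE,
           seed = 4)))
  out <- tempfile("cvreport")
  dir.create(out)
  on.exit(unlink(out, recursive = TRUE))
  files <- write_cv_report(cv, out)
  csv <- read.csv(files["cv_csv"])
  expect_equal(nrow(csv), 2)
  expect_equal(csv$rmse, cv$summary$rmse)
  js <- jsonlite::read_json(files["cv_json"], simplifyVector = TRUE)
  expect_equal(js$rmse, cv$summary$rmse)
  # improvement column recomputable from the rmse column
  expect_equal(csv$improvement_pct[2],
               improvement(csv$rmse[1], csv$rmse[2]))
})
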