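test_that("model semivariance has the exact-interpolation closed forms", {
  sph <- variogram_model("spherical", 0.3, 0.7, 10)
  expect_equal(model_gamma(sph, 0), 0)          # gamma(0) = 0 convention
  expect_equal(model_gamma(sph, 10), 1)         # sill reached at the range
  expect_equal(model_gamma(sph, 25), 1)         # flat beyond
  gau <- variogram_model("gaussian", 0, 1, 1)
  expect_equal(model_gamma(gau, 0), 0)
  expect_equal(model_gamma(gau, 1), 1 - exp(-3))   # 95%-sill range convention
  expect_error(model_gamma(sph, -1), "negative")
})

test_that("sill effect is the nugget share of the sill", {
  expect_equal(sill_effect(variogram_model("spherical", 0, 5, 1)), 0)
  expect_equal(sill_effect(variogram_model("spherical", 5, 0, 1)), 1)
  expect_equal(sill_effect(variogram_model("spherical", 1, 3, 1)), 0.25)
  expect_error(sill_effect(variogram_model("spherical", 0, 0, 1)), "zero sill")
})

test_that("empirical semivariogram matches direct pair arithmetic", {
  # colinear triple 0,2,0 at unit spacing, one bin up to lag 1.5: the two
  # unit-lag pairs each contribute (0-2)^2, gamma = (4+4)/(2*2) = 2
  loc <- rbind(c(0, 0), c(1, 0), c(2, 0))
  emp <- empirical_semivariogram(loc, c(0, 2, 0), n_bins = 1, max_lag = 1.5)
  expect_equal(emp$gamma[1], 2)
  expect_equal(emp$n_pairs[1], 2L)
  # identical values -> zero everywhere
  set.seed(1)
  locs <- matrix(runif(40), ncol = 2)
  emp0 <- empirical_semivariogram(locs, rep(3, 20))
  expect_true(all(emp0$gamma == 0))
  # invariant under reordering
  vals <- rnorm(20)
  p <- sample(20)
  e1 <- empirical_semivariogram(locs, vals)
  e2 <- empirical_semivariogram(locs[p, ], vals[p])
  expect_equal(e1, e2)
  expect_error(empirical_semivariogram(matrix(1, 4, 2), 1:4), "coincident")
})

test_that("variogram fitting recovers a noiseless model within 1%", {
  for (fam in c("spherical", "gaussian")) {
    truth <- variogram_model(fam, 0.1, 0.9, 30)
    h <- seq(1.5, 45, length.out = 12)
    emp <- structure(data.frame(h = h, gamma = model_gamma(truth, h),
                                n_pairs = rep(50, 12)),
                     class = c("vk_emp_variogram", "data.frame"))
    fit <- fit_variogram(emp)
    expect_identical(fit$family, fam)
    expect_equal(fit$nugget, truth$nugget, tolerance = 0.01)
    expect_equal(fit$psill, truth$psill, tolerance = 0.01)
    expect_equal(fit$range, truth$range, tolerance = 0.01)
    expect_equal(fit$sill, fit$nugget + fit$psill)
  }
})

test_that("white noise yields a nugget-dominated fit", {
  set.seed(42)
  locs <- matrix(runif(600, 0, 100), ncol = 2)
  vals <- rnorm(300)
  fit <- fit_variogram(empirical_semivariogram(locs, vals))
  expect_gt(sill_effect(fit), 0.7)
})

test_that("ordinary kriging is exact, unbiased, and matches a hand solve", {
  set.seed(7)
  locs <- matrix(runif(10, 0, 10), ncol = 2)
  vals <- rnorm(5, 10, 2)
  model <- variogram_model("spherical", 0.2, 1, 6)
  # exactness at observations
  ok <- ok_predict(model, locs, vals, locs)
  expect_equal(ok$predictions, vals, tolerance = 1e-8)
  # weights sum to one everywhere
  tg <- matrix(runif(20, 0, 10), ncol = 2)
  ok2 <- ok_predict(model, locs, vals, tg)
  expect_equal(rowSums(ok2$weights), rep(1, 10), tolerance = 1e-10)
  # oracle equivalence at n <= 5
  for (k in seq_len(nrow(tg))) {
    expect_equal(ok2$predictions[k], oracle_ok(model, locs, vals, tg[k, ]),
                 tolerance = 1e-8)
  }
  # pure nugget: every weight 1/n, prediction = sample mean
  nug <- variogram_model("spherical", 1, 0, 1)
  ok3 <- ok_predict(nug, locs, vals, cbind(5, 5))
  expect_equal(as.vector(ok3$weights), rep(1 / 5, 5), tolerance = 1e-10)
  expect_equal(ok3$predictions, mean(vals))
  # translation invariance
  ok4 <- ok_predict(model, locs + 100, vals, tg + 100)
  expect_equal(ok4$predictions, ok2$predictions, tolerance = 1e-8)
  # duplicate locations are refused
  expect_error(ok_predict(model, rbind(c(0, 0), c(0, 0), c(1, 1)),
                          1:3, cbind(2, 2)), "duplicate")
})

test_that("simulated fields reproduce their generating variogram", {
  # 200-point spherical fields over 20 seeds: median recovered sill within
  # 20% and range within 30% of truth
  truth <- variogram_model("spherical", 100, 900, 2)
  sills <- ranges <- numeric(20)
  for (s in 1:20) {
    set.seed(s)
    locs <- matrix(runif(400, 0, 10), ncol = 2)
    z <- simulate_variogram_field(truth, locs)
    fit <- fit_variogram(empirical_semivariogram(locs, z))
    sills[s] <- fit$sill; ranges[s] <- fit$range
  }
  expect_lt(abs(median(sills) - truth$sill) / truth$sill, 0.2)
  expect_lt(abs(median(ranges) - truth$range) / truth$range, 0.3)
})

test_that("degenerate truth fields simulate as zero", {
  locs <- matrix(runif(20), ncol = 2)
  z <- simulate_variogram_field(variogram_model("spherical", 0, 0, 1), locs)
  expect_identical(z, rep(0, 10))
})
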