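test_that("height normalization flattens ground and preserves heights", {
  set.seed(2)
  cl <- vk_cloud(toy_cloud(z_canopy = c(15, 8, 12), ground_z = 100))
  nc <- normalize_heights(cl)
  expect_true(all(abs(nc$z[nc$is_ground]) < 1e-9))
  expect_setequal(round(nc$z[!nc$is_ground], 6), c(15, 8, 12))
  # no ground points: falls back to the DEM, else errors
  canopy_only <- cl[!cl$is_ground, ]
  dem <- vk_grid(matrix(100, 5, 5), origin = c(-10, -10), pixel = 10)
  nc2 <- normalize_heights(canopy_only, dem = dem)
  expect_setequal(round(nc2$z, 6), c(15, 8, 12))
  expect_error(normalize_heights(canopy_only), "no ground points")
})

test_that("height metrics match direct statistics with linear percentiles", {
  set.seed(4)
  cl <- vk_cloud(toy_cloud(z_canopy = 1:100))
  m <- height_metrics(cl, cutoff_m = 0)
  expect_equal(unname(m["H_50"]), 50.5)
  expect_equal(unname(m["H_max"]), 100)
  expect_equal(unname(m["H_mean"]), 50.5)
  z <- 1:100
  expect_equal(unname(m["H_mad"]), mean(abs(z - mean(z))))
  expect_equal(unname(m["H_crr"]),
               (mean(z) - min(z)) / (max(z) - min(z)))
  # percentile monotonicity
  pct <- m[paste0("H_", c(1, 5, 10, 20, 25, 30, 40, 50, 60, 70, 75, 80,
                          90, 95, 99))]
  expect_true(all(diff(pct) >= 0))
  # brute-force moment oracle on a random cloud
  set.seed(8)
  zz <- rlnorm(400, 2.5, 0.4) + 2
  cl2 <- vk_cloud(toy_cloud(z_canopy = zz))
  m2 <- height_metrics(cl2, cutoff_m = 2)
  mu <- mean(zz); m2c <- mean((zz - mu)^2)
  expect_equal(unname(m2["H_skew"]), mean((zz - mu)^3) / m2c^1.5)
  expect_equal(unname(m2["H_kurt"]), mean((zz - mu)^4) / m2c^2)
  expect_equal(unname(m2["H_cv"]), sd(zz) / mu)
})

test_that("degenerate spread yields zero-valued dispersion metrics", {
  set.seed(5)
  cl <- vk_cloud(toy_cloud(z_canopy = rep(7, 10)))
  expect_warning(m <- height_metrics(cl, cutoff_m = 2), "zero spread")
  expect_equal(unname(m[c("H_std", "H_var", "H_mad", "H_cv", "H_crr")]),
               rep(0, 5))
})

test_that("density slices partition the canopy points", {
  set.seed(6)
  cl <- vk_cloud(toy_cloud(z_canopy = runif(5000, 2.0001, 12)))
  d <- density_metrics(cl)
  expect_equal(sum(d), 1)
  expect_true(all(abs(d - 0.1) < 0.02))
  # single height: all mass in the lowest slice
  cl1 <- vk_cloud(toy_cloud(z_canopy = rep(9, 5)))
  expect_equal(unname(density_metrics(cl1)), c(1, rep(0, 9)))
})

test_that("intensity metrics mirror the height statistics", {
  set.seed(7)
  cl <- vk_cloud(toy_cloud(z_canopy = c(5, 6, 7),
                           intensity = c(10, 20, 30)))
  m <- intensity_metrics(cl)
  expect_equal(unname(m["I_mean"]), 20)
  expect_equal(unname(m["I_mad"]), 20 / 3)
  expect_true(all(diff(m[c("I_1", "I_50", "I_99")]) >= 0))
  cl2 <- vk_cloud(toy_cloud(z_canopy = c(5, 6, 7), intensity = rep(77, 3)))
  expect_warning(m2 <- intensity_metrics(cl2), "zero spread")
  expect_equal(unname(m2[c("I_std", "I_cv")]), c(0, 0))
})

test_that("metric vector has 61 shuffle-invariant components", {
  set.seed(10)
  cl <- vk_cloud(toy_cloud(z_canopy = runif(200, 3, 20),
                           intensity = runif(200, 50, 200)))
  m <- cloud_metrics(cl)
  expect_length(m, 61)
  perm <- sample(nrow(cl))
  expect_equal(cloud_metrics(vk_cloud(cl[perm, ])), m)
})

test_that("CHM rasterization takes per-pixel maxima and fills gaps", {
  # constant-height canopy over a filled grid
  g <- expand.grid(x = seq(0.5, 9.5, 1), y = seq(0.5, 9.5, 1))
  cl <- vk_cloud(data.frame(x = g$x, y = g$y, z = 10, intensity = 1,
                            is_ground = FALSE))
  chm <- rasterize_chm(cl, pixel_m = 1)
  expect_true(all(chm$values == 10))
  # single tall point dominates its pixel
  cl2 <- vk_cloud(rbind(cl, data.frame(x = 3.4, y = 3.4, z = 20,
                                       intensity = 1, is_ground = FALSE)))
  expect_equal(max(rasterize_chm(cl2, pixel_m = 1)$values), 20)
})

test_that("tree detection counts well-separated crowns", {
  # two cones of apex heights 10 and 20 on a 40 x 40 half-metre grid
  px <- 0.5
  xc <- (seq_len(40) - 0.5) * px
  cone <- function(cx, cy, h, r) {
    d <- sqrt(outer((xc - cy)^2, (xc - cx)^2, "+"))
    pmax(h * (1 - d / r), 0)
  }
  # apexes placed exactly on cell centres so the CHM carries the true tops
  chm <- vk_grid(pmax(cone(4.75, 4.75, 10, 4), cone(14.75, 14.75, 20, 4)),
                 pixel = px)
  det <- detect_trees(chm, min_height_m = 2, window_px = 5)
  expect_identical(det$N, 2L)
  expect_equal(det$H, 15)
  expect_gt(det$W, 0)
  # single cone
  det1 <- detect_trees(vk_grid(cone(9.75, 9.75, 12, 5), pixel = px))
  expect_identical(det1$N, 1L)
  expect_equal(det1$H, 12)
  # monotone ramp has no interior local maximum
  ramp <- vk_grid(matrix(rep(seq(3, 30, length.out = 30), each = 30), 30, 30),
                  pixel = 1)
  det0 <- detect_trees(ramp)
  expect_identical(det0$N, 0L)
  expect_true(is.na(det0$H) && is.na(det0$W))
})
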