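test_that("DEM generation respects range, determinism, and slope bounds", {
  cfg <- small_config(seed = 5L)
  dem <- generate_dem(cfg)
  expect_gte(min(dem$values), cfg$elev_range_m[1])
  expect_lte(max(dem$values), cfg$elev_range_m[2])
  # same seed identical, different seed different
  expect_identical(generate_dem(small_config(seed = 5L))$values, dem$values)
  expect_false(identical(generate_dem(small_config(seed = 6L))$values,
                         dem$values))
  # flat configuration: constant grid, zero slope
  flat <- small_config(seed = 1L, elev_range_m = c(300, 300),
                       dem_amplitude = 0)
  dflat <- generate_dem(flat)
  expect_true(all(dflat$values == 300))
  expect_true(all(horn_slope(dflat) == 0))
  # empirical slope stays within a plausible hill-terrain envelope
  expect_true(all(horn_slope(dem) >= 0 & horn_slope(dem) <= 30))
})

test_that("stand truth honours the species mix and volume closure", {
  cfg <- landscape_config(seed = 11L)
  dem <- generate_dem(cfg)
  stand <- generate_stand_truth(cfg, dem)
  expect_equal(nrow(stand$plots), 52)
  expect_equal(as.vector(table(stand$plots$species)[
    c("larix", "koraiensis", "sylvestris")]), c(41, 5, 6))
  # closure: stored true volume equals the volume module on the tree list
  for (i in c(1, 17, 52)) {
    id <- stand$plots$plot_id[i]
    tr <- stand$trees[stand$trees$plot_id == id, ]
    expect_equal(stand$plots$true_volume_m3ha[i],
                 plot_volume_per_ha(tr, stand$plots$area_ha[i]),
                 tolerance = 1e-9)
  }
  # plots are pairwise non-overlapping (conservative half-diagonal rule)
  d <- as.matrix(dist(stand$plots[, c("center_x", "center_y")]))
  lim <- outer(stand$plots$side_m, stand$plots$side_m, "+") / sqrt(2)
  diag(d) <- Inf
  expect_true(all(d > lim))
  # degenerate residual field: all zeros
  cfg0 <- small_config(seed = 2L,
                       residual_variogram = variogram_model("spherical",
                                                            0, 0, 1))
  st0 <- generate_stand_truth(cfg0, generate_dem(cfg0))
  expect_true(all(st0$plots$residual_truth_m3ha == 0))
  expect_equal(st0$plots$observed_m3ha, st0$plots$true_volume_m3ha)
})

test_that("planted residual fields show their variogram at the range", {
  # over 20 replicate stands, the mean empirical semivariance near the
  # truth range should sit within 25% of the truth sill
  truth <- variogram_model("spherical", 100, 900, 2)
  gam <- numeric(20)
  for (s in 1:20) {
    cfg <- landscape_config(seed = s, residual_variogram = truth)
    dem <- generate_dem(cfg)
    stand <- generate_stand_truth(cfg, dem)
    loc <- as.matrix(stand$plots[, c("center_x", "center_y")]) / 1000
    emp <- empirical_semivariogram(loc, stand$plots$residual_truth_m3ha,
                                   n_bins = 8, max_lag = 4)
    gam[s] <- emp$gamma[which.min(abs(emp$h - truth$range))]
  }
  expect_lt(abs(mean(gam) - truth$sill) / truth$sill, 0.25)
})

test_that("point clouds satisfy density, geometry, and ground flags", {
  cfg <- small_config(seed = 3L)
  dem <- generate_dem(cfg)
  stand <- generate_stand_truth(cfg, dem)
  p <- stand$plots[1, ]
  tr <- stand$trees[stand$trees$plot_id == p$plot_id, ]
  cl <- generate_point_cloud(p, tr, dem, cfg)
  expect_gte(nrow(cl), p$area_ha * 1e4 * cfg$point_density_per_m2)
  # canopy points lie within (0, max tree height] above the terrain
  gz <- grid_sample(dem, cl$x, cl$y)
  above <- cl$z - gz
  expect_lte(max(above[!cl$is_ground]), max(tr$height_m) + 1e-6)
  expect_gt(max(above[!cl$is_ground]), 0)
  # treeless plot: ground returns only
  cl0 <- generate_point_cloud(p, tr[0, ], dem, cfg)
  expect_true(all(cl0$is_ground))
})

test_that("RGB tiles are green-dominant under crowns and non-degenerate", {
  cfg <- small_config(seed = 4L)
  dem <- generate_dem(cfg)
  stand <- generate_stand_truth(cfg, dem)
  p <- stand$plots[1, ]
  tr <- stand$trees[stand$trees$plot_id == p$plot_id, ]
  # fully covering crown, zero noise: G strictly dominates everywhere
  big <- tr[1, ]; big$x_m <- p$center_x; big$y_m <- p$center_y
  big$crown_radius_m <- 9.9
  small_plot <- p; small_plot$side_m <- 10; small_plot$area_ha <- 0.01
  tile0 <- generate_rgb_tile(small_plot, big, cfg, noise_sd = 0)
  expect_true(all(tile0$G > tile0$R & tile0$G > tile0$B))
  expect_gt(unname(vegetation_indices(tile0)["NGRDI"]), 0)
  # default tile: every band spans more than one gray level
  tile <- generate_rgb_tile(p, tr, cfg)
  for (bn in c("R", "G", "B"))
    expect_gt(length(unique(as.vector(tile[[bn]]))), 1)
})

test_that("stand summary features align with observed volume", {
  cfg <- small_config(seed = 8L)
  stand <- generate_stand_truth(cfg, generate_dem(cfg))
  tab <- stand_summary_features(stand)
  expect_equal(tab$M, stand$plots$observed_m3ha)
  expect_equal(dim(attr(tab, "locations")), c(12L, 2L))
  expect_true(all(is.finite(as.matrix(tab))))
})
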