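test_that("vegetation indices take their closed-form values on flat colors", {
  # gray tile: every symmetric difference index is 0
  m <- matrix(100, 6, 6)
  vi <- vegetation_indices(vk_tile(m, m, m))
  for (nm in c("NGRDI", "EXG", "VDVI", "MGRVI", "GLI", "NGBDI"))
    expect_equal(unname(vi[nm]), 0, info = nm)
  # CIVE at r = g = b = 1/3: (0.44 - 0.88 + 0.39)/3 + 18.79
  expect_equal(unname(vi["CIVE"]), (0.44 - 0.88 + 0.39) / 3 + 18.79)
  expect_equal(unname(vi["RGRI"]), 1)
  expect_equal(unname(vi["GBRI"]), 1)
  expect_equal(unname(vi["DEVI"]), 1)
  # WI has r = g everywhere: masked to NA
  expect_true(is.na(vi["WI"]))
  expect_length(vi, 17)
  expect_named(vi, vegetation_index_names())
})

test_that("combination indices are consistent with their components", {
  set.seed(3)
  tile <- vk_tile(matrix(runif(64, 30, 220), 8, 8),
                  matrix(runif(64, 30, 220), 8, 8),
                  matrix(runif(64, 30, 220), 8, 8))
  R <- as.numeric(tile$R); G <- as.numeric(tile$G); B <- as.numeric(tile$B)
  tot <- R + G + B
  r <- R / tot; g <- G / tot; b <- B / tot
  EXG <- 2 * g - r - b
  EXGR <- EXG - 1.4 * r - g
  CIVE <- 0.44 * r - 0.88 * g + 0.39 * b + 18.79
  VEG <- g / (r^0.67 * b^0.33)
  vi <- vegetation_indices(tile)
  expect_equal(unname(vi["COM"]),
               mean(0.25 * EXG + 0.3 * EXGR + 0.33 * CIVE + 0.12 * VEG))
  expect_equal(unname(vi["COM2"]),
               mean(0.36 * EXG + 0.47 * CIVE + 0.17 * VEG))
  expect_equal(unname(vi["EXR"]), mean(1.4 * r - g))
})

test_that("chromatic-coordinate indices are brightness invariant", {
  set.seed(9)
  R <- matrix(runif(49, 20, 120), 7, 7)
  G <- matrix(runif(49, 20, 120), 7, 7)
  B <- matrix(runif(49, 20, 120), 7, 7)
  v1 <- vegetation_indices(vk_tile(R, G, B))
  v2 <- vegetation_indices(vk_tile(2 * R, 2 * G, 2 * B))
  chrom <- c("EXG", "CIVE", "VEG", "EXGR", "WI", "RGRI", "GBRI", "GLI",
             "COM", "COM2", "EXR", "NGRDI", "VDVI", "NGBDI", "MGRVI",
             "GBRVI", "DEVI")
  expect_equal(v1[chrom], v2[chrom], tolerance = 1e-12)
})

test_that("GLCM features take single-cell values on a constant band", {
  f <- glcm_features(matrix(5, 6, 6))
  expect_equal(unname(f["contrast"]), 0)
  expect_equal(unname(f["heterogeneity"]), 0)
  expect_equal(unname(f["entropy"]), 0)
  expect_equal(unname(f["homogeneity"]), 1)
  expect_equal(unname(f["second_moment"]), 1)
  expect_equal(unname(f["variance"]), 0)
  expect_equal(unname(f["correlation"]), 0)
})

test_that("GLCM features equal brute-force enumeration on toy images", {
  stripes <- matrix(rep(c(0, 1), 8), 4, 4)       # 2-level vertical stripes
  expect_equal(glcm_features(stripes, levels = 2), oracle_glcm(stripes, 2))
  set.seed(11)
  for (k in 1:4) {
    img <- matrix(sample(0:255, 36, replace = TRUE), 6, 6)
    expect_equal(glcm_features(img), oracle_glcm(img), tolerance = 1e-12)
  }
  # probability bounds hold on an arbitrary band
  f <- glcm_features(matrix(rnorm(100), 10, 10))
  expect_gte(unname(f["entropy"]), 0)
  expect_gt(unname(f["second_moment"]), 0)
  expect_lte(unname(f["second_moment"]), 1)
})

test_that("three-band texture block has 24 named columns", {
  set.seed(5)
  tile <- vk_tile(matrix(runif(64), 8, 8), matrix(runif(64), 8, 8),
                  matrix(runif(64), 8, 8))
  tx <- tile_texture_features(tile)
  expect_length(tx, 24)
  expect_identical(names(tx)[1:2], c("R_mean", "R_variance"))
})

test_that("terrain factors recover altitude and plane slope", {
  flat <- vk_grid(matrix(173, 20, 20), pixel = 10)
  tf <- terrain_factors(flat, c(100, 100))
  expect_equal(unname(tf["h"]), 173)
  expect_equal(unname(tf["slope"]), 0)
  # inclined plane z = 0.1 x: slope = atan(0.1) everywhere
  xc <- (seq_len(30) - 0.5) * 10
  plane <- vk_grid(matrix(rep(0.1 * xc, each = 30), 30, 30), pixel = 10)
  tf2 <- terrain_factors(plane, c(150, 150))
  expect_equal(unname(tf2["slope"]), atan(0.1) * 180 / pi, tolerance = 1e-6)
  expect_error(terrain_factors(flat, c(1000, 0)), "outside")
})
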