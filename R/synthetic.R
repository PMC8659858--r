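#' Synthetic landscape configuration
#'
#' Bundles every parameter of the synthetic study area generator. The
#' defaults emulate the reference field campaign the package is designed
#' around: 52 square conifer plots of 0.06-0.2 ha split 41/5/6 between
#' larch (`larix`), Korean pine (`koraiensis`) and Scots pine
#' (`sylvestris`), rolling terrain between 170 and 575 m with slopes
#' overlapping 10-20 degrees, LiDAR point density of at least 2.8 points
#' per square metre (default 3), 12 cm RGB pixels, and a spatially
#' autocorrelated stand-volume residual field with a spherical variogram
#' in the range of the reference residual parameters (nugget 800,
#' partial sill 4500 (m3/ha)^2, range 3.5 km).
#'
#' @param n_plots number of plots (>= 3).
#' @param area_range_ha plot area range in hectares, within (0, 1].
#' @param species_mix named integer vector of per-species plot counts;
#'   must sum to `n_plots`.
#' @param elev_range_m DEM elevation range (min may equal max for a flat
#'   landscape).
#' @param slope_range_deg target slope range for the generated terrain.
#' @param point_density_per_m2 LiDAR point density floor, > 0.
#' @param pixel_size_m RGB pixel size, m.
#' @param dem_pixel_m DEM cell size, m.
#' @param extent_m side length of the square study area, m.
#' @param residual_variogram a [variogram_model()] describing the truth
#'   residual field; its range is in kilometres.
#' @param trend_coefficients optional named numeric vector adding linear
#'   terrain trends (`h`, `slope`) to the observed volume; default none.
#' @param noise_sd additional iid observation noise on the response,
#'   m3/ha (default 0: unstructured variance is carried by the nugget).
#' @param stem_density_range stems per hectare at the reference size
#'   class, drawn uniformly per plot and scaled down for larger-sized
#'   plots by the self-thinning coupling.
#' @param dbh_meanlog,dbh_sdlog within-plot lognormal DBH distribution
#'   parameters (cm scale) at the reference size class.
#' @param size_shift_range per-plot uniform range of the size-class shift
#'   added to `dbh_meanlog` (an age/site proxy: plots differ mainly in
#'   tree size, which moves heights with them, as in plantation
#'   chronosequences where stand volume is strongly height-driven).
#' @param self_thinning exponent coupling stem density to the size class
#'   (`density x exp(-self_thinning x shift)`): larger-sized plots carry
#'   fewer stems.
#' @param dem_amplitude relative harmonic amplitude (0 gives a flat DEM
#'   at the lower elevation bound).
#' @param seed integer; fully determines the generated landscape.
#' @return list of class `vk_config`.
#' @export
landscape_config <- function(n_plots = 52L,
                             area_range_ha = c(0.06, 0.2),
                             species_mix = c(larix = 41L, koraiensis = 5L,
                                             sylvestris = 6L),
                             elev_range_m = c(170, 575),
                             slope_range_deg = c(10, 20),
                             point_density_per_m2 = 3,
                             pixel_size_m = 0.12,
                             dem_pixel_m = 25,
                             extent_m = 10000,
                             residual_variogram =
                               variogram_model("spherical", 800, 4500, 3.5),
                             trend_coefficients = NULL,
                             noise_sd = 0,
                             stem_density_range = c(1100, 1300),
                             dbh_meanlog = log(18), dbh_sdlog = 0.3,
                             size_shift_range = c(-0.35, 0.45),
                             self_thinning = 0.8,
                             dem_amplitude = 1,
                             seed = 1L) {
  stopifnot(n_plots >= 3,
            area_range_ha[1] > 0, area_range_ha[2] <= 1,
            area_range_ha[1] <= area_range_ha[2],
            point_density_per_m2 > 0, pixel_size_m > 0,
            elev_range_m[1] <= elev_range_m[2],
            sum(species_mix) == n_plots,
            all(names(species_mix) %in% volume_params()$species))
  structure(as.list(environment()), class = "vk_config")
}

#' Generate a synthetic DEM
#'
#' Smooth elevation surface built as a sum of six low-frequency
#' directional harmonics (wavelengths 1.8-3.2 km, seeded directions and
#' phases), rescaled linearly into the configured elevation range. A
#' collapsed elevation range or zero amplitude yields a constant grid.
#'
#' @param config a [landscape_config()].
#' @return a [vk_grid()] covering the square study area.
#' @export
generate_dem <- function(config) {
  if (config$elev_range_m[1] > config$elev_range_m[2])
    stop("generate_dem: degenerate elevation range (min > max)")
  np <- ceiling(config$extent_m / config$dem_pixel_m)
  xc <- (seq_len(np) - 0.5) * config$dem_pixel_m
  z <- matrix(0, np, np)
  if (config$dem_amplitude > 0 &&
      config$elev_range_m[2] > config$elev_range_m[1]) {
    with_seed(child_seed(config$seed, 10L), {
      K <- 6L
      theta <- stats::runif(K, 0, pi)
      lambda <- stats::runif(K, 1800, 3200)
      phase <- stats::runif(K, 0, 2 * pi)
      amp <- stats::runif(K, 0.5, 1)
      for (k in seq_len(K)) {
        proj <- outer(xc * sin(theta[k]), xc * cos(theta[k]), "+")
        z <- z + amp[k] * sin(2 * pi * proj / lambda[k] + phase[k])
      }
    })
    zr <- range(z)
    lo <- config$elev_range_m[1]; hi <- config$elev_range_m[2]
    inset <- 0.002 * (hi - lo)
    z <- (z - zr[1]) / (zr[2] - zr[1]) *
      ((hi - inset) - (lo + inset)) * config$dem_amplitude + lo + inset
  } else {
    z[] <- config$elev_range_m[1]
  }
  vk_grid(z, origin = c(0, 0), pixel = config$dem_pixel_m)
}

# species-specific saturating height-diameter curves (Chapman-Richards
# shape H = 1.3 + A (1 - exp(-k D))^p) with bounded Gaussian noise
hd_params <- function() {
  data.frame(species = c("larix", "koraiensis", "sylvestris"),
             A = c(27, 22, 24), k = c(0.07, 0.06, 0.065),
             p = c(1.2, 1.3, 1.25))
}

tree_height_from_dbh <- function(species, dbh, h_sd = 1) {
  hp <- hd_params()
  i <- match(species, hp$species)
  h <- 1.3 + hp$A[i] * (1 - exp(-hp$k[i] * dbh))^hp$p[i] +
    stats::rnorm(length(dbh), sd = h_sd)
  pmax(h, 2)
}

#' Generate plot truth: placement, tree lists, volumes, residual field
#'
#' Places `n_plots` non-overlapping square plots in the study area,
#' draws per-plot tree lists (stem density uniform over the configured
#' range, lognormal DBH, saturating height-diameter curve with Gaussian
#' noise, conical crowns), computes the true per-hectare volume with the
#' volume module, and samples a zero-mean Gaussian random field with the
#' configured truth variogram at the plot centres (Cholesky
#' factorization). The observed response is
#' `true volume + residual + optional trend + iid noise`.
#'
#' @param config a [landscape_config()].
#' @param dem a [generate_dem()] result covering the study area.
#' @return list of class `vk_stand`: `plots` (data.frame `plot_id`,
#'   `center_x`, `center_y`, `area_ha`, `side_m`, `species`, `n_trees`,
#'   `true_volume_m3ha`, `residual_truth_m3ha`, `observed_m3ha`) and
#'   `trees` (data.frame `plot_id`, `species`, `dbh_cm`, `height_m`,
#'   `x_m`, `y_m`, `crown_radius_m`).
#' @export
generate_stand_truth <- function(config, dem) {
  ext <- grid_extent(dem)
  n <- config$n_plots
  species <- rep(names(config$species_mix), config$species_mix)

  with_seed(child_seed(config$seed, 20L), {
    species <- sample(species)
    areas <- stats::runif(n, config$area_range_ha[1], config$area_range_ha[2])
    sides <- sqrt(areas * 1e4)
    # rejection placement: squares cannot overlap if centres are at least
    # the sum of half-diagonals apart (conservative)
    cx <- numeric(0); cy <- numeric(0)
    tries <- 0L
    while (length(cx) < n) {
      tries <- tries + 1L
      if (tries > 1000L * n)
        stop("generate_stand_truth: could not place ", n,
             " non-overlapping plots; reduce n_plots or areas")
      k <- length(cx) + 1L
      m <- sides[k] / sqrt(2) + 1
      x <- stats::runif(1, ext["xmin"] + m, ext["xmax"] - m)
      y <- stats::runif(1, ext["ymin"] + m, ext["ymax"] - m)
      if (k > 1) {
        mind <- (sides[k] + sides[seq_len(k - 1L)]) / sqrt(2) + 1
        if (any(sqrt((cx - x)^2 + (cy - y)^2) < mind)) next
      }
      cx <- c(cx, x); cy <- c(cy, y)
    }

    size_shift <- stats::runif(n, config$size_shift_range[1],
                               config$size_shift_range[2])
    stem_density <- stats::runif(n, config$stem_density_range[1],
                                 config$stem_density_range[2]) *
      exp(-config$self_thinning * size_shift)
    trees <- vector("list", n)
    true_vol <- numeric(n)
    for (i in seq_len(n)) {
      nt <- max(1L, round(areas[i] * stem_density[i]))
      dbh <- stats::rlnorm(nt, config$dbh_meanlog + size_shift[i],
                           config$dbh_sdlog)
      hgt <- tree_height_from_dbh(rep(species[i], nt), dbh)
      crw <- pmin(pmax(0.06 * hgt + 0.4 + stats::rnorm(nt, sd = 0.15),
                       0.3), 9.9)
      trees[[i]] <- data.frame(
        plot_id = sprintf("plot%02d", i), species = species[i],
        dbh_cm = dbh, height_m = hgt,
        x_m = stats::runif(nt, cx[i] - sides[i] / 2, cx[i] + sides[i] / 2),
        y_m = stats::runif(nt, cy[i] - sides[i] / 2, cy[i] + sides[i] / 2),
        crown_radius_m = crw)
      true_vol[i] <- plot_volume_per_ha(trees[[i]], areas[i])
    }

    resid <- simulate_variogram_field(config$residual_variogram,
                                      cbind(cx, cy) / 1000)
    observed <- true_vol + resid
    if (!is.null(config$trend_coefficients)) {
      slope_grid <- horn_slope(dem)
      for (nm in names(config$trend_coefficients)) {
        tf <- vapply(seq_len(n), function(i)
          terrain_factors(dem, c(cx[i], cy[i]), slope_grid)[[nm]],
          numeric(1))
        observed <- observed + config$trend_coefficients[[nm]] * tf
      }
    }
    if (config$noise_sd > 0)
      observed <- observed + stats::rnorm(n, sd = config$noise_sd)

    structure(list(
      plots = data.frame(
        plot_id = sprintf("plot%02d", seq_len(n)),
        center_x = cx, center_y = cy, area_ha = areas, side_m = sides,
        species = species, n_trees = vapply(trees, nrow, integer(1)),
        true_volume_m3ha = true_vol, residual_truth_m3ha = resid,
        observed_m3ha = observed),
      trees = do.call(rbind, trees)), class = "vk_stand")
  })
}

#' Generate a synthetic LiDAR point cloud for one plot
#'
#' Ground returns are sampled uniformly over the plot square at the DEM
#' surface (flagged ground); each tree adds crown returns inside a
#' vertical cone with apex at the tree top and base radius equal to the
#' crown radius at 40% of tree height. Intensities are drawn from
#' separate ground and canopy distributions (canopy brighter). The total
#' point count is at least `area x density`.
#'
#' @param plot one row of the `plots` table of a [generate_stand_truth()].
#' @param trees the tree list of that plot.
#' @param dem the landscape DEM.
#' @param config the [landscape_config()].
#' @return a [vk_cloud()].
#' @export
generate_point_cloud <- function(plot, trees, dem, config) {
  side <- plot$side_m
  area_m2 <- plot$area_ha * 1e4
  with_seed(child_seed(config$seed, 30L + match(plot$plot_id,
                                                sprintf("plot%02d", 1:1000))), {
    n_ground <- ceiling(area_m2 * config$point_density_per_m2)
    gx <- stats::runif(n_ground, plot$center_x - side / 2,
                       plot$center_x + side / 2)
    gy <- stats::runif(n_ground, plot$center_y - side / 2,
                       plot$center_y + side / 2)
    gz <- grid_sample(dem, gx, gy)
    ground <- data.frame(x = gx, y = gy, z = gz,
                         intensity = pmin(pmax(stats::rnorm(n_ground, 40, 10),
                                               0), 255),
                         is_ground = TRUE)
    canopy <- NULL
    if (!is.null(trees) && nrow(trees) > 0) {
      per_tree <- pmax(3L, ceiling(pi * trees$crown_radius_m^2 *
                                     config$point_density_per_m2))
      idx <- rep(seq_len(nrow(trees)), per_tree)
      nt <- length(idx)
      ht <- trees$height_m[idx]; cr <- trees$crown_radius_m[idx]
      base <- 0.4 * ht
      u <- stats::runif(nt)              # relative height within the crown
      hz <- base + u * (ht - base)
      rad <- cr * (ht - hz) / (ht - base) * sqrt(stats::runif(nt))
      ang <- stats::runif(nt, 0, 2 * pi)
      px <- trees$x_m[idx] + rad * cos(ang)
      py <- trees$y_m[idx] + rad * sin(ang)
      gzc <- grid_sample(dem, pmin(pmax(px, grid_extent(dem)["xmin"]),
                                   grid_extent(dem)["xmax"]),
                         pmin(pmax(py, grid_extent(dem)["ymin"]),
                              grid_extent(dem)["ymax"]))
      canopy <- data.frame(x = px, y = py, z = gzc + hz,
                           intensity = pmin(pmax(stats::rnorm(nt, 120, 25),
                                                 0), 255),
                           is_ground = FALSE)
    }
    vk_cloud(rbind(ground, canopy))
  })
}

#' Generate a synthetic RGB tile for one plot
#'
#' 3-band 0-255 integer raster over the plot square: pixels under any
#' crown disk are green-dominant, gaps brown/gray-dominant, with Gaussian
#' pixel noise so texture statistics are non-degenerate.
#'
#' @inheritParams generate_point_cloud
#' @param noise_sd per-band pixel noise sd in gray levels (default 8).
#' @return a [vk_tile()] georeferenced to the plot extent.
#' @export
generate_rgb_tile <- function(plot, trees, config, noise_sd = 8) {
  stopifnot(config$pixel_size_m > 0)
  side <- plot$side_m
  p <- config$pixel_size_m
  npx <- max(3L, ceiling(side / p))
  x0 <- plot$center_x - side / 2; y0 <- plot$center_y - side / 2
  xc <- x0 + (seq_len(npx) - 0.5) * p
  yc <- y0 + (seq_len(npx) - 0.5) * p
  canopy <- matrix(FALSE, npx, npx)
  if (!is.null(trees) && nrow(trees) > 0) {
    for (t in seq_len(nrow(trees))) {
      jx <- which(abs(xc - trees$x_m[t]) <= trees$crown_radius_m[t])
      iy <- which(abs(yc - trees$y_m[t]) <= trees$crown_radius_m[t])
      if (length(jx) == 0 || length(iy) == 0) next
      d2 <- outer((yc[iy] - trees$y_m[t])^2, (xc[jx] - trees$x_m[t])^2, "+")
      canopy[iy, jx] <- canopy[iy, jx] | (d2 <= trees$crown_radius_m[t]^2)
    }
  }
  base <- list(R = ifelse(canopy, 60, 120),
               G = ifelse(canopy, 130, 100),
               B = ifelse(canopy, 55, 80))
  with_seed(child_seed(config$seed, 60L + match(plot$plot_id,
                                                sprintf("plot%02d", 1:1000))), {
    bands <- lapply(base, function(m) {
      v <- m + if (noise_sd > 0) stats::rnorm(length(m), sd = noise_sd) else 0
      matrix(pmin(pmax(round(v), 0), 255), npx, npx)
    })
    vk_tile(bands$R, bands$G, bands$B, origin = c(x0, y0), pixel = p)
  })
}

#' Tree-list summary features of a generated stand
#'
#' A cheap plot-level predictor table derived directly from the synthetic
#' tree lists (no point clouds or imagery): quadratic mean and maximum
#' DBH, mean and maximum height, Lorey-style basal-area-weighted height,
#' stem density, basal area per hectare, and plot area, with the observed
#' volume as response `M`. Used for truth-only simulation studies where
#' the question is the behaviour of the regression and kriging stages,
#' not of the feature extractors.
#'
#' @param stand a [generate_stand_truth()] result.
#' @return data.frame with `M` and 8 predictors; attribute `locations`
#'   holds plot centres (m).
#' @export
stand_summary_features <- function(stand) {
  plots <- stand$plots
  rows <- lapply(seq_len(nrow(plots)), function(i) {
    tr <- stand$trees[stand$trees$plot_id == plots$plot_id[i], ]
    ba <- pi * (tr$dbh_cm / 200)^2            # basal area per stem, m2
    c(dq = sqrt(mean(tr$dbh_cm^2)), dmax = max(tr$dbh_cm),
      hmean = mean(tr$height_m), hmax = max(tr$height_m),
      hlorey = sum(tr$height_m * ba) / sum(ba),
      stems_ha = nrow(tr) / plots$area_ha[i],
      ba_ha = sum(ba) / plots$area_ha[i],
      area = plots$area_ha[i])
  })
  out <- cbind(data.frame(M = plots$observed_m3ha),
               as.data.frame(do.call(rbind, rows)))
  attr(out, "locations") <- as.matrix(plots[, c("center_x", "center_y")])
  out
}

#' Generate a complete synthetic landscape
#'
#' Convenience wrapper running [generate_dem()], [generate_stand_truth()],
#' and per-plot [generate_point_cloud()] and [generate_rgb_tile()].
#'
#' @param config a [landscape_config()].
#' @param tiles,clouds logical: generate the RGB tiles / point clouds
#'   (disable for cheap truth-only studies).
#' @return list of class `vk_landscape` with `config`, `dem`, `stand`,
#'   `clouds` (named list), `tiles` (named list).
#' @export
generate_landscape <- function(config = landscape_config(), tiles = TRUE,
                               clouds = TRUE) {
  dem <- generate_dem(config)
  stand <- generate_stand_truth(config, dem)
  ids <- stand$plots$plot_id
  cl <- tl <- NULL
  if (clouds) {
    cl <- lapply(seq_along(ids), function(i)
      generate_point_cloud(stand$plots[i, ],
                           stand$trees[stand$trees$plot_id == ids[i], ],
                           dem, config))
    names(cl) <- ids
  }
  if (tiles) {
    tl <- lapply(seq_along(ids), function(i)
      generate_rgb_tile(stand$plots[i, ],
                        stand$trees[stand$trees$plot_id == ids[i], ],
                        config))
    names(tl) <- ids
  }
  structure(list(config = config, dem = dem, stand = stand,
                 clouds = cl, tiles = tl), class = "vk_landscape")
}
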