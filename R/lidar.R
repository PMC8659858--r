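#' Point cloud container
#'
#' Validates a per-plot point cloud: a data.frame with columns `x`, `y`,
#' `z` (m), `intensity` (arbitrary 0-255) and `is_ground` (logical).
#'
#' @param df data.frame with the required columns.
#' @return the data.frame, with class `vk_cloud` prepended.
#' @export
vk_cloud <- function(df) {
  need <- c("x", "y", "z", "intensity", "is_ground")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0)
    stop("vk_cloud: missing column(s): ", paste(missing, collapse = ", "))
  df$is_ground <- as.logical(df$is_ground)
  class(df) <- c("vk_cloud", "data.frame")
  df
}

# grid of mean ground elevation with iterative neighbour fill, used as the
# ground surface for height normalization
ground_surface <- function(cloud, res = 2) {
  g <- cloud[cloud$is_ground, , drop = FALSE]
  x0 <- min(cloud$x) - res / 2; y0 <- min(cloud$y) - res / 2
  nx <- max(1L, ceiling((max(cloud$x) - x0) / res))
  ny <- max(1L, ceiling((max(cloud$y) - y0) / res))
  jj <- pmin(pmax(floor((g$x - x0) / res) + 1L, 1L), nx)
  ii <- pmin(pmax(floor((g$y - y0) / res) + 1L, 1L), ny)
  cell <- (jj - 1L) * ny + ii
  sums <- rep(0, nx * ny); cnts <- rep(0L, nx * ny)
  for (k in seq_along(cell)) {
    sums[cell[k]] <- sums[cell[k]] + g$z[k]
    cnts[cell[k]] <- cnts[cell[k]] + 1L
  }
  z <- matrix(ifelse(cnts > 0, sums / pmax(cnts, 1L), NA_real_), ny, nx)
  # fill empty cells from the mean of filled 3x3 neighbours, repeatedly
  for (pass in seq_len(nx + ny)) {
    nas <- is.na(z)
    if (!any(nas)) break
    padded <- rbind(NA, cbind(NA, z, NA), NA)
    acc <- matrix(0, ny, nx); cnt <- matrix(0, ny, nx)
    for (di in -1:1) for (dj in -1:1) {
      nb <- padded[(2 + di):(ny + 1 + di), (2 + dj):(nx + 1 + dj)]
      ok <- !is.na(nb)
      acc[ok] <- acc[ok] + nb[ok]
      cnt <- cnt + ok
    }
    fill <- nas & cnt > 0
    z[fill] <- acc[fill] / cnt[fill]
  }
  vk_grid(z, origin = c(x0, y0), pixel = res)
}

#' Height-normalize a point cloud
#'
#' Replaces each point's elevation with its height above ground. Ground
#' elevation under each point is interpolated from a regular grid of mean
#' ground-point elevations (cell size `res`, empty cells filled from
#' neighbours), or sampled from the supplied DEM when the cloud carries no
#' ground-flagged points. Negative heights are clamped to 0.
#'
#' @param cloud a [vk_cloud()].
#' @param dem optional [vk_grid()] fallback ground model.
#' @param res ground-grid cell size, m (default 2).
#' @return the cloud with `z` replaced by height above ground (class
#'   `vk_cloud`, attribute `normalized = TRUE`).
#' @export
normalize_heights <- function(cloud, dem = NULL, res = 2) {
  cloud <- vk_cloud(cloud)
  if (any(cloud$is_ground)) {
    surf <- ground_surface(cloud, res = res)
    gz <- grid_sample(surf, cloud$x, cloud$y)
  } else if (!is.null(dem)) {
    gz <- grid_sample(dem, cloud$x, cloud$y)
  } else {
    stop("normalize_heights: no ground points and no DEM supplied")
  }
  cloud$z <- pmax(cloud$z - gz, 0)
  attr(cloud, "normalized") <- TRUE
  cloud
}

percentile_levels <- function() {
  c(1, 5, 10, 20, 25, 30, 40, 50, 60, 70, 75, 80, 90, 95, 99)
}

# shared summary statistics over a numeric vector: 15 percentiles (linear
# interpolation between order statistics), max/min/mean/median/sd/var/mad,
# population skewness and (non-excess) kurtosis, cv, optionally the canopy
# relief ratio (mean - min)/(max - min)
stat_block <- function(v, prefix, crr = FALSE) {
  pls <- percentile_levels()
  nm <- c(paste0(prefix, "_", pls),
          paste0(prefix, "_", c("max", "min", "mean", "med", "std", "var",
                                "mad")),
          paste0(prefix, "_", c("skew", "kurt")),
          if (crr) paste0(prefix, "_crr"),
          paste0(prefix, "_cv"))
  if (length(v) < 2) {
    warning("fewer than 2 usable points; ", prefix, " metrics set to NA")
    out <- rep(NA_real_, length(nm)); names(out) <- nm
    return(out)
  }
  q <- stats::quantile(v, pls / 100, names = FALSE, type = 7)
  mu <- mean(v); sdv <- stats::sd(v)
  m2 <- mean((v - mu)^2)
  degenerate <- m2 == 0
  if (degenerate)
    warning(prefix, " metrics: zero spread; moment ratios emitted as 0")
  skew <- if (degenerate) 0 else mean((v - mu)^3) / m2^1.5
  kurt <- if (degenerate) 0 else mean((v - mu)^4) / m2^2
  rng <- max(v) - min(v)
  crr_val <- if (rng == 0) 0 else (mu - min(v)) / rng
  out <- c(q, max(v), min(v), mu, stats::median(v), sdv, sdv^2,
           mean(abs(v - mu)), skew, kurt,
           if (crr) crr_val,
           if (mu == 0) 0 else sdv / mu)
  names(out) <- nm
  out
}

#' Height metrics of a normalized cloud
#'
#' 26 statistics of point heights above the understory cutoff: 15
#' percentiles, max/min/mean/median/sd/variance/mean-absolute-deviation,
#' population skewness and non-excess kurtosis, canopy relief ratio
#' `(mean - min)/(max - min)`, and coefficient of variation.
#'
#' @param cloud a [normalize_heights()] result.
#' @param cutoff_m understory height cutoff, m (default 2): only points
#'   with `z > cutoff_m` enter the statistics.
#' @return named numeric vector of 26 values (`H_*`).
#' @export
height_metrics <- function(cloud, cutoff_m = 2) {
  stat_block(cloud$z[cloud$z > cutoff_m], "H", crr = TRUE)
}

#' Height density metrics
#'
#' Splits the above-cutoff height range `[min z, max z]` into ten
#' equal-height layers and reports the fraction of points per layer
#' (`H_d0` lowest ... `H_d9` highest, top boundary inclusive). A cloud
#' with zero height spread puts all mass in `H_d0`. Fractions sum to 1
#' whenever any above-cutoff point exists.
#'
#' @inheritParams height_metrics
#' @return named numeric vector `H_d0` ... `H_d9`.
#' @export
density_metrics <- function(cloud, cutoff_m = 2) {
  z <- cloud$z[cloud$z > cutoff_m]
  nm <- paste0("H_d", 0:9)
  if (length(z) == 0) {
    warning("density_metrics: no above-cutoff points; NA")
    out <- rep(NA_real_, 10); names(out) <- nm
    return(out)
  }
  rng <- range(z)
  if (rng[1] == rng[2]) {
    out <- c(1, rep(0, 9)); names(out) <- nm
    return(out)
  }
  w <- (rng[2] - rng[1]) / 10
  layer <- pmin(floor((z - rng[1]) / w), 9)
  out <- tabulate(layer + 1L, nbins = 10L) / length(z)
  names(out) <- nm
  out
}

#' Intensity metrics of a normalized cloud
#'
#' 25 statistics of the return intensities of above-cutoff points: the
#' same percentile and moment block as [height_metrics()] but without the
#' canopy relief ratio.
#'
#' @inheritParams height_metrics
#' @return named numeric vector of 25 values (`I_*`).
#' @export
intensity_metrics <- function(cloud, cutoff_m = 2) {
  stat_block(cloud$intensity[cloud$z > cutoff_m], "I", crr = FALSE)
}

#' All point-cloud metrics of a plot
#'
#' Concatenates [height_metrics()] (26), [density_metrics()] (10) and
#' [intensity_metrics()] (25) into the 61-variable metric vector.
#'
#' @inheritParams height_metrics
#' @return named numeric vector of 61 values.
#' @export
cloud_metrics <- function(cloud, cutoff_m = 2) {
  c(height_metrics(cloud, cutoff_m),
    density_metrics(cloud, cutoff_m),
    intensity_metrics(cloud, cutoff_m))
}

#' Rasterize a canopy height model
#'
#' Per-pixel maximum of normalized heights; pixels without points are
#' filled by a single pass of the 3x3 median of populated neighbours, any
#' still-empty pixel by 0.
#'
#' @param cloud a [normalize_heights()] result.
#' @param pixel_m CHM cell size, m.
#' @param extent optional `c(xmin, xmax, ymin, ymax)`; defaults to the
#'   cloud's bounding box.
#' @return a [vk_grid()].
#' @export
rasterize_chm <- function(cloud, pixel_m = 0.5, extent = NULL) {
  stopifnot(pixel_m > 0)
  if (nrow(cloud) == 0) {
    if (is.null(extent)) extent <- c(0, pixel_m, 0, pixel_m)
  } else if (is.null(extent)) {
    extent <- c(min(cloud$x), max(cloud$x) + 1e-9,
                min(cloud$y), max(cloud$y) + 1e-9)
  }
  nx <- max(1L, ceiling((extent[2] - extent[1]) / pixel_m))
  ny <- max(1L, ceiling((extent[4] - extent[3]) / pixel_m))
  z <- matrix(NA_real_, ny, nx)
  if (nrow(cloud) > 0) {
    jj <- pmin(pmax(floor((cloud$x - extent[1]) / pixel_m) + 1L, 1L), nx)
    ii <- pmin(pmax(floor((cloud$y - extent[3]) / pixel_m) + 1L, 1L), ny)
    ord <- order(cloud$z)   # later (higher) writes win
    z[cbind(ii[ord], jj[ord])] <- cloud$z[ord]
  }
  nas <- which(is.na(z), arr.ind = TRUE)
  if (nrow(nas) > 0 && any(!is.na(z))) {
    zf <- z
    for (k in seq_len(nrow(nas))) {
      i <- nas[k, 1]; j <- nas[k, 2]
      nb <- z[max(1, i - 1):min(ny, i + 1), max(1, j - 1):min(nx, j + 1)]
      nb <- nb[!is.na(nb)]
      if (length(nb) > 0) zf[i, j] <- stats::median(nb)
    }
    z <- zf
  }
  z[is.na(z)] <- 0
  vk_grid(z, origin = c(extent[1], extent[3]), pixel = pixel_m)
}

#' Detect tree tops on a CHM
#'
#' Tree tops are cells that strictly exceed every other cell of their
#' sliding `window_px` x `window_px` neighbourhood and exceed
#' `min_height_m`; only cells with a full window inside the grid are
#' candidates. Crown regions assign each canopy cell
#' (`CHM > min_height_m`) to its nearest top; the mean crown width W is
#' the mean over tops of the diameter of a circle with the region's area.
#' This local-maxima detector stands in for marker-watershed segmentation
#' with interactive seed editing, which is not reproducible in code.
#'
#' @param chm a [vk_grid()] canopy height model.
#' @param min_height_m minimum top height, m (default 2).
#' @param window_px odd window size in pixels (default 5).
#' @return list with `N` (top count), `H` (mean top height, m), `W` (mean
#'   crown width, m), and `tops` (data.frame x, y, height). `H` and `W`
#'   are `NA` when no top is found.
#' @export
detect_trees <- function(chm, min_height_m = 2, window_px = 5L) {
  z <- chm$values
  ny <- nrow(z); nx <- ncol(z)
  half <- window_px %/% 2
  tops <- NULL
  if (ny >= window_px && nx >= window_px) {
    for (i in (half + 1):(ny - half)) {
      for (j in (half + 1):(nx - half)) {
        v <- z[i, j]
        if (v <= min_height_m) next
        w <- z[(i - half):(i + half), (j - half):(j + half)]
        if (v < max(w)) next
        # plateau tie-break: only the first cell (column-major within the
        # window) attaining the maximum counts as the top
        if (which.max(w) == (half * window_px + half + 1L))
          tops <- rbind(tops, c(i, j, v))
      }
    }
  }
  if (is.null(tops)) {
    return(list(N = 0L, H = NA_real_, W = NA_real_,
                tops = data.frame(x = numeric(0), y = numeric(0),
                                  height = numeric(0))))
  }
  p <- chm$pixel
  tx <- chm$origin[1] + (tops[, 2] - 0.5) * p
  ty <- chm$origin[2] + (tops[, 1] - 0.5) * p
  canopy <- which(z > min_height_m, arr.ind = TRUE)
  cx <- chm$origin[1] + (canopy[, 2] - 0.5) * p
  cy <- chm$origin[2] + (canopy[, 1] - 0.5) * p
  d2 <- outer(cx, tx, "-")^2 + outer(cy, ty, "-")^2
  nearest <- max.col(-d2, ties.method = "first")
  areas <- tabulate(nearest, nbins = nrow(tops)) * p^2
  list(N = nrow(tops), H = mean(tops[, 3]),
       W = mean(2 * sqrt(areas / pi)),
       tops = data.frame(x = tx, y = ty, height = tops[, 3]))
}
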