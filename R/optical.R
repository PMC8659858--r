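#' RGB raster tile
#'
#' Three-band integer raster (0-255) with georeferencing, same cell
#' convention as [vk_grid()].
#'
#' @param R,G,B numeric matrices of equal shape.
#' @param origin,pixel as in [vk_grid()].
#' @return object of class `vk_tile`.
#' @export
vk_tile <- function(R, G, B, origin = c(0, 0), pixel = 1) {
  stopifnot(identical(dim(R), dim(G)), identical(dim(R), dim(B)))
  structure(list(R = R, G = G, B = B, origin = as.numeric(origin),
                 pixel = as.numeric(pixel)),
            class = "vk_tile")
}

#' Names of the visible vegetation indices
#' @return character vector of the 17 index abbreviations.
#' @export
vegetation_index_names <- function() {
  c("NGRDI", "EXG", "CIVE", "VEG", "EXGR", "WI", "VDVI", "RGRI", "NGBDI",
    "GBRI", "GBRVI", "MGRVI", "DEVI", "GLI", "COM", "COM2", "EXR")
}

#' Visible-band vegetation indices of a tile
#'
#' Computes 17 vegetation indices from the R, G, B bands per pixel and
#' averages each over the tile's valid pixels. Lower-case r, g, b are the
#' chromatic coordinates r = R/(R+G+B) etc. Pixels with R+G+B = 0 are
#' masked globally; pixels where an individual index's denominator
#' vanishes (e.g. WI with r = g) are masked for that index only. An index
#' with no valid pixel is returned as `NA`.
#'
#' Formulas (as tabulated in the visible-index literature; VEG uses
#' exponent a = 0.67; EXGR is taken literally as `EXG - 1.4 r - g`):
#' NGRDI = (G-R)/(G+R); EXG = 2g-r-b; CIVE = 0.44r-0.88g+0.39b+18.79;
#' VEG = g/(r^0.67 b^0.33); EXGR = EXG-1.4r-g; WI = (g-b)/(r-g);
#' VDVI = (2G-R-B)/(2G+R+B); RGRI = r/g; NGBDI = (G-B)/(G+B); GBRI = b/g;
#' GBRVI = (G^2-BR)/(G^2+BR); MGRVI = (G^2-R^2)/(G^2+R^2);
#' DEVI = (G+R+B)/(3G); GLI = (2g-r-b)/(2g+r+b);
#' COM = 0.25EXG+0.3EXGR+0.33CIVE+0.12VEG; COM2 = 0.36EXG+0.47CIVE+0.17VEG;
#' EXR = 1.4r-g.
#'
#' @param tile a [vk_tile()].
#' @return named numeric vector of 17 plot-mean index values.
#' @export
vegetation_indices <- function(tile) {
  R <- as.numeric(tile$R); G <- as.numeric(tile$G); B <- as.numeric(tile$B)
  tot <- R + G + B
  valid <- tot > 0
  r <- ifelse(valid, R / tot, NA_real_)
  g <- ifelse(valid, G / tot, NA_real_)
  b <- ifelse(valid, B / tot, NA_real_)

  safe_div <- function(num, den, tol = 0) {
    out <- ifelse(abs(den) > tol, num / den, NA_real_)
    out
  }
  EXG <- 2 * g - r - b
  CIVE <- 0.44 * r - 0.88 * g + 0.39 * b + 18.79
  VEG <- safe_div(g, r^0.67 * b^(1 - 0.67))
  EXGR <- EXG - 1.4 * r - g
  idx <- list(
    NGRDI = safe_div(G - R, G + R),
    EXG = EXG,
    CIVE = CIVE,
    VEG = VEG,
    EXGR = EXGR,
    WI = safe_div(g - b, r - g),
    VDVI = safe_div(2 * G - R - B, 2 * G + R + B),
    RGRI = safe_div(r, g),
    NGBDI = safe_div(G - B, G + B),
    GBRI = safe_div(b, g),
    GBRVI = safe_div(G^2 - B * R, G^2 + B * R),
    MGRVI = safe_div(G^2 - R^2, G^2 + R^2),
    DEVI = safe_div(G + R + B, 3 * G),
    GLI = safe_div(2 * g - r - b, 2 * g + r + b),
    COM = 0.25 * EXG + 0.3 * EXGR + 0.33 * CIVE + 0.12 * VEG,
    COM2 = 0.36 * EXG + 0.47 * CIVE + 0.17 * VEG,
    EXR = 1.4 * r - g
  )
  out <- vapply(idx, function(v) {
    v <- v[valid & is.finite(v)]
    if (length(v) == 0) NA_real_ else mean(v)
  }, numeric(1))
  out[vegetation_index_names()]
}

#' Names of the GLCM texture features
#' @return character vector of the 8 feature names.
#' @export
glcm_feature_names <- function() {
  c("mean", "variance", "homogeneity", "contrast", "heterogeneity",
    "entropy", "second_moment", "correlation")
}

#' GLCM texture features of a single band
#'
#' Quantizes the band into `levels` equal-width bins over its min-max
#' range, then for each pixel whose `window` x `window` neighbourhood lies
#' fully inside the band builds the symmetric gray-level co-occurrence
#' matrix of the window at offset `(dx, dy)` and computes eight
#' Haralick-style statistics ("heterogeneity" is dissimilarity; entropy
#' uses the natural log; correlation is defined as 0 for windows with zero
#' marginal variance). The plot-level value of each feature is the
#' unweighted mean over those interior pixels.
#'
#' @param band numeric matrix.
#' @param levels quantization levels (default 64).
#' @param window square window size in pixels (default 3).
#' @param dx,dy co-occurrence offset in pixels (default both 1).
#' @return named numeric vector of 8 plot-mean features.
#' @export
glcm_features <- function(band, levels = 64L, window = 3L, dx = 1L, dy = 1L) {
  stopifnot(is.matrix(band), levels >= 2, window >= 2, !(dx == 0 && dy == 0))
  rng <- range(band)
  q <- if (rng[2] > rng[1]) {
    pmin(floor((band - rng[1]) / (rng[2] - rng[1]) * levels), levels - 1L)
  } else {
    band * 0L
  }
  storage.mode(q) <- "integer"
  stats <- glcm_window_stats(q, as.integer(levels), as.integer(window),
                             as.integer(dx), as.integer(dy))
  if (nrow(stats) == 0)
    stop("glcm_features: band smaller than the processing window")
  out <- colMeans(stats)
  names(out) <- glcm_feature_names()
  out
}

#' Texture features of all three bands of a tile
#'
#' @param tile a [vk_tile()].
#' @param ... passed to [glcm_features()].
#' @return named numeric vector of 24 values, names `<band>_<feature>`
#'   with bands `R`, `G`, `B`.
#' @export
tile_texture_features <- function(tile, ...) {
  out <- unlist(lapply(c("R", "G", "B"), function(bn) {
    f <- glcm_features(tile[[bn]], ...)
    names(f) <- paste(bn, names(f), sep = "_")
    f
  }))
  out
}

#' Terrain factors at a plot centre
#'
#' Altitude by bilinear DEM sampling and slope (degrees) by Horn's 3x3
#' method sampled at the centre.
#'
#' @param dem a [vk_grid()] of elevations (m).
#' @param plot_center length-2 coordinates (m).
#' @param slope_grid optional precomputed [horn_slope()] matrix for `dem`,
#'   to avoid recomputation across plots.
#' @return named numeric `c(h = altitude_m, slope = slope_deg)`.
#' @export
terrain_factors <- function(dem, plot_center, slope_grid = NULL) {
  if (is.null(slope_grid)) slope_grid <- horn_slope(dem)
  sg <- vk_grid(slope_grid, origin = dem$origin, pixel = dem$pixel)
  c(h = grid_sample(dem, plot_center[1], plot_center[2]),
    slope = grid_sample(sg, plot_center[1], plot_center[2]))
}
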