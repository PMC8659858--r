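#' Regular raster grid
#'
#' Lightweight container for single-band regular grids (DEM, CHM, image
#' bands): a numeric matrix plus georeferencing. Cell `[i, j]` covers the
#' half-open square `[x0 + (j-1)p, x0 + j*p) x [y0 + (i-1)p, y0 + i*p)`,
#' so row 1 is the southernmost row and sampling uses the centre-of-pixel
#' convention (the centre of cell `[i, j]` is at
#' `(x0 + (j - 0.5) p, y0 + (i - 0.5) p)`).
#'
#' @param values numeric matrix, `nrow` cells along y, `ncol` along x.
#' @param origin numeric length-2, coordinates of the grid's south-west corner.
#' @param pixel cell size in the coordinate units (metres throughout the
#'   package), a single positive number.
#' @return an object of class `vk_grid`.
#' @export
vk_grid <- function(values, origin = c(0, 0), pixel = 1) {
  stopifnot(is.matrix(values), length(origin) == 2, pixel > 0)
  structure(list(values = values, origin = as.numeric(origin),
                 pixel = as.numeric(pixel)),
            class = "vk_grid")
}

#' @export
print.vk_grid <- function(x, ...) {
  cat(sprintf("<vk_grid %d x %d, pixel %g, origin (%g, %g), range [%g, %g]>\n",
              nrow(x$values), ncol(x$values), x$pixel,
              x$origin[1], x$origin[2],
              min(x$values), max(x$values)))
  invisible(x)
}

#' Grid extent
#'
#' @param grid a [vk_grid()].
#' @return named numeric `c(xmin, xmax, ymin, ymax)`.
#' @export
grid_extent <- function(grid) {
  c(xmin = grid$origin[1],
    xmax = grid$origin[1] + ncol(grid$values) * grid$pixel,
    ymin = grid$origin[2],
    ymax = grid$origin[2] + nrow(grid$values) * grid$pixel)
}

#' Bilinear sampling of a grid
#'
#' Samples grid values at arbitrary coordinates by bilinear interpolation
#' between the four surrounding cell centres; coordinates within the outer
#' half-pixel ring are clamped to the nearest centre. Points outside the
#' grid extent are an error.
#'
#' @param grid a [vk_grid()].
#' @param x,y coordinate vectors of equal length.
#' @return numeric vector of interpolated values.
#' @export
grid_sample <- function(grid, x, y) {
  stopifnot(length(x) == length(y))
  ext <- grid_extent(grid)
  if (any(x < ext["xmin"] | x > ext["xmax"] | y < ext["ymin"] | y > ext["ymax"]))
    stop("grid_sample: point outside grid extent")
  p <- grid$pixel
  # continuous index of the cell centre: centre of cell j is at (j - 0.5)
  cx <- (x - grid$origin[1]) / p + 0.5
  cy <- (y - grid$origin[2]) / p + 0.5
  nx <- ncol(grid$values); ny <- nrow(grid$values)
  cx <- pmin(pmax(cx, 1), nx)
  cy <- pmin(pmax(cy, 1), ny)
  j0 <- pmin(floor(cx), nx - 1L); j0[nx == 1L] <- 1L
  i0 <- pmin(floor(cy), ny - 1L); i0[ny == 1L] <- 1L
  j1 <- pmin(j0 + 1L, nx); i1 <- pmin(i0 + 1L, ny)
  tx <- cx - j0; ty <- cy - i0
  v <- grid$values
  v00 <- v[cbind(i0, j0)]; v01 <- v[cbind(i0, j1)]
  v10 <- v[cbind(i1, j0)]; v11 <- v[cbind(i1, j1)]
  (1 - ty) * ((1 - tx) * v00 + tx * v01) + ty * ((1 - tx) * v10 + tx * v11)
}

#' Slope by Horn's method
#'
#' Computes slope in degrees from an elevation grid using Horn's 3x3
#' weighted finite differences (the standard GIS slope operator). Edge
#' cells are handled by replicating the border row/column.
#'
#' @param grid a [vk_grid()] of elevations (same units as the pixel size).
#' @return a matrix of slope values in degrees, same shape as the grid.
#' @export
horn_slope <- function(grid) {
  z <- grid$values
  ny <- nrow(z); nx <- ncol(z)
  if (ny < 2 || nx < 2) return(matrix(0, ny, nx))
  up <- function(m) m[c(1L, seq_len(ny - 1L)), , drop = FALSE]     # shift from south
  dn <- function(m) m[c(seq_len(ny)[-1L], ny), , drop = FALSE]
  lf <- function(m) m[, c(1L, seq_len(nx - 1L)), drop = FALSE]
  rt <- function(m) m[, c(seq_len(nx)[-1L], nx), drop = FALSE]
  # neighbours in compass terms; row index increases northward
  e <- rt(z); w <- lf(z); n <- dn(z); s <- up(z)
  ne <- rt(dn(z)); nw <- lf(dn(z)); se <- rt(up(z)); sw <- lf(up(z))
  p <- grid$pixel
  dzdx <- ((ne + 2 * e + se) - (nw + 2 * w + sw)) / (8 * p)
  dzdy <- ((ne + 2 * n + nw) - (se + 2 * s + sw)) / (8 * p)
  atan(sqrt(dzdx^2 + dzdy^2)) * 180 / pi
}

#' Write / read a grid as flat binary plus JSON sidecar
#'
#' Persists a [vk_grid()] as little-endian float64 values in column-major
#' order (`<prefix>.bin`) with a JSON sidecar (`<prefix>.json`) recording
#' origin, pixel size, and shape `[nrow, ncol]`. This plain-binary dialect
#' keeps the package free of geospatial raster dependencies while staying
#' trivially readable from any language.
#'
#' @param grid a [vk_grid()].
#' @param prefix file path without extension.
#' @return `prefix`, invisibly.
#' @export
write_grid <- function(grid, prefix) {
  con <- file(paste0(prefix, ".bin"), "wb")
  on.exit(close(con))
  writeBin(as.numeric(grid$values), con, size = 8, endian = "little")
  meta <- list(origin = grid$origin, pixel_size_m = grid$pixel,
               shape = c(nrow(grid$values), ncol(grid$values)),
               order = "column-major", row1 = "south")
  jsonlite::write_json(meta, paste0(prefix, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(prefix)
}

#' @rdname write_grid
#' @export
read_grid <- function(prefix) {
  meta <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  sh <- as.integer(meta$shape)
  con <- file(paste0(prefix, ".bin"), "rb")
  on.exit(close(con))
  v <- readBin(con, what = "numeric", n = prod(sh), size = 8, endian = "little")
  vk_grid(matrix(v, nrow = sh[1], ncol = sh[2]),
          origin = as.numeric(meta$origin), pixel = meta$pixel_size_m)
}
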