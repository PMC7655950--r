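# Horn (1981) 3x3 finite-difference gradients, the convention used by
# mainstream GIS terrain tools. Returns east and north gradient components
# (dz/dx, dz/dy with y pointing north); cells whose 3x3 window touches the
# border or a nodata cell come back NA.
horn_gradients <- function(dem) {
  stopifnot(is_scene_raster(dem))
  z <- dem$values
  nr <- nrow(z); nc <- ncol(z)
  if (nr < 3 || nc < 3) stop("DEM needs at least 3x3 valid cells")
  if (all(is.na(z))) stop("DEM is entirely nodata")
  cs <- dem$cell_size

  # shifted views of the 3x3 neighbourhood of each interior cell:
  # rows run north -> south, so "up" (smaller row index) is north.
  w <- function(dr, dc) z[(2:(nr - 1)) + dr, (2:(nc - 1)) + dc]
  a <- w(-1, -1); b <- w(-1, 0); cc <- w(-1, 1)
  d <- w(0, -1);                 f <- w(0, 1)
  g <- w(1, -1);  h <- w(1, 0);  i <- w(1, 1)

  gx <- ((cc + 2 * f + i) - (a + 2 * d + g)) / (8 * cs)   # +east
  gy <- ((a + 2 * b + cc) - (g + 2 * h + i)) / (8 * cs)   # +north

  full <- function(m) {
    out <- matrix(NA_real_, nr, nc)
    out[2:(nr - 1), 2:(nc - 1)] <- m
    out
  }
  list(gx = full(gx), gy = full(gy))
}

#' Slope from a DEM
#'
#' Per-cell slope in degrees, `atan(sqrt(gx^2 + gy^2))`, with gradients by
#' the Horn 3x3 weighted-difference scheme. Border cells and cells whose
#' window touches nodata are nodata.
#'
#' @param dem a [scene_raster] elevation grid (metres) of at least 3x3
#'   valid cells.
#' @return a [scene_raster] with band `"slope"` (degrees, `[0, 90]`).
#' @export
slope <- function(dem) {
  gr <- horn_gradients(dem)
  s <- atan(sqrt(gr$gx^2 + gr$gy^2)) * 180 / pi
  scene_raster(s, dem$cell_size, origin = dem$origin, band = "slope")
}

#' Aspect from a DEM
#'
#' Downslope azimuth in degrees clockwise from north — the compass
#' direction the surface faces. Flat cells (gradient magnitude below
#' `flat_tol`) are nodata.
#'
#' @inheritParams slope
#' @param flat_tol gradient magnitude (m/m) below which a cell counts as
#'   flat (default 1e-8).
#' @return a [scene_raster] with band `"aspect"` (degrees, `[0, 360)`).
#' @export
aspect <- function(dem, flat_tol = 1e-8) {
  gr <- horn_gradients(dem)
  a <- (atan2(-gr$gx, -gr$gy) * 180 / pi) %% 360
  flat <- sqrt(gr$gx^2 + gr$gy^2) < flat_tol
  a[flat] <- NA_real_
  scene_raster(a, dem$cell_size, origin = dem$origin, band = "aspect")
}
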