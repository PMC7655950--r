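#' In-memory raster grid
#'
#' Lightweight container for the single-band gridded products the package
#' works with: elevation (m), slope (degrees), aspect (degrees), a colour
#' band (0--255), a categorical facies code or a segment id. Row 1 is the
#' northernmost row; column 1 the westernmost. `origin` is the (x, y)
#' map coordinate of the *outer* corner of the top-left cell, so the cell
#' centre of `[1, 1]` sits at `origin + (cell_size/2, -cell_size/2)`.
#'
#' @param values numeric or integer matrix (rows = north to south).
#' @param cell_size cell edge length in metres (> 0).
#' @param origin length-2 numeric, map coordinate of the top-left corner.
#' @param nodata sentinel value marking invalid cells; stored cells equal to
#'   it are treated as missing (internally they are held as `NA`).
#' @param band one of `"elevation"`, `"slope"`, `"aspect"`, `"colour"`,
#'   `"class"`, `"segment"`.
#' @return an object of class `scene_raster`.
#' @export
scene_raster <- function(values, cell_size, origin = c(0, 0),
                         nodata = -9999, band = "elevation") {
  if (!is.matrix(values)) stop("`values` must be a matrix")
  if (nrow(values) < 1 || ncol(values) < 1)
    stop("raster dimensions must be positive")
  if (!is.numeric(cell_size) || length(cell_size) != 1 || cell_size <= 0)
    stop("`cell_size` must be a single positive number")
  band <- match.arg(band,
    c("elevation", "slope", "aspect", "colour", "class", "segment"))
  values[!is.na(values) & values == nodata] <- NA
  structure(
    list(values = values, cell_size = cell_size,
         origin = as.numeric(origin), nodata = nodata, band = band),
    class = "scene_raster")
}

#' @export
print.scene_raster <- function(x, ...) {
  v <- x$values
  cat(sprintf("<scene_raster> %d x %d cells, %.4g m/cell, band: %s\n",
              nrow(v), ncol(v), x$cell_size, x$band))
  ok <- !is.na(v)
  if (any(ok)) {
    cat(sprintf("  valid cells: %d (%.1f%%), range [%.4g, %.4g]\n",
                sum(ok), 100 * mean(ok), min(v[ok]), max(v[ok])))
  } else {
    cat("  all cells nodata\n")
  }
  invisible(x)
}

#' @export
dim.scene_raster <- function(x) dim(x$values)

#' @rdname scene_raster
#' @param x object to test.
#' @export
is_scene_raster <- function(x) inherits(x, "scene_raster")

#' Three-band colour raster (orthomosaic)
#'
#' @param bands list of three matrices (R, G, B) sharing one shape, values
#'   on 0--255.
#' @inheritParams scene_raster
#' @return an object of class `scene_ortho` holding three `scene_raster`
#'   colour bands.
#' @export
scene_ortho <- function(bands, cell_size, origin = c(0, 0)) {
  if (length(bands) != 3) stop("an orthomosaic needs exactly 3 bands")
  d <- dim(bands[[1]])
  for (b in bands) if (!identical(dim(b), d)) stop("band shapes differ")
  structure(
    list(bands = lapply(bands, scene_raster, cell_size = cell_size,
                        origin = origin, band = "colour"),
         cell_size = cell_size, origin = as.numeric(origin)),
    class = "scene_ortho")
}

#' @export
print.scene_ortho <- function(x, ...) {
  d <- dim(x$bands[[1]]$values)
  cat(sprintf("<scene_ortho> %d x %d cells, 3 bands, %.4g m/cell\n",
              d[1], d[2], x$cell_size))
  invisible(x)
}

check_same_geometry <- function(a, b) {
  if (!identical(dim(a$values), dim(b$values)))
    stop("rasters are not co-registered: shapes differ")
  if (abs(a$cell_size - b$cell_size) > 1e-12)
    stop("rasters are not co-registered: cell sizes differ")
  invisible(TRUE)
}

#' Write / read a raster as an ESRI ASCII grid
#'
#' Plain-text interchange for single-band rasters (the `.asc` format read by
#' standard GIS tools). Aspect rasters follow the ArcGIS convention on
#' export: flat (nodata) aspect cells are written as -1.
#'
#' @param x a [scene_raster].
#' @param path file path to write to / read from.
#' @param band band meaning to assign on read (see [scene_raster]).
#' @return `write_esri_ascii` returns `path` invisibly; `read_esri_ascii`
#'   returns a [scene_raster].
#' @export
write_esri_ascii <- function(x, path) {
  stopifnot(is_scene_raster(x))
  v <- x$values
  nd <- if (x$band == "aspect") -1 else x$nodata
  v[is.na(v)] <- nd
  yll <- x$origin[2] - nrow(v) * x$cell_size
  hdr <- c(
    sprintf("ncols %d", ncol(v)),
    sprintf("nrows %d", nrow(v)),
    sprintf("xllcorner %.10g", x$origin[1]),
    sprintf("yllcorner %.10g", yll),
    sprintf("cellsize %.10g", x$cell_size),
    sprintf("NODATA_value %.10g", nd))
  body <- apply(v, 1, function(r) paste(format(r, trim = TRUE,
                                               scientific = FALSE),
                                        collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' @rdname write_esri_ascii
#' @export
read_esri_ascii <- function(path, band = "elevation") {
  ln <- readLines(path)
  hdr <- ln[1:6]
  kv <- do.call(rbind, strsplit(trimws(hdr), "\\s+"))
  key <- tolower(kv[, 1]); val <- as.numeric(kv[, 2])
  names(val) <- key
  ncols <- as.integer(val[["ncols"]]); nrows <- as.integer(val[["nrows"]])
  cs <- val[["cellsize"]]; nd <- val[["nodata_value"]]
  body <- strsplit(trimws(ln[-(1:6)]), "\\s+")
  v <- t(vapply(body, function(r) as.numeric(r), numeric(ncols)))
  if (nrow(v) != nrows) stop("row count does not match header")
  origin <- c(val[["xllcorner"]], val[["yllcorner"]] + nrows * cs)
  scene_raster(v, cs, origin = origin, nodata = nd, band = band)
}

#' Write / read a facies legend as sidecar JSON
#'
#' Maps integer class codes in a categorical raster to facies names.
#'
#' @param legend named integer vector, e.g. `c(LCF = 1, DCF = 2, ...)`.
#' @param path JSON file path.
#' @return `read_facies_legend` returns the named integer vector.
#' @export
write_facies_legend <- function(legend, path) {
  jsonlite::write_json(as.list(legend), path, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_facies_legend
#' @export
read_facies_legend <- function(path) {
  l <- jsonlite::read_json(path, simplifyVector = TRUE)
  unlist(l)
}
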