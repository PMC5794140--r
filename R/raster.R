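#' Lightweight in-memory raster
#'
#' A `sep_raster` is a numeric matrix plus grid geometry: the lower-left
#' corner of the grid (`xmin`, `ymin`), a square pixel size in CRS units, and
#' a CRS tag. Row 1 of the matrix is the northernmost row (map orientation).
#' `NA` cells are nodata. Pixel cells are half-open intervals
#' `[xmin + i*pixel, xmin + (i+1)*pixel)` so every location maps to exactly
#' one cell.
#'
#' Distance- and buffer-based operations require a metric CRS (`units = "m"`);
#' passing a degree-unit raster to those stages is an error.
#'
#' @param values numeric or integer matrix (row 1 = top).
#' @param xmin,ymin coordinates of the lower-left grid corner.
#' @param pixel pixel size (> 0) in CRS units.
#' @param crs a CRS tag from [metric_crs()] or [geographic_crs()].
#' @return an object of class `sep_raster`.
#' @examples
#' r <- sep_raster(matrix(1:12, 3, 4), xmin = 0, ymin = 0, pixel = 30)
#' rast_extent(r)
#' @export
sep_raster <- function(values, xmin = 0, ymin = 0, pixel = 30,
                       crs = metric_crs()) {
  if (!is.matrix(values)) stop("`values` must be a matrix")
  if (!is.numeric(pixel) || length(pixel) != 1L || !is.finite(pixel) ||
      pixel <= 0) {
    stop("`pixel` must be a single positive number")
  }
  if (!is.list(crs) || is.null(crs$units)) stop("`crs` must name its units")
  structure(
    list(values = values, xmin = as.numeric(xmin), ymin = as.numeric(ymin),
         pixel = as.numeric(pixel), crs = crs),
    class = "sep_raster"
  )
}

#' CRS tags
#'
#' Minimal CRS descriptors carrying a name and a linear unit. The pipeline
#' only needs to know whether coordinates are in meters (projected) or
#' degrees (geographic); meter units are enforced wherever Euclidean
#' distances or buffers are computed.
#'
#' @param name free-text CRS identifier.
#' @return a list with elements `name` and `units`.
#' @export
metric_crs <- function(name = "local-metric") list(name = name, units = "m")

#' @rdname metric_crs
#' @export
geographic_crs <- function(name = "WGS84") list(name = name, units = "deg")

#' @export
print.sep_raster <- function(x, ...) {
  v <- x$values
  cat(sprintf("sep_raster: %d rows x %d cols, pixel %g %s\n",
              nrow(v), ncol(v), x$pixel, x$crs$units))
  cat(sprintf("  extent: x [%g, %g], y [%g, %g]  (CRS: %s)\n",
              x$xmin, x$xmin + ncol(v) * x$pixel,
              x$ymin, x$ymin + nrow(v) * x$pixel, x$crs$name))
  cat(sprintf("  values: %d nodata, range [%g, %g]\n",
              sum(is.na(v)),
              suppressWarnings(min(v, na.rm = TRUE)),
              suppressWarnings(max(v, na.rm = TRUE))))
  invisible(x)
}

#' Raster geometry accessors
#'
#' @param r a [sep_raster()].
#' @return `rast_extent()` returns `c(xmin, ymin, xmax, ymax)`;
#'   `rast_values()` the value matrix; `rast_dim()` `c(nrow, ncol)`.
#' @export
rast_extent <- function(r) {
  c(xmin = r$xmin, ymin = r$ymin,
    xmax = r$xmin + ncol(r$values) * r$pixel,
    ymax = r$ymin + nrow(r$values) * r$pixel)
}

#' @rdname rast_extent
#' @export
rast_values <- function(r) r$values

#' @rdname rast_extent
#' @param value replacement matrix of identical dimensions.
#' @export
`rast_values<-` <- function(r, value) {
  if (!identical(dim(value), dim(r$values))) stop("dimension mismatch")
  r$values <- value
  r
}

#' @rdname rast_extent
#' @export
rast_dim <- function(r) dim(r$values)

#' Build a raster sharing another raster's grid
#'
#' @param r template [sep_raster()].
#' @param values matrix, or a single value recycled to the template's shape.
#' @export
rast_like <- function(r, values) {
  if (!is.matrix(values)) {
    values <- matrix(values, nrow(r$values), ncol(r$values))
  }
  sep_raster(values, r$xmin, r$ymin, r$pixel, r$crs)
}

#' Map between coordinates and raster cells
#'
#' Uses the half-open cell convention: a point on a cell's lower/left edge
#' belongs to that cell; a point on the grid's upper/right outer edge is
#' outside. Coordinates outside the extent give `NA` row/col.
#'
#' @param r a [sep_raster()].
#' @param x,y coordinate vectors (equal length).
#' @param row,col cell index vectors (row 1 = top).
#' @return `xy_to_rc()` a matrix with columns `row`, `col`;
#'   `rc_to_xy()` a matrix with columns `x`, `y` (cell centers).
#' @export
xy_to_rc <- function(r, x, y) {
  nr <- nrow(r$values); nc <- ncol(r$values)
  jx <- floor((x - r$xmin) / r$pixel)
  jy <- floor((y - r$ymin) / r$pixel)
  bad <- jx < 0 | jx >= nc | jy < 0 | jy >= nr |
    !is.finite(jx) | !is.finite(jy)
  row <- nr - jy
  col <- jx + 1
  row[bad] <- NA_integer_
  col[bad] <- NA_integer_
  cbind(row = as.integer(row), col = as.integer(col))
}

#' @rdname xy_to_rc
#' @export
rc_to_xy <- function(r, row, col) {
  nr <- nrow(r$values)
  cbind(x = r$xmin + (col - 0.5) * r$pixel,
        y = r$ymin + (nr - row + 0.5) * r$pixel)
}

#' Look up raster values at point locations (nearest pixel center)
#'
#' @param r a [sep_raster()].
#' @param x,y coordinate vectors.
#' @return vector of cell values; `NA` outside the extent.
#' @export
rast_lookup <- function(r, x, y) {
  rc <- xy_to_rc(r, x, y)
  out <- rep(r$values[1][NA], length(x))
  ok <- !is.na(rc[, 1])
  out[ok] <- r$values[cbind(rc[ok, 1], rc[ok, 2])]
  out
}

#' Check that rasters share one grid
#'
#' @param ... two or more [sep_raster()] objects.
#' @return `TRUE` invisibly; error on mismatch.
#' @export
assert_aligned <- function(...) {
  rs <- list(...)
  a <- rs[[1]]
  for (b in rs[-1]) {
    same <- identical(dim(a$values), dim(b$values)) &&
      isTRUE(all.equal(c(a$xmin, a$ymin, a$pixel),
                       c(b$xmin, b$ymin, b$pixel))) &&
      identical(a$crs$units, b$crs$units)
    if (!same) stop("rasters are not aligned on one grid")
  }
  invisible(TRUE)
}

#' Require meter units for distance computations
#'
#' @param r a [sep_raster()] or a CRS tag.
#' @export
assert_metric <- function(r) {
  crs <- if (inherits(r, "sep_raster")) r$crs else r
  if (!identical(crs$units, "m")) {
    stop("a metric (meter-unit) CRS is required for distance/buffer ",
         "operations; got units = '", crs$units, "'")
  }
  invisible(TRUE)
}
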