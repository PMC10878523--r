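#' Georeferenced single-band raster
#'
#' Minimal raster container used throughout: a numeric matrix (rows = y from
#' the top, cols = x) plus band name, acquisition month and georeference.
#' Missing observations (clouds, gaps, divide-by-zero pixels) are `NA`; the
#' missing-value mask is therefore always congruent with the values by
#' construction.
#'
#' @param values numeric matrix
#' @param band band or index name, e.g. `"NDVI"`
#' @param date acquisition month as an integer month index (see [ym()])
#' @param origin numeric length-2, map coordinates of the top-left corner
#' @param pixel_size pixel edge length in metres (> 0)
#' @return an object of class `raster_grid`
#' @export
raster_grid <- function(values, band = "value", date = NA_integer_,
                        origin = c(0, 0), pixel_size = 30) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  if (!is.numeric(pixel_size) || length(pixel_size) != 1 || pixel_size <= 0)
    stop("'pixel_size' must be a positive scalar")
  structure(list(values = values, band = as.character(band),
                 date = as.integer(date), origin = as.numeric(origin),
                 pixel_size = as.numeric(pixel_size)),
            class = "raster_grid")
}

#' @method dim raster_grid
#' @export
dim.raster_grid <- function(x) dim(x$values)

#' @method as.matrix raster_grid
#' @export
as.matrix.raster_grid <- function(x, ...) x$values

#' @method print raster_grid
#' @export
print.raster_grid <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<raster_grid> %s  %d x %d @ %gm  date %s  (%d NA)\n",
              x$band, d[1], d[2], x$pixel_size,
              if (is.na(x$date)) "-" else format_ym(x$date),
              sum(is.na(x$values))))
  invisible(x)
}

#' @method plot raster_grid
#' @export
plot.raster_grid <- function(x, ...) {
  z <- t(x$values)[, nrow(x$values):1, drop = FALSE]
  graphics::image(z, main = x$band, asp = nrow(x$values) / ncol(x$values),
                  axes = FALSE, ...)
  invisible(x)
}

#' Area of one pixel in hectares
#' @param x a `raster_grid` or a pixel size in metres
#' @export
pixel_area_ha <- function(x) {
  ps <- if (inherits(x, "raster_grid")) x$pixel_size else x
  ps * ps / 1e4
}

stop_unless_congruent <- function(...) {
  gs <- Filter(Negate(is.null), list(...))
  dims <- lapply(gs, function(g) dim(g$values))
  if (length(unique(dims)) > 1) stop("raster grids have mismatching shapes")
  ps <- vapply(gs, function(g) g$pixel_size, numeric(1))
  if (length(unique(ps)) > 1) stop("raster grids have mismatching pixel sizes")
  invisible(TRUE)
}
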