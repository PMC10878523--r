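#' Write a raster to TIFF with a georeference sidecar
#'
#' TIFF samples are stored on [0, 1] at 32 bits, so values are min-max
#' rescaled on write and restored on read from the sidecar; the validity
#' mask travels as a second page. Band name, date, origin, pixel size and
#' the value range go to a small JSON sidecar next to the image.
#'
#' @param grid a [raster_grid]
#' @param path output path (`.tif`)
#' @return `path`, invisibly
#' @export
write_raster_tiff <- function(grid, path) {
  v <- grid$values
  ok <- is.finite(v)
  vmin <- if (any(ok)) min(v[ok]) else 0
  vmax <- if (any(ok)) max(v[ok]) else 1
  span <- if (vmax > vmin) vmax - vmin else 1
  scaled <- (v - vmin) / span
  scaled[!ok] <- 0
  tiff::writeTIFF(list(scaled, ok + 0), path, bits.per.sample = 32L,
                  reduce = FALSE)
  meta <- list(band = grid$band, date = grid$date, origin = grid$origin,
               pixel_size = grid$pixel_size, vmin = vmin, vmax = vmax)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_raster_tiff
#' @export
read_raster_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  v <- pages[[1]]
  meta_path <- paste0(path, ".json")
  if (!file.exists(meta_path)) return(raster_grid(v))
  m <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  span <- if (m$vmax > m$vmin) m$vmax - m$vmin else 1
  v <- v * span + m$vmin
  if (length(pages) > 1) v[pages[[2]] < 0.5] <- NA_real_
  raster_grid(v, band = m$band,
              date = if (is.null(m$date)) NA_integer_ else m$date,
              origin = m$origin, pixel_size = m$pixel_size)
}

# exterior rings have positive signed area under the clockwise-in-screen
# convention used by pixel_polygon; holes are negative
ring_is_exterior <- function(ring) ring_signed_area(ring) > 0

point_in_ring <- function(pt, ring) {
  x <- ring[, 1]; y <- ring[, 2]; n <- nrow(ring) - 1
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    if ((y[i] > pt[2]) != (y[j] > pt[2]) &&
        pt[1] < (x[j] - x[i]) * (pt[2] - y[i]) / (y[j] - y[i]) + x[i])
      inside <- !inside
    j <- i
  }
  inside
}

event_geojson_geometry <- function(event) {
  scale_ring <- function(ring) {
    lapply(seq_len(nrow(ring)), function(i)
      c(ring[i, 1] * event$pixel_size, -ring[i, 2] * event$pixel_size))
  }
  ext <- Filter(ring_is_exterior, event$polygon)
  holes <- Filter(Negate(ring_is_exterior), event$polygon)
  polys <- lapply(ext, function(e) {
    mine <- Filter(function(h) point_in_ring(colMeans(h[-nrow(h), , drop = FALSE]), e),
                   holes)
    c(list(scale_ring(e)), lapply(mine, scale_ring))
  })
  list(type = "MultiPolygon", coordinates = polys)
}

#' Export an event catalog as GeoJSON and CSV
#'
#' GeoJSON carries exact pixel-boundary polygons (holes preserved) with id,
#' date, area and severity properties; the CSV is the flat event summary.
#'
#' @param events list of `fire_event`
#' @param geojson_path,csv_path output paths (either may be `NULL`)
#' @export
write_event_catalog <- function(events, geojson_path = NULL, csv_path = NULL) {
  if (!is.null(geojson_path)) {
    features <- lapply(events, function(e) list(
      type = "Feature",
      geometry = event_geojson_geometry(e),
      properties = list(id = e$id, date = format_ym(e$fire_ym),
                        area_ha = e$area_ha,
                        mean_max_dnbr = mean(e$max_dnbr, na.rm = TRUE),
                        max_max_dnbr = suppressWarnings(
                          max(e$max_dnbr, na.rm = TRUE)))))
    jsonlite::write_json(list(type = "FeatureCollection", features = features),
                         geojson_path, auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(csv_path)) {
    df <- do.call(rbind, lapply(events, function(e) data.frame(
      id = e$id, date = format_ym(e$fire_ym), ym = e$fire_ym,
      n_pixels = length(e$pixels), area_ha = e$area_ha,
      mean_max_dnbr = mean(e$max_dnbr, na.rm = TRUE))))
    if (is.null(df)) df <- data.frame(id = integer(), date = character(),
                                      ym = integer(), n_pixels = integer(),
                                      area_ha = numeric(),
                                      mean_max_dnbr = numeric())
    write.csv(df, csv_path, row.names = FALSE)
  }
  invisible(NULL)
}

#' Persist / restore a scene truth as JSON
#'
#' @param truth a `scene_truth`
#' @param path JSON path
#' @export
write_truth_json <- function(truth, path) {
  burned <- which(vapply(truth$burn_dates, length, integer(1)) > 0)
  obj <- list(dim = dim(truth$landcover),
              landcover = as.character(truth$landcover),
              zones = as.character(truth$zones),
              catalog = truth$catalog,
              pixel_sets = truth$pixel_sets,
              burned_pixels = burned,
              burn_dates = truth$burn_dates[burned],
              burn_count = as.integer(truth$burn_count),
              pixel_size = truth$config$pixel_size)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_truth_json
#' @param config the `scene_config` the truth was generated under
#' @export
read_truth_json <- function(path, config) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  d <- o$dim
  as_ragged <- function(x) {
    if (is.matrix(x)) lapply(seq_len(nrow(x)), function(i) x[i, ])
    else if (!is.list(x)) as.list(x)
    else x
  }
  o$burn_dates <- as_ragged(o$burn_dates)
  o$pixel_sets <- as_ragged(o$pixel_sets)
  burn_dates <- vector("list", prod(d))
  for (i in seq_along(o$burned_pixels))
    burn_dates[[o$burned_pixels[i]]] <- as.integer(o$burn_dates[[i]])
  scene_truth(
    landcover = matrix(factor(o$landcover, c("forest", "savanna")), d[1], d[2]),
    zones = matrix(factor(o$zones, ZONE_LEVELS), d[1], d[2]),
    catalog = o$catalog,
    pixel_sets = lapply(o$pixel_sets, as.integer),
    burn_dates = burn_dates,
    burn_count = matrix(o$burn_count, d[1], d[2]),
    config = config)
}

# small deterministic polynomial hash for config fingerprints
config_hash <- function(txt) {
  bytes <- as.integer(charToRaw(txt))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}
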