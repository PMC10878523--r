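#' Spectral indices from reflectance bands
#'
#' NDVI = (NIR - Red) / (NIR + Red); NBR = (NIR - SWIR2) / (NIR + SWIR2).
#' Output pixels are masked (`NA`) wherever any input band is masked or the
#' denominator is zero; division-by-zero pixels are masked rather than
#' clamped, so downstream statistics never see fabricated extremes.
#'
#' @param red,nir,swir2 congruent [raster_grid] objects acquired on the same
#'   date. `swir2` is unused for NDVI and `red` for NBR; pass `NULL` then.
#' @param which `"NDVI"` or `"NBR"`
#' @return a [raster_grid] with values in `[-1, 1]`
#' @export
compute_index <- function(red, nir, swir2 = NULL, which = c("NDVI", "NBR")) {
  which <- match.arg(which)
  a <- nir$values
  b <- if (which == "NDVI") red$values else swir2$values
  if (which == "NDVI") stop_unless_congruent(red, nir) else
    stop_unless_congruent(nir, swir2)
  den <- a + b
  out <- (a - b) / den
  out[!is.na(den) & den == 0] <- NA_real_
  raster_grid(out, band = which, date = nir$date,
              origin = nir$origin, pixel_size = nir$pixel_size)
}

#' Monthly median composite
#'
#' Per-pixel median over all unmasked observations acquired in the requested
#' month; a pixel with no unmasked observation stays masked. This is the
#' standard gap-handling composite for cloudy optical archives.
#'
#' @param stack list of congruent [raster_grid] objects
#' @param month integer month index ([ym()]); default: composite everything
#' @return a [raster_grid] dated at `month`
#' @export
monthly_median_composite <- function(stack, month = NULL) {
  if (length(stack) == 0) stop("empty stack")
  do.call(stop_unless_congruent, stack)
  if (!is.null(month)) {
    stack <- Filter(function(g) !is.na(g$date) && g$date == month, stack)
    if (length(stack) == 0) stop("no observations in requested month")
  }
  arr <- vapply(stack, function(g) g$values, stack[[1]]$values)
  dim(arr) <- c(dim(stack[[1]]$values), length(stack))
  out <- apply(arr, c(1, 2), function(v) {
    v <- v[!is.na(v)]
    if (length(v) == 0) NA_real_ else median(v)
  })
  g1 <- stack[[1]]
  raster_grid(out, band = g1$band,
              date = if (is.null(month)) g1$date else as.integer(month),
              origin = g1$origin, pixel_size = g1$pixel_size)
}

#' Differenced normalized burn ratio
#'
#' dNBR = NBR(pre) - NBR(post). Positive values indicate burn-driven
#' vegetation loss; regrowth gives negative values and is never a fire
#' signal. Masked wherever either input is masked.
#'
#' @param nbr_pre,nbr_post congruent NBR [raster_grid]s, pre date < post date
#' @return a [raster_grid] named `"dNBR"`, dated at the post image
#' @export
dnbr <- function(nbr_pre, nbr_post) {
  stop_unless_congruent(nbr_pre, nbr_post)
  if (!is.na(nbr_pre$date) && !is.na(nbr_post$date) &&
      nbr_pre$date >= nbr_post$date)
    stop("pre-fire image must precede post-fire image")
  raster_grid(nbr_pre$values - nbr_post$values, band = "dNBR",
              date = nbr_post$date, origin = nbr_post$origin,
              pixel_size = nbr_post$pixel_size)
}

#' Per-pixel maximum dNBR over an event's fire month
#'
#' Burn severity for one fire event: for each pixel of the event, the maximum
#' dNBR over all (unmasked) observations dated in the event month. Pixels
#' with no unmasked observation return `NA`.
#'
#' @param event a `fire_event` (see [group_to_polygons()])
#' @param dnbr_stack list of dNBR [raster_grid]s covering the event month
#' @return numeric vector of max dNBR aligned with `event$pixels`
#' @export
max_severity <- function(event, dnbr_stack) {
  in_month <- Filter(function(g) !is.na(g$date) && g$date == event$fire_ym,
                     dnbr_stack)
  if (length(in_month) == 0) stop("event month not covered by dNBR stack")
  vals <- vapply(in_month, function(g) g$values[event$pixels],
                 numeric(length(event$pixels)))
  vals <- matrix(vals, nrow = length(event$pixels))
  apply(vals, 1, function(v) if (all(is.na(v))) NA_real_ else max(v, na.rm = TRUE))
}
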