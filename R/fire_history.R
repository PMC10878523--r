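#' Accumulate fire events into per-pixel history layers
#'
#' Chronological accumulation of a dated event catalog into per-pixel burn
#' counts, ordered burn dates, per-pixel maximum dNBR across events, and the
#' per-burn severity records used for severity-by-burn-count summaries.
#' Pixels outside the forest mask carry no history.
#'
#' @param events list of `fire_event`
#' @param forest_mask logical matrix (the forest base map)
#' @param pixel_size pixel edge (m); defaults to the events' pixel size
#' @return a `fire_history`
#' @export
accumulate_history <- function(events, forest_mask,
                               pixel_size = if (length(events) > 0)
                                 events[[1]]$pixel_size else 30) {
  nr <- nrow(forest_mask); nc <- ncol(forest_mask)
  burn_count <- matrix(0L, nr, nc)
  max_dnbr <- matrix(NA_real_, nr, nc)
  burn_dates <- vector("list", nr * nc)
  severity <- NULL
  if (length(events) > 0) {
    events <- events[order(vapply(events, `[[`, integer(1), "fire_ym"))]
    for (e in events) {
      px <- e$pixels[forest_mask[e$pixels]]
      if (length(px) == 0) next
      sel <- match(px, e$pixels)
      last <- vapply(burn_dates[px], function(d)
        if (length(d) == 0) -Inf else max(d), numeric(1))
      if (any(last >= e$fire_ym))
        stop("per-pixel burn dates must be strictly increasing")
      burn_count[px] <- burn_count[px] + 1L
      for (i in seq_along(px))
        burn_dates[[px[i]]] <- c(burn_dates[[px[i]]], e$fire_ym)
      mx <- e$max_dnbr[sel]
      cur <- max_dnbr[px]
      max_dnbr[px] <- pmax(cur, mx, na.rm = TRUE)
      max_dnbr[px][is.na(cur) & is.na(mx)] <- NA_real_
      severity <- rbind(severity, data.frame(
        pixel = px, event = e$id, event_ym = e$fire_ym,
        burn_number = burn_count[px], max_dnbr = mx))
    }
  }
  structure(list(burn_count = burn_count, burn_dates = burn_dates,
                 max_dnbr = max_dnbr, severity = severity,
                 forest_mask = forest_mask, pixel_size = pixel_size),
            class = "fire_history")
}

#' @method print fire_history
#' @export
print.fire_history <- function(x, ...) {
  pa <- pixel_area_ha(x$pixel_size)
  cat(sprintf("<fire_history> %d x %d, burned %.1f ha of %.1f ha forest, up to %d burns\n",
              nrow(x$burn_count), ncol(x$burn_count),
              sum(x$burn_count > 0 & x$forest_mask) * pa,
              sum(x$forest_mask) * pa, max(x$burn_count)))
  invisible(x)
}

#' Months since the last fire
#'
#' @param history a `fire_history`
#' @param reference_ym reference month index; must not precede any burn date
#' @return integer matrix of months elapsed since the last burn; never-burned
#'   pixels are `NA` (the "never" sentinel, deliberately distinct from 0)
#' @export
time_since_fire <- function(history, reference_ym) {
  last <- vapply(history$burn_dates, function(d)
    if (length(d) == 0) NA_integer_ else max(d), integer(1))
  if (any(last > reference_ym, na.rm = TRUE))
    stop("reference date precedes a recorded burn")
  matrix(as.integer(reference_ym) - last, nrow(history$burn_count),
         ncol(history$burn_count))
}

#' Landscape and per-event burn summaries
#'
#' Landscape table: area and fraction of the forest mask in each final
#' burn-count class (class 0 included, so class areas sum exactly to the
#' forest area). Event table: area, previously-burned area and fraction, and
#' the breakdown of each event's pixels by prior burn count. Severity table:
#' per-pixel max dNBR of the burn that gave the pixel each count (not the
#' lifetime maximum).
#'
#' @param history a `fire_history`
#' @param events the event list the history was accumulated from
#' @return list of data.frames `landscape`, `events`, `severity`
#' @export
burn_summary <- function(history, events) {
  pa <- pixel_area_ha(history$pixel_size)
  fm <- history$forest_mask
  counts <- history$burn_count[fm]
  kmax <- max(counts, 0)
  landscape <- data.frame(burn_count = 0:kmax,
                          area_ha = vapply(0:kmax, function(k)
                            sum(counts == k) * pa, numeric(1)))
  landscape$fraction <- landscape$area_ha / (sum(fm) * pa)

  ev <- NULL
  if (length(events) > 0) {
    events <- events[order(vapply(events, `[[`, integer(1), "fire_ym"))]
    sev <- history$severity
    for (e in events) {
      px <- e$pixels[fm[e$pixels]]
      rec <- sev[sev$event == e$id, , drop = FALSE]
      prior <- rec$burn_number - 1L
      ev <- rbind(ev, data.frame(
        event = e$id, ym = e$fire_ym, date = format_ym(e$fire_ym),
        area_ha = length(px) * pa,
        prev_burned_ha = sum(prior > 0) * pa,
        frac_prev_burned = if (length(px) > 0) mean(prior > 0) else 0,
        max_prior_burns = if (length(prior) > 0) max(prior) else 0L))
    }
  }
  severity <- NULL
  if (!is.null(history$severity)) {
    s <- history$severity
    severity <- do.call(rbind, lapply(sort(unique(s$burn_number)), function(k) {
      v <- s$max_dnbr[s$burn_number == k]
      data.frame(burn_number = k, n_pixels = length(v),
                 mean_max_dnbr = mean(v, na.rm = TRUE),
                 median_max_dnbr = median(v, na.rm = TRUE))
    }))
  }
  list(landscape = landscape, events = ev, severity = severity)
}

#' @method summary fire_history
#' @export
summary.fire_history <- function(object, events = list(), ...) {
  burn_summary(object, events)
}

#' Fraction of re-burned area whose previous burn falls in a lag window
#'
#' Over all (pixel, burn) pairs with burn number >= 2, the lag to the
#' pixel's previous burn is computed; returns the fraction of those pairs
#' with lag inside `[min_lag, max_lag]` months (e.g. 12-60 for "one to five
#' years prior").
#'
#' @param history a `fire_history`
#' @param min_lag,max_lag window bounds in months (inclusive)
#' @export
reburn_fraction <- function(history, min_lag = 12, max_lag = 60) {
  lags <- unlist(lapply(history$burn_dates, function(d)
    if (length(d) >= 2) diff(d) else numeric(0)))
  if (length(lags) == 0) return(NA_real_)
  mean(lags >= min_lag & lags <= max_lag)
}
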