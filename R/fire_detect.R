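#' Gap-aware monthly dNBR series
#'
#' dNBR at month t is the last valid NBR observation before t minus NBR at
#' t, so a single missing composite does not erase the burn spike — the
#' pre-fire reference simply reaches further back, mirroring how pre/post
#' image pairs are chosen around cloud gaps.
#'
#' @param nbr_values NBR values per month (NA = gap)
#' @param dates month indices
#' @param location optional `c(row, col)`
#' @return a [pixel_series()] named `"dNBR"` (first month is always NA)
#' @export
dnbr_series <- function(nbr_values, dates, location = NULL) {
  n <- length(nbr_values)
  out <- rep(NA_real_, n)
  prev <- NA_real_
  for (t in seq_len(n)) {
    if (!is.na(prev) && !is.na(nbr_values[t])) out[t] <- prev - nbr_values[t]
    if (!is.na(nbr_values[t])) prev <- nbr_values[t]
  }
  series <- pixel_series(dates, pmin(pmax(out, -2), 2) / 2, location, "dNBR")
  series$values <- out  # dNBR spans [-2, 2]; bypass the index-range check
  series
}

#' The fire rule: negative trend break matched with a dNBR spike
#'
#' A pixel is a fire candidate if and only if it has a negative break in its
#' NDVI trend and the maximum dNBR within the 95% confidence interval of the
#' break date reaches the threshold (0.2 by default). The fire month is the
#' month of that maximum (earliest on ties).
#'
#' @param brk a `trend_break` with its confidence interval attached
#'   (see [break_confidence_interval()])
#' @param dnbr_series a dNBR [pixel_series()] covering the CI
#' @param threshold minimum dNBR regarded as a burn signal
#' @return a `fire_candidate` or `NULL`
#' @export
match_break_with_dnbr <- function(brk, dnbr_series, threshold = 0.2) {
  if (is.na(brk$ci_lo) || is.na(brk$ci_hi))
    stop("break carries no confidence interval")
  d <- dnbr_series$dates
  if (brk$ci_lo > max(d) || brk$ci_hi < min(d))
    stop("confidence interval outside dNBR series span")
  if (brk$sign >= 0) return(NULL)
  # each dNBR observation measures the change over (previous valid month,
  # this month]; it belongs to the CI when that coverage intersects it, so a
  # spike observed just after a cloud gap at the fire month still counts
  valid <- which(!is.na(dnbr_series$values))
  if (length(valid) == 0) return(NULL)
  cov_start <- d[valid]
  cov_start[-1] <- d[valid[-length(valid)]] + 1L
  win <- valid[cov_start <= brk$ci_hi & d[valid] >= brk$ci_lo]
  if (length(win) == 0) return(NULL)
  v <- dnbr_series$values[win]
  mx <- max(v)
  if (mx < threshold) return(NULL)
  at <- win[which(v == mx)[1]]
  structure(list(location = dnbr_series$location, brk = brk,
                 fire_ym = as.integer(max(brk$ci_lo, min(d[at], brk$ci_hi))),
                 max_dnbr = mx),
            class = "fire_candidate")
}

# gap-aware dNBR for every pixel at once: value matrix [pixel, month] plus
# the column index of the previous valid observation (coverage start - 1)
dnbr_matrix <- function(nbr_mat) {
  nm <- ncol(nbr_mat)
  out <- matrix(NA_real_, nrow(nbr_mat), nm)
  prev_col <- matrix(NA_integer_, nrow(nbr_mat), nm)
  prev <- rep(NA_real_, nrow(nbr_mat))
  prev_at <- rep(NA_integer_, nrow(nbr_mat))
  for (t in seq_len(nm)) {
    cur <- nbr_mat[, t]
    out[, t] <- prev - cur
    prev_col[, t] <- prev_at
    seen <- !is.na(cur)
    prev[seen] <- cur[seen]
    prev_at[seen] <- t
  }
  list(dnbr = out, prev_col = prev_col)
}

#' Scan an archive for per-pixel fire candidates
#'
#' Applies [scan_breaks()] to the NDVI stack and the fire rule to each
#' negative break using the gap-aware dNBR series of the same pixel.
#'
#' @param archive a `scene_archive`
#' @param mask logical matrix restricting the scan (forest base map)
#' @param threshold dNBR burn threshold
#' @param harmonic_order,min_segment_fraction,max_breaks,penalty,level
#'   break-detection parameters, see [fit_season_trend()] / [detect_breaks()]
#' @param breaks optional precomputed break table from [scan_breaks()];
#'   computed from the archive when `NULL`
#' @return data.frame of candidates: pixel, row, col, fire_ym, max_dnbr,
#'   break date and magnitude
#' @export
fire_candidates <- function(archive, mask, threshold = 0.2,
                            harmonic_order = 2, min_segment_fraction = 0.15,
                            max_breaks = 3, penalty = "BIC", level = 0.95,
                            breaks = NULL) {
  nr <- dim(archive$red)[1]; nc <- dim(archive$red)[2]
  brks <- if (!is.null(breaks)) breaks else {
    ndvi <- archive_index(archive, "NDVI")
    scan_breaks(ndvi, archive$dates, mask, harmonic_order,
                min_segment_fraction, max_breaks, penalty, level)
  }
  neg <- brks[brks$magnitude < 0, , drop = FALSE]
  nbr <- archive_index(archive, "NBR")
  dim(nbr) <- c(nr * nc, length(archive$dates))
  dm <- dnbr_matrix(nbr)
  dates <- archive$dates
  out <- vector("list", nrow(neg)); nout <- 0
  for (i in seq_len(nrow(neg))) {
    p <- neg$pixel[i]
    valid <- which(!is.na(dm$dnbr[p, ]))
    if (length(valid) == 0) next
    # coverage of each dNBR observation: (previous valid month, this month]
    cov_start <- dates[dm$prev_col[p, valid]] + 1L
    win <- valid[cov_start <= neg$ci_hi[i] & dates[valid] >= neg$ci_lo[i]]
    if (length(win) == 0) next
    v <- dm$dnbr[p, win]
    mx <- max(v)
    if (mx < threshold) next
    at <- win[which(v == mx)[1]]
    fire_ym <- max(neg$ci_lo[i], min(dates[at], neg$ci_hi[i]))
    nout <- nout + 1
    out[[nout]] <- data.frame(pixel = p, row = neg$row[i],
                              col = neg$col[i],
                              fire_ym = fire_ym, max_dnbr = mx,
                              break_ym = neg$date[i],
                              magnitude = neg$magnitude[i])
  }
  if (nout == 0)
    return(data.frame(pixel = integer(), row = integer(), col = integer(),
                      fire_ym = integer(), max_dnbr = numeric(),
                      break_ym = integer(), magnitude = numeric()))
  do.call(rbind, out[seq_len(nout)])
}

#' A dated burn polygon
#'
#' @param id event id
#' @param fire_ym fire month index
#' @param pixels linear pixel indices (column-major)
#' @param dim grid dimensions `c(nrow, ncol)`
#' @param pixel_size pixel edge (m)
#' @param max_dnbr per-pixel max dNBR aligned with `pixels`
#' @param provenance per-pixel `"rule"` or `"refined"`
#' @return a `fire_event`; its polygon rings cover exactly the pixel set
#' @export
fire_event <- function(id, fire_ym, pixels, dim, pixel_size,
                       max_dnbr = rep(NA_real_, length(pixels)),
                       provenance = rep("rule", length(pixels))) {
  pixels <- as.integer(pixels)
  o <- order(pixels)
  structure(list(id = id, fire_ym = as.integer(fire_ym), pixels = pixels[o],
                 dim = dim, pixel_size = pixel_size,
                 area_ha = length(pixels) * pixel_area_ha(pixel_size),
                 max_dnbr = max_dnbr[o], provenance = provenance[o],
                 polygon = pixel_polygon(pixels, dim)),
            class = "fire_event")
}

#' @method print fire_event
#' @export
print.fire_event <- function(x, ...) {
  cat(sprintf("<fire_event> #%s  %s  %.2f ha (%d px, %d ring(s))\n",
              x$id, format_ym(x$fire_ym), x$area_ha, length(x$pixels),
              length(x$polygon)))
  invisible(x)
}

#' Trace the exact boundary rings of a pixel set
#'
#' Edge-cancellation polygonization: every pixel contributes its four
#' directed boundary edges, internal edges cancel, and the remaining edges
#' chain into closed rings (holes included). The signed ring areas sum to
#' the pixel count exactly.
#'
#' @param pixels linear pixel indices
#' @param dim grid dimensions
#' @return list of closed rings, each an (x, y) matrix in pixel units
#'   (y increases downward, matching row order)
#' @export
pixel_polygon <- function(pixels, dim) {
  nr <- dim[1]; nc <- dim[2]
  inset <- rep(FALSE, nr * nc); inset[pixels] <- TRUE
  r <- (pixels - 1L) %% nr + 1L; c_ <- (pixels - 1L) %/% nr + 1L
  vid <- function(x, y) y * (nc + 1L) + x  # lattice corner id
  has <- function(rr, cc) rr >= 1 & rr <= nr & cc >= 1 & cc <= nc &
    inset[pmax(1L, (cc - 1L) * nr + rr)]
  up <- !has(r - 1L, c_); dn <- !has(r + 1L, c_)
  lf <- !has(r, c_ - 1L); rt <- !has(r, c_ + 1L)
  # clockwise in (x, y-down): keeps the filled cell on the right throughout
  from <- c(vid(c_ - 1L, r - 1L)[up], vid(c_, r)[dn],
            vid(c_ - 1L, r)[lf], vid(c_, r - 1L)[rt])
  to <- c(vid(c_, r - 1L)[up], vid(c_ - 1L, r)[dn],
          vid(c_ - 1L, r - 1L)[lf], vid(c_, r)[rt])
  used <- rep(FALSE, length(from))
  out_edges <- split(seq_along(from), from)
  rings <- list()
  for (e0 in seq_along(from)) {
    if (used[e0]) next
    ring <- integer(0)
    e <- e0
    repeat {
      used[e] <- TRUE
      ring <- c(ring, from[e])
      nxt <- out_edges[[as.character(to[e])]]
      nxt <- nxt[!used[nxt]]
      if (length(nxt) == 0) break
      e <- nxt[1]
    }
    ring <- c(ring, to[e])
    x <- ring %% (nc + 1L); y <- ring %/% (nc + 1L)
    rings[[length(rings) + 1]] <- cbind(x = x, y = y)
  }
  rings
}

ring_signed_area <- function(ring) {
  x <- ring[, 1]; y <- ring[, 2]
  n <- nrow(ring)
  sum(x[-n] * y[-1] - x[-1] * y[-n]) / 2
}

#' Group fire candidates into dated event polygons
#'
#' Candidates are binned by fire month and connected pixels (rook adjacency
#' by default) form one event per component. Components in adjacent months
#' that touch or overlap are merged into a single event — a cloud gap at the
#' fire month shifts a minority of pixels to the following composite, and
#' such fragments belong to the same probable fire period. The event month
#' is the candidate-weighted modal month (earliest on ties).
#'
#' @param candidates data.frame from [fire_candidates()]
#' @param dim grid dimensions
#' @param pixel_size pixel edge (m)
#' @param connectivity 4 (rook) or 8 (queen)
#' @param merge_adjacent_months merge touching components one month apart
#' @return list of `fire_event` (pre-filter)
#' @export
group_to_polygons <- function(candidates, dim, pixel_size, connectivity = 4,
                              merge_adjacent_months = TRUE) {
  if (nrow(candidates) == 0) return(list())
  nr <- dim[1]; nc <- dim[2]
  comps <- list()
  for (m in sort(unique(candidates$fire_ym))) {
    px <- candidates$pixel[candidates$fire_ym == m]
    mask <- matrix(FALSE, nr, nc); mask[px] <- TRUE
    lab <- .label_components_cpp(mask, as.integer(connectivity))
    for (l in seq_len(max(lab))) {
      comps[[length(comps) + 1]] <- list(ym = m, pixels = which(lab == l))
    }
  }
  k <- length(comps)
  parent <- seq_len(k)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  if (merge_adjacent_months && k > 1) {
    halo <- lapply(comps, function(cp) {
      px <- cp$pixels
      r <- (px - 1L) %% nr + 1L; c_ <- (px - 1L) %/% nr + 1L
      unique(c(px, px[r > 1] - 1L, px[r < nr] + 1L,
               px[c_ > 1] - nr, px[c_ < nc] + nr))
    })
    for (i in seq_len(k - 1)) for (j in (i + 1):k) {
      if (abs(comps[[i]]$ym - comps[[j]]$ym) != 1) next
      if (length(intersect(halo[[i]], comps[[j]]$pixels)) > 0) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[rj] <- ri
      }
    }
  }
  roots <- vapply(seq_len(k), find, integer(1))
  events <- list()
  for (g in unique(roots)) {
    members <- comps[roots == g]
    px <- sort(unique(unlist(lapply(members, `[[`, "pixels"))))
    wt <- vapply(members, function(m) length(m$pixels), integer(1))
    yms <- vapply(members, `[[`, integer(1), "ym")
    agg <- tapply(wt, yms, sum)
    fire_ym <- as.integer(names(agg))[order(-agg, as.integer(names(agg)))][1]
    mx <- vapply(px, function(p) {
      v <- candidates$max_dnbr[candidates$pixel == p]
      if (length(v) == 0) NA_real_ else max(v)
    }, numeric(1))
    events[[length(events) + 1]] <-
      fire_event(length(events) + 1L, fire_ym, px, dim, pixel_size, mx)
  }
  events <- events[order(vapply(events, `[[`, integer(1), "fire_ym"))]
  for (i in seq_along(events)) events[[i]]$id <- i
  events
}

#' Minimum-mapping-unit filter
#'
#' Removes events whose area is below the minimum mapping unit (5 ha by
#' default: 55 pixels at 30 m are removed, 56 retained).
#'
#' @param events list of `fire_event`
#' @param min_area_ha minimum area in hectares
#' @export
filter_min_area <- function(events, min_area_ha = 5) {
  Filter(function(e) e$area_ha >= min_area_ha, events)
}

#' Refine an event perimeter by object-based classification
#'
#' The differenced NDVI image bracketing the fire month is segmented with
#' SLIC; segments dominated by candidate pixels train the burn class and
#' segments free of candidates train the non-burn class; the classifier
#' relabels every segment and the refined pixel set is the connected burn
#' region that intersects the original candidates. If the candidate core
#' shows no vegetation-loss contrast against the background (below
#' `min_contrast` in differenced NDVI), the event is dropped — the automated
#' stand-in for manual confirmation against high-resolution imagery.
#'
#' @param event a `fire_event`
#' @param ndvi_pre,ndvi_post NDVI [raster_grid]s bracketing the fire month
#' @param n_segments,compactness SLIC parameters; segments default to about
#'   16 pixels so the refined perimeter can follow the burn boundary closely
#' @param min_contrast minimum dNDVI separation between candidate core and
#'   background for the event to be confirmed
#' @param core_fraction candidate fraction above which a segment trains the
#'   burn class
#' @param seed classifier seed
#' @return the refined `fire_event`, or `NULL` when the event is dropped
#' @export
refine_perimeter <- function(event, ndvi_pre, ndvi_post, n_segments = NULL,
                             compactness = 0.2, min_contrast = 0.1,
                             core_fraction = 0.5, seed = 1) {
  stop_unless_congruent(ndvi_pre, ndvi_post)
  dndvi <- ndvi_pre$values - ndvi_post$values
  if (is.null(n_segments)) n_segments <- max(4L, ceiling(length(dndvi) / 16))
  segs <- slic_segment(dndvi, n_segments, compactness)
  lv <- as.vector(segs$labels)
  incand <- rep(FALSE, length(lv)); incand[event$pixels] <- TRUE
  ids <- segs$features$segment
  frac <- vapply(ids, function(i) mean(incand[lv == i]), numeric(1))
  core <- ids[frac >= core_fraction]
  bg <- ids[frac == 0]
  if (length(core) == 0 || length(bg) == 0) return(NULL)
  mean_d <- segs$features$mean_b1
  contrast <- mean(mean_d[match(core, ids)]) - mean(mean_d[match(bg, ids)])
  if (!is.finite(contrast) || contrast < min_contrast) return(NULL)
  # balance the classes: a background sample a few times the burn-core size
  # keeps the decision boundary between the classes instead of letting the
  # vast background majority push it into the faint-burn range
  if (length(bg) > 3 * length(core))
    bg <- with_seed(seed + 1L, sample(bg, 3 * length(core)))
  labels <- data.frame(segment = c(core, bg),
                       class = rep(c("burn", "nonburn"),
                                   c(length(core), length(bg))))
  cls <- train_and_classify(segs, labels, seed = seed)
  # a segment is burn-like if the classifier says so or if its own mean
  # vegetation loss clears the confirmation contrast
  burn_ids <- ids[cls$segment_class == "burn" | mean_d >= min_contrast]
  burn <- matrix(segs$labels %in% burn_ids, nrow(dndvi), ncol(dndvi))
  if (!any(burn)) return(NULL)
  comp <- .label_components_cpp(burn, 4L)
  keep_comps <- unique(comp[event$pixels])
  keep_comps <- keep_comps[keep_comps > 0]
  if (length(keep_comps) == 0) return(NULL)
  seg_px <- which(matrix(comp %in% keep_comps, nrow(dndvi), ncol(dndvi)))
  # segments propose extent, pixels confirm: a segment-added pixel must
  # itself show vegetation loss, so mixed boundary segments cannot leak
  # unburned ground into the perimeter. Rule-detected pixels stay: a trend
  # break corroborated by dNBR is stronger evidence than one noisy
  # differenced composite
  seg_px <- seg_px[!is.na(dndvi[seg_px]) & dndvi[seg_px] >= min_contrast]
  px <- sort(union(seg_px, event$pixels))
  old <- match(px, event$pixels)
  fire_event(event$id, event$fire_ym, px, event$dim, event$pixel_size,
             max_dnbr = ifelse(is.na(old), NA_real_, event$max_dnbr[old]),
             provenance = ifelse(is.na(old), "refined", "rule"))
}

# union events that overlap (or touch via shared pixels) within one month of
# each other — refinement can expand two fragments of one burn until they
# collide, and one location cannot burn twice in the same fire period
merge_overlapping_events <- function(events, month_tol = 1) {
  k <- length(events)
  if (k <= 1) return(events)
  parent <- seq_len(k)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    if (abs(events[[i]]$fire_ym - events[[j]]$fire_ym) > month_tol) next
    if (length(intersect(events[[i]]$pixels, events[[j]]$pixels)) == 0) next
    ri <- find(i); rj <- find(j)
    if (ri != rj) parent[rj] <- ri
  }
  roots <- vapply(seq_len(k), find, integer(1))
  out <- list()
  for (g in unique(roots)) {
    members <- events[roots == g]
    if (length(members) == 1) { out[[length(out) + 1]] <- members[[1]]; next }
    sizes <- vapply(members, function(e) length(e$pixels), integer(1))
    px <- sort(unique(unlist(lapply(members, `[[`, "pixels"))))
    mx <- rep(NA_real_, length(px)); prov <- rep("refined", length(px))
    for (e in members) {
      at <- match(e$pixels, px)
      mx[at] <- pmax(mx[at], e$max_dnbr, na.rm = TRUE)
      prov[at][e$provenance == "rule"] <- "rule"
    }
    m0 <- members[[which.max(sizes)]]
    out[[length(out) + 1]] <- fire_event(m0$id, m0$fire_ym, px, m0$dim,
                                         m0$pixel_size, mx, prov)
  }
  out <- out[order(vapply(out, `[[`, integer(1), "fire_ym"))]
  for (i in seq_along(out)) out[[i]]$id <- i
  out
}

#' End-to-end fire detection on an archive
#'
#' Runs the candidate scan, spatial grouping, minimum-mapping-unit filter
#' and (optionally) perimeter refinement, returning the dated event catalog.
#' Per-pixel max dNBR of refinement-added pixels is recomputed from the
#' dNBR series around the event month.
#'
#' @inheritParams fire_candidates
#' @param min_area_ha minimum mapping unit (applied to the unsupervised map,
#'   not re-applied after refinement)
#' @param connectivity component connectivity (4 or 8)
#' @param refine run perimeter refinement
#' @param refine_args list of extra arguments for [refine_perimeter()]
#' @param candidates optional precomputed candidate table
#' @return list with `events`, `candidates`, `dropped` (event ids rejected
#'   by refinement)
#' @export
detect_fires <- function(archive, mask, threshold = 0.2, min_area_ha = 5,
                         connectivity = 4, harmonic_order = 2,
                         min_segment_fraction = 0.15, max_breaks = 3,
                         penalty = "BIC", level = 0.95, refine = TRUE,
                         refine_args = list(), candidates = NULL) {
  dims <- dim(archive$red)[1:2]
  cand <- if (!is.null(candidates)) candidates else
    fire_candidates(archive, mask, threshold, harmonic_order,
                    min_segment_fraction, max_breaks, penalty, level)
  events <- group_to_polygons(cand, dims, archive$pixel_size, connectivity)
  events <- filter_min_area(events, min_area_ha)
  dropped <- integer(0)
  if (refine && length(events) > 0) {
    ndvi <- archive_index(archive, "NDVI")
    nbr <- archive_index(archive, "NBR")
    dim(nbr) <- c(prod(dims), length(archive$dates))
    dnm <- dnbr_matrix(nbr)$dnbr
    med_slice <- function(idx) {
      idx <- idx[idx >= 1 & idx <= length(archive$dates)]
      apply(ndvi[, , idx, drop = FALSE], c(1, 2), median, na.rm = TRUE)
    }
    refined <- list()
    for (e in events) {
      ti <- match(e$fire_ym, archive$dates)
      # pre image: the same calendar months one year earlier, so the
      # difference cancels seasonality exactly and isolates this fire's
      # marginal NDVI loss (an earlier burn in the previous dry season is
      # already part of the reference level)
      pre_idx <- if (ti > 12) (ti - 12):(ti - 10) else (ti - 3):(ti - 1)
      pre <- raster_grid(med_slice(pre_idx), "NDVI", e$fire_ym - 1L,
                         pixel_size = archive$pixel_size)
      post <- raster_grid(med_slice(ti:(ti + 2)), "NDVI", e$fire_ym,
                          pixel_size = archive$pixel_size)
      r <- do.call(refine_perimeter, c(list(e, pre, post), refine_args))
      if (is.null(r)) { dropped <- c(dropped, e$id); next }
      # severity for refinement-added pixels from the event-month dNBR
      need <- which(is.na(r$max_dnbr))
      if (length(need) > 0) {
        win <- match(e$fire_ym, archive$dates) + (-1:1)
        win <- win[win >= 1 & win <= ncol(dnm)]
        r$max_dnbr[need] <- apply(dnm[r$pixels[need], win, drop = FALSE], 1,
                                  function(v) if (all(is.na(v))) NA_real_
                                  else max(v, na.rm = TRUE))
      }
      refined[[length(refined) + 1]] <- r
    }
    events <- merge_overlapping_events(refined)
  }
  list(events = events, candidates = cand, dropped = dropped)
}
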