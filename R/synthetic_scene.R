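#' Configuration of a synthetic forest/savanna fire scene
#'
#' Bundles every knob of the synthetic-scene generator. The defaults emulate
#' the study system the pipeline was designed for: a few-thousand-hectare
#' semi-deciduous dry-forest / savanna mosaic observed monthly at 30 m for 37
#' years, with a handful of late-dry-season fires in the final decade that
#' abruptly depress NDVI (no subsequent recovery) and spike dNBR, and
#' GEDI-like 25 m lidar footprints whose structure responds to burn history.
#'
#' @param nrow,ncol grid dimensions in pixels
#' @param pixel_size pixel edge in metres (30 = Landsat-class)
#' @param start_year,end_year archive span; one composite per calendar month
#' @param forest_fraction fraction of pixels that are forest at archive start
#' @param patch_scale Gaussian correlation length (pixels) of the land-cover
#'   field; larger gives larger contiguous forest patches
#' @param seasonal per-class NDVI/NBR seasonal parameters (mean, amplitude)
#'   and the calendar month of peak greenness
#' @param noise_sd observation noise sd on the index scale
#' @param missing_prob probability a pixel-month is lost to cloud/gap
#' @param fire_schedule data.frame with columns `year`, `month` (must lie in
#'   the May-October dry season), `area_ha`, and `origin` (0 = place at a
#'   random forest location, k > 0 = seed inside the footprint of scheduled
#'   event k, so later fires overlap earlier burn scars)
#' @param ndvi_drop NDVI level drop at a pixel's first burn
#' @param ndvi_drop_decay multiplier on the drop for each successive burn
#'   (regrowth between fires is zero by default, so the vegetation signal
#'   left to lose shrinks with each burn)
#' @param ndvi_floor lowest NDVI level a burned pixel can reach
#' @param dnbr_mag dNBR spike magnitude at a pixel's first burn
#' @param dnbr_increment added dNBR per prior burn (severity increases with
#'   each successive burn)
#' @param nbr_persist persistent NBR depression after a burn
#' @param nbr_floor lowest persistent NBR level
#' @param max_burns_per_pixel fires avoid ground already burned this many
#'   times, so repeatedly burned cores plateau at the burn-count depth the
#'   regime produces (3 by default) instead of accumulating spectrally
#'   invisible re-burns
#' @param recovery_rate NDVI recovered per month after a fire (0 = none)
#' @param n_footprints number of lidar footprints to simulate over the
#'   whole grid; the default leaves roughly 1,500 after quality, forest and
#'   zone filtering, the analyzed sample size a multi-orbit spaceborne-lidar
#'   campaign yields over a site of this extent
#' @param fp_baseline per-class baselines for PAI (m2/m2), canopy cover
#'   (fraction) and canopy height (m)
#' @param fp_burned_offset structural loss at the first burn, applied to
#'   every burned footprint regardless of count: the initial fire causes a
#'   drastic drop while later fires cause minor additional loss, so group
#'   differences concentrate between never-burned and burned ground
#' @param fp_coef_nfires fixed-effect change per additional fire for
#'   PAI/CC/CH
#' @param fp_coef_months fixed-effect change per month since the last fire
#' @param fp_noise_sd footprint-level residual sd per metric
#' @param fp_zone_sd,fp_season_sd sd of zone and season random intercepts
#' @param fp_years years in which footprints are acquired
#' @param n_orbits number of distinct acquisition orbits
#' @param quality_fail_rate fraction of footprints failing the quality flag
#' @param seed integer random seed governing every stochastic element
#' @return a validated `scene_config` list
#' @export
scene_config <- function(nrow = 100, ncol = 100, pixel_size = 30,
                         start_year = 1985, end_year = 2022,
                         forest_fraction = 0.6, patch_scale = 8,
                         seasonal = list(
                           forest  = c(ndvi_mean = 0.80, ndvi_amp = 0.05,
                                       nbr_mean = 0.55, nbr_amp = 0.03),
                           savanna = c(ndvi_mean = 0.45, ndvi_amp = 0.25,
                                       nbr_mean = 0.25, nbr_amp = 0.10),
                           peak_month = 2),
                         noise_sd = 0.05, missing_prob = 0.10,
                         fire_schedule = default_fire_schedule(),
                         ndvi_drop = 0.35, ndvi_drop_decay = 0.65,
                         ndvi_floor = 0.05,
                         dnbr_mag = 0.45, dnbr_increment = 0.10,
                         nbr_persist = 0.25, nbr_floor = -0.9,
                         max_burns_per_pixel = 3L,
                         recovery_rate = 0,
                         n_footprints = 4000,
                         fp_baseline = list(
                           forest  = c(pai = 3.5, cc = 0.78, ch = 12),
                           savanna = c(pai = 0.8, cc = 0.25, ch = 2)),
                         fp_burned_offset = c(pai = -1.2, cc = -0.30, ch = -4),
                         fp_coef_nfires = c(pai = -0.2, cc = -0.071, ch = -0.114),
                         fp_coef_months = c(pai = 0, cc = 0, ch = -0.041),
                         fp_noise_sd = c(pai = 0.45, cc = 0.05, ch = 0.45),
                         fp_zone_sd = c(pai = 0.08, cc = 0.01, ch = 0.15),
                         fp_season_sd = c(pai = 0.05, cc = 0.008, ch = 0.10),
                         fp_years = NULL, n_orbits = 8,
                         quality_fail_rate = 0.05,
                         seed = 1L) {
  if (nrow <= 0 || ncol <= 0) stop("grid dimensions must be positive")
  if (forest_fraction < 0 || forest_fraction > 1)
    stop("forest_fraction must lie in [0, 1]")
  if (noise_sd < 0 || missing_prob < 0 || missing_prob > 1 ||
      any(fp_noise_sd < 0) || any(fp_zone_sd < 0) || any(fp_season_sd < 0))
    stop("noise parameters must be non-negative (probabilities in [0, 1])")
  if (end_year < start_year) stop("end_year before start_year")
  fs <- fire_schedule
  if (nrow(fs) > 0) {
    if (!all(fs$month %in% DRY_SEASON_MONTHS))
      stop("fires must fall in the May-October dry season")
    if (any(fs$year < start_year | fs$year > end_year))
      stop("fire scheduled outside the archive time span")
    if (any(fs$origin > seq_len(nrow(fs)) - 1))
      stop("fire origin must reference an earlier scheduled event")
  }
  if (is.null(fp_years)) fp_years <- seq(max(start_year, end_year - 2), end_year)
  cfg <- list(nrow = as.integer(nrow), ncol = as.integer(ncol),
              pixel_size = pixel_size, start_year = start_year,
              end_year = end_year, forest_fraction = forest_fraction,
              patch_scale = patch_scale, seasonal = seasonal,
              noise_sd = noise_sd, missing_prob = missing_prob,
              fire_schedule = fs, ndvi_drop = ndvi_drop,
              ndvi_drop_decay = ndvi_drop_decay, ndvi_floor = ndvi_floor,
              dnbr_mag = dnbr_mag, dnbr_increment = dnbr_increment,
              nbr_persist = nbr_persist, nbr_floor = nbr_floor,
              max_burns_per_pixel = as.integer(max_burns_per_pixel),
              recovery_rate = recovery_rate, n_footprints = n_footprints,
              fp_baseline = fp_baseline,
              fp_burned_offset = fp_burned_offset,
              fp_coef_nfires = fp_coef_nfires,
              fp_coef_months = fp_coef_months, fp_noise_sd = fp_noise_sd,
              fp_zone_sd = fp_zone_sd, fp_season_sd = fp_season_sd,
              fp_years = fp_years, n_orbits = as.integer(n_orbits),
              quality_fail_rate = quality_fail_rate, seed = as.integer(seed))
  class(cfg) <- "scene_config"
  cfg
}

#' Default fire schedule of the synthetic benchmark
#'
#' Six late-dry-season fires: two minor events early on, then escalating
#' fires that each overlap the scar of the previous one, so parts of the
#' landscape burn two and three times while the burned area grows rapidly.
#'
#' @return data.frame with columns year, month, area_ha, origin
#' @export
default_fire_schedule <- function() {
  data.frame(year = c(2014, 2014, 2017, 2018, 2019, 2021),
             month = c(9, 10, 9, 10, 9, 10),
             area_ha = c(6, 8, 25, 40, 70, 150),
             origin = c(0, 0, 0, 3, 4, 5))
}

# evaluate a block of code under a derived seed, restoring the RNG state
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed %% .Machine$integer.max)
  force(code)
}

# circular Gaussian smoothing of a matrix via 2-D FFT (torus boundary)
smooth_field <- function(z, sigma) {
  nr <- nrow(z); nc <- ncol(z)
  gr <- exp(-0.5 * (pmin(0:(nr - 1), nr - 0:(nr - 1)) / sigma)^2)
  gc <- exp(-0.5 * (pmin(0:(nc - 1), nc - 0:(nc - 1)) / sigma)^2)
  k <- outer(gr, gc); k <- k / sum(k)
  Re(fft(fft(z) * fft(k), inverse = TRUE)) / length(z)
}

#' Generate the land-cover and management-zone maps
#'
#' Land cover is a thresholded smooth Gaussian random field: forest forms
#' contiguous patches covering exactly the configured fraction of pixels.
#' The zone map is a nested-frame layout with all five management zones
#' (peripheral outermost, then community, buffer, service, core innermost),
#' mirroring a park whose protection level increases toward the interior.
#'
#' @param config a [scene_config()]
#' @return list with factor matrices `landcover` and `zones`
#' @export
generate_landscape <- function(config) {
  stopifnot(inherits(config, "scene_config"))
  nr <- config$nrow; nc <- config$ncol
  lc <- with_seed(config$seed + 1L, {
    z <- smooth_field(matrix(rnorm(nr * nc), nr, nc), config$patch_scale)
    f <- config$forest_fraction
    if (f >= 1) matrix(TRUE, nr, nc)
    else if (f <= 0) matrix(FALSE, nr, nc)
    else {
      thr <- quantile(z, 1 - f, names = FALSE)
      keep <- z > thr
      # resolve quantile ties so the pixel share is exact
      short <- round(f * nr * nc) - sum(keep)
      if (short > 0) {
        at_thr <- which(z == thr | (!keep & z >= thr))
        keep[head(at_thr, short)] <- TRUE
      }
      keep
    }
  })
  landcover <- matrix(factor(ifelse(lc, "forest", "savanna"),
                             levels = c("forest", "savanna")), nr, nc)
  zones <- zone_layout(nr, nc)
  list(landcover = landcover, zones = zones)
}

ZONE_LEVELS <- c("peripheral", "community", "buffer", "service", "core")

# nested frames: outer ring peripheral, innermost core
zone_layout <- function(nr, nc) {
  half <- floor(min(nr, nc) / 2)
  w <- pmax(1, round(half * c(0.20, 0.25, 0.25, 0.15)))
  edges <- cumsum(c(0, w))
  r <- row(matrix(0, nr, nc)); c_ <- col(matrix(0, nr, nc))
  depth <- pmin(r - 1, nr - r, c_ - 1, nc - c_)
  z <- matrix(ZONE_LEVELS[5], nr, nc)
  for (i in 4:1) z[depth < edges[i + 1]] <- ZONE_LEVELS[i]
  matrix(factor(z, levels = ZONE_LEVELS), nr, nc)
}

# grow a connected patch of n_pix pixels inside `allowed`, rook adjacency.
# Random frontier weights give organic shapes; the smoothness bonus favours
# frontier pixels already flanked by the patch, so the perimeter advances as
# a front (fire-like) rather than sprouting one-pixel tendrils.
grow_patch <- function(allowed, seed_px, n_pix, smoothness = 0.35) {
  nr <- nrow(allowed); nc <- ncol(allowed)
  w <- matrix(runif(nr * nc), nr, nc)
  in_patch <- rep(FALSE, nr * nc)
  push <- function(px, frontier) {
    r <- (px - 1L) %% nr + 1L; c_ <- (px - 1L) %/% nr + 1L
    nb <- c(if (r > 1) px - 1L, if (r < nr) px + 1L,
            if (c_ > 1) px - nr, if (c_ < nc) px + nr)
    nb <- nb[allowed[nb] & !in_patch[nb]]
    union(frontier, nb)
  }
  flanked <- function(px) {
    r <- (px - 1L) %% nr + 1L; c_ <- (px - 1L) %/% nr + 1L
    cnt <- numeric(length(px))
    up <- pmax(px - 1L, 1L); cnt <- cnt + (r > 1) * in_patch[up]
    dn <- pmin(px + 1L, nr * nc); cnt <- cnt + (r < nr) * in_patch[dn]
    lf <- pmax(px - nr, 1L); cnt <- cnt + (c_ > 1) * in_patch[lf]
    rt <- pmin(px + nr, nr * nc); cnt <- cnt + (c_ < nc) * in_patch[rt]
    cnt
  }
  if (!allowed[seed_px]) stop("patch seed outside allowed area")
  in_patch[seed_px] <- TRUE
  frontier <- push(seed_px, integer(0))
  while (sum(in_patch) < n_pix) {
    frontier <- frontier[!in_patch[frontier]]
    # a fire hemmed in by unburnable ground stops spreading short of target
    if (length(frontier) == 0) break
    nxt <- frontier[which.min(w[frontier] - smoothness * flanked(frontier))]
    in_patch[nxt] <- TRUE
    frontier <- push(nxt, setdiff(frontier, nxt))
  }
  which(in_patch)
}

seasonal_cycle <- function(months_ym, mean, amp, peak_month) {
  mean + amp * cos(2 * pi * (ym_month(months_ym) - peak_month) / 12)
}

#' Simulate the monthly reflectance archive and its ground truth
#'
#' Builds monthly Red/NIR/SWIR2 reflectance for every pixel so that the
#' derived NDVI and NBR follow the configured seasonal dynamics, injects the
#' scheduled fires (step drop in NDVI with zero recovery by default; a
#' one-month NBR spike whose magnitude grows with each successive burn plus a
#' persistent NBR depression), adds observation noise, and knocks out
#' pixel-months at the configured missing-data rate. The returned
#' `scene_truth` records exactly which pixels burned when — the oracle every
#' downstream test compares against.
#'
#' @param config a [scene_config()]
#' @param landscape output of [generate_landscape()] under the same config
#' @return list with elements `archive` (a `scene_archive`) and `truth`
#'   (a `scene_truth`)
#' @export
simulate_archive <- function(config, landscape) {
  stopifnot(inherits(config, "scene_config"))
  nr <- config$nrow; nc <- config$ncol; npx <- nr * nc
  months <- ym(config$start_year, 1):ym(config$end_year, 12)
  nm <- length(months)
  lc <- landscape$landcover
  forest <- lc == "forest"
  pk <- config$seasonal$peak_month

  season_of_class <- function(cls, what) {
    p <- config$seasonal[[cls]]
    seasonal_cycle(months, p[[paste0(what, "_mean")]],
                   p[[paste0(what, "_amp")]], pk)
  }
  ndvi <- matrix(0, npx, nm); nbr <- matrix(0, npx, nm)
  for (cls in c("forest", "savanna")) {
    idx <- which(as.vector(lc == cls))
    if (length(idx) == 0) next
    ndvi[idx, ] <- rep(season_of_class(cls, "ndvi"), each = length(idx))
    nbr[idx, ] <- rep(season_of_class(cls, "nbr"), each = length(idx))
  }

  fs <- config$fire_schedule
  burn_count <- integer(npx)
  burn_dates <- vector("list", npx)
  pixel_sets <- list(); catalog <- NULL
  if (nrow(fs) > 0) {
    fs <- fs[order(ym(fs$year, fs$month)), , drop = FALSE]
    with_seed(config$seed + 2L, {
      for (e in seq_len(nrow(fs))) {
        n_pix <- max(1L, round(fs$area_ha[e] / pixel_area_ha(config$pixel_size)))
        # fires spread through forest not yet burned out (burn-count cap)
        burnable <- forest & matrix(burn_count < config$max_burns_per_pixel,
                                    nr, nc)
        if (n_pix > sum(burnable))
          stop("target area exceeds available forest")
        seed_px <- if (fs$origin[e] > 0) {
          cand <- intersect(pixel_sets[[fs$origin[e]]], which(as.vector(burnable)))
          if (length(cand) == 0) cand <- which(as.vector(burnable))
          cand[sample.int(length(cand), 1)]
        } else {
          fpx <- which(as.vector(burnable))
          fpx[sample.int(length(fpx), 1)]
        }
        px <- grow_patch(burnable, seed_px, n_pix)
        t_fire <- match(ym(fs$year[e], fs$month[e]), months)
        if (is.na(t_fire)) stop("fire scheduled outside the archive time span")
        # NDVI: step down, smaller with each successive burn, optional linear
        # recovery toward the pre-burn level
        for (p in px) {
          k <- burn_count[p] + 1L
          drop_k <- config$ndvi_drop * config$ndvi_drop_decay^(k - 1)
          lvl <- ndvi[p, t_fire:nm]
          dropped <- pmax(config$ndvi_floor, lvl[1] - drop_k) - lvl[1]
          reco <- pmin(config$recovery_rate * (seq_along(lvl) - 1), -dropped)
          ndvi[p, t_fire:nm] <- lvl + dropped + reco
          # NBR: one-month spike of pulse_k relative to the previous month,
          # then a persistent depression
          pulse_k <- config$dnbr_mag + config$dnbr_increment * (k - 1)
          pre <- nbr[p, t_fire:nm]
          post <- pmax(config$nbr_floor, pre - config$nbr_persist)
          nbr[p, t_fire:nm] <- post
          nbr[p, t_fire] <- nbr[p, max(1, t_fire - 1)] - pulse_k
          burn_count[p] <- k
          burn_dates[[p]] <- c(burn_dates[[p]], months[t_fire])
        }
        pixel_sets[[e]] <- px
        catalog <- rbind(catalog, data.frame(
          event = e, year = fs$year[e], month = fs$month[e],
          ym = ym(fs$year[e], fs$month[e]), n_pixels = length(px),
          area_ha = length(px) * pixel_area_ha(config$pixel_size)))
      }
    })
  }

  with_seed(config$seed + 5L, {
    if (config$noise_sd > 0) {
      ndvi <- ndvi + matrix(rnorm(npx * nm, sd = config$noise_sd), npx, nm)
      nbr <- nbr + matrix(rnorm(npx * nm, sd = config$noise_sd), npx, nm)
    }
    ndvi <- pmin(pmax(ndvi, -0.99), 0.99)
    nbr <- pmin(pmax(nbr, -0.99), 0.99)
    if (config$missing_prob > 0) {
      gone <- matrix(runif(npx * nm) < config$missing_prob, npx, nm)
      ndvi[gone] <- NA_real_; nbr[gone] <- NA_real_
    }
  })

  # reflectance consistent with both indices: fixed NIR, solve Red and SWIR2
  nir_val <- 0.4
  red <- nir_val * (1 - ndvi) / (1 + ndvi)
  swir2 <- nir_val * (1 - nbr) / (1 + nbr)
  nir <- matrix(nir_val, npx, nm); nir[is.na(red)] <- NA_real_

  archive <- structure(list(
    red = array(red, c(nr, nc, nm)), nir = array(nir, c(nr, nc, nm)),
    swir2 = array(swir2, c(nr, nc, nm)), dates = months,
    pixel_size = config$pixel_size, origin = c(0, 0)),
    class = "scene_archive")
  truth <- scene_truth(landcover = lc, zones = landscape$zones,
                       catalog = catalog, pixel_sets = pixel_sets,
                       burn_dates = burn_dates,
                       burn_count = matrix(burn_count, nr, nc),
                       config = config)
  list(archive = archive, truth = truth)
}

#' Ground-truth record of a synthetic scene
#'
#' Validates and packages the generator's fire catalog: every catalogued
#' pixel lies inside the grid, per-pixel burn dates are strictly increasing,
#' and each event's area equals its pixel count times the pixel area.
#'
#' @param landcover,zones factor matrices from [generate_landscape()]
#' @param catalog event table (id, year, month, ym, n_pixels, area_ha)
#' @param pixel_sets list of linear pixel-index vectors, one per event
#' @param burn_dates per-pixel list of burn month indices
#' @param burn_count integer matrix of total burns per pixel
#' @param config the generating [scene_config()]
#' @return a `scene_truth` object
#' @export
scene_truth <- function(landcover, zones, catalog, pixel_sets, burn_dates,
                        burn_count, config) {
  npx <- length(landcover)
  pa <- pixel_area_ha(config$pixel_size)
  if (!is.null(catalog)) {
    for (e in seq_len(nrow(catalog))) {
      px <- pixel_sets[[e]]
      if (any(px < 1 | px > npx)) stop("catalogued fire pixel outside grid")
      if (length(px) != catalog$n_pixels[e] ||
          abs(catalog$area_ha[e] - length(px) * pa) > 1e-9)
        stop("catalog area inconsistent with pixel set")
    }
  }
  bad <- vapply(burn_dates, function(d) length(d) > 1 && any(diff(d) <= 0),
                logical(1))
  if (any(bad)) stop("per-pixel burn dates must be strictly increasing")
  structure(list(landcover = landcover, zones = zones,
                 catalog = catalog, pixel_sets = pixel_sets,
                 burn_dates = burn_dates, burn_count = burn_count,
                 config = config),
            class = "scene_truth")
}

#' @method print scene_truth
#' @export
print.scene_truth <- function(x, ...) {
  cat(sprintf("<scene_truth> %d x %d, %d fire event(s), %.1f ha burned\n",
              nrow(x$landcover), ncol(x$landcover),
              if (is.null(x$catalog)) 0L else nrow(x$catalog),
              sum(x$burn_count > 0) * pixel_area_ha(x$config$pixel_size)))
  invisible(x)
}

#' Extract one month of one band as a raster_grid
#' @param archive a `scene_archive`
#' @param band `"red"`, `"nir"`, `"swir2"`, `"NDVI"` or `"NBR"`
#' @param month integer month index ([ym()])
#' @export
archive_grid <- function(archive, band, month) {
  i <- match(month, archive$dates)
  if (is.na(i)) stop("month outside archive span")
  vals <- if (band %in% c("red", "nir", "swir2")) archive[[band]][, , i]
  else archive_index(archive, band)[, , i]
  raster_grid(vals, band = band, date = month,
              origin = archive$origin, pixel_size = archive$pixel_size)
}

#' Full index stack of an archive as a 3-D array
#' @param archive a `scene_archive`
#' @param which `"NDVI"` or `"NBR"`
#' @export
archive_index <- function(archive, which = c("NDVI", "NBR")) {
  which <- match.arg(which)
  if (which == "NDVI") (archive$nir - archive$red) / (archive$nir + archive$red)
  else (archive$nir - archive$swir2) / (archive$nir + archive$swir2)
}

#' Simulate lidar footprints over a scene
#'
#' Draws GEDI-like 25 m footprints at random grid locations, assigns each to
#' one of a small number of acquisition orbits (each orbit = one acquisition
#' date in the final archive years), and generates plant area index, canopy
#' cover and canopy height as class baseline + fixed effects of burn count
#' and months-since-fire + zone and season random intercepts + noise.
#' Canopy cover is clipped to `[0, 1]`, PAI and height to non-negative.
#'
#' @param config a [scene_config()]
#' @param truth a `scene_truth` for the same scene
#' @param seed RNG seed for the footprint draw (defaults to `config$seed + 3`
#'   so repeated draws over one scene are independent replicates)
#' @return data.frame, one row per footprint, including the true burn
#'   covariates used by the generator
#' @export
simulate_footprints <- function(config, truth, seed = config$seed + 3L) {
  n <- config$n_footprints
  if (n <= 0) stop("zero footprints requested")
  nr <- config$nrow; nc <- config$ncol
  with_seed(seed, {
    px <- sample.int(nr * nc, n, replace = TRUE)
    r <- (px - 1L) %% nr + 1L; c_ <- (px - 1L) %/% nr + 1L
    # distinct calendar months per orbit: acquisition campaigns spread
    # through the year, so both seasons are always observed
    orbit_dates <- ym(sample(config$fp_years, config$n_orbits, replace = TRUE),
                      sample(1:12, config$n_orbits,
                             replace = config$n_orbits > 12))
    orbit <- sample.int(config$n_orbits, n, replace = TRUE)
    date <- orbit_dates[orbit]
    lc <- as.character(truth$landcover[px])
    zone <- as.character(truth$zones[px])
    nfires <- integer(n); msince <- rep(NA_integer_, n)
    for (i in seq_len(n)) {
      d <- truth$burn_dates[[px[i]]]
      d <- d[d <= date[i]]
      nfires[i] <- length(d)
      if (length(d) > 0) msince[i] <- date[i] - max(d)
    }
    zone_off <- lapply(c(pai = "pai", cc = "cc", ch = "ch"), function(m)
      setNames(rnorm(length(ZONE_LEVELS), 0, config$fp_zone_sd[[m]]), ZONE_LEVELS))
    season_off <- lapply(c(pai = "pai", cc = "cc", ch = "ch"), function(m)
      setNames(rnorm(2, 0, config$fp_season_sd[[m]]), c("dry", "wet")))
    seas <- season_of(date)
    metric <- function(m) {
      base <- vapply(lc, function(x) config$fp_baseline[[x]][[m]], numeric(1))
      base + config$fp_burned_offset[[m]] * (nfires >= 1) +
        config$fp_coef_nfires[[m]] * nfires +
        config$fp_coef_months[[m]] * ifelse(is.na(msince), 0, msince) +
        zone_off[[m]][zone] + season_off[[m]][seas] +
        rnorm(n, 0, config$fp_noise_sd[[m]])
    }
    pai <- pmax(0, metric("pai"))
    cc <- pmin(1, pmax(0, metric("cc")))
    ch <- pmax(0, metric("ch"))
    quality_ok <- runif(n) >= config$quality_fail_rate
    data.frame(id = seq_len(n), row = r, col = c_, pixel = px,
               x = (c_ - 0.5) * config$pixel_size,
               y = -(r - 0.5) * config$pixel_size,
               date = date, orbit = orbit, season = seas,
               zone = zone, landcover = lc,
               n_fires_true = nfires, months_since_true = msince,
               pai = unname(pai), cc = unname(cc), ch = unname(ch),
               quality_ok = quality_ok)
  })
}
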