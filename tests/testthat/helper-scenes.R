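# Shared fixtures: small, fast synthetic scenes built in code.
# Heavy fixtures are cached for the session so several test files can share
# one simulation.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# compact 40x40 scene, 14 years, two fires two years apart
small_config <- function(seed = 11, noise_sd = 0.05, missing_prob = 0.1,
                         ...) {
  args <- list(nrow = 40, ncol = 40, start_year = 2008, end_year = 2021,
               forest_fraction = 0.6, noise_sd = noise_sd,
               missing_prob = missing_prob,
               fire_schedule = data.frame(year = c(2015, 2017),
                                          month = c(9, 10),
                                          area_ha = c(10, 20),
                                          origin = c(0, 1)),
               n_footprints = 500, seed = seed)
  args[names(list(...))] <- list(...)
  do.call(scene_config, args)
}

small_scene <- function(...) {
  cfg <- small_config(...)
  landscape <- generate_landscape(cfg)
  sim <- simulate_archive(cfg, landscape)
  list(config = cfg, landscape = landscape,
       archive = sim$archive, truth = sim$truth)
}

# noise-free, gap-free variant (exact-arithmetic oracle runs)
noiseless_scene <- function(...) small_scene(noise_sd = 0, missing_prob = 0, ...)

# monthly sinusoid + optional level steps, as a pixel_series
synthetic_series <- function(n_months = 120, mean = 0.7, amp = 0.1,
                             noise_sd = 0, steps = NULL, start = ym(2000, 1),
                             seed = NULL, missing = integer(0)) {
  if (!is.null(seed)) set.seed(seed)
  dates <- start + 0:(n_months - 1)
  v <- mean + amp * cos(2 * pi * (ym_month(dates) - 2) / 12)
  if (!is.null(steps)) for (i in seq_len(nrow(steps))) {
    at <- steps$at[i]
    v[at:n_months] <- v[at:n_months] + steps$size[i]
  }
  if (noise_sd > 0) v <- v + rnorm(n_months, sd = noise_sd)
  v[missing] <- NA
  pixel_series(dates, pmin(pmax(v, -1), 1))
}

# tiny raster helper
grid_of <- function(values, nr = NULL, band = "value", date = NA_integer_) {
  if (is.matrix(values)) m <- values
  else m <- matrix(values, nr, length(values) / nr)
  raster_grid(m, band = band, date = date)
}
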