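test_that("scene configuration enforces its invariants", {
  expect_error(scene_config(nrow = 0), "positive")
  expect_error(scene_config(forest_fraction = 1.4), "\\[0, 1\\]")
  expect_error(scene_config(noise_sd = -1), "non-negative")
  expect_error(scene_config(
    fire_schedule = data.frame(year = 2015, month = 2, area_ha = 10,
                               origin = 0)), "dry season")
  expect_error(scene_config(
    start_year = 2000, end_year = 2010,
    fire_schedule = data.frame(year = 2015, month = 9, area_ha = 10,
                               origin = 0)), "time span")
})

test_that("landscape generation is seeded, exact and structured", {
  cfg <- small_config()
  a <- generate_landscape(cfg)
  b <- generate_landscape(cfg)
  expect_identical(a, b)   # same seed, same maps

  all_forest <- generate_landscape(small_config(forest_fraction = 1))
  expect_true(all(all_forest$landcover == "forest"))

  cfg7 <- scene_config(nrow = 100, ncol = 100, forest_fraction = 0.7,
                       fire_schedule = data.frame(year = integer(),
                                                  month = integer(),
                                                  area_ha = numeric(),
                                                  origin = integer()))
  share <- mean(generate_landscape(cfg7)$landcover == "forest")
  expect_lt(abs(share - 0.7), 0.05)

  # forest forms patches, not salt-and-pepper: horizontally adjacent pixels
  # agree far more often than under independent assignment
  lc <- a$landcover == "forest"
  agree <- mean(lc[, -1] == lc[, -ncol(lc)])
  p <- mean(lc)
  expect_gt(agree, p^2 + (1 - p)^2 + 0.15)

  expect_setequal(unique(as.character(a$zones)),
                  c("peripheral", "community", "buffer", "service", "core"))
})

test_that("archive simulation honours the fire schedule and its bookkeeping", {
  # empty schedule: no catalog, no trend steps beyond the seasonal cycle
  quiet_cfg <- small_config(noise_sd = 0, missing_prob = 0)
  quiet_cfg$fire_schedule <- quiet_cfg$fire_schedule[0, ]
  quiet <- simulate_archive(quiet_cfg, generate_landscape(quiet_cfg))
  expect_null(quiet$truth$catalog)
  ndvi <- archive_index(quiet$archive, "NDVI")
  rng <- apply(ndvi, c(1, 2), function(v) diff(range(v)))
  amp <- vapply(c(forest = "forest", savanna = "savanna"), function(cl)
    2 * quiet_cfg$seasonal[[cl]][["ndvi_amp"]], numeric(1))
  lc <- as.character(quiet$truth$landcover)
  expect_equal(as.vector(rng), unname(amp[lc]), tolerance = 0.02)

  # 50-ha target: area bookkeeping exact to one pixel
  cfg50 <- small_config()
  cfg50$fire_schedule <- data.frame(year = 2015, month = 9, area_ha = 50,
                                    origin = 0)
  t50 <- simulate_archive(cfg50, generate_landscape(cfg50))$truth
  expect_lt(abs(t50$catalog$n_pixels * 0.09 - 50), 0.09 + 1e-9)
  expect_equal(t50$catalog$area_ha, t50$catalog$n_pixels * 0.09)

  # determinism: identical seeds give bitwise-identical archives
  s1 <- simulate_archive(cfg50, generate_landscape(cfg50))
  expect_identical(s1$archive$red, simulate_archive(
    cfg50, generate_landscape(cfg50))$archive$red)

  expect_error(simulate_archive(
    small_config(fire_schedule = data.frame(year = 2015, month = 9,
                                            area_ha = 5000, origin = 0)),
    generate_landscape(small_config())), "exceeds available forest")
})

test_that("scene truth is a consistent oracle", {
  sc <- cached("noisy_small", small_scene())
  tr <- sc$truth
  # burn counts equal the number of catalog events containing each pixel
  counts <- integer(length(tr$landcover))
  for (px in tr$pixel_sets) counts[px] <- counts[px] + 1L
  expect_identical(as.vector(tr$burn_count), counts)
  # dates strictly increasing by construction
  expect_true(all(vapply(tr$burn_dates, function(d)
    length(d) < 2 || all(diff(d) > 0), logical(1))))
  # every catalogued pixel inside the grid
  expect_true(all(unlist(tr$pixel_sets) >= 1 &
                  unlist(tr$pixel_sets) <= length(tr$landcover)))
})

test_that("burned forest NDVI never rebounds when recovery is off", {
  sc <- cached("noiseless_small", noiseless_scene())
  tr <- sc$truth
  ndvi <- archive_index(sc$archive, "NDVI")
  dim(ndvi) <- c(length(tr$landcover), length(sc$archive$dates))
  drop1 <- sc$config$ndvi_drop
  for (e in seq_len(nrow(tr$catalog))) {
    px <- tr$pixel_sets[[e]]
    ti <- match(tr$catalog$ym[e], sc$archive$dates)
    pre <- rowMeans(ndvi[px, (ti - 12):(ti - 1), drop = FALSE])
    post <- rowMeans(ndvi[px, ti:(ti + 11), drop = FALSE])
    expect_true(all(post <= pre - drop1 * sc$config$ndvi_drop_decay^2 / 2))
  }
})

test_that("footprint generator respects its contracts", {
  sc <- cached("noisy_small", small_scene())
  cfg <- sc$config

  expect_error(simulate_footprints(small_config(n_footprints = 0), sc$truth),
               "zero footprints")

  # degenerate: all effects and noises zero, one metric value per class
  flat <- cfg
  flat$fp_burned_offset[] <- 0; flat$fp_coef_nfires[] <- 0
  flat$fp_coef_months[] <- 0; flat$fp_noise_sd[] <- 0
  flat$fp_zone_sd[] <- 0; flat$fp_season_sd[] <- 0
  fp0 <- simulate_footprints(flat, sc$truth)
  expect_equal(length(unique(fp0$pai[fp0$landcover == "forest"])), 1)
  expect_equal(length(unique(fp0$ch[fp0$landcover == "savanna"])), 1)

  allfail <- cfg; allfail$quality_fail_rate <- 1
  expect_true(all(!simulate_footprints(allfail, sc$truth)$quality_ok))

  # ranges
  fp <- simulate_footprints(cfg, sc$truth)
  expect_true(all(fp$cc >= 0 & fp$cc <= 1))
  expect_true(all(fp$pai >= 0 & fp$ch >= 0))
  expect_true(all(fp$season %in% c("dry", "wet")))

  # same seed reproduces; different seed gives a fresh replicate
  expect_identical(fp, simulate_footprints(cfg, sc$truth))
  expect_false(identical(fp$pai,
                         simulate_footprints(cfg, sc$truth, seed = 999)$pai))
})

test_that("PAI group means decline with burn count at the default effects", {
  big <- cached("bench_scene", {
    cfg <- scene_config(seed = 1)
    landscape <- generate_landscape(cfg)
    sim <- simulate_archive(cfg, landscape)
    list(config = cfg, archive = sim$archive, truth = sim$truth)
  })
  cfg <- big$config; cfg$n_footprints <- 1500
  fp <- simulate_footprints(cfg, big$truth)
  fp <- fp[fp$landcover == "forest" & fp$n_fires_true <= 2, ]
  means <- tapply(fp$pai, fp$n_fires_true, mean)
  expect_true(all(diff(means) < 0))  # unburned > 1 fire > 2 fires
})
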