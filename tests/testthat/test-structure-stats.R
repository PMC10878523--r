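test_that("Kruskal-Wallis H matches the hand-rank formula", {
  kw <- kruskal_wallis(c(1, 2, 3, 4, 5, 6, 7, 8, 9),
                       rep(c("a", "b", "c"), each = 3))
  expect_equal(kw$statistic, 7.2)
  expect_equal(kw$df, 2)

  # label permutation leaves H unchanged
  set.seed(14)
  v <- rnorm(30); g <- sample(3, 30, replace = TRUE)
  relabel <- c("x", "y", "z")[g]
  expect_equal(kruskal_wallis(v, g)$statistic,
               kruskal_wallis(v, relabel)$statistic)

  expect_error(kruskal_wallis(1:5, rep("a", 5)), ">= 2 groups")
})

test_that("H and p agree with stats::kruskal.test on random tables", {
  set.seed(33)
  for (i in 1:15) {
    n <- sample(10:50, 1)
    v <- round(rnorm(n), sample(0:2, 1))  # rounding forces ties
    g <- sample(2:4, 1)
    grp <- sample(g, n, replace = TRUE)
    if (length(unique(grp)) < 2) next
    ours <- kruskal_wallis(v, grp)
    ref <- stats::kruskal.test(v, factor(grp))
    expect_equal(ours$statistic, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(ours$p.value, ref$p.value, tolerance = 1e-10)
    expect_equal(ours$statistic, bf_kruskal(v, grp), tolerance = 1e-10)
  }
})

test_that("Dunn's test follows the pooled-rank formula and Bonferroni", {
  set.seed(41)
  v <- rnorm(40); g <- sample(4, 40, replace = TRUE)
  d <- dunn_posthoc(v, g)
  expect_equal(d$comparisons, 6)   # C(4,2)
  for (i in 1:3) for (j in (i + 1):4) {
    expect_equal(d$z[i, j], unname(bf_dunn_z(v, g, i, j)), tolerance = 1e-10)
    raw <- 2 * pnorm(-abs(d$z[i, j]))
    expect_equal(d$p[i, j], min(1, raw * 6), tolerance = 1e-12)
  }

  # two groups: factor 1, p equals the unadjusted p, and z is the same
  # comparison the two-group H makes
  v2 <- rnorm(20); g2 <- rep(1:2, 10)
  d2 <- dunn_posthoc(v2, g2)
  expect_equal(d2$p[1, 2], 2 * pnorm(-abs(d2$z[1, 2])))
  h2 <- kruskal_wallis(v2, g2)$statistic
  expect_equal(d2$z[1, 2]^2, h2, tolerance = 1e-10)

  # three well-separated groups: all pairwise significant
  sep <- c(rnorm(15), rnorm(15) + 8, rnorm(15) + 16)
  gs <- rep(1:3, each = 15)
  d3 <- dunn_posthoc(sep, gs)
  expect_true(all(d3$p[upper.tri(d3$p)] < 0.05))
})

test_that("footprints are filtered and joined with temporal causality", {
  fm <- matrix(TRUE, 10, 10); fm[, 10] <- FALSE
  zones <- matrix(factor("buffer", levels = ZONE <-
    c("peripheral", "community", "buffer", "service", "core")), 10, 10)
  zones[1, ] <- "peripheral"
  h <- accumulate_history(list(
    fire_event(1, ym(2019, 9), c(22, 23), c(10, 10), 30,
               max_dnbr = c(0.5, 0.5))), fm)
  fp <- data.frame(id = 1:5, row = c(2, 3, 2, 1, 5), col = c(3, 3, 3, 3, 10),
                   date = c(ym(2020, 1), ym(2019, 1), ym(2020, 1),
                            ym(2020, 1), ym(2020, 1)),
                   orbit = 1, quality_ok = c(TRUE, TRUE, FALSE, TRUE, TRUE),
                   pai = 2, cc = 0.5, ch = 8)
  tab <- filter_and_attach(fp, h, fm, zones)
  # kept: rows 1 and 2 (row 3 fails quality, row 4 peripheral, row 5 non-forest)
  expect_equal(tab$id, c(1, 2))
  expect_equal(tab$n_fires, c(1L, 0L))          # row 2 predates the fire
  expect_equal(tab$months_since, c(4L, NA))
  expect_equal(tab$season, c("wet", "wet"))
  expect_error(filter_and_attach(transform(fp, row = 99), h, fm, zones),
               "outside grid")
})

test_that("attached covariates equal generator truth on a synthetic scene", {
  sc <- cached("noisy_small", small_scene())
  fp <- simulate_footprints(sc$config, sc$truth)
  truth_events <- lapply(seq_len(nrow(sc$truth$catalog)), function(e)
    fire_event(e, sc$truth$catalog$ym[e], sc$truth$pixel_sets[[e]],
               dim(sc$truth$landcover), sc$config$pixel_size))
  h <- accumulate_history(truth_events, sc$truth$landcover == "forest")
  tab <- filter_and_attach(fp, h, sc$truth$landcover == "forest",
                           sc$truth$zones)
  expect_identical(tab$n_fires, tab$n_fires_true)
  expect_identical(tab$months_since, tab$months_since_true)
})

test_that("the mixed model identifies the generator exactly without noise", {
  sc <- cached("noisy_small", small_scene())
  cfg <- sc$config
  cfg$fp_noise_sd[] <- 0; cfg$fp_zone_sd[] <- 0; cfg$fp_season_sd[] <- 0
  cfg$n_footprints <- 2000
  fp <- simulate_footprints(cfg, sc$truth)
  truth_events <- lapply(seq_len(nrow(sc$truth$catalog)), function(e)
    fire_event(e, sc$truth$catalog$ym[e], sc$truth$pixel_sets[[e]],
               dim(sc$truth$landcover), cfg$pixel_size))
  h <- accumulate_history(truth_events, sc$truth$landcover == "forest")
  tab <- filter_and_attach(fp, h, sc$truth$landcover == "forest",
                           sc$truth$zones)
  m <- fit_structure_model(tab, "pai")
  cf <- m$coefficients
  expect_equal(cf$estimate[cf$term == "n_fires"],
               unname(cfg$fp_coef_nfires["pai"]), tolerance = 1e-6)
  expect_equal(cf$estimate[cf$term == "n_months"],
               unname(cfg$fp_coef_months["pai"]), tolerance = 1e-6)

  # zero zone/season variance under real noise: singular fit is reported
  cfg2 <- sc$config
  cfg2$fp_zone_sd[] <- 0; cfg2$fp_season_sd[] <- 0
  fp2 <- simulate_footprints(cfg2, sc$truth)
  tab2 <- filter_and_attach(fp2, h, sc$truth$landcover == "forest",
                            sc$truth$zones)
  expect_true(fit_structure_model(tab2, "pai")$singular)
})

test_that("mixed-model estimates are invariant to factor relabeling", {
  sc <- cached("noisy_small", small_scene())
  fp <- simulate_footprints(sc$config, sc$truth)
  truth_events <- lapply(seq_len(nrow(sc$truth$catalog)), function(e)
    fire_event(e, sc$truth$catalog$ym[e], sc$truth$pixel_sets[[e]],
               dim(sc$truth$landcover), sc$config$pixel_size))
  h <- accumulate_history(truth_events, sc$truth$landcover == "forest")
  tab <- filter_and_attach(fp, h, sc$truth$landcover == "forest",
                           sc$truth$zones)
  m1 <- fit_structure_model(tab, "cc")
  tab2 <- tab
  tab2$zone <- paste0("Z_", tab2$zone)
  tab2$season <- ifelse(tab2$season == "dry", "saison_seche", "saison_pluies")
  m2 <- fit_structure_model(tab2, "cc")
  expect_equal(m1$coefficients$estimate, m2$coefficients$estimate,
               tolerance = 1e-8)

  one_season <- tab[tab$season == "dry", ]
  expect_error(fit_structure_model(one_season, "cc"), "levels")
})

test_that("recovery assessment labels effect directions correctly", {
  sc <- cached("noisy_small", small_scene())
  truth_events <- lapply(seq_len(nrow(sc$truth$catalog)), function(e)
    fire_event(e, sc$truth$catalog$ym[e], sc$truth$pixel_sets[[e]],
               dim(sc$truth$landcover), sc$config$pixel_size))
  h <- accumulate_history(truth_events, sc$truth$landcover == "forest")

  # strong positive months effect: labelled recovering
  up <- sc$config
  up$fp_coef_months[] <- c(0.05, 0.01, 0.1)
  fp_up <- simulate_footprints(up, sc$truth)
  tab_up <- filter_and_attach(fp_up, h, sc$truth$landcover == "forest",
                              sc$truth$zones)
  rec <- recovery_assessment(tab_up, responses = "pai")
  expect_equal(rec$label[rec$effect == "n_months"], "recovering")

  # all effects zero: flat at the nominal error rate
  null <- sc$config
  null$fp_burned_offset[] <- 0; null$fp_coef_nfires[] <- 0
  null$fp_coef_months[] <- 0
  fp0 <- simulate_footprints(null, sc$truth, seed = 77)
  tab0 <- filter_and_attach(fp0, h, sc$truth$landcover == "forest",
                            sc$truth$zones)
  rec0 <- recovery_assessment(tab0)
  expect_gte(sum(rec0$label == "flat"), 5)   # 6 effects, alpha = 0.05
})
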