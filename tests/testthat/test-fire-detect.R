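make_break <- function(sign = -1, ci_lo, ci_hi, date = ci_lo) {
  structure(list(index = 50L, date = as.integer(date),
                 magnitude = sign * 0.3, sign = sign, all_breaks = 50L,
                 rss = 1, n_segments = 2L,
                 ci_lo = as.integer(ci_lo), ci_hi = as.integer(ci_hi)),
            class = "trend_break")
}

test_that("the fire rule matches negative breaks with dNBR spikes", {
  dates <- ym(2019, 1) + 0:23
  nbr <- rep(0.6, 24)
  nbr[10] <- 0.25   # spike of 0.35 at month 10
  ds <- dnbr_series(nbr, dates)
  brk <- make_break(-1, ci_lo = dates[9], ci_hi = dates[12], date = dates[10])

  cand <- match_break_with_dnbr(brk, ds)
  expect_s3_class(cand, "fire_candidate")
  expect_equal(cand$fire_ym, dates[10])
  expect_equal(cand$max_dnbr, 0.35)

  # below threshold: no candidate
  weak <- rep(0.6, 24); weak[10] <- 0.45
  expect_null(match_break_with_dnbr(brk, dnbr_series(weak, dates)))
  # positive break: sign gate
  expect_null(match_break_with_dnbr(make_break(1, dates[9], dates[12]), ds))
  # CI outside the series span
  far <- make_break(-1, ym(2030, 1), ym(2030, 5))
  expect_error(match_break_with_dnbr(far, ds), "outside")
})

test_that("a spike hidden behind a cloud gap is still matched", {
  dates <- ym(2019, 1) + 0:23
  nbr <- rep(0.6, 24)
  nbr[10] <- NA       # fire month composite lost
  nbr[11:24] <- 0.30  # persistent post-fire depression
  ds <- dnbr_series(nbr, dates)
  # dNBR observed at month 11 covers the gap (month 10, month 11]
  brk <- make_break(-1, ci_lo = dates[10], ci_hi = dates[10],
                    date = dates[10])
  cand <- match_break_with_dnbr(brk, ds)
  expect_s3_class(cand, "fire_candidate")
  expect_equal(cand$fire_ym, dates[10])
  expect_equal(cand$max_dnbr, 0.3)
})

test_that("raising the threshold never enlarges the candidate set", {
  sc <- cached("noisy_small", small_scene())
  mask <- sc$truth$landcover == "forest"
  brks <- cached("noisy_small_breaks",
                 scan_breaks(archive_index(sc$archive, "NDVI"),
                             sc$archive$dates, mask))
  sizes <- vapply(c(0.2, 0.3, 0.4, 0.5), function(thr)
    nrow(fire_candidates(sc$archive, mask, thr, breaks = brks)), integer(1))
  expect_true(all(diff(sizes) <= 0))
})

test_that("grouping follows the declared connectivity", {
  base <- data.frame(max_dnbr = 0.4, fire_ym = ym(2020, 9),
                     break_ym = ym(2020, 9), magnitude = -0.3)
  # edge-sharing pixels: one component
  cand <- cbind(data.frame(pixel = c(1, 2), row = c(1, 2), col = c(1, 1)),
                base)
  expect_length(group_to_polygons(cand, c(4, 4), 30), 1)
  # diagonal-only contact: two components under rook, one under queen
  diag_cand <- cbind(data.frame(pixel = c(1, 6), row = c(1, 2),
                                col = c(1, 2)), base)
  expect_length(group_to_polygons(diag_cand, c(4, 4), 30), 2)
  expect_length(group_to_polygons(diag_cand, c(4, 4), 30,
                                  connectivity = 8), 1)
})

test_that("adjacent-month fragments merge into one fire period", {
  pxA <- c(5, 6, 7); pxB <- c(8, 9)   # contiguous column segment split
  cand <- data.frame(pixel = c(pxA, pxB), row = c(5:7, 8:9), col = 1,
                     max_dnbr = 0.4,
                     fire_ym = c(rep(ym(2020, 9), 3), rep(ym(2020, 10), 2)),
                     break_ym = ym(2020, 9), magnitude = -0.3)
  ev <- group_to_polygons(cand, c(12, 12), 30)
  expect_length(ev, 1)
  expect_equal(ev[[1]]$fire_ym, ym(2020, 9))  # pixel-weighted modal month
  # two months apart: kept separate
  cand2 <- cand
  cand2$fire_ym[4:5] <- ym(2020, 11)
  expect_length(group_to_polygons(cand2, c(12, 12), 30), 2)
})

test_that("the minimum mapping unit keeps 5.04 ha and drops 4.95 ha", {
  mk <- function(npx) fire_event(1, ym(2020, 9), seq_len(npx),
                                 c(60, 60), 30)
  expect_length(filter_min_area(list(mk(56))), 1)   # 5.04 ha
  expect_length(filter_min_area(list(mk(55))), 0)   # 4.95 ha
  expect_length(filter_min_area(list(mk(55)), min_area_ha = 0), 1)
})

test_that("event polygons cover exactly the pixel set", {
  # a ring of pixels with a hole
  m <- matrix(FALSE, 8, 8)
  m[2:6, 2:6] <- TRUE
  m[3:5, 3:5] <- FALSE  # hole
  px <- which(m)
  ev <- fire_event(1, ym(2020, 9), px, c(8, 8), 30)
  areas <- vapply(ev$polygon, firescape:::ring_signed_area, numeric(1))
  expect_equal(sum(areas), length(px))       # signed areas cancel the hole
  expect_length(ev$polygon, 2)               # exterior ring + hole ring
  expect_equal(ev$area_ha, length(px) * 0.09)
})

test_that("noiseless fires are recovered as exact truth components", {
  sc <- cached("noiseless_small", noiseless_scene())
  mask <- sc$truth$landcover == "forest"
  res <- cached("noiseless_small_detect",
                detect_fires(sc$archive, mask, refine = TRUE))
  expect_length(res$events, nrow(sc$truth$catalog))
  for (e in res$events) {
    j <- which(sc$truth$catalog$ym == e$fire_ym)
    expect_setequal(e$pixels, sc$truth$pixel_sets[[j]])
    expect_true(all(e$provenance == "rule"))
  }
})

test_that("refinement drops candidates without vegetation-loss contrast", {
  # an NDVI artifact with a dNBR spike but uniform dNDVI: no burn evidence
  set.seed(42)
  flat <- matrix(rnorm(1600, 0, 0.01), 40, 40)
  pre <- raster_grid(matrix(0.7, 40, 40) + flat, "NDVI", ym(2020, 8))
  post <- raster_grid(matrix(0.7, 40, 40) + flat, "NDVI", ym(2020, 10))
  ev <- fire_event(1, ym(2020, 9), 400 + 1:60, c(40, 40), 30)
  expect_null(refine_perimeter(ev, pre, post))
})

test_that("refinement restores a speckled boundary to F1 >= 0.9", {
  sc <- cached("noiseless_small", noiseless_scene())
  truth_px <- sc$truth$pixel_sets[[2]]
  m <- sc$truth$catalog$ym[2]
  ndvi <- archive_index(sc$archive, "NDVI")
  ti <- match(m, sc$archive$dates)
  med <- function(idx) apply(ndvi[, , idx], c(1, 2), median, na.rm = TRUE)
  pre <- raster_grid(med((ti - 3):(ti - 1)), "NDVI", m - 1L)
  post <- raster_grid(med(ti:(ti + 2)), "NDVI", m)
  # candidate set with ~10% boundary speckle: drop some true pixels, add
  # neighbouring false ones
  set.seed(6)
  drop_n <- round(0.1 * length(truth_px))
  speckled <- setdiff(truth_px, sample(truth_px, drop_n))
  halo <- setdiff(unique(c(truth_px + 1, truth_px - 1, truth_px + 40,
                           truth_px - 40)), truth_px)
  halo <- halo[halo >= 1 & halo <= 1600]
  speckled <- sort(c(speckled, sample(halo, drop_n)))
  ev <- fire_event(1, m, speckled, c(40, 40), 30)
  r <- refine_perimeter(ev, pre, post)
  expect_false(is.null(r))
  tp <- length(intersect(r$pixels, truth_px))
  f1 <- 2 * tp / (length(r$pixels) + length(truth_px))
  expect_gte(f1, 0.9)
  expect_true(all(r$provenance[!r$pixels %in% speckled] == "refined"))
})
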