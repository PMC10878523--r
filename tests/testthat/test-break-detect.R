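test_that("pixel series validates its inputs", {
  expect_error(pixel_series(c(1, 2), 1), "lengths differ")
  expect_error(pixel_series(c(2, 1), c(0.1, 0.2)), "increasing")
  expect_error(pixel_series(1:2, c(0.1, 1.5)), "outside")
  s <- pixel_series(ym(2000, 1) + 0:5, c(0.1, NA, 0.3, 0.2, NA, 0.4))
  expect_s3_class(s, "pixel_series")
})

test_that("season-trend fit recovers a pure seasonal cycle", {
  s <- synthetic_series(n_months = 120, mean = 0.7, amp = 0.1)
  fit <- fit_season_trend(s)
  expect_lt(abs(fit$trend_coef[2]), 1e-8)              # flat trend
  expect_lt(abs(seasonal_amplitude(fit) - 0.1) / 0.1, 0.01)
  expect_length(detect_breaks(fit), 0)

  const <- pixel_series(ym(2000, 1) + 0:59, rep(0.5, 60))
  cfit <- fit_season_trend(const)
  expect_equal(seasonal_amplitude(cfit), 0, tolerance = 1e-10)
  expect_lt(cfit$rss, 1e-20)
  expect_length(detect_breaks(cfit), 0)

  expect_error(fit_season_trend(pixel_series(1:10, rep(0.5, 10))), "short")
  expect_error(fit_season_trend(pixel_series(1:30, rep(NA_real_, 30))),
               "missing")
})

test_that("a level drop splits the trend into two dated segments", {
  s <- synthetic_series(n_months = 300, steps = data.frame(at = 200,
                                                           size = -0.4))
  fit <- fit_season_trend(s)
  brks <- detect_breaks(fit)
  expect_length(brks, 1)
  expect_equal(brks[[1]]$n_segments, 2)
  expect_equal(brks[[1]]$date, s$dates[200])
  expect_lt(abs(brks[[1]]$magnitude + 0.4), 0.02)
  expect_equal(brks[[1]]$sign, -1)
})

test_that("dynamic-programming breakpoints equal brute-force search", {
  set.seed(101)
  for (rep in 1:8) {
    n <- sample(40:60, 1)
    nb <- sample(0:2, 1)
    steps <- if (nb > 0)
      data.frame(at = sort(sample(10:(n - 10), nb)),
                 size = runif(nb, -0.5, 0.5)) else NULL
    s <- synthetic_series(n_months = n, noise_sd = 0.08, steps = steps)
    fit <- fit_season_trend(s)
    for (m in 1:2) {
      dp <- .dp_breakpoints_cpp(fit$t, fit$deseason, fit$min_seg,
                                fit$min_edge, m)
      bf <- brute_force_breaks(fit, m)
      expect_equal(dp$rss[m + 1], bf$rss, tolerance = 1e-8)
      expect_identical(as.integer(dp$breaks[[m + 1]]), as.integer(bf$breaks))
    }
  }
})

test_that("false positives are rare and true drops are recovered", {
  set.seed(77)
  # null: stable seasonal series, modest noise
  fp <- vapply(1:40, function(i) {
    s <- synthetic_series(n_months = 120, noise_sd = 0.02)
    length(detect_breaks(fit_season_trend(s))) > 0
  }, logical(1))
  expect_lte(mean(fp), 0.05)

  # power: a 0.4 drop under noise 0.05 is recovered as a negative break
  # dated within +-2 months
  hits <- vapply(1:40, function(i) {
    s <- synthetic_series(n_months = 120, noise_sd = 0.05,
                          steps = data.frame(at = 60, size = -0.4))
    brks <- detect_breaks(fit_season_trend(s))
    any(vapply(brks, function(b) b$sign < 0 &&
                 abs(b$date - s$dates[60]) <= 2, logical(1)))
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("two well-separated drops are both found, in order", {
  set.seed(55)
  ok <- vapply(1:10, function(i) {
    s <- synthetic_series(n_months = 180, noise_sd = 0.05,
                          steps = data.frame(at = c(60, 120),
                                             size = c(-0.4, -0.3)))
    brks <- detect_breaks(fit_season_trend(s))
    length(brks) == 2 && all(vapply(brks, `[[`, 0, "sign") < 0) &&
      brks[[1]]$date < brks[[2]]$date &&
      abs(brks[[1]]$date - s$dates[60]) <= 2 &&
      abs(brks[[2]]$date - s$dates[120]) <= 2
  }, logical(1))
  expect_gte(mean(ok), 0.9)
})

test_that("break confidence intervals behave like inverted tests", {
  # noiseless step: CI collapses to the break month
  s0 <- synthetic_series(n_months = 120, steps = data.frame(at = 60,
                                                            size = -0.4))
  fit0 <- fit_season_trend(s0)
  b0 <- break_confidence_interval(fit0, detect_breaks(fit0)[[1]])
  expect_equal(b0$ci_lo, b0$date)
  expect_equal(b0$ci_hi, b0$date)

  # nesting: 99% interval contains the 95% interval
  set.seed(8)
  s <- synthetic_series(n_months = 120, noise_sd = 0.08,
                        steps = data.frame(at = 60, size = -0.3))
  fit <- fit_season_trend(s)
  b <- detect_breaks(fit)[[1]]
  ci95 <- break_confidence_interval(fit, b, 0.95)
  ci99 <- break_confidence_interval(fit, b, 0.99)
  expect_lte(ci99$ci_lo, ci95$ci_lo)
  expect_gte(ci99$ci_hi, ci95$ci_hi)
  expect_true(ci95$ci_lo <= b$date && b$date <= ci95$ci_hi)

  # the injected break's interval widens with noise (50-replicate averages)
  set.seed(12)
  width_at <- function(sd) {
    mean(vapply(1:50, function(i) {
      s <- synthetic_series(n_months = 120, noise_sd = sd,
                            steps = data.frame(at = 60, size = -0.3))
      fit <- fit_season_trend(s)
      brks <- detect_breaks(fit)
      if (length(brks) == 0) return(NA_real_)
      at <- which.min(vapply(brks, function(b)
        abs(b$date - s$dates[60]), numeric(1)))
      ci <- break_confidence_interval(fit, brks[[at]])
      as.numeric(ci$ci_hi - ci$ci_lo)
    }, numeric(1)), na.rm = TRUE)
  }
  w <- vapply(c(0.02, 0.05, 0.1), width_at, numeric(1))
  expect_true(all(diff(w) >= 0))
})

test_that("adding a constant shifts levels but not breaks", {
  set.seed(21)
  s <- synthetic_series(n_months = 140, noise_sd = 0.05,
                        steps = data.frame(at = 70, size = -0.35))
  s_shift <- s
  s_shift$values <- s$values - 0.2
  b1 <- detect_breaks(fit_season_trend(s))
  b2 <- detect_breaks(fit_season_trend(s_shift))
  expect_equal(length(b1), length(b2))
  expect_equal(vapply(b1, `[[`, 0L, "date"), vapply(b2, `[[`, 0L, "date"))
  expect_equal(vapply(b1, `[[`, 0, "magnitude"),
               vapply(b2, `[[`, 0, "magnitude"), tolerance = 1e-8)
})

test_that("cloud gaps do not fabricate breaks", {
  set.seed(31)
  fp <- vapply(1:20, function(i) {
    s <- synthetic_series(n_months = 150, noise_sd = 0.03,
                          missing = sample(150, 30))
    length(detect_breaks(fit_season_trend(s))) > 0
  }, logical(1))
  expect_lte(mean(fp), 0.1)
})
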