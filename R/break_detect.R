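#' One pixel's dated index time series
#'
#' @param dates integer month indices ([ym()]), strictly increasing
#' @param values index values in `[-1, 1]` or `NA` for cloud gaps
#' @param location optional `c(row, col)`
#' @param index index name
#' @return a `pixel_series`
#' @export
pixel_series <- function(dates, values, location = NULL, index = "NDVI") {
  if (length(dates) != length(values)) stop("dates/values lengths differ")
  if (length(dates) > 1 && any(diff(dates) <= 0))
    stop("dates must be strictly increasing")
  ok <- !is.na(values)
  if (any(values[ok] < -1 - 1e-9 | values[ok] > 1 + 1e-9))
    stop("index values outside [-1, 1]")
  structure(list(dates = as.integer(dates), values = as.numeric(values),
                 location = location, index = index),
            class = "pixel_series")
}

#' @method print pixel_series
#' @export
print.pixel_series <- function(x, ...) {
  cat(sprintf("<pixel_series> %s, %d months (%d observed), %s..%s\n",
              x$index, length(x$dates), sum(!is.na(x$values)),
              format_ym(min(x$dates)), format_ym(max(x$dates))))
  invisible(x)
}

#' Season-trend decomposition of a monthly series
#'
#' Fits value = trend + seasonal + residual where the seasonal component is a
#' sum of annual harmonics `a_k sin(2 pi k t / 12) + b_k cos(2 pi k t / 12)`
#' for `k <= harmonic_order`, estimated jointly with a linear trend by least
#' squares on the observed months only (gaps are never interpolated, so
#' clouds cannot fabricate breaks). The deseasonalized series (trend +
#' residual) is what the piecewise-linear break search operates on.
#'
#' @param series a [pixel_series()]
#' @param harmonic_order number of annual harmonics (default 2 captures a
#'   uni-modal wet/dry cycle with some asymmetry)
#' @param min_segment_fraction minimum trend-segment length as a fraction of
#'   the number of observed months (interior segments)
#' @param min_seg_cap absolute ceiling (observations) on the interior
#'   minimum-segment length. On multidecadal archives a pure fractional
#'   minimum would forbid trend segments shorter than several years, making
#'   fire-return intervals of one to two years — common in repeatedly
#'   burning landscapes - undetectable; the cap keeps the floor below an
#'   annual fire-return interval regardless of record length.
#' @param min_edge minimum length (observations) of the first and last trend
#'   segments. Relaxing the boundary segments below the interior minimum
#'   keeps disturbances near the start or end of the record detectable; the
#'   default caps at 10 observations and never exceeds the interior minimum.
#' @return a `season_trend_fit`
#' @export
fit_season_trend <- function(series, harmonic_order = 2,
                             min_segment_fraction = 0.15, min_seg_cap = 8L,
                             min_edge = NULL) {
  obs <- which(!is.na(series$values))
  if (length(obs) == 0) stop("all-missing series")
  if (length(obs) < 24) stop("series too short: need >= 24 observed months")
  t <- as.numeric(series$dates[obs])
  y <- series$values[obs]
  n <- length(y)
  S <- seasonal_design(t, harmonic_order)
  X <- cbind(1, t, S)
  fit <- stats::lm.fit(X, y)
  seas_coef <- coef(fit)[-(1:2)]
  seasonal <- drop(S %*% seas_coef)
  structure(list(t = t, y = y, dates = series$dates[obs],
                 seasonal = seasonal, seas_coef = seas_coef,
                 trend_coef = coef(fit)[1:2],
                 deseason = y - seasonal,
                 fitted = drop(X %*% coef(fit)),
                 rss = sum(fit$residuals^2),
                 harmonic_order = harmonic_order,
                 min_seg = max(3L, min(ceiling(min_segment_fraction * n),
                                       as.integer(min_seg_cap))),
                 min_edge = if (is.null(min_edge))
                   max(3L, min(ceiling(min_segment_fraction * n),
                               as.integer(min_seg_cap), 10L))
                 else as.integer(min_edge),
                 n = n, location = series$location, index = series$index),
            class = "season_trend_fit")
}

seasonal_design <- function(t, K) {
  if (K < 1) return(matrix(0, length(t), 0))
  do.call(cbind, lapply(seq_len(K), function(k)
    cbind(sin(2 * pi * k * t / 12), cos(2 * pi * k * t / 12))))
}

#' @method print season_trend_fit
#' @export
print.season_trend_fit <- function(x, ...) {
  cat(sprintf("<season_trend_fit> %d obs, K=%d harmonics, RSS %.4g\n",
              x$n, x$harmonic_order, x$rss))
  invisible(x)
}

#' Seasonal amplitude of a fitted decomposition
#' @param fit a `season_trend_fit`
#' @return amplitude (half peak-to-trough) of the fitted seasonal component
#' @export
seasonal_amplitude <- function(fit) {
  if (length(fit$seasonal) == 0) return(0)
  (max(fit$seasonal) - min(fit$seasonal)) / 2
}

# Numerically-degenerate RSS floor: below this per-observation level the
# series is treated as exactly fitted (relevant for noise-free simulations)
RSS_FLOOR <- 1e-16

#' Detect dated structural breaks in the trend
#'
#' Searches the deseasonalized series for the optimal segmentation into
#' piecewise-linear trend segments by dynamic programming (for each number of
#' breaks, the breakpoints exactly minimize the residual sum of squares over
#' all admissible positions), then selects the number of breaks by an
#' information criterion. Each returned break carries its date (first
#' observed month of the new regime), the step magnitude (trend level after
#' minus before, evaluated at the break date), and its sign.
#'
#' @param fit a [fit_season_trend()] result
#' @param max_breaks maximum number of breaks to consider
#' @param penalty `"BIC"` or the stricter `"LWZ"` modified criterion
#' @return list of `trend_break` objects (empty when no break is supported)
#' @export
detect_breaks <- function(fit, max_breaks = 3, penalty = c("BIC", "LWZ")) {
  penalty <- match.arg(penalty)
  n <- fit$n
  dp <- .dp_breakpoints_cpp(fit$t, fit$deseason, fit$min_seg, fit$min_edge,
                            max_breaks)
  feasible <- is.finite(dp$rss)
  rss <- pmax(dp$rss, n * RSS_FLOOR)
  ms <- seq_along(dp$rss) - 1L
  k <- 3 * ms + 2  # 2 params per segment + 1 per break position
  pen <- if (penalty == "BIC") k * log(n) else 0.299 * k * log(n)^2.1
  ic <- ifelse(feasible, n * log(rss / n) + pen, Inf)
  m <- ms[which.min(ic)]
  if (m == 0) return(list())
  bps <- dp$breaks[[m + 1]]
  lapply(seq_along(bps), function(i)
    make_trend_break(fit, bps, i, rss = dp$rss[m + 1]))
}

# 1-based observation bounds of the segments left and right of break i
segment_bounds <- function(bps, i, n) {
  list(l_start = if (i == 1) 1L else bps[i - 1] + 1L, l_end = bps[i],
       r_start = bps[i] + 1L,
       r_end = if (i == length(bps)) n else bps[i + 1])
}

make_trend_break <- function(fit, bps, i, rss) {
  b <- segment_bounds(bps, i, fit$n)
  tau <- fit$t[b$r_start]
  lev <- function(a, z) {
    idx <- a:z
    cf <- stats::lm.fit(cbind(1, fit$t[idx]), fit$deseason[idx])$coefficients
    cf[1] + cf[2] * tau
  }
  mag <- unname(lev(b$r_start, b$r_end) - lev(b$l_start, b$l_end))
  structure(list(index = bps[i], date = as.integer(fit$dates[b$r_start]),
                 magnitude = mag, sign = sign(mag),
                 all_breaks = bps, rss = rss, n_segments = length(bps) + 1L,
                 ci_lo = NA_integer_, ci_hi = NA_integer_),
            class = "trend_break")
}

#' @method print trend_break
#' @export
print.trend_break <- function(x, ...) {
  cat(sprintf("<trend_break> %s  magnitude %+.3f  CI [%s, %s]\n",
              format_ym(x$date), x$magnitude,
              if (is.na(x$ci_lo)) "-" else format_ym(x$ci_lo),
              if (is.na(x$ci_hi)) "-" else format_ym(x$ci_hi)))
  invisible(x)
}

#' Confidence interval for a break date by RSS inversion
#'
#' Holding all other breaks fixed, the break is repositioned across every
#' admissible month and the full-model RSS recorded. The CI is the contiguous
#' set of candidate dates (containing the estimate) whose RSS lies within the
#' chi-square level-quantile inversion bound of the minimum:
#' `RSS(b) <= RSS_min + sigma2_hat * qchisq(level, 1)`. With noise-free data
#' the interval collapses to the break month.
#'
#' @param fit the `season_trend_fit` the break came from
#' @param brk a `trend_break` from [detect_breaks()]
#' @param level confidence level
#' @return the break with `ci_lo`/`ci_hi` (month indices) filled in
#' @export
break_confidence_interval <- function(fit, brk, level = 0.95) {
  which_b <- match(brk$index, brk$all_breaks)
  rep <- .reposition_rss_cpp(fit$t, fit$deseason, brk$all_breaks,
                             which_b, fit$min_seg, fit$min_edge)
  rss_min <- min(rep$rss)
  df <- fit$n - 2 * (length(brk$all_breaks) + 1)
  sigma2 <- max(rss_min, fit$n * RSS_FLOOR) / max(df, 1)
  thr <- rss_min + sigma2 * qchisq(level, 1)
  ok <- rep$rss <= thr + 1e-12
  est <- match(brk$index, rep$pos)
  # contiguous run of admissible positions containing the estimate
  runs <- rle(ok)
  ends <- cumsum(runs$lengths); starts <- ends - runs$lengths + 1
  run <- which(runs$values & starts <= est & est <= ends)
  if (length(run) == 0) { lo <- hi <- est } else {
    lo <- starts[run]; hi <- ends[run]
  }
  # a break after observation b dates the new regime at dates[b + 1], but the
  # disturbance itself lies anywhere in the observation gap (dates[b],
  # dates[b + 1]]; the interval therefore starts the month after the last
  # pre-break observation so cloud-gapped fire months stay inside it
  brk$ci_lo <- as.integer(fit$dates[rep$pos[lo]] + 1L)
  brk$ci_hi <- as.integer(fit$dates[rep$pos[hi] + 1])
  brk$ci_level <- level
  brk
}

#' Scan every masked pixel of an index stack for breaks
#'
#' Batch driver for the per-pixel decomposition: fits the season-trend model,
#' detects breaks, and attaches confidence intervals. Pixels with fewer than
#' 24 observed months are skipped.
#'
#' @param index_arr 3-D array `[row, col, month]` of index values (NA = gap)
#' @param dates month indices of the third dimension
#' @param mask logical matrix; only `TRUE` pixels are scanned
#' @inheritParams fit_season_trend
#' @inheritParams detect_breaks
#' @param level CI level
#' @return data.frame, one row per break: pixel, row, col, date, magnitude,
#'   ci_lo, ci_hi
#' @export
scan_breaks <- function(index_arr, dates, mask, harmonic_order = 2,
                        min_segment_fraction = 0.15, max_breaks = 3,
                        penalty = "BIC", level = 0.95) {
  nr <- dim(index_arr)[1]; nc <- dim(index_arr)[2]
  dim(index_arr) <- c(nr * nc, dim(index_arr)[3])
  px_all <- which(as.vector(mask))
  out <- vector("list", length(px_all)); nout <- 0
  for (p in px_all) {
    v <- index_arr[p, ]
    if (sum(!is.na(v)) < 24) next
    fit <- fit_season_trend(pixel_series(dates, v), harmonic_order,
                            min_segment_fraction)
    brks <- detect_breaks(fit, max_breaks, penalty)
    if (length(brks) == 0) next
    for (b in brks) {
      b <- break_confidence_interval(fit, b, level)
      nout <- nout + 1
      out[[nout]] <- data.frame(pixel = p, row = (p - 1L) %% nr + 1L,
                                col = (p - 1L) %/% nr + 1L,
                                date = b$date, magnitude = b$magnitude,
                                ci_lo = b$ci_lo, ci_hi = b$ci_hi)
    }
  }
  if (nout == 0)
    return(data.frame(pixel = integer(), row = integer(), col = integer(),
                      date = integer(), magnitude = numeric(),
                      ci_lo = integer(), ci_hi = integer()))
  do.call(rbind, out[seq_len(nout)])
}

#' Exhaustive brute-force breakpoint search
#'
#' Reference implementation for validating the dynamic program: enumerates
#' every admissible combination of break positions and returns the one with
#' minimal total RSS. Exponential in the number of breaks; intended for short
#' series only.
#'
#' @inheritParams detect_breaks
#' @param n_breaks exact number of breaks to place
#' @return list with `breaks` (1-based last-obs indices) and `rss`
#' @export
brute_force_breaks <- function(fit, n_breaks) {
  n <- fit$n; h <- fit$min_seg; he <- fit$min_edge
  segrss <- function(a, z) {
    idx <- a:z
    sum(stats::lm.fit(cbind(1, fit$t[idx]), fit$deseason[idx])$residuals^2)
  }
  if (n_breaks == 0) return(list(breaks = integer(0), rss = segrss(1, n)))
  cand <- utils::combn(seq(he, n - he), n_breaks, simplify = FALSE)
  cand <- Filter(function(b) {
    lens <- diff(c(0, b, n))
    lens[1] >= he && lens[length(lens)] >= he &&
      all(lens[-c(1, length(lens))] >= h)
  }, cand)
  if (length(cand) == 0) stop("no admissible break combination")
  rss <- vapply(cand, function(b) {
    bounds <- c(0, b, n)
    sum(vapply(seq_len(length(bounds) - 1), function(i)
      segrss(bounds[i] + 1, bounds[i + 1]), numeric(1)))
  }, numeric(1))
  best <- which.min(rss)
  list(breaks = cand[[best]], rss = rss[best])
}
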