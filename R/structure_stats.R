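#' Join lidar footprints to fire history
#'
#' Keeps footprints that pass the quality flag, fall inside the forest base
#' map and outside excluded management zones (the peripheral zone by
#' default), and attaches the burn covariates relative to each footprint's
#' acquisition date: only burns strictly before or at acquisition count, so
#' a footprint acquired before its pixel's first fire has `n_fires = 0`.
#'
#' @param footprints data.frame from [simulate_footprints()] or a user table
#'   with columns row, col, date, orbit, quality_ok, pai, cc, ch
#' @param history a `fire_history`
#' @param forest_mask logical matrix
#' @param zones factor matrix of management zones
#' @param exclude_zones zones removed from analysis
#' @return analysis data.frame with `n_fires`, `months_since` (NA = never
#'   burned), `season`, `zone`
#' @export
filter_and_attach <- function(footprints, history, forest_mask, zones,
                              exclude_zones = "peripheral") {
  nr <- nrow(forest_mask); nc <- ncol(forest_mask)
  if (any(footprints$row < 1 | footprints$row > nr |
          footprints$col < 1 | footprints$col > nc))
    stop("footprint outside grid")
  px <- (footprints$col - 1L) * nr + footprints$row
  keep <- footprints$quality_ok & forest_mask[px] &
    !(as.character(zones[px]) %in% exclude_zones)
  fp <- footprints[keep, , drop = FALSE]
  px <- px[keep]
  nfires <- integer(nrow(fp)); msince <- rep(NA_integer_, nrow(fp))
  for (i in seq_len(nrow(fp))) {
    d <- history$burn_dates[[px[i]]]
    d <- d[d <= fp$date[i]]
    nfires[i] <- length(d)
    if (length(d) > 0) msince[i] <- fp$date[i] - max(d)
  }
  fp$pixel <- px
  fp$n_fires <- nfires
  fp$months_since <- msince
  fp$season <- season_of(fp$date)
  fp$zone <- as.character(zones[px])
  fp
}

#' Kruskal-Wallis rank test
#'
#' Implemented from the rank-sum formula with the standard ties correction:
#' `H = [12 / (N(N+1))] * sum(R_j^2 / n_j) - 3(N+1)`, divided by
#' `1 - sum(t^3 - t) / (N^3 - N)`; p from chi-square with (groups - 1) df.
#'
#' @param values numeric vector
#' @param groups group labels (same length)
#' @return list with `statistic` (H), `df`, `p.value`, `n`
#' @export
kruskal_wallis <- function(values, groups) {
  ok <- !is.na(values) & !is.na(groups)
  values <- values[ok]; groups <- factor(groups[ok])
  if (nlevels(groups) < 2) stop("need >= 2 groups")
  if (any(tabulate(groups) == 0)) stop("empty group")
  N <- length(values)
  r <- rank(values)
  Rj <- tapply(r, groups, sum)
  nj <- tabulate(groups)
  H <- 12 / (N * (N + 1)) * sum(Rj^2 / nj) - 3 * (N + 1)
  ties <- table(values)
  C <- 1 - sum(ties^3 - ties) / (N^3 - N)
  if (C > 0) H <- H / C
  df <- nlevels(groups) - 1
  list(statistic = unname(H), df = df,
       p.value = pchisq(H, df, lower.tail = FALSE), n = N)
}

#' Dunn's post-hoc test with multiplicity correction
#'
#' Pairwise z statistics from the pooled ranks shared with the
#' Kruskal-Wallis test, with the ties correction in the standard error:
#' `z_ij = (Rbar_i - Rbar_j) / sqrt([N(N+1)/12 - sum(t^3 - t)/(12(N-1))] *
#' (1/n_i + 1/n_j))`. Two-sided p-values are multiplied by the number of
#' comparisons (Bonferroni) and capped at 1.
#'
#' @param values numeric vector
#' @param groups group labels
#' @param correction `"bonferroni"` or `"none"`
#' @return list with matrices `z` and `p` (adjusted) plus the comparison count
#' @export
dunn_posthoc <- function(values, groups, correction = c("bonferroni", "none")) {
  correction <- match.arg(correction)
  ok <- !is.na(values) & !is.na(groups)
  values <- values[ok]; groups <- factor(groups[ok])
  g <- nlevels(groups)
  if (g < 2) stop("need >= 2 groups")
  N <- length(values)
  r <- rank(values)
  Rbar <- tapply(r, groups, mean)
  nj <- tabulate(groups)
  ties <- table(values)
  s2 <- N * (N + 1) / 12 - sum(ties^3 - ties) / (12 * (N - 1))
  z <- matrix(NA_real_, g, g, dimnames = list(levels(groups), levels(groups)))
  m <- choose(g, 2)
  for (i in seq_len(g - 1)) for (j in (i + 1):g) {
    zz <- (Rbar[i] - Rbar[j]) / sqrt(s2 * (1 / nj[i] + 1 / nj[j]))
    z[i, j] <- z[j, i] <- unname(zz)
  }
  p <- 2 * pnorm(-abs(z))
  if (correction == "bonferroni") {
    p <- p * m
    p[!is.na(p) & p > 1] <- 1
  }
  list(z = z, p = p, comparisons = m)
}

#' Linear mixed model of a structure metric on burn history
#'
#' Fits `response ~ n_fires + n_months + (1 | season) + (1 | zone)` by
#' restricted maximum likelihood, where `n_fires` is the number of fires
#' before acquisition and `n_months` the months since the last fire.
#' Following the months-since-last-fire definition, the model is fit on
#' burned footprints only by default; setting `include_unburned = TRUE`
#' keeps never-burned footprints with `n_months` coded 0.
#'
#' @param table analysis table from [filter_and_attach()]
#' @param response `"pai"`, `"cc"` or `"ch"`
#' @param include_unburned include never-burned footprints
#' @return a `structure_model`: coefficient table (estimate, SE,
#'   Satterthwaite df, t, p), random-effect standard deviations, n, and a
#'   singular-fit flag (reported, never silently dropped)
#' @export
fit_structure_model <- function(table, response = c("pai", "cc", "ch"),
                                include_unburned = FALSE) {
  response <- match.arg(response)
  d <- table
  if (!include_unburned) d <- d[d$n_fires >= 1, , drop = FALSE]
  d$n_months <- ifelse(is.na(d$months_since), 0, d$months_since)
  d <- d[complete.cases(d[, c(response, "n_fires", "n_months",
                              "season", "zone")]), , drop = FALSE]
  if (length(unique(d$season)) < 2 || length(unique(d$zone)) < 2)
    stop("need >= 2 levels in each random grouping (season, zone)")
  fml <- stats::as.formula(paste(response,
                                 "~ n_fires + n_months + (1 | season) + (1 | zone)"))
  fit <- suppressMessages(lmerTest::lmer(
    fml, data = d,
    control = lme4::lmerControl(check.conv.singular = "ignore",
                                calc.derivs = FALSE)))
  cf <- as.data.frame(summary(fit)$coefficients)
  names(cf) <- c("estimate", "se", "df", "t", "p")
  cf$term <- rownames(cf); rownames(cf) <- NULL
  vc <- as.data.frame(lme4::VarCorr(fit))
  structure(list(response = response,
                 coefficients = cf[, c("term", "estimate", "se", "df", "t", "p")],
                 varcomp = data.frame(group = vc$grp, sd = vc$sdcor),
                 n = nrow(d), singular = lme4::isSingular(fit),
                 include_unburned = include_unburned, model = fit),
            class = "structure_model")
}

#' @method print structure_model
#' @export
print.structure_model <- function(x, ...) {
  cat(sprintf("<structure_model> %s, n = %d%s\n", x$response, x$n,
              if (x$singular) " (singular random-effect fit)" else ""))
  print(x$coefficients, digits = 3)
  invisible(x)
}

#' Directional recovery and fire-frequency assessment
#'
#' For each structure metric, labels the months-since-fire effect and the
#' fire-count effect as `"recovering"` (positive, p < alpha), `"declining"`
#' (negative, p < alpha) or `"flat"` from the fitted mixed models.
#'
#' @param table analysis table from [filter_and_attach()]
#' @param responses metrics to assess
#' @param alpha significance level
#' @param include_unburned passed to [fit_structure_model()]
#' @return data.frame with one row per response x effect: estimate, p, label
#' @export
recovery_assessment <- function(table, responses = c("pai", "cc", "ch"),
                                alpha = 0.05, include_unburned = FALSE) {
  out <- NULL
  for (resp in responses) {
    m <- fit_structure_model(table, resp, include_unburned)
    for (term in c("n_fires", "n_months")) {
      row <- m$coefficients[m$coefficients$term == term, ]
      label <- if (row$p >= alpha) "flat"
        else if (row$estimate > 0) "recovering" else "declining"
      out <- rbind(out, data.frame(response = resp, effect = term,
                                   estimate = row$estimate, se = row$se,
                                   p = row$p, label = label))
    }
  }
  out
}
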