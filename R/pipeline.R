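#' Pipeline configuration
#'
#' Bundles every stage parameter with the synthetic-scene configuration (or
#' user-supplied inputs) and the seed. Stage names, in execution order:
#' `simulate`, `basemap`, `breaks`, `detect`, `history`, `stats`.
#'
#' @param scene a [scene_config()] (used by the `simulate` stage)
#' @param stages character vector of stages to run
#' @param threshold dNBR fire threshold
#' @param min_area_ha minimum mapping unit (ha)
#' @param connectivity 4 or 8
#' @param harmonic_order,min_segment_fraction,max_breaks,penalty
#'   break-detection parameters
#' @param ci_level confidence level for break dating
#' @param refine run perimeter refinement
#' @param basemap_segments SLIC segment count for the forest base map
#' @param label_fraction fraction of segments labeled for base-map training
#' @param classifier `"mlp"` or `"logistic"`
#' @param include_unburned include never-burned footprints in mixed models
#' @param seed master seed (defaults to the scene seed)
#' @return a `pipeline_config`
#' @export
pipeline_config <- function(scene = scene_config(),
                            stages = c("simulate", "basemap", "breaks",
                                       "detect", "history", "stats"),
                            threshold = 0.2, min_area_ha = 5,
                            connectivity = 4, harmonic_order = 2,
                            min_segment_fraction = 0.15, max_breaks = 3,
                            penalty = "BIC", ci_level = 0.95, refine = TRUE,
                            basemap_segments = 150, label_fraction = 0.2,
                            classifier = "mlp", include_unburned = FALSE,
                            seed = scene$seed) {
  if (threshold < 0) stop("threshold must be >= 0")
  if (min_area_ha < 0) stop("min_area_ha must be >= 0")
  if (ci_level <= 0 || ci_level >= 1) stop("ci_level must lie in (0, 1)")
  structure(list(scene = scene, stages = stages, threshold = threshold,
                 min_area_ha = min_area_ha, connectivity = connectivity,
                 harmonic_order = harmonic_order,
                 min_segment_fraction = min_segment_fraction,
                 max_breaks = max_breaks, penalty = penalty,
                 ci_level = ci_level, refine = refine,
                 basemap_segments = basemap_segments,
                 label_fraction = label_fraction, classifier = classifier,
                 include_unburned = include_unburned,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

need_product <- function(state, what) {
  if (is.null(state[[what]]))
    stop(sprintf("stage dependency missing: %s", what), call. = FALSE)
  state[[what]]
}

#' Run the pipeline end to end
#'
#' Executes the enabled stages in order — synthetic scene, forest base map,
#' per-pixel break scan, fire detection, history accumulation, structure
#' statistics — writing every intermediate product plus a manifest (config
#' hash, seed, per-stage timings and counts) into a fresh run directory.
#' Runs with the same config and seed are reproducible.
#'
#' @param config a [pipeline_config()]
#' @param out_dir run directory; must not already contain a manifest
#'   (one run directory per invocation). Default: a fresh temp directory.
#' @param archive,truth,footprints optional user-supplied inputs replacing
#'   the `simulate` stage products
#' @param quiet suppress stage logging
#' @return a `pipeline_run` list with all stage products, the evaluation
#'   inputs and the manifest
#' @export
run_pipeline <- function(config, out_dir = tempfile("firescape_run_"),
                         archive = NULL, truth = NULL, footprints = NULL,
                         quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  if (file.exists(file.path(out_dir, "manifest.json")))
    stop("run directory already holds a manifest; runs are never overwritten")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  state <- list(archive = archive, truth = truth, footprints = footprints)
  manifest <- list(config_hash = config_hash(jsonlite::toJSON(
    config[setdiff(names(config), "scene")], auto_unbox = TRUE,
    digits = NA, force = TRUE)),
    seed = config$seed, stages = list())
  log_stage <- function(name, t0, counts) {
    if (!quiet) message(sprintf("[%s] %.1fs %s", name,
                                as.numeric(Sys.time()) - t0,
                                paste(names(counts), unlist(counts),
                                      sep = "=", collapse = " ")))
    manifest$stages[[name]] <<- c(list(seconds = round(
      as.numeric(Sys.time()) - t0, 2)), counts)
  }

  if ("simulate" %in% config$stages) {
    t0 <- as.numeric(Sys.time())
    landscape <- generate_landscape(config$scene)
    sim <- simulate_archive(config$scene, landscape)
    state$archive <- sim$archive; state$truth <- sim$truth
    state$footprints <- simulate_footprints(config$scene, sim$truth)
    write_truth_json(state$truth, file.path(out_dir, "truth.json"))
    write.csv(state$footprints, file.path(out_dir, "footprints.csv"),
              row.names = FALSE)
    log_stage("simulate", t0, list(
      pixels = prod(dim(landscape$landcover)),
      months = length(state$archive$dates),
      truth_events = if (is.null(state$truth$catalog)) 0L
                     else nrow(state$truth$catalog),
      footprints = nrow(state$footprints)))
  }

  if ("basemap" %in% config$stages) {
    t0 <- as.numeric(Sys.time())
    arch <- need_product(state, "archive")
    truth_ <- need_product(state, "truth")
    feats <- slic_segment(
      list(apply(archive_index(arch, "NDVI")[, , 1:12, drop = FALSE],
                 c(1, 2), median, na.rm = TRUE),
           apply(archive_index(arch, "NBR")[, , 1:12, drop = FALSE],
                 c(1, 2), median, na.rm = TRUE)),
      config$basemap_segments)
    labels <- training_labels_from_truth(feats, truth_$landcover,
                                         config$label_fraction,
                                         seed = config$seed + 11L)
    cls <- train_and_classify(feats, labels, classifier = config$classifier,
                              seed = config$seed + 12L)
    state$basemap <- list(mask = cls$map == "forest", classified = cls,
                          segments = feats)
    write_raster_tiff(raster_grid(state$basemap$mask + 0, "forest_mask",
                                  pixel_size = arch$pixel_size),
                      file.path(out_dir, "forest_mask.tif"))
    log_stage("basemap", t0, list(forest_pixels = sum(state$basemap$mask),
                                  segments = nrow(feats$features)))
  }

  if ("breaks" %in% config$stages) {
    t0 <- as.numeric(Sys.time())
    arch <- need_product(state, "archive")
    bm <- need_product(state, "basemap")
    state$breaks <- scan_breaks(archive_index(arch, "NDVI"), arch$dates,
                                bm$mask, config$harmonic_order,
                                config$min_segment_fraction,
                                config$max_breaks, config$penalty,
                                config$ci_level)
    write.csv(state$breaks, file.path(out_dir, "breaks.csv"),
              row.names = FALSE)
    log_stage("breaks", t0, list(breaks = nrow(state$breaks),
                                 pixels_scanned = sum(bm$mask)))
  }

  if ("detect" %in% config$stages) {
    t0 <- as.numeric(Sys.time())
    arch <- need_product(state, "archive")
    bm <- need_product(state, "basemap")
    brks <- need_product(state, "breaks")
    cand <- fire_candidates(arch, bm$mask, config$threshold, breaks = brks)
    res <- detect_fires(arch, bm$mask, config$threshold,
                        config$min_area_ha, config$connectivity,
                        refine = config$refine, candidates = cand)
    state$candidates <- cand
    state$events <- res$events
    write_event_catalog(res$events, file.path(out_dir, "events.geojson"),
                        file.path(out_dir, "events.csv"))
    log_stage("detect", t0, list(candidates = nrow(cand),
                                 events = length(res$events),
                                 dropped = length(res$dropped)))
  }

  if ("history" %in% config$stages) {
    t0 <- as.numeric(Sys.time())
    bm <- need_product(state, "basemap")
    events <- need_product(state, "events")
    arch <- need_product(state, "archive")
    state$history <- accumulate_history(events, bm$mask, arch$pixel_size)
    state$summary <- burn_summary(state$history, events)
    write_raster_tiff(raster_grid(state$history$burn_count + 0, "burn_count",
                                  pixel_size = arch$pixel_size),
                      file.path(out_dir, "burn_count.tif"))
    write.csv(state$summary$landscape,
              file.path(out_dir, "burn_landscape.csv"), row.names = FALSE)
    if (!is.null(state$summary$events))
      write.csv(state$summary$events, file.path(out_dir, "burn_events.csv"),
                row.names = FALSE)
    log_stage("history", t0, list(
      burned_pixels = sum(state$history$burn_count > 0),
      max_burns = max(state$history$burn_count)))
  }

  if ("stats" %in% config$stages) {
    t0 <- as.numeric(Sys.time())
    fp <- need_product(state, "footprints")
    hist_ <- need_product(state, "history")
    bm <- need_product(state, "basemap")
    truth_ <- need_product(state, "truth")
    tab <- filter_and_attach(fp, hist_, bm$mask, truth_$zones)
    state$analysis <- tab
    kw <- lapply(c(pai = "pai", cc = "cc", ch = "ch"), function(m)
      if (length(unique(tab$n_fires)) >= 2)
        kruskal_wallis(tab[[m]], tab$n_fires) else NULL)
    models <- tryCatch(
      recovery_assessment(tab, include_unburned = config$include_unburned),
      error = function(e) NULL)
    state$stats <- list(kruskal = kw, recovery = models)
    write.csv(tab, file.path(out_dir, "analysis_table.csv"),
              row.names = FALSE)
    jsonlite::write_json(list(
      kruskal = lapply(kw, function(k) k[c("statistic", "df", "p.value", "n")]),
      recovery = models), file.path(out_dir, "structure_stats.json"),
      auto_unbox = TRUE, digits = NA, force = TRUE)
    log_stage("stats", t0, list(n_analysis = nrow(tab)))
  }

  manifest$products <- list.files(out_dir)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  state$manifest <- manifest
  state$out_dir <- out_dir
  class(state) <- "pipeline_run"
  invisible(state)
}

#' @method print pipeline_run
#' @export
print.pipeline_run <- function(x, ...) {
  cat(sprintf("<pipeline_run> %s\n  stages: %s\n", x$out_dir,
              paste(names(x$manifest$stages), collapse = ", ")))
  if (!is.null(x$events))
    cat(sprintf("  events detected: %d\n", length(x$events)))
  invisible(x)
}

#' Score a synthetic run against its ground truth
#'
#' Event-level precision and recall (a detected and a truth event match when
#' their pixel intersection-over-union reaches `iou` and their months differ
#' by at most `month_tol`; matching is one-to-one, greedy by overlap), the
#' fire-month error distribution, the burn-count confusion matrix over the
#' truth forest area, and — when models were fit — the recovery of the
#' generator's fixed-effect coefficients. With zero truth fires and zero
#' detections both precision and recall are vacuously 1 (logged).
#'
#' @param run a `pipeline_run` (or a list with `events`, `history`, `stats`)
#' @param truth a `scene_truth`
#' @param iou intersection-over-union threshold for an event match
#' @param month_tol fire-month tolerance (months)
#' @return an `evaluation` list
#' @export
evaluate_against_truth <- function(run, truth, iou = 0.5, month_tol = 1) {
  det <- run$events
  tc <- truth$catalog
  nt <- if (is.null(tc)) 0L else nrow(tc)
  nd <- length(det)
  pairs <- NULL
  for (i in seq_len(nd)) for (j in seq_len(nt)) {
    if (abs(det[[i]]$fire_ym - tc$ym[j]) > month_tol) next
    inter <- length(intersect(det[[i]]$pixels, truth$pixel_sets[[j]]))
    un <- length(union(det[[i]]$pixels, truth$pixel_sets[[j]]))
    if (inter / un >= iou)
      pairs <- rbind(pairs, data.frame(det = i, truth = j, iou = inter / un,
                                       month_error = det[[i]]$fire_ym - tc$ym[j]))
  }
  matched <- NULL
  if (!is.null(pairs)) {
    pairs <- pairs[order(-pairs$iou), , drop = FALSE]
    used_d <- used_t <- integer(0)
    for (r in seq_len(nrow(pairs))) {
      if (pairs$det[r] %in% used_d || pairs$truth[r] %in% used_t) next
      matched <- rbind(matched, pairs[r, ])
      used_d <- c(used_d, pairs$det[r]); used_t <- c(used_t, pairs$truth[r])
    }
  }
  nm <- if (is.null(matched)) 0L else nrow(matched)
  precision <- if (nd == 0) 1 else nm / nd
  recall <- if (nt == 0) 1 else nm / nt
  confusion <- NULL
  if (!is.null(run$history)) {
    fm <- run$history$forest_mask
    confusion <- table(truth = truth$burn_count[fm],
                       detected = run$history$burn_count[fm])
  }
  coef_recovery <- NULL
  if (!is.null(run$stats$recovery)) {
    rec <- run$stats$recovery
    cfg <- truth$config
    rec$truth <- ifelse(rec$effect == "n_fires",
                        cfg$fp_coef_nfires[rec$response],
                        cfg$fp_coef_months[rec$response])
    rec$within_2se <- abs(rec$estimate - rec$truth) <= 2 * rec$se
    coef_recovery <- rec
  }
  structure(list(n_truth = nt, n_detected = nd, n_matched = nm,
                 precision = precision, recall = recall,
                 vacuous = (nd == 0 && nt == 0),
                 month_errors = if (is.null(matched)) integer(0)
                                else matched$month_error,
                 matches = matched, confusion = confusion,
                 coef_recovery = coef_recovery),
            class = "evaluation")
}

#' @method print evaluation
#' @export
print.evaluation <- function(x, ...) {
  cat(sprintf("<evaluation> precision %.3f  recall %.3f  (%d/%d matched%s)\n",
              x$precision, x$recall, x$n_matched, max(x$n_truth, x$n_detected),
              if (x$vacuous) "; vacuous empty-vs-empty convention" else ""))
  if (length(x$month_errors) > 0)
    cat(sprintf("  fire-month error: mean abs %.2f, max abs %d\n",
                mean(abs(x$month_errors)), max(abs(x$month_errors))))
  invisible(x)
}
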