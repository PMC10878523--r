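#' SLIC superpixel segmentation
#'
#' Simple Linear Iterative Clustering: localized k-means over joint
#' (spatial, spectral) space. Cluster centers are seeded on a regular grid of
#' spacing `S = sqrt(n_pixels / n_segments)`; each iteration assigns pixels
#' within a 2S window of each center by the combined distance
#' `D^2 = d_spectral^2 + compactness^2 * (d_spatial / S)^2` (bands are
#' z-scored first, so `compactness` is unitless; small values favour spectral
#' homogeneity). Orphaned fragments are merged into the dominant neighbouring
#' segment afterwards, so segments are spatially connected and every pixel
#' belongs to exactly one segment.
#'
#' @param image a [raster_grid], matrix, or list of these (multi-band)
#' @param n_segments requested number of segments (>= 1)
#' @param compactness spatial regularity weight
#' @param max_iter number of assignment/update sweeps
#' @return a `segment_set`: `labels` matrix plus per-segment `features`
#'   (size, centroid, mean/sd per band)
#' @export
slic_segment <- function(image, n_segments, compactness = 0.2, max_iter = 10) {
  bands <- as_band_list(image)
  nr <- nrow(bands[[1]]); nc <- ncol(bands[[1]]); npx <- nr * nc
  if (n_segments < 1) stop("n_segments must be >= 1")
  if (n_segments > npx) stop("n_segments exceeds pixel count")
  nb <- length(bands)
  # gap-fill with the band median before clustering; the same filled values
  # feed the segment features so they stay finite
  bands <- lapply(bands, function(b) {
    b[is.na(b)] <- median(b, na.rm = TRUE)
    b
  })
  feat <- vapply(bands, function(b) {
    v <- as.vector(b)
    s <- sd(v)
    if (!is.finite(s) || s == 0) s <- 1
    (v - mean(v)) / s
  }, numeric(npx))
  feat <- matrix(feat, npx, nb)
  if (n_segments == 1) {
    labels <- matrix(1L, nr, nc)
    return(segment_set(labels, bands))
  }

  S <- sqrt(npx / n_segments)
  cr <- seq(S / 2, nr, by = S); cc_ <- seq(S / 2, nc, by = S)
  centers <- expand.grid(r = cr, c = cc_)
  k <- nrow(centers)
  px_r <- rep(seq_len(nr), times = nc); px_c <- rep(seq_len(nc), each = nr)
  cf <- matrix(0, k, nb)
  for (j in seq_len(k)) {
    p0 <- (round(pmin(nc, pmax(1, centers$c[j]))) - 1L) * nr +
      round(pmin(nr, pmax(1, centers$r[j])))
    cf[j, ] <- feat[p0, ]
  }
  lab <- integer(npx); best <- rep(Inf, npx)
  for (it in seq_len(max_iter)) {
    best[] <- Inf; lab[] <- 0L
    for (j in seq_len(k)) {
      rwin <- which(abs(px_r - centers$r[j]) <= 2 * S &
                    abs(px_c - centers$c[j]) <= 2 * S)
      if (length(rwin) == 0) next
      dsp <- ((px_r[rwin] - centers$r[j])^2 + (px_c[rwin] - centers$c[j])^2) / S^2
      dft <- rowSums((feat[rwin, , drop = FALSE] -
                        matrix(cf[j, ], length(rwin), nb, byrow = TRUE))^2)
      d <- dft + compactness^2 * dsp
      upd <- d < best[rwin]
      best[rwin[upd]] <- d[upd]
      lab[rwin[upd]] <- j
    }
    # any pixel outside every window: nearest center by space
    off <- which(lab == 0L)
    if (length(off) > 0) {
      for (p in off) {
        d <- (px_r[p] - centers$r)^2 + (px_c[p] - centers$c)^2
        lab[p] <- which.min(d)
      }
    }
    for (j in seq_len(k)) {
      mine <- lab == j
      if (!any(mine)) next
      centers$r[j] <- mean(px_r[mine]); centers$c[j] <- mean(px_c[mine])
      cf[j, ] <- colMeans(feat[mine, , drop = FALSE])
    }
  }
  labels <- matrix(lab, nr, nc)
  labels <- enforce_connectivity(labels)
  segment_set(labels, bands)
}

as_band_list <- function(image) {
  if (inherits(image, "raster_grid")) image <- list(image)
  if (is.matrix(image)) image <- list(image)
  bands <- lapply(image, function(b)
    if (inherits(b, "raster_grid")) b$values else b)
  if (length(unique(lapply(bands, dim))) > 1)
    stop("bands have mismatching shapes")
  bands
}

# split disconnected fragments of each label, relabel the largest fragment
# with the original id and absorb the rest into their dominant neighbour
enforce_connectivity <- function(labels) {
  nr <- nrow(labels); nc <- ncol(labels)
  repeat {
    changed <- FALSE
    for (l in sort(unique(as.vector(labels)))) {
      comp <- .label_components_cpp(labels == l, 4L)
      ncomp <- max(comp)
      if (ncomp <= 1) next
      sizes <- tabulate(comp[comp > 0], ncomp)
      keep <- which.max(sizes)
      for (ci in seq_len(ncomp)) {
        if (ci == keep) next
        px <- which(comp == ci)
        nbv <- neighbour_values(labels, px)
        nbv <- nbv[nbv != l]
        labels[px] <- if (length(nbv) > 0)
          as.integer(names(which.max(table(nbv)))) else l
        changed <- changed || length(nbv) > 0
      }
    }
    if (!changed) break
  }
  # compact label ids
  matrix(match(labels, sort(unique(as.vector(labels)))), nr, nc)
}

neighbour_values <- function(labels, px) {
  nr <- nrow(labels); npx <- length(labels)
  r <- (px - 1L) %% nr + 1L; c_ <- (px - 1L) %/% nr + 1L
  nb <- c(px[r > 1] - 1L, px[r < nr] + 1L, px[c_ > 1] - nr,
          px[c_ < ncol(labels)] + nr)
  nb <- setdiff(nb[nb >= 1 & nb <= npx], px)
  labels[nb]
}

#' Per-segment feature table
#' @param labels integer matrix of segment ids (a partition of the grid)
#' @param bands list of band matrices
#' @return a `segment_set`
#' @export
segment_set <- function(labels, bands) {
  ids <- sort(unique(as.vector(labels)))
  nr <- nrow(labels)
  px_r <- rep(seq_len(nr), times = ncol(labels))
  px_c <- rep(seq_len(ncol(labels)), each = nr)
  lv <- as.vector(labels)
  feats <- data.frame(segment = ids,
                      size = as.vector(tabulate(lv, max(ids)))[ids],
                      centroid_row = vapply(ids, function(i) mean(px_r[lv == i]), 1),
                      centroid_col = vapply(ids, function(i) mean(px_c[lv == i]), 1))
  for (b in seq_along(bands)) {
    v <- as.vector(bands[[b]])
    feats[[paste0("mean_b", b)]] <- vapply(ids, function(i)
      mean(v[lv == i], na.rm = TRUE), 1)
    sdv <- vapply(ids, function(i) sd(v[lv == i], na.rm = TRUE), 1)
    sdv[is.na(sdv)] <- 0
    feats[[paste0("sd_b", b)]] <- sdv
  }
  if (any(!is.finite(as.matrix(feats))))
    stop("non-finite segment features")
  structure(list(labels = labels, features = feats), class = "segment_set")
}

#' @method print segment_set
#' @export
print.segment_set <- function(x, ...) {
  cat(sprintf("<segment_set> %d segments over %d x %d\n",
              nrow(x$features), nrow(x$labels), ncol(x$labels)))
  invisible(x)
}

#' Train a classifier on labeled segments and paint the map
#'
#' Object-based classification: a small feed-forward network (default,
#' mirroring a multi-layer-perceptron workflow) or multinomial logistic
#' regression is trained on per-segment spectral features (mean and sd per
#' band), every segment is assigned a class, and the per-pixel map is
#' obtained by painting segment labels. Deterministic for a fixed seed.
#'
#' @param segments a `segment_set`
#' @param labels training table: data.frame with `segment` + `class`, or
#'   `row` + `col` + `class` (points are mapped to their segment)
#' @param classifier `"mlp"` or `"logistic"`
#' @param hidden,decay,maxit network hyper-parameters (mlp only)
#' @param seed RNG seed for weight initialization
#' @return a `classified_map`: per-segment classes, painted factor matrix,
#'   and training accuracy
#' @export
train_and_classify <- function(segments, labels, classifier = c("mlp", "logistic"),
                               hidden = 4, decay = 1e-3, maxit = 300, seed = 1) {
  classifier <- match.arg(classifier)
  if (!"segment" %in% names(labels)) {
    if (!all(c("row", "col") %in% names(labels)))
      stop("labels need 'segment' or 'row'+'col' columns")
    labels$segment <- segments$labels[cbind(labels$row, labels$col)]
  }
  labels <- labels[!duplicated(labels$segment), , drop = FALSE]
  fcols <- grep("^(mean|sd)_b", names(segments$features), value = TRUE)
  X <- as.matrix(segments$features[, fcols, drop = FALSE])
  rownames(X) <- segments$features$segment
  tr_idx <- match(labels$segment, segments$features$segment)
  if (anyNA(tr_idx)) stop("training labels reference unknown segments")
  Xtr <- X[tr_idx, , drop = FALSE]
  if (anyNA(Xtr)) stop("training features contain missing values")
  y <- factor(labels$class)

  if (nlevels(y) < 2) {
    seg_class <- factor(rep(levels(y), nrow(X)), levels = levels(y))
    acc <- 1
  } else {
    mu <- colMeans(Xtr); s <- apply(Xtr, 2, sd); s[s == 0] <- 1
    Z <- scale(X, mu, s); Ztr <- Z[tr_idx, , drop = FALSE]
    if (classifier == "mlp") {
      fit <- with_seed(seed, nnet::nnet(Ztr, nnet::class.ind(y), size = hidden,
                                        decay = decay, maxit = maxit,
                                        softmax = TRUE, trace = FALSE))
      pr <- predict(fit, Z)
      seg_class <- factor(levels(y)[max.col(pr, ties.method = "first")],
                          levels = levels(y))
    } else {
      df <- data.frame(Ztr); df$.class <- y
      fit <- with_seed(seed, nnet::multinom(.class ~ ., df, trace = FALSE))
      seg_class <- factor(as.character(predict(fit, data.frame(Z))),
                          levels = levels(y))
    }
    acc <- mean(seg_class[tr_idx] == y)
  }
  map <- matrix(seg_class[match(segments$labels, segments$features$segment)],
                nrow(segments$labels), ncol(segments$labels))
  structure(list(segment_class = setNames(seg_class, segments$features$segment),
                 map = map, training_accuracy = acc, classifier = classifier),
            class = "classified_map")
}

#' @method print classified_map
#' @export
print.classified_map <- function(x, ...) {
  cat(sprintf("<classified_map> %s, %d segments, training accuracy %.3f\n",
              x$classifier, length(x$segment_class), x$training_accuracy))
  invisible(x)
}

#' Binary forest base map at archive start
#'
#' Median NDVI and NBR composites over the first years of the archive are
#' segmented with SLIC and classified forest / non-forest from the supplied
#' training labels. The resulting mask restricts all downstream time-series
#' analysis to pixels that were forest at the start of the record.
#'
#' @param archive a `scene_archive`
#' @param labels training table (see [train_and_classify()]); classes must
#'   include `"forest"`
#' @param base_years number of initial years to composite
#' @param n_segments,compactness SLIC parameters
#' @param ... passed to [train_and_classify()]
#' @return list with `mask` (logical matrix), `classified` and `segments`
#' @export
forest_base_map <- function(archive, labels, base_years = 1,
                            n_segments = 150, compactness = 0.2, ...) {
  idx <- seq_len(min(12 * base_years, length(archive$dates)))
  ndvi <- archive_index(archive, "NDVI")[, , idx, drop = FALSE]
  nbr <- archive_index(archive, "NBR")[, , idx, drop = FALSE]
  med <- function(a) apply(a, c(1, 2), median, na.rm = TRUE)
  segs <- slic_segment(list(med(ndvi), med(nbr)), n_segments, compactness)
  cls <- train_and_classify(segs, labels, ...)
  list(mask = cls$map == "forest", classified = cls, segments = segs)
}

#' Sample segment training labels from a reference land-cover map
#'
#' Labels a fraction of segments with their majority reference class —
#' stands in for the manual photo-interpretation that produces training data
#' for real archives.
#'
#' @param segments a `segment_set`
#' @param reference factor matrix of reference classes
#' @param fraction fraction of segments to label
#' @param seed RNG seed for the sample
#' @return data.frame with `segment` and `class`
#' @export
training_labels_from_truth <- function(segments, reference, fraction = 0.2,
                                       seed = 1) {
  ids <- segments$features$segment
  lv <- as.vector(segments$labels); rv <- as.character(reference)
  with_seed(seed, {
    take <- sample(ids, max(2, round(fraction * length(ids))))
    cls <- vapply(take, function(i) {
      names(which.max(table(rv[lv == i])))
    }, character(1))
    data.frame(segment = take, class = cls)
  })
}
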