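#' Proximity-map training target
#'
#' Builds the regression target for one annotation: for every pixel `p` of
#' the annotated region, the maximum over annotated points `pt` of a
#' unit-peak Gaussian kernel centred on `pt`,
#' `max_pt exp(-((y-py)^2/(2*sy^2) + (x-px)^2/(2*sx^2)))`.
#' Taking the maximum rather than the sum keeps pixels between two nearby
#' cells from outscoring the true centres, which is what allows touching
#' cells to be separated downstream.  Kernels are truncated at 3 sigma; an
#' empty point list yields the all-zero (background) target.
#'
#' @param ann a [training_annotation()].
#' @param sigma kernel width in pixels, scalar (isotropic, recommended for
#'   roughly spherical cells) or `c(sy, sx)`.  Choose a sigma smaller than
#'   the cell radius.
#' @return object of class `proximity_target`: list with `values` (matrix
#'   over the region, in `[0, 1]`), `sigma`, `region`.
#' @examples
#' a <- training_annotation("cell", 0, 0, c(0, 0, 20, 20),
#'                          points = cbind(10, 10))
#' tg <- build_target(a, sigma = 2)
#' tg$values[11, 11]      # 1 at the annotated point
#' tg$values[11, 13]      # exp(-0.5) two pixels away
#' @export
build_target <- function(ann, sigma) {
  stopifnot(inherits(ann, "training_annotation"))
  sigma <- as.numeric(sigma)
  if (length(sigma) == 1L) sigma <- c(sigma, sigma)
  if (length(sigma) != 2L || any(sigma <= 0)) stop("sigma must be positive")
  r <- ann$region
  ys <- r[1]:r[3]
  xs <- r[2]:r[4]
  vals <- matrix(0, length(ys), length(xs))
  if (nrow(ann$points)) {
    for (i in seq_len(nrow(ann$points))) {
      dy2 <- (ys - ann$points[i, 1])^2 / (2 * sigma[1]^2)
      dx2 <- (xs - ann$points[i, 2])^2 / (2 * sigma[2]^2)
      k <- exp(-outer(dy2, dx2, `+`))
      k[outer(dy2, dx2, `+`) > 4.5] <- 0  # truncate beyond 3 sigma
      vals <- pmax(vals, k)
    }
  }
  structure(list(values = vals, sigma = sigma, region = r),
            class = "proximity_target")
}

#' Train the proximity-map regressor
#'
#' Fits an ensemble of regression trees mapping per-pixel filter-bank
#' feature vectors to proximity-target values over the annotated regions.
#' Pixels are subsampled uniformly without replacement at `sample_rate`,
#' stratified per region.  One ensemble is fitted per annotated class.
#' Defaults: 30 trees, depth 10, minimum split 20 samples, sample rate
#' 1/5, `ceiling(n_features / 3)` features considered per node.
#'
#' @param volumes a [volume_image()] or list of them (the training set;
#'   annotations reference volumes by their `volume` index).
#' @param annotations list of [training_annotation()].
#' @param sigma proximity-kernel width in pixels (see [build_target()]).
#' @param n_trees,max_depth,min_split forest hyperparameters.
#' @param sample_rate fraction of annotated-region pixels used.
#' @param scales,include_raw filter-bank configuration
#'   (see [compute_filter_bank()]).
#' @param seed RNG seed; identical inputs and seed give identical models.
#' @return object of class `forest_model`.
#' @export
train_proximity <- function(volumes, annotations, sigma,
                            n_trees = 30, max_depth = 10, min_split = 20,
                            sample_rate = 1 / 5,
                            scales = c(1, 2, 4, 8, 16), include_raw = TRUE,
                            seed = 0) {
  if (inherits(volumes, "volume_image")) volumes <- list(volumes)
  if (length(annotations) == 0) stop("at least one annotation is required")
  stopifnot(all(vapply(annotations, inherits, TRUE, "training_annotation")))
  volumes <- lapply(volumes, normalize_volume)
  nch <- dim(volumes[[1]]$data)[5]
  for (v in volumes)
    if (dim(v$data)[5] != nch) stop("inconsistent channel count across volumes")
  fspec <- feature_spec(scales, include_raw, nch)

  # features are cached per annotated plane (several annotations may share
  # a plane, e.g. different classes)
  cache <- new.env(parent = emptyenv())
  plane_features <- function(vi, t, z) {
    key <- paste(vi, t, z, sep = ":")
    if (!is.null(cache[[key]])) return(cache[[key]])
    vol <- volumes[[vi]]
    d <- dim(vol$data)
    if (t < 0 || t >= d[1] || z < 0 || z >= d[2])
      stop(sprintf("annotation plane (t=%d, z=%d) out of range", t, z))
    fs <- compute_filter_bank(vol_plane(vol, t, z), scales, include_raw)
    cache[[key]] <- fs
    fs
  }

  set.seed(as.integer(seed))
  classes <- unique(vapply(annotations, `[[`, "", "class_id"))
  per_class <- setNames(vector("list", length(classes)), classes)
  for (ann in annotations) {
    vol <- volumes[[ann$volume]]
    d <- dim(vol$data)
    if (ann$region[3] >= d[3] || ann$region[4] >= d[4])
      stop("annotation region outside plane bounds")
    fs <- plane_features(ann$volume, ann$t, ann$z)
    X <- features_in_region(fs, ann$region)
    y <- as.vector(build_target(ann, sigma)$values)
    n <- length(y)
    keep <- sort(sample.int(n, max(1L, ceiling(n * sample_rate))))
    per_class[[ann$class_id]] <-
      c(per_class[[ann$class_id]], list(list(X = X[keep, , drop = FALSE],
                                             y = y[keep])))
  }

  forests <- lapply(per_class, function(parts) {
    X <- do.call(rbind, lapply(parts, `[[`, "X"))
    y <- unlist(lapply(parts, `[[`, "y"))
    if (length(y) < min_split)
      stop("fewer sampled pixels than the minimum split size")
    colnames(X) <- paste0("f", seq_len(ncol(X)))
    ranger::ranger(x = X, y = y,
                   num.trees = n_trees, max.depth = max_depth,
                   min.node.size = min_split,
                   mtry = ceiling(ncol(X) / 3),
                   # ranger takes seed 0 as "randomize"; shift to keep
                   # every user seed (including 0) reproducible
                   seed = (as.integer(seed) %% 2147483646L) + 1L,
                   num.threads = 1, verbose = FALSE)
  })

  structure(list(
    forests = forests,
    classes = classes,
    hyperparams = list(n_trees = n_trees, max_depth = max_depth,
                       min_split = min_split, sample_rate = sample_rate,
                       features_per_node_rule = "n/3"),
    feature_params = list(scales = scales, include_raw = include_raw,
                          n_channels = nch),
    feature_spec = fspec,
    n_features = nrow(fspec),
    kernel_sigma = if (length(sigma) == 1L) c(sigma, sigma) else sigma,
    seed = as.integer(seed),
    format_version = 1L
  ), class = "forest_model")
}

#' @export
print.forest_model <- function(x, ...) {
  cat(sprintf(
    "forest_model: classes [%s], %d features (%d scales%s, %d channel(s))\n",
    paste(x$classes, collapse = ", "), x$n_features,
    length(x$feature_params$scales),
    if (x$feature_params$include_raw) " + raw" else "",
    x$feature_params$n_channels))
  h <- x$hyperparams
  cat(sprintf("  trees=%d depth=%d min_split=%d sample_rate=%.3g sigma=(%g,%g)\n",
              h$n_trees, h$max_depth, h$min_split, h$sample_rate,
              x$kernel_sigma[1], x$kernel_sigma[2]))
  invisible(x)
}

#' Save/load a trained model
#'
#' The serialized file embeds the hyperparameters, feature specification
#' and kernel sigma used at training; `load_model` validates them and a
#' reloaded model predicts voxelwise-identically to the original.
#'
#' @param model a `forest_model` from [train_proximity()].
#' @param path file path.
#' @return `load_model` returns the `forest_model`.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "forest_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "forest_model") || is.null(model$format_version))
    stop("not a centrofind model file")
  expected <- nrow(feature_spec(model$feature_params$scales,
                                model$feature_params$include_raw,
                                model$feature_params$n_channels))
  if (expected != model$n_features ||
      model$forests[[1]]$num.independent.variables != model$n_features)
    stop("model feature specification does not match its ensemble")
  model
}

#' Predict a proximity map for one plane
#'
#' @param model a `forest_model`.
#' @param plane matrix `(y, x)` or array `(y, x, c)`, already normalized.
#' @param class class id to predict (default: first trained class).
#' @return matrix `(y, x)` of proximity scores clipped to `[0, 1]`.
#' @export
predict_plane <- function(model, plane, class = model$classes[1]) {
  fs <- compute_filter_bank(plane, model$feature_params$scales,
                            model$feature_params$include_raw)
  nf <- dim(fs)[3]
  if (nf != model$n_features)
    stop(sprintf("feature mismatch: plane yields %d features, model expects %d",
                 nf, model$n_features))
  X <- matrix(fs, nrow = prod(dim(fs)[1:2]), ncol = nf)
  colnames(X) <- paste0("f", seq_len(nf))
  p <- predict(model$forests[[class]], data = X, num.threads = 1)$predictions
  matrix(pmin(1, pmax(0, p)), dim(fs)[1], dim(fs)[2])
}

#' Predict a 3D proximity volume
#'
#' Evaluates each z-plane of the given timepoint independently with the 2D
#' regressor and stacks the per-plane proximity maps into a volume; the 3D
#' structure is exploited later by the blob-detection step.  The input
#' volume is percentile-normalized internally (same as during training).
#'
#' @param model a `forest_model`.
#' @param vol a [volume_image()].
#' @param t 0-based timepoint.
#' @param class class id to predict.
#' @param normalized set TRUE if `vol` is already normalized.
#' @return object of class `proximity_volume`: `values` array
#'   `(1, z, y, x)` in `[0, 1]`, `class_id`, `t0 = t`.
#' @export
predict_volume <- function(model, vol, t = 0, class = model$classes[1],
                           normalized = FALSE) {
  stopifnot(inherits(model, "forest_model"), inherits(vol, "volume_image"))
  if (dim(vol$data)[5] != model$feature_params$n_channels)
    stop("channel count does not match the model's feature specification")
  if (!normalized) vol <- normalize_volume(vol)
  d <- dim(vol$data)
  out <- array(0, dim = c(1, d[2], d[3], d[4]))
  for (z in seq_len(d[2]) - 1L)
    out[1, z + 1L, , ] <- predict_plane(model, vol_plane(vol, t, z), class)
  proximity_volume(out, class_id = class, t0 = t)
}

#' Predict proximity volumes for several timepoints and classes
#'
#' Computes the filter bank once per plane and reuses it across classes,
#' which roughly halves the cost of two-class (e.g. "cell" plus
#' "dividing") time-series prediction.
#'
#' @param model a `forest_model`.
#' @param vol a [volume_image()].
#' @param ts 0-based timepoints.
#' @param classes class ids (default: all trained classes).
#' @return named list (by class) of `proximity_volume` objects whose
#'   `values` have one leading slot per timepoint in `ts`.
#' @export
predict_series <- function(model, vol, ts = NULL, classes = model$classes) {
  stopifnot(inherits(model, "forest_model"), inherits(vol, "volume_image"))
  if (dim(vol$data)[5] != model$feature_params$n_channels)
    stop("channel count does not match the model's feature specification")
  vol <- normalize_volume(vol)
  d <- dim(vol$data)
  if (is.null(ts)) ts <- seq_len(d[1]) - 1L
  out <- lapply(classes, function(cl) array(0, c(length(ts), d[2], d[3], d[4])))
  names(out) <- classes
  nf <- model$n_features
  for (i in seq_along(ts)) {
    for (z in seq_len(d[2]) - 1L) {
      fs <- compute_filter_bank(vol_plane(vol, ts[i], z),
                                model$feature_params$scales,
                                model$feature_params$include_raw)
      X <- matrix(fs, nrow = prod(dim(fs)[1:2]), ncol = nf)
      colnames(X) <- paste0("f", seq_len(nf))
      for (cl in classes) {
        p <- predict(model$forests[[cl]], data = X,
                     num.threads = 1)$predictions
        out[[cl]][i, z + 1L, , ] <- matrix(pmin(1, pmax(0, p)), d[3], d[4])
      }
    }
  }
  lapply(setNames(classes, classes), function(cl)
    proximity_volume(out[[cl]], class_id = cl, t0 = ts[1], ts = ts))
}

#' Proximity volume container
#'
#' @param values array `(t, z, y, x)` of proximity scores in `[0, 1]`.
#' @param class_id cell class the map scores.
#' @param t0 0-based timepoint of the first slot.
#' @param ts optional explicit timepoint vector (defaults to consecutive).
#' @return object of class `proximity_volume`.
#' @export
proximity_volume <- function(values, class_id = "cell", t0 = 0, ts = NULL) {
  stopifnot(length(dim(values)) == 4L)
  if (min(values) < 0 || max(values) > 1)
    stop("proximity values must lie in [0, 1]")
  if (is.null(ts)) ts <- t0 + seq_len(dim(values)[1]) - 1L
  structure(list(values = values, class_id = class_id, ts = as.integer(ts)),
            class = "proximity_volume")
}
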