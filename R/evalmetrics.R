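#' Optimal tolerance-limited point matching and detection scoring
#'
#' Matches predicted centres to ground-truth centres one-to-one among all
#' pairs within the distance tolerance, maximizing the number of matches
#' and, among maximum matchings, minimizing the total distance (solved as
#' a maximum-weight bipartite matching).  Optimal matching is
#' order-independent, unlike greedy nearest-first matching, which can drop
#' matches in crossing configurations.
#'
#' Precision is the fraction of detections that are correct, recall the
#' fraction of true centres detected, and F1 their harmonic mean.
#' Conventions for empty sets: with no detections and no truth all three
#' scores are 1 (vacuous); with truth but no detections precision is 0.
#'
#' @param pred a [detection_set()] or numeric matrix with columns
#'   `(z, y, x)` (a leading `t` column is accepted and must be constant).
#' @param truth ground-truth centres, same formats as `pred`.
#' @param tolerance matching radius in voxels: scalar, or `c(rz, ry, rx)`
#'   to scale each axis before computing distances.
#' @return object of class `eval_result`: counts `tp, fp, fn`, scores
#'   `precision, recall, f1`, the `tolerance`, and `matches`, a data.frame
#'   of `(pred_index, truth_index, distance)` (1-based indices into the
#'   coordinate lists, Euclidean distance in the tolerance-scaled metric
#'   times the mean tolerance).
#' @examples
#' truth <- rbind(c(0, 0, 0), c(0, 0, 5))
#' pred  <- rbind(c(0, 0, 1), c(0, 0, 4))
#' match_and_score(pred, truth, tolerance = 2)$f1
#' @export
match_and_score <- function(pred, truth, tolerance) {
  P <- as_centre_matrix(pred)
  G <- as_centre_matrix(truth)
  tol <- as.numeric(tolerance)
  if (length(tol) == 1L) tol <- rep(tol, 3)
  if (length(tol) != 3L || any(tol <= 0)) stop("tolerance must be positive")
  m <- match_within(P, G, tol)
  tp <- nrow(m)
  fp <- nrow(P) - tp
  fn <- nrow(G) - tp
  precision <- if (tp + fp > 0) tp / (tp + fp) else if (fn > 0) 0 else 1
  recall <- if (tp + fn > 0) tp / (tp + fn) else if (fp > 0) 0 else 1
  f1 <- if (precision + recall > 0)
    2 * precision * recall / (precision + recall) else 0
  structure(list(tp = tp, fp = fp, fn = fn, precision = precision,
                 recall = recall, f1 = f1, tolerance = tol, matches = m),
            class = "eval_result")
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf("eval_result: tp=%d fp=%d fn=%d | P=%.3f R=%.3f F1=%.3f\n",
              x$tp, x$fp, x$fn, x$precision, x$recall, x$f1))
  invisible(x)
}

# Coerce detections / data frames / matrices to an n x 3 (z, y, x) matrix.
as_centre_matrix <- function(x) {
  if (inherits(x, "detection_set")) x <- x$records
  if (is.data.frame(x)) {
    stopifnot(all(c("z", "y", "x") %in% names(x)))
    return(cbind(x$z, x$y, x$x))
  }
  x <- as.matrix(x)
  if (length(x) == 0) return(matrix(numeric(0), ncol = 3))
  if (ncol(x) == 4L) {
    if (length(unique(x[, 1])) > 1L)
      stop("matching expects centres from a single timepoint")
    x <- x[, 2:4, drop = FALSE]
  }
  stopifnot(ncol(x) == 3L)
  x
}

# Maximum-cardinality, minimum-total-distance one-to-one matching among
# pairs with tolerance-scaled distance <= 1.  Returns a data.frame
# (pred_index, truth_index, distance); `distance` is in voxels for scalar
# tolerances.
match_within <- function(P, G, tol) {
  empty <- data.frame(pred_index = integer(0), truth_index = integer(0),
                      distance = numeric(0))
  if (nrow(P) == 0 || nrow(G) == 0) return(empty)
  Ps <- sweep(P, 2, tol, `/`)
  Gs <- sweep(G, 2, tol, `/`)
  d2 <- outer(rowSums(Ps^2), rowSums(Gs^2), `+`) - 2 * Ps %*% t(Gs)
  d <- sqrt(pmax(d2, 0)) * mean(tol)  # pmax keeps d2's dim
  ok <- which(d <= mean(tol) + 1e-9, arr.ind = TRUE)
  if (nrow(ok) == 0) return(empty)
  dist <- d[ok]
  # edge weight: any extra match outweighs any redistribution of distances
  big <- (length(dist) + 1) * (max(dist) + 1)
  np <- nrow(P)
  g <- igraph::make_bipartite_graph(
    types = c(rep(FALSE, np), rep(TRUE, nrow(G))),
    edges = as.vector(t(cbind(ok[, 1], np + ok[, 2]))),
    directed = FALSE)
  mm <- igraph::max_bipartite_match(g, weights = big - dist)
  mate <- mm$matching
  pi <- which(!is.na(mate[seq_len(np)]))
  ti <- mate[pi] - np
  key <- paste(ok[, 1], ok[, 2])
  dd <- dist[match(paste(pi, ti), key)]
  data.frame(pred_index = as.integer(pi), truth_index = as.integer(ti),
             distance = dd)
}

#' Score a batch of images
#'
#' @param preds list of detection sets (or centre matrices), one per image.
#' @param truths list of ground-truth centre lists, same length.
#' @param tolerance matching radius (see [match_and_score()]).
#' @return object of class `batch_score`: `per_image` data.frame of
#'   precision/recall/F1 per image and `summary` with the mean and sample
#'   standard deviation of each metric (`sd` is 0 with `n_images = 1`,
#'   flagged by `single_image = TRUE`).
#' @export
score_batch <- function(preds, truths, tolerance) {
  if (length(preds) != length(truths))
    stop("preds and truths must have the same length")
  rows <- lapply(seq_along(preds), function(i) {
    r <- match_and_score(preds[[i]], truths[[i]], tolerance)
    data.frame(image = i, tp = r$tp, fp = r$fp, fn = r$fn,
               precision = r$precision, recall = r$recall, f1 = r$f1)
  })
  per <- do.call(rbind, rows)
  n <- nrow(per)
  summ <- list(
    n_images = n,
    single_image = n == 1L,
    precision_mean = mean(per$precision),
    precision_sd = if (n > 1) sd(per$precision) else 0,
    recall_mean = mean(per$recall),
    recall_sd = if (n > 1) sd(per$recall) else 0,
    f1_mean = mean(per$f1),
    f1_sd = if (n > 1) sd(per$f1) else 0)
  structure(list(per_image = per, summary = summ), class = "batch_score")
}

#' @export
print.batch_score <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "batch_score over %d image(s): F1 %.3f +/- %.3f | P %.3f +/- %.3f | R %.3f +/- %.3f\n",
    s$n_images, s$f1_mean, s$f1_sd, s$precision_mean, s$precision_sd,
    s$recall_mean, s$recall_sd))
  invisible(x)
}
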