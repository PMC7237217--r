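#' Point-and-click training annotation
#'
#' One annotated 2D plane: a rectangular region plus the clicked cell-centre
#' points of one cell class.  An empty point list is valid and marks a
#' background-only region — annotating background is important for keeping
#' false positives down, since the regressor must also learn what is *not*
#' a cell centre.
#'
#' @param class_id label of the annotated cell class (character).
#' @param t,z 0-based timepoint and plane indices.
#' @param region axis-aligned rectangle `c(y0, x0, y1, x1)` (0-based,
#'   inclusive) with positive area.
#' @param points numeric matrix with columns `(y, x)` of centre clicks
#'   inside `region`; may have zero rows.
#' @param volume 1-based index of the source volume within the training set.
#' @return an object of class `training_annotation`.
#' @export
training_annotation <- function(class_id, t, z, region, points = NULL,
                                volume = 1L) {
  region <- as.numeric(region)
  if (length(region) != 4L || region[3] <= region[1] || region[4] <= region[2])
    stop("`region` must be c(y0, x0, y1, x1) with y1 > y0 and x1 > x0")
  if (is.null(points)) points <- matrix(numeric(0), ncol = 2)
  points <- as.matrix(points)
  if (ncol(points) != 2L) stop("`points` must have columns (y, x)")
  if (nrow(points) > 0) {
    inside <- points[, 1] >= region[1] & points[, 1] <= region[3] &
      points[, 2] >= region[2] & points[, 2] <= region[4]
    if (!all(inside)) stop("every point must lie inside `region`")
  }
  structure(list(class_id = as.character(class_id), t = as.integer(t),
                 z = as.integer(z), region = region, points = points,
                 volume = as.integer(volume)),
            class = "training_annotation")
}

#' Read/write annotations as structured text (JSON)
#'
#' @param annotations list of [training_annotation()].
#' @param path file path.
#' @return `read_annotations` returns a list of [training_annotation()].
#' @export
write_annotations <- function(annotations, path) {
  recs <- lapply(annotations, function(a)
    list(class_id = a$class_id, t = a$t, z = a$z, region = a$region,
         points = if (nrow(a$points)) unname(a$points) else list(),
         volume = a$volume))
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_annotations
#' @export
read_annotations <- function(path) {
  recs <- jsonlite::read_json(path, simplifyVector = TRUE,
                              simplifyDataFrame = FALSE)
  lapply(recs, function(r) {
    pts <- r$points
    if (is.list(pts)) pts <- do.call(rbind, pts)
    training_annotation(r$class_id, r$t, r$z, unlist(r$region), pts,
                        volume = r$volume %||% 1L)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Cell-centre detections
#'
#' A set of detected cell centres for one class: 0-based voxel coordinates
#' `(t, z, y, x)` with the detection score (blob response relative to the
#' per-timepoint maximum).  Rows are ordered by `t`, then score descending.
#'
#' @param records data.frame with columns `t, z, y, x, score` (and
#'   optionally `border`, flagging centres within an object radius of the
#'   volume border).
#' @param class_id detected class label.
#' @return an object of class `detection_set`.
#' @export
detection_set <- function(records = NULL, class_id = "cell") {
  if (is.null(records) || nrow(records) == 0) {
    records <- data.frame(t = integer(0), z = integer(0), y = integer(0),
                          x = integer(0), score = numeric(0),
                          border = logical(0))
  }
  if (!all(c("t", "z", "y", "x", "score") %in% names(records)))
    stop("records must have columns t, z, y, x, score")
  if (is.null(records$border)) records$border <- FALSE
  records <- records[order(records$t, -records$score,
                           records$z, records$y, records$x), , drop = FALSE]
  rownames(records) <- NULL
  if (anyDuplicated(records[c("t", "z", "y", "x")]))
    stop("duplicate detections at identical (t, z, y, x)")
  structure(list(records = records, class_id = as.character(class_id)),
            class = "detection_set")
}

#' @export
print.detection_set <- function(x, ...) {
  cat(sprintf("detection_set '%s': %d detections over %d timepoint(s)\n",
              x$class_id, nrow(x$records),
              length(unique(x$records$t))))
  if (nrow(x$records)) print(head(x$records, 5))
  invisible(x)
}

#' Save/load detections as CSV
#'
#' Columns `t, z, y, x, score, class`; one row per detection, 0-based
#' integer voxel indices, rows sorted by `t` then score descending.
#'
#' @param d a [detection_set()].
#' @param path CSV path.
#' @return `load_detections` returns a [detection_set()].
#' @export
save_detections <- function(d, path) {
  stopifnot(inherits(d, "detection_set"))
  df <- d$records[c("t", "z", "y", "x", "score")]
  # 17 significant digits: doubles survive the text round trip exactly
  df$score <- formatC(df$score, digits = 17, format = "g")
  df$class <- rep(d$class_id, nrow(df))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname save_detections
#' @export
load_detections <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  cls <- if (nrow(df)) df$class[1] else "cell"
  detection_set(df[setdiff(names(df), "class")], class_id = cls)
}
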