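#' Vial layout: regions of interest for each rearing vial
#'
#' @param rois Data frame with columns `vial`, `x_min`, `y_min`, `x_max`,
#'   `y_max`; 1-3 pairwise non-overlapping rectangles, vial ids increasing
#'   left to right.
#' @return Tibble of class `vial_layout`.
#' @export
vial_layout <- function(rois) {
  stopifnot(is.data.frame(rois), nrow(rois) >= 1, nrow(rois) <= 3,
            all(c("vial", "x_min", "y_min", "x_max", "y_max") %in% names(rois)))
  rois <- as_tibble(rois)[order(rois$x_min), ]
  if (nrow(rois) > 1L) {
    for (i in seq_len(nrow(rois) - 1L)) {
      if (rois$x_max[i] > rois$x_min[i + 1L]) abort("vial ROIs overlap")
    }
  }
  structure(rois, class = c("vial_layout", class(rois)))
}

#' Calibrate vial regions from backlit frames
#'
#' One-time calibration: locates up to `n_vials_max` vertical vial strips in
#' one or more grayscale frames of the backlit scene (vial walls darker than
#' background). Pixels are binarized by a two-class intensity split (1-D
#' 2-means, the minimum within-class variance threshold), the column-wise
#' foreground fraction is smoothed with a running mean, and the widest
#' plateaus above half the peak density become the vial ROIs, ordered left
#' to right. A manual `override` layout, when supplied, is returned
#' verbatim — the escape hatch when automatic calibration fails.
#'
#' @param frames A numeric matrix (rows = image rows, values in `[0,1]`) or
#'   a list of same-sized matrices (averaged).
#' @param n_vials_max Maximum number of vials to find (default 3).
#' @param override Optional [vial_layout()] (or data frame of ROIs)
#'   returned as-is.
#' @return A [vial_layout()].
#' @export
calibrate_vials <- function(frames, n_vials_max = 3, override = NULL) {
  if (!is.null(override)) {
    return(if (inherits(override, "vial_layout")) override else vial_layout(override))
  }
  if (is.matrix(frames)) frames <- list(frames)
  stopifnot(length(frames) >= 1, all(vapply(frames, is.matrix, logical(1))))
  dims <- vapply(frames, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    abort("calibration frames must share dimensions")
  }
  img <- Reduce(`+`, frames) / length(frames)
  px <- as.vector(img)
  if (diff(range(px)) < 1e-6) {
    abort("no vial-like region found (uniform image); supply a manual ROI override")
  }
  # two-class intensity split: 1-D k-means minimizes within-class variance;
  # a regular subsample of pixels is plenty for a global threshold
  if (length(px) > 1e5) px <- px[round(seq(1, length(px), length.out = 1e5))]
  km <- kmeans(px, centers = range(px), iter.max = 50)
  thr <- mean(km$centers)
  fg <- img < thr  # vials and specimens are darker than the backlight
  prof <- colMeans(fg)
  w <- max(3L, .largest_odd(round(ncol(img) / 50)))
  prof_s <- as.numeric(stats::filter(prof, rep(1 / w, w), sides = 2))
  prof_s[is.na(prof_s)] <- prof[is.na(prof_s)]
  cut <- 0.5 * max(prof_s)
  r <- rle(prof_s > cut)
  if (!any(r$values)) {
    abort("no vial-like region found; supply a manual ROI override")
  }
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- tibble(start = starts[r$values], end = ends[r$values],
                 width = r$lengths[r$values])
  runs <- runs[runs$width >= ncol(img) / 20, , drop = FALSE]  # discard slivers
  if (!nrow(runs)) abort("no vial-like region found; supply a manual ROI override")
  runs <- runs[order(-runs$width), , drop = FALSE]
  runs <- runs[seq_len(min(n_vials_max, nrow(runs))), , drop = FALSE]
  runs <- runs[order(runs$start), , drop = FALSE]
  vial_layout(tibble(
    vial = seq_len(nrow(runs)),
    x_min = runs$start - 1, y_min = 0,
    x_max = runs$end, y_max = nrow(img)
  ))
}

#' Assign detections to vials
#'
#' Sets each detection's `vial` to the ROI containing its box center;
#' detections whose center lies outside every ROI are dropped. A center on
#' a shared boundary goes to the lower vial id (deterministic tie-break).
#' Per-vial streams can then be tracked independently.
#'
#' @param detections Detection tibble.
#' @param layout A [vial_layout()].
#' @return The detections with `vial` filled in, out-of-ROI rows removed.
#' @export
assign_vials <- function(detections, layout) {
  stopifnot(is.data.frame(detections), inherits(layout, "vial_layout"))
  cx <- (detections$x_min + detections$x_max) / 2
  cy <- (detections$y_min + detections$y_max) / 2
  vial <- rep(NA_integer_, nrow(detections))
  for (i in order(layout$vial, decreasing = TRUE)) {
    hit <- cx >= layout$x_min[i] & cx <= layout$x_max[i] &
      cy >= layout$y_min[i] & cy <= layout$y_max[i]
    vial[hit] <- layout$vial[i]  # lower ids assigned last win boundary ties
  }
  out <- detections[!is.na(vial), , drop = FALSE]
  out$vial <- vial[!is.na(vial)]
  out
}
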