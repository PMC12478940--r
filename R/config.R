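#' Tracker and analysis configuration
#'
#' Bundles every tunable of the tracking / event-extraction pipeline with its
#' default. Defaults reproduce the study conditions of a 14-day circadian
#' recording at one frame per 10 minutes.
#'
#' @param iou_threshold Minimum bounding-box IoU for association; association
#'   requires IoU strictly greater than this (default 0.6, i.e. "more than
#'   60%" overlap).
#' @param max_gap_frames A track may be re-observed after up to
#'   `max_gap_frames - 1` missed frames: candidates are tracks last seen at
#'   any of t-1, ..., t-`max_gap_frames` (default 4).
#' @param min_track_length Trajectories covering fewer than this many frames
#'   are discarded (default 30).
#' @param median_window Width of the centered median filter applied to each
#'   track's stage sequence; odd (default 5).
#' @param event_window_tau Width of the sliding majority window used to mark
#'   pupation/eclosion time points; odd (default 7).
#' @param frame_interval_min Minutes between consecutive frames (default 10).
#' @param tracked_classes Stages that found and extend tracks (default all
#'   four trackable stages). Detections of other classes are ignored by the
#'   tracker.
#' @return A list of class `tracker_config`.
#' @examples
#' cfg <- tracker_config()
#' cfg$iou_threshold
#' @export
tracker_config <- function(iou_threshold = 0.6,
                           max_gap_frames = 4L,
                           min_track_length = 30L,
                           median_window = 5L,
                           event_window_tau = 7L,
                           frame_interval_min = 10,
                           tracked_classes = stage_levels()) {
  stopifnot(
    is.numeric(iou_threshold), length(iou_threshold) == 1L,
    iou_threshold > 0, iou_threshold < 1,
    max_gap_frames >= 1, min_track_length >= 1,
    median_window >= 1, median_window %% 2 == 1,
    event_window_tau >= 1, event_window_tau %% 2 == 1,
    frame_interval_min > 0
  )
  if (!all(tracked_classes %in% stage_levels())) {
    abort("tracked_classes must be a subset of the four trackable stages")
  }
  structure(
    list(
      iou_threshold = iou_threshold,
      max_gap_frames = as.integer(max_gap_frames),
      min_track_length = as.integer(min_track_length),
      median_window = as.integer(median_window),
      event_window_tau = as.integer(event_window_tau),
      frame_interval_min = frame_interval_min,
      tracked_classes = tracked_classes
    ),
    class = "tracker_config"
  )
}

#' @export
print.tracker_config <- function(x, ...) {
  cat("<tracker_config>\n")
  for (nm in setdiff(names(x), "tracked_classes")) {
    cat(sprintf("  %-18s %s\n", nm, format(x[[nm]])))
  }
  cat(sprintf("  %-18s %s\n", "tracked_classes",
              paste(x$tracked_classes, collapse = ", ")))
  invisible(x)
}

#' Read or write a tracker configuration as YAML
#'
#' The on-disk format mirrors [tracker_config()] field for field; missing
#' fields take their defaults.
#'
#' @param path File path.
#' @return `read_tracker_config()`: a `tracker_config`.
#' @export
read_tracker_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(tracker_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    abort(paste0("unknown configuration field(s): ", paste(unknown, collapse = ", ")))
  }
  do.call(tracker_config, raw)
}

#' @rdname read_tracker_config
#' @param config A `tracker_config`.
#' @export
write_tracker_config <- function(config, path) {
  stopifnot(inherits(config, "tracker_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
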