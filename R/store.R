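#' Persist and reload pipeline results
#'
#' Saves tracks, events, sensor streams and the configuration snapshot into
#' a single self-describing JSON container with a versioned layout:
#' `meta` (format version, creation timestamp, configuration,
#' `frame_interval_min`), `tracks` (one column-oriented record per track:
#' frames, boxes, raw and smoothed stages, observed flags), a flat `events`
#' table, and `sensors` (one array per channel on a shared time axis).
#' Numbers are written at full precision so `load_results(save_results(x))`
#' reproduces every field; the format version is checked on read.
#'
#' @param tracks Track tibble ([track_detections()], possibly smoothed).
#' @param events Event tibble ([collect_events()]), or NULL.
#' @param sensors Optional tibble of sensor readings: `time_min` plus any of
#'   `temperature`, `humidity`, `pressure`, `light` (passthrough storage).
#' @param config A [tracker_config()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
save_results <- function(tracks, events = NULL, sensors = NULL,
                         config = attr(tracks, "config") %||% tracker_config(),
                         path) {
  stopifnot(is.data.frame(tracks))
  ids <- unique(tracks$track_id)
  track_recs <- lapply(ids, function(id) {
    tr <- tracks[tracks$track_id == id, , drop = FALSE]
    tr <- tr[order(tr$frame), , drop = FALSE]
    rec <- list(
      track_id = id,
      frames = tr$frame,
      x_min = tr$x_min, y_min = tr$y_min, x_max = tr$x_max, y_max = tr$y_max,
      stages_raw = stage_ordinal(tr$stage),
      observed = as.logical(tr$observed %||% rep(TRUE, nrow(tr)))
    )
    if (!is.null(tr$stage_smoothed)) rec$stages_smoothed <- stage_ordinal(tr$stage_smoothed)
    if (!is.null(tr$vial)) rec$vial <- tr$vial[1L]
    rec
  })
  obj <- list(
    meta = list(
      format_version = 1L,
      created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
      frame_interval_min = config$frame_interval_min,
      config = unclass(config),
      stage_codes = stats::setNames(as.list(0:3), stage_levels())
    ),
    tracks = track_recs,
    events = if (is.null(events) || !nrow(events)) NULL else {
      list(track_id = events$track_id, event_type = events$event_type,
           frame = events$frame, time_min = events$time_min)
    },
    sensors = if (is.null(sensors)) NULL else as.list(sensors)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null", pretty = FALSE)
  invisible(path)
}

#' @rdname save_results
#' @return `load_results()`: list with `tracks`, `events`, `sensors`
#'   tibbles (events/sensors may be NULL) and `config`.
#' @export
load_results <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  obj <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  ver <- obj$meta$format_version
  if (is.null(ver) || ver != 1L) {
    abort(sprintf("unsupported result format version: %s", ver %||% "missing"))
  }
  cfg_raw <- obj$meta$config
  cfg <- do.call(tracker_config, cfg_raw[names(formals(tracker_config))[
    names(formals(tracker_config)) %in% names(cfg_raw)]])
  tracks <- bind_rows(lapply(obj$tracks, function(rec) {
    tb <- tibble(
      track_id = rec$track_id,
      frame = as.integer(rec$frames),
      time_min = as.integer(rec$frames) * cfg$frame_interval_min,
      x_min = as.numeric(rec$x_min), y_min = as.numeric(rec$y_min),
      x_max = as.numeric(rec$x_max), y_max = as.numeric(rec$y_max),
      stage = ordinal_stage(as.integer(rec$stages_raw)),
      observed = as.logical(rec$observed)
    )
    if (!is.null(rec$stages_smoothed)) {
      tb$stage_smoothed <- ordinal_stage(as.integer(rec$stages_smoothed))
    }
    if (!is.null(rec$vial)) tb$vial <- rec$vial
    tb
  }))
  if (!nrow(tracks)) {
    tracks <- tibble(track_id = integer(), frame = integer(), time_min = numeric(),
                     x_min = numeric(), y_min = numeric(), x_max = numeric(),
                     y_max = numeric(), stage = character(), observed = logical())
  }
  attr(tracks, "config") <- cfg
  events <- if (is.null(obj$events)) NULL else {
    tibble(track_id = as.integer(obj$events$track_id),
           event_type = as.character(obj$events$event_type),
           frame = as.integer(obj$events$frame),
           time_min = as.numeric(obj$events$time_min))
  }
  sensors <- if (is.null(obj$sensors)) NULL else as_tibble(obj$sensors)
  list(tracks = tracks, events = events, sensors = sensors, config = cfg)
}

#' Export events or a periodogram as CSV
#'
#' Plain CSV export for downstream chronobiology tooling.
#'
#' @param x Event tibble or `ls_periodogram`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
export_csv <- function(x, path) {
  if (inherits(x, "ls_periodogram")) x <- tidy(x)
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

#' Run the full analysis pipeline on a detection file
#'
#' Ingest, optional vial assignment, tracking, stage smoothing, short-track
#' filtering, event extraction and rhythm estimation, with optional
#' persistence — everything downstream of the detector in one call. Fully
#' deterministic for fixed inputs.
#'
#' @param detections_path JSON-lines detection file (see
#'   [read_detections()]), or a detection tibble.
#' @param config A [tracker_config()] or path to a YAML config.
#' @param out_path Optional path: results are saved there via
#'   [save_results()].
#' @param layout Optional [vial_layout()]; when given, detections are
#'   assigned to vials first and each vial is tracked independently.
#' @param event_type Event type fed to the rhythm analysis (default
#'   `"eclosion"`, the circadian readout).
#' @param sensors Optional sensor tibble stored alongside.
#' @return List of class `pipeline_summary`: `tracks`, `events`,
#'   `periodogram` (NULL if too few events), and counts
#'   (`n_detections`, `n_tracks`, `n_pupation`, `n_eclosion`,
#'   `peak_period_h`, `p_value`).
#' @export
run_pipeline <- function(detections_path, config = tracker_config(),
                         out_path = NULL, layout = NULL,
                         event_type = "eclosion", sensors = NULL) {
  if (is.character(config)) config <- read_tracker_config(config)
  dets <- if (is.data.frame(detections_path)) detections_path else {
    read_detections(detections_path, dialect = "jsonl")
  }
  if (!is.null(layout)) dets <- assign_vials(dets, layout)
  tracks <- track_detections(dets, config)
  if (nrow(tracks)) {
    tracks <- smooth_stages(tracks, window = config$median_window)
    tracks <- filter_short_tracks(tracks, min_len = config$min_track_length)
  }
  events <- collect_events(tracks, config)
  ev_sel <- events[events$event_type == event_type, , drop = FALSE]
  periodogram <- if (nrow(ev_sel) >= 8L) {
    tryCatch(estimate_rhythm(ev_sel), error = function(e) NULL)
  } else NULL
  if (!is.null(out_path)) {
    save_results(tracks, events, sensors = sensors, config = config, path = out_path)
  }
  structure(
    list(
      tracks = tracks, events = events, periodogram = periodogram,
      n_detections = nrow(dets),
      n_tracks = length(unique(tracks$track_id)),
      n_pupation = sum(events$event_type == "pupation"),
      n_eclosion = sum(events$event_type == "eclosion"),
      peak_period_h = if (is.null(periodogram)) NA_real_ else periodogram$peak_period_h,
      p_value = if (is.null(periodogram)) NA_real_ else periodogram$p_value
    ),
    class = "pipeline_summary"
  )
}

#' @export
print.pipeline_summary <- function(x, ...) {
  cat("<pipeline_summary>\n")
  cat(sprintf("  detections: %d   tracks kept: %d\n", x$n_detections, x$n_tracks))
  cat(sprintf("  pupation events: %d   eclosion events: %d\n",
              x$n_pupation, x$n_eclosion))
  if (!is.na(x$peak_period_h)) {
    cat(sprintf("  rhythm peak: %.2f h (p = %.3g)\n", x$peak_period_h, x$p_value))
  } else {
    cat("  rhythm: not estimated (too few events)\n")
  }
  invisible(x)
}

#' @rdname run_pipeline
#' @param x A `pipeline_summary`.
#' @param ... Unused.
#' @return `glance()`: one-row tibble of the summary counts.
#' @export
glance.pipeline_summary <- function(x, ...) {
  tibble(n_detections = x$n_detections, n_tracks = x$n_tracks,
         n_pupation = x$n_pupation, n_eclosion = x$n_eclosion,
         peak_period_h = x$peak_period_h, p_value = x$p_value)
}
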