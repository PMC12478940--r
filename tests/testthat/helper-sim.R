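# A small, fast colony for unit tests: 6 animals, 60 h at 10-min frames
# (360 frames), development compressed so all stages appear.
small_colony <- function(seed = 11, n_animals = 6L) {
  simulate_colony(
    rhythm_preset("iso31", duration_h = 60, onset_h = 30, n_animals = n_animals),
    seed = seed,
    pupal_duration_h = 20, wander_h = 6
  )
}

# Detections for one stationary box over a frame range.
stationary_dets <- function(frames, box = c(0, 0, 100, 44), stage = "full_pupa",
                            jitter = 0) {
  tibble::tibble(
    frame = frames,
    x_min = box[1] + rnorm(length(frames), 0, jitter),
    y_min = box[2] + rnorm(length(frames), 0, jitter),
    x_max = box[3] + rnorm(length(frames), 0, jitter),
    y_max = box[4] + rnorm(length(frames), 0, jitter),
    stage = stage
  )
}

# Map each kept track to the ground-truth object whose boxes it reproduces
# (noise-free scenes: exact coordinate equality). Returns a tibble
# track_id -> object with the count of distinct objects per track.
match_tracks_to_objects <- function(tracks, truth) {
  key <- function(f, x, y) paste(f, round(x, 6), round(y, 6), sep = "|")
  truth_key <- key(truth$frame, truth$x_min, truth$y_min)
  obj <- truth$object[match(key(tracks$frame, tracks$x_min, tracks$y_min), truth_key)]
  out <- tibble::tibble(track_id = tracks$track_id, object = obj)
  dplyr::summarise(dplyr::group_by(out, track_id),
                   n_objects = dplyr::n_distinct(object),
                   object = object[1], .groups = "drop")
}

# Match tracks to specimens by pupal-site proximity (robust to box jitter).
match_tracks_to_specimens <- function(tracks, animals) {
  stage_col <- if ("stage_smoothed" %in% names(tracks)) "stage_smoothed" else "stage"
  pup <- tracks[tracks[[stage_col]] %in% c("full_pupa", "empty_pupa"), , drop = FALSE]
  agg <- dplyr::summarise(
    dplyr::group_by(pup, track_id),
    cx = median((x_min + x_max) / 2), cy = median((y_min + y_max) / 2),
    .groups = "drop"
  )
  agg$specimen <- vapply(seq_len(nrow(agg)), function(i) {
    which.min((animals$site_x - agg$cx[i])^2 + (animals$site_y - agg$cy[i])^2)
  }, integer(1))
  agg
}
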