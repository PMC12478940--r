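#' Median-smooth developmental stage sequences
#'
#' Applies a centered running median (default width 5) to each track's stage
#' sequence on the ordinal scale (larva = 0 < full pupa = 1 < empty pupa = 2
#' < adult = 3) and decodes the result back to stage labels. Isolated
#' per-frame misclassifications disappear while genuine transitions (runs
#' longer than half the window) survive in place. The first and last
#' `floor(window/2)` frames of each track keep their raw labels (the
#' centered window does not fit there). Boxes and positions are untouched.
#'
#' Smoothing expects the gapless sequences produced by the tracker (inferred
#' frames carry the held stage), so the filter never sees missing frames.
#'
#' @param tracks Track tibble from [track_detections()].
#' @param window Odd window width, default 5.
#' @return The input with a `stage_smoothed` column added (or replaced).
#' @examples
#' tr <- tibble::tibble(track_id = 1, frame = 0:4, stage =
#'   c("full_pupa", "full_pupa", "empty_pupa", "full_pupa", "full_pupa"))
#' smooth_stages(tr)$stage_smoothed  # the isolated empty_pupa is removed
#' @export
smooth_stages <- function(tracks, window = 5L) {
  stopifnot(is.data.frame(tracks), window >= 1, window %% 2 == 1)
  tracks <- as_tibble(tracks)
  tracks <- tracks[order(tracks$track_id, tracks$frame), , drop = FALSE]
  ords <- stage_ordinal(tracks$stage)
  smoothed <- unlist(lapply(
    split(ords, tracks$track_id),
    function(x) {
      if (length(x) <= 2L || window == 1L) return(x)
      as.integer(runmed(x, k = min(window, .largest_odd(length(x))), endrule = "keep"))
    }
  ), use.names = FALSE)
  # split() orders groups by factor level; scatter back to original rows
  idx <- unlist(split(seq_len(nrow(tracks)), tracks$track_id), use.names = FALSE)
  out <- integer(nrow(tracks))
  out[idx] <- smoothed
  tracks$stage_smoothed <- ordinal_stage(out)
  tracks
}

.largest_odd <- function(n) if (n %% 2 == 1L) n else n - 1L

#' Discard short trajectories
#'
#' Long recordings accumulate thousands of short spurious trajectories,
#' mostly from adult flies that move too fast to be tracked at a 10-minute
#' frame interval. Tracks covering fewer than `min_len` frames (gap-filled
#' frames count towards the length) are removed; order is preserved.
#'
#' @param tracks Track tibble.
#' @param min_len Minimum number of covered frames to keep a track
#'   (default 30): tracks below 30 are discarded, tracks of exactly 30 kept.
#' @return Filtered track tibble (attributes preserved).
#' @export
filter_short_tracks <- function(tracks, min_len = 30L) {
  stopifnot(is.data.frame(tracks))
  len <- table(tracks$track_id)
  keep_ids <- as.integer(names(len)[len >= min_len])
  out <- tracks[tracks$track_id %in% keep_ids, , drop = FALSE]
  attr(out, "config") <- attr(tracks, "config")
  out
}

#' Extract pupation and eclosion time points from one track
#'
#' Scans the smoothed stage sequence with a sliding window of `tau` frames:
#' a time point `t` is marked as the event time if a majority (at least
#' `ceiling(tau/2)`, i.e. 4 of 7 under the default) of the frames
#' `t, ..., t + tau - 1` carry the full-pupa class (pupation) or the
#' empty-pupa class (eclosion). The earliest qualifying `t` is reported,
#' which systematically precedes the visible transition by up to
#' `floor(tau/2)` frames — a known, documented bias of the rule. Windows
#' that would run past the end of the track are not evaluated. Pupation
#' additionally requires some earlier frame with a different label (a track
#' that begins as a full pupa was already pupated when first seen); a
#' pupation window found after the eclosion point is discarded so that
#' reported events always appear in developmental order.
#'
#' @param track Rows of a single track (tibble with `frame` and
#'   `stage_smoothed`), gapless and smoothed.
#' @param tau Odd window width, default 7.
#' @param frame_interval_min Minutes per frame (used for `time_min`).
#' @return Tibble with columns `track_id`, `event_type`
#'   (`"pupation"`/`"eclosion"`), `frame`, `time_min`; zero to two rows.
#' @export
extract_events <- function(track, tau = 7L, frame_interval_min = 10) {
  stopifnot(is.data.frame(track), tau %% 2 == 1, tau >= 1)
  if (!"stage_smoothed" %in% names(track)) {
    abort("track has no stage_smoothed column; run smooth_stages() first")
  }
  if (length(unique(track$track_id %||% 1L)) > 1L) {
    abort("extract_events() works on a single track; see collect_events()")
  }
  track <- track[order(track$frame), , drop = FALSE]
  s <- track$stage_smoothed
  L <- length(s)
  need <- ceiling(tau / 2)
  find_onset <- function(lab) {
    if (L < tau) return(NA_integer_)
    hit <- as.integer(s == lab)
    # windowed counts over positions 1 .. L - tau + 1
    cs <- cumsum(c(0L, hit))
    wc <- cs[(tau + 1L):(L + 1L)] - cs[1:(L - tau + 1L)]
    pos <- which(wc >= need)
    if (length(pos)) pos[1L] else NA_integer_
  }
  pup <- find_onset("full_pupa")
  ecl <- find_onset("empty_pupa")
  # pupation only counts when the track was seen before pupating
  if (!is.na(pup) && !any(s[seq_len(pup - 1L)] != "full_pupa")) pup <- NA_integer_
  # developmental order: a pupation majority at/after the eclosion point is
  # a smoothing artifact, not a second pupation
  if (!is.na(pup) && !is.na(ecl) && pup > ecl) pup <- NA_integer_
  id <- if ("track_id" %in% names(track)) track$track_id[1L] else NA_integer_
  out <- tibble(
    track_id = id,
    event_type = c("pupation", "eclosion")[c(!is.na(pup), !is.na(ecl))],
    frame = track$frame[c(pup, ecl)[!is.na(c(pup, ecl))]]
  )
  out$time_min <- out$frame * frame_interval_min
  out
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Collect events across all tracks
#'
#' Runs [extract_events()] over every track and returns the concatenated
#' records sorted by time. For circadian analyses the record set is usually
#' restricted to eclosion events only.
#'
#' @param tracks Smoothed, filtered track tibble.
#' @param config A [tracker_config()]; supplies `event_window_tau` and
#'   `frame_interval_min`.
#' @param event_type Optional filter: `"pupation"` or `"eclosion"`.
#' @return Tibble `track_id, event_type, frame, time_min` sorted by time.
#' @export
collect_events <- function(tracks, config = attr(tracks, "config") %||% tracker_config(),
                           event_type = NULL) {
  stopifnot(is.data.frame(tracks))
  if (!nrow(tracks)) {
    return(tibble(track_id = integer(), event_type = character(),
                  frame = integer(), time_min = numeric()))
  }
  out <- bind_rows(lapply(
    split(tracks, tracks$track_id),
    extract_events,
    tau = config$event_window_tau,
    frame_interval_min = config$frame_interval_min
  ))
  if (!is.null(event_type)) {
    event_type <- match.arg(event_type, c("pupation", "eclosion"))
    out <- out[out$event_type == event_type, , drop = FALSE]
  }
  arrange(out, .data$time_min, .data$track_id)
}
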