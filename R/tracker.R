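#' Create an empty tracker state
#'
#' Holds the mutable bookkeeping of the frame-by-frame tracker: the active
#' tracks (those observed within the last `max_gap_frames` frames, each
#' represented by its last observed box and stage), the per-frame records
#' accumulated so far, and the next free track id.
#'
#' @param config A [tracker_config()].
#' @return A list of class `tracker_state`.
#' @export
tracker_state <- function(config = tracker_config()) {
  structure(
    list(
      config = config,
      # active-track table (parallel vectors)
      id = integer(), x_min = numeric(), y_min = numeric(),
      x_max = numeric(), y_max = numeric(), stage_ord = integer(),
      last_obs = integer(),
      next_id = 1L,
      last_frame = -Inf,
      records = list(),   # one matrix per processed frame
      n_dropped = 0L      # detections of untracked classes
    ),
    class = "tracker_state"
  )
}

# One accumulated record block: columns
# id, frame, x_min, y_min, x_max, y_max, stage_ord, observed
.rec_block <- function(id, frame, boxes, stage_ord, observed) {
  boxes <- unname(boxes)
  cbind(id = unname(id), frame = unname(frame),
        x_min = boxes[, 1L], y_min = boxes[, 2L],
        x_max = boxes[, 3L], y_max = boxes[, 4L],
        stage_ord = unname(stage_ord), observed = as.numeric(observed))
}

#' Advance the tracker by one frame
#'
#' Associates the detections of frame `frame` with the active tracks by
#' maximum-weight assignment on the dummy-augmented IoU matrix
#' ([build_association_matrix()], [solve_matching()]). Candidate tracks are
#' those last observed at any of the previous `max_gap_frames` frames, each
#' represented by its last observed box and raw (smoothing-free) stage.
#' Matched tracks are extended; if frames were skipped, the gap is filled
#' with the last observed box and stage, flagged as inferred
#' (`observed = FALSE`). Unmatched detections of tracked classes found new
#' tracks in reading order. Tracks unobserved for `max_gap_frames` frames
#' drop out of the candidate set (they are closed; the t-2..t-4 window
#' extends active tracks only, it does not reopen closed ones).
#'
#' @param state A `tracker_state`.
#' @param dets Data frame of detections for one frame: columns
#'   `x_min, y_min, x_max, y_max, stage` (may have zero rows).
#' @param frame Integer frame index, strictly greater than any frame already
#'   processed.
#' @return The updated `tracker_state`.
#' @export
track_step <- function(state, dets, frame) {
  cfg <- state$config
  frame <- as.integer(frame)
  if (frame <= state$last_frame) {
    abort(sprintf("out-of-order frame: %d after %d", frame, as.integer(state$last_frame)))
  }
  state$last_frame <- frame

  # retire tracks that have fallen out of the association window
  stale <- state$last_obs < frame - cfg$max_gap_frames
  if (any(stale)) {
    keep <- !stale
    for (f in c("id", "x_min", "y_min", "x_max", "y_max", "stage_ord", "last_obs")) {
      state[[f]] <- state[[f]][keep]
    }
  }

  if (is.null(dets)) dets <- tibble(x_min = numeric(), y_min = numeric(),
                                    x_max = numeric(), y_max = numeric(),
                                    stage = character())
  tracked <- dets$stage %in% cfg$tracked_classes
  state$n_dropped <- state$n_dropped + sum(!tracked)
  dets <- dets[tracked, , drop = FALSE]
  n <- nrow(dets)
  m <- length(state$id)

  matched_det <- integer(0)
  if (m > 0L && n > 0L) {
    cand <- data.frame(
      x_min = state$x_min, y_min = state$y_min,
      x_max = state$x_max, y_max = state$y_max,
      stage = ordinal_stage(state$stage_ord)
    )
    A <- build_association_matrix(cand, dets, cfg)
    pairs <- solve_matching(A)
    if (nrow(pairs)) {
      db <- as.matrix(dets[, c("x_min", "y_min", "x_max", "y_max")])
      ti <- pairs$track; dj <- pairs$det
      # bridge skipped frames with the held box/stage, flagged inferred
      for (k in which(frame - state$last_obs[ti] > 1L)) {
        t1 <- ti[k]
        gap <- (state$last_obs[t1] + 1L):(frame - 1L)
        held <- matrix(c(state$x_min[t1], state$y_min[t1],
                         state$x_max[t1], state$y_max[t1]),
                       nrow = length(gap), ncol = 4L, byrow = TRUE)
        state$records[[length(state$records) + 1L]] <-
          .rec_block(state$id[t1], gap, held, state$stage_ord[t1], FALSE)
      }
      ords <- stage_ordinal(dets$stage[dj])
      state$records[[length(state$records) + 1L]] <-
        .rec_block(state$id[ti], frame, db[dj, , drop = FALSE], ords, TRUE)
      state$x_min[ti] <- db[dj, 1L]; state$y_min[ti] <- db[dj, 2L]
      state$x_max[ti] <- db[dj, 3L]; state$y_max[ti] <- db[dj, 4L]
      state$stage_ord[ti] <- ords
      state$last_obs[ti] <- frame
      matched_det <- dj
    }
  }

  new_idx <- setdiff(seq_len(n), matched_det)
  if (length(new_idx)) {
    db <- as.matrix(dets[new_idx, c("x_min", "y_min", "x_max", "y_max"), drop = FALSE])
    ids <- state$next_id + seq_along(new_idx) - 1L
    state$next_id <- state$next_id + length(new_idx)
    ords <- stage_ordinal(dets$stage[new_idx])
    state$records[[length(state$records) + 1L]] <-
      .rec_block(ids, frame, db, ords, TRUE)
    state$id <- c(state$id, ids)
    state$x_min <- c(state$x_min, db[, 1L]); state$y_min <- c(state$y_min, db[, 2L])
    state$x_max <- c(state$x_max, db[, 3L]); state$y_max <- c(state$y_max, db[, 4L])
    state$stage_ord <- c(state$stage_ord, ords)
    state$last_obs <- c(state$last_obs, rep(frame, length(new_idx)))
  }
  state
}

#' Track a detection stream into identity-preserving trajectories
#'
#' Drives [track_step()] over every frame of a detection table and returns
#' the assembled trajectories. Every detection of a tracked class ends up in
#' exactly one track; track ids are assigned in first-appearance order (by
#' frame, then reading order within the frame). The result is deterministic
#' for fixed input.
#'
#' @param detections Tibble of detections as produced by
#'   [read_detections()] or [corrupt_detections()]: columns `frame`,
#'   `x_min`, `y_min`, `x_max`, `y_max`, `stage` (others are carried along
#'   but ignored). Multiple vials should be tracked separately (see
#'   [assign_vials()]); if a `vial` column with more than one value is
#'   present, each vial is tracked independently and ids stay globally
#'   unique.
#' @param config A [tracker_config()].
#' @return Tibble with one row per track-frame: `track_id`, `frame`,
#'   `time_min`, `x_min`, `y_min`, `x_max`, `y_max`, `stage`, `observed`
#'   (FALSE for gap-filled, inferred records), plus `vial` if the input had
#'   one. The `tracker_config` used is attached as attribute `config`.
#' @examples
#' dets <- tibble::tibble(
#'   frame = rep(0:9, each = 1), x_min = 0, y_min = 0, x_max = 10, y_max = 10,
#'   stage = "full_pupa"
#' )
#' tr <- track_detections(dets)
#' nrow(tr)  # 10 frames, one track
#' @export
track_detections <- function(detections, config = tracker_config()) {
  stopifnot(is.data.frame(detections))
  need <- c("frame", "x_min", "y_min", "x_max", "y_max", "stage")
  miss <- setdiff(need, names(detections))
  if (length(miss)) abort(paste0("detections lack column(s): ", paste(miss, collapse = ", ")))

  has_vial <- "vial" %in% names(detections) &&
    length(unique(detections$vial[!is.na(detections$vial)])) > 1L
  if (has_vial) {
    # per-vial streams are tracked independently; NA-vial detections (not
    # assigned to any vial) form their own stream
    vials <- sort(unique(detections$vial), na.last = TRUE)
    offset <- 0L
    parts <- vector("list", length(vials))
    for (i in seq_along(vials)) {
      rows <- if (is.na(vials[i])) which(is.na(detections$vial)) else
        which(detections$vial == vials[i])
      sub_in <- detections[rows, , drop = FALSE]
      sub_in$vial <- NULL
      sub <- track_detections(sub_in, config)
      if (nrow(sub)) {
        sub$track_id <- sub$track_id + offset
        offset <- max(sub$track_id)
        sub$vial <- vials[i]
      }
      parts[[i]] <- sub
    }
    out <- bind_rows(parts)
    attr(out, "config") <- config
    attr(out, "n_dropped") <- sum(vapply(parts, function(p)
      attr(p, "n_dropped") %||% 0L, numeric(1)))
    return(out)
  }

  detections <- detections[order(detections$frame), , drop = FALSE]
  state <- tracker_state(config)
  frames <- unique(detections$frame)
  idx <- split(seq_len(nrow(detections)), factor(detections$frame, levels = frames))
  for (k in seq_along(frames)) {
    state <- track_step(state, detections[idx[[k]], , drop = FALSE], frames[k])
  }
  recs <- do.call(rbind, state$records)
  if (is.null(recs)) {
    out <- tibble(track_id = integer(), frame = integer(), time_min = numeric(),
                  x_min = numeric(), y_min = numeric(), x_max = numeric(),
                  y_max = numeric(), stage = character(), observed = logical())
  } else {
    o <- order(recs[, "id"], recs[, "frame"])
    recs <- recs[o, , drop = FALSE]
    rownames(recs) <- NULL
    out <- tibble(
      track_id = as.integer(recs[, "id"]),
      frame = as.integer(recs[, "frame"]),
      time_min = recs[, "frame"] * config$frame_interval_min,
      x_min = recs[, "x_min"], y_min = recs[, "y_min"],
      x_max = recs[, "x_max"], y_max = recs[, "y_max"],
      stage = ordinal_stage(as.integer(recs[, "stage_ord"])),
      observed = recs[, "observed"] > 0
    )
  }
  if ("vial" %in% names(detections) && nrow(out)) {
    out$vial <- detections$vial[1L]
  }
  attr(out, "config") <- config
  attr(out, "n_dropped") <- state$n_dropped
  out
}
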