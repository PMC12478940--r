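#' Plot developmental stage timelines of tracks
#'
#' One horizontal line per track, colored by (smoothed, if available)
#' developmental stage — a compact view of when each specimen pupated and
#' eclosed.
#'
#' @param tracks Track tibble.
#' @param max_tracks Cap on the number of tracks drawn (default 60).
#' @return A ggplot.
#' @export
plot_stage_timelines <- function(tracks, max_tracks = 60L) {
  stopifnot(is.data.frame(tracks))
  ids <- unique(tracks$track_id)
  tracks <- tracks[tracks$track_id %in% head(ids, max_tracks), , drop = FALSE]
  stage_col <- if ("stage_smoothed" %in% names(tracks)) "stage_smoothed" else "stage"
  df <- tibble(
    t_d = tracks$time_min / 60 / 24,
    track = factor(tracks$track_id),
    stage = factor(tracks[[stage_col]], levels = stage_levels())
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$t_d, .data$track, colour = .data$stage)) +
    ggplot2::geom_line(linewidth = 1.5) +
    ggplot2::labs(x = "time (days)", y = "track", colour = "stage")
}
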