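#' Read a detection stream
#'
#' Two dialects are supported. The canonical `jsonl` format holds one frame
#' per line, self-describing and append-friendly for long recordings:
#'
#' ```
#' {"frame":0,"time_min":0,"detections":[
#'   {"bbox":[450,450,550,550],"stage":"full_pupa","confidence":0.97,"vial":1}]}
#' ```
#'
#' Boxes are absolute pixel corners `(x_min, y_min, x_max, y_max)`, origin
#' top-left. The `yolo_txt` dialect reads a directory of per-frame text
#' files (`<anything>_<frameindex>.txt` or `<frameindex>.txt`, one line per
#' detection: `class cx cy w h [confidence]` in normalized center/size
#' coordinates) plus a sidecar `meta.yaml` declaring `image_width`,
#' `image_height`, `class_map` (class index in file order, 0-based, to stage
#' name) and optionally `frame_interval_min`; normalized coordinates are
#' converted to absolute corners.
#'
#' @param path File (`jsonl`) or directory (`yolo_txt`).
#' @param dialect `"jsonl"` or `"yolo_txt"`.
#' @return Detection tibble: `frame`, `time_min`, `x_min`, `y_min`,
#'   `x_max`, `y_max`, `stage`, `confidence`, `vial` (NA when absent),
#'   sorted by frame. Frames listed with no detections contribute no rows.
#' @export
read_detections <- function(path, dialect = c("jsonl", "yolo_txt")) {
  dialect <- match.arg(dialect)
  switch(dialect,
         jsonl = .read_jsonl(path),
         yolo_txt = .read_yolo(path))
}

.det_cols <- c("frame", "time_min", "x_min", "y_min", "x_max", "y_max",
               "stage", "confidence", "vial")

.empty_dets <- function() {
  tibble(frame = integer(), time_min = numeric(), x_min = numeric(),
         y_min = numeric(), x_max = numeric(), y_max = numeric(),
         stage = character(), confidence = numeric(), vial = integer())
}

.read_jsonl <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) return(.empty_dets())
  known <- c(stage_levels(trackable_only = FALSE))
  blocks <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    rec <- tryCatch(jsonlite::fromJSON(lines[i], simplifyVector = TRUE),
                    error = function(e) NULL)
    if (is.null(rec) || is.null(rec$frame)) {
      abort(sprintf("%s:%d: malformed frame record", path, i))
    }
    dets <- rec$detections
    if (is.null(dets) || NROW(dets) == 0L) next
    bb <- dets$bbox
    bb <- if (is.list(bb)) do.call(rbind, bb) else matrix(bb, ncol = 4L)
    if (ncol(bb) != 4L) abort(sprintf("%s:%d: bbox must have 4 coordinates", path, i))
    if (!all(dets$stage %in% known)) {
      abort(sprintf("%s:%d: unknown stage '%s'", path, i,
                    setdiff(dets$stage, known)[1L]))
    }
    blocks[[i]] <- tibble(
      frame = as.integer(rec$frame),
      time_min = as.numeric(rec$time_min %||% NA_real_),
      x_min = bb[, 1L], y_min = bb[, 2L], x_max = bb[, 3L], y_max = bb[, 4L],
      stage = dets$stage,
      confidence = as.numeric(dets$confidence %||% NA_real_),
      vial = as.integer(dets$vial %||% NA_integer_)
    )
  }
  out <- bind_rows(blocks)
  if (!nrow(out)) return(.empty_dets())
  if (any(out$confidence < 0 | out$confidence > 1, na.rm = TRUE)) {
    abort(paste0(path, ": confidence outside [0, 1]"))
  }
  arrange(out, .data$frame)
}

.read_yolo <- function(path) {
  if (!dir.exists(path)) abort(paste0("no such directory: ", path))
  meta_path <- file.path(path, "meta.yaml")
  if (!file.exists(meta_path)) abort(paste0("yolo_txt dialect needs a sidecar ", meta_path))
  meta <- yaml::read_yaml(meta_path)
  for (f in c("image_width", "image_height", "class_map")) {
    if (is.null(meta[[f]])) abort(paste0(meta_path, ": missing field ", f))
  }
  W <- meta$image_width; H <- meta$image_height
  cmap <- unlist(meta$class_map)  # 0-based class index -> stage name, file order
  interval <- meta$frame_interval_min %||% 10
  files <- sort(list.files(path, pattern = "\\.txt$", full.names = TRUE))
  blocks <- list()
  for (f in files) {
    fr <- suppressWarnings(as.integer(sub(".*?(\\d+)\\.txt$", "\\1", basename(f))))
    if (is.na(fr)) abort(paste0(f, ": cannot parse a frame index from the file name"))
    lines <- readLines(f, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    if (!length(lines)) next
    fields <- strsplit(trimws(lines), "\\s+")
    nf <- lengths(fields)
    if (any(nf < 5L | nf > 6L)) {
      abort(sprintf("%s:%d: expected 'class cx cy w h [conf]'", f, which(nf < 5L | nf > 6L)[1L]))
    }
    num <- suppressWarnings(lapply(fields, as.numeric))
    if (any(vapply(num, anyNA, logical(1)))) {
      abort(sprintf("%s:%d: non-numeric field", f, which(vapply(num, anyNA, logical(1)))[1L]))
    }
    m <- do.call(rbind, lapply(num, function(v) c(v, NA)[1:6]))
    cls_idx <- as.integer(m[, 1L])
    if (any(cls_idx < 0L | cls_idx >= length(cmap))) {
      abort(sprintf("%s: unknown class index %d", f, cls_idx[cls_idx < 0L | cls_idx >= length(cmap)][1L]))
    }
    blocks[[length(blocks) + 1L]] <- tibble(
      frame = fr, time_min = fr * interval,
      x_min = (m[, 2L] - m[, 4L] / 2) * W, y_min = (m[, 3L] - m[, 5L] / 2) * H,
      x_max = (m[, 2L] + m[, 4L] / 2) * W, y_max = (m[, 3L] + m[, 5L] / 2) * H,
      stage = unname(cmap[cls_idx + 1L]),
      confidence = m[, 6L], vial = NA_integer_
    )
  }
  out <- bind_rows(blocks)
  if (!nrow(out)) return(.empty_dets())
  arrange(out, .data$frame)
}

#' Write detections in the canonical JSON-lines dialect
#'
#' One frame per line; the exact inverse of `read_detections(dialect =
#' "jsonl")` (lossless roundtrip for all fields).
#'
#' @param detections Detection tibble (see [read_detections()]).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_detections <- function(detections, path) {
  stopifnot(is.data.frame(detections))
  frames <- sort(unique(detections$frame))
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (fr in frames) {
    d <- detections[detections$frame == fr, , drop = FALSE]
    rec <- list(
      frame = fr,
      time_min = d$time_min[1L],
      detections = lapply(seq_len(nrow(d)), function(k) {
        list(bbox = c(d$x_min[k], d$y_min[k], d$x_max[k], d$y_max[k]),
             stage = d$stage[k], confidence = d$confidence[k], vial = d$vial[k])
      })
    )
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA, null = "null",
                                na = "null"), con)
  }
  invisible(path)
}
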