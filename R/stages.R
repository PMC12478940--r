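#' Developmental stage labels
#'
#' The detector distinguishes five object classes: the four trackable
#' developmental stages of *Drosophila melanogaster* — wandering third-instar
#' larva, full (filled) pupa, empty pupa and adult fly — plus an
#' `out_of_focus` class that absorbs blurred background objects on the far
#' side of the vial. Out-of-focus detections are accepted by the readers but
#' never tracked or counted.
#'
#' The four trackable stages carry an ordinal code encoding developmental
#' order (`larva` = 0, `full_pupa` = 1, `empty_pupa` = 2, `adult` = 3). The
#' ordinal scale is what median smoothing of stage sequences operates on;
#' `adult` sits above `empty_pupa` so that pupal/adult confusions never
#' collapse into the larval range.
#'
#' @param trackable_only If `TRUE` (default) return only the four trackable
#'   stages, otherwise include `out_of_focus`.
#' @return `stage_levels()`: character vector of stage names in ordinal order.
#' @examples
#' stage_levels()
#' stage_ordinal(c("larva", "empty_pupa"))
#' @export
stage_levels <- function(trackable_only = TRUE) {
  lv <- c("larva", "full_pupa", "empty_pupa", "adult")
  if (trackable_only) lv else c(lv, "out_of_focus")
}

#' @rdname stage_levels
#' @param stage Character vector of stage names.
#' @return `stage_ordinal()`: integer ordinal codes (0-based); errors on
#'   `out_of_focus` or unknown names.
#' @export
stage_ordinal <- function(stage) {
  ord <- match(stage, stage_levels()) - 1L
  if (anyNA(ord)) {
    bad <- unique(stage[is.na(ord)])
    abort(paste0(
      "stage(s) without an ordinal code: ", paste(bad, collapse = ", "),
      " (only the four trackable stages have one)"
    ))
  }
  ord
}

#' @rdname stage_levels
#' @param ordinal Integer vector of ordinal codes in 0..3.
#' @return `ordinal_stage()`: character stage names.
#' @export
ordinal_stage <- function(ordinal) {
  if (any(ordinal < 0L | ordinal > 3L)) abort("ordinal codes must lie in 0..3")
  stage_levels()[ordinal + 1L]
}

# 4x4 logical adjacency over ordinals 0..3; row/col index = ordinal + 1.
# larva <-> full_pupa <-> empty_pupa chain; adult only adjacent to itself:
# an adult is a new free-moving object appearing at eclosion, not the
# continuation of the pupal case it left behind.
.stage_adjacency <- local({
  m <- diag(4) > 0
  m[1, 2] <- m[2, 1] <- TRUE  # larva <-> full_pupa
  m[2, 3] <- m[3, 2] <- TRUE  # full_pupa <-> empty_pupa
  m
})

#' Are two developmental stages the same or adjacent?
#'
#' Temporal association of a detection with a track requires, besides
#' sufficient bounding-box overlap, that the two records carry the same or
#' adjacent developmental stages. Adjacency follows the developmental chain
#' larva - full pupa - empty pupa; `adult` is adjacent only to itself
#' (eclosing adults found new tracks). The relation is symmetric and
#' reflexive: per-frame misclassifications may transiently "reverse" a stage
#' and are repaired later by median smoothing.
#'
#' @param a,b Character vectors of trackable stage names (recycled).
#' @return Logical vector.
#' @examples
#' stage_adjacent("full_pupa", "empty_pupa")  # TRUE
#' stage_adjacent("larva", "empty_pupa")      # FALSE
#' @export
stage_adjacent <- function(a, b) {
  .stage_adjacency[cbind(stage_ordinal(a) + 1L, stage_ordinal(b) + 1L)]
}
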