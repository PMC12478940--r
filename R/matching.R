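#' Intersection-over-union of axis-aligned bounding boxes
#'
#' Boxes are given in continuous pixel coordinates with origin at the top
#' left, as `(x_min, y_min, x_max, y_max)` with `x_max > x_min`,
#' `y_max > y_min`. IoU (the Jaccard index) is the ratio of intersection area
#' to union area, in `[0, 1]`; disjoint boxes score 0.
#'
#' @param a,b Numeric vectors of length 4, or 4-column matrices (rows paired,
#'   recycled if one side has a single row).
#' @return Numeric vector of IoU values.
#' @examples
#' bbox_iou(c(0, 0, 10, 10), c(5, 0, 15, 10))  # 1/3
#' @export
bbox_iou <- function(a, b) {
  a <- .as_box_matrix(a)
  b <- .as_box_matrix(b)
  if (nrow(a) == 1L && nrow(b) > 1L) a <- a[rep(1L, nrow(b)), , drop = FALSE]
  if (nrow(b) == 1L && nrow(a) > 1L) b <- b[rep(1L, nrow(a)), , drop = FALSE]
  stopifnot(nrow(a) == nrow(b))
  iw <- pmin(a[, 3], b[, 3]) - pmax(a[, 1], b[, 1])
  ih <- pmin(a[, 4], b[, 4]) - pmax(a[, 2], b[, 2])
  inter <- pmax(iw, 0) * pmax(ih, 0)
  union <- (a[, 3] - a[, 1]) * (a[, 4] - a[, 2]) +
    (b[, 3] - b[, 1]) * (b[, 4] - b[, 2]) - inter
  unname(inter / union)
}

.as_box_matrix <- function(x) {
  if (is.matrix(x)) {
    stopifnot(ncol(x) == 4L)
    m <- x
  } else {
    stopifnot(length(x) == 4L)
    m <- matrix(as.numeric(x), nrow = 1L)
  }
  if (any(m[, 3] <= m[, 1]) || any(m[, 4] <= m[, 2])) {
    abort("invalid bounding box: x_max must exceed x_min and y_max must exceed y_min")
  }
  m
}

# All-pairs IoU between the rows of two box matrices: (nrow(a) x nrow(b)).
iou_cross <- function(a, b) {
  m <- nrow(a); n <- nrow(b)
  if (m == 0L || n == 0L) return(matrix(numeric(0), m, n))
  iw <- outer(a[, 3], b[, 3], pmin) - outer(a[, 1], b[, 1], pmax)
  ih <- outer(a[, 4], b[, 4], pmin) - outer(a[, 2], b[, 2], pmax)
  inter <- pmax(iw, 0) * pmax(ih, 0)
  area_a <- (a[, 3] - a[, 1]) * (a[, 4] - a[, 2])
  area_b <- (b[, 3] - b[, 1]) * (b[, 4] - b[, 2])
  inter / (outer(area_a, area_b, `+`) - inter)
}

#' Is a detection admissible as the continuation of a track?
#'
#' A detection may extend a track only if the IoU of its box with the track's
#' last observed box strictly exceeds `config$iou_threshold` ("more than
#' 60%" under the default) and the two developmental stages are the same or
#' adjacent (see [stage_adjacent()]).
#'
#' @param track_box,det_box Length-4 numeric boxes (or paired 4-column
#'   matrices).
#' @param track_stage,det_stage Trackable stage names.
#' @param config A [tracker_config()].
#' @return Logical vector.
#' @export
admissible <- function(track_box, track_stage, det_box, det_stage,
                       config = tracker_config()) {
  bbox_iou(track_box, det_box) > config$iou_threshold &
    stage_adjacent(track_stage, det_stage)
}

#' Score placed in the association matrix for inadmissible pairs
#'
#' Any negative constant works: the solver maximizes, and pairing both
#' members with 0-scored dummies always beats an inadmissible pair.
#' @export
FORBIDDEN <- -1

#' Build the dummy-augmented association score matrix
#'
#' For `m` candidate tracks and `n` new detections the matrix has shape
#' `(m + n) x (n + m)`. The top-left `m x n` real block holds the IoU for
#' admissible pairs and [FORBIDDEN] otherwise; the dummy row/column blocks
#' are 0, so an unmatched track or detection is always assignable to a dummy
#' at no cost, and the bottom-right dummy-dummy block is 0 (dummies matching
#' each other carry no score). Maximizing total score over perfect matchings
#' of this matrix therefore associates exactly those pairs that beat leaving
#' both sides unmatched.
#'
#' @param tracks Data frame with columns `x_min, y_min, x_max, y_max, stage`
#'   (one row per candidate track, holding its last observed box and stage),
#'   or NULL/empty.
#' @param dets Data frame with the same columns (one row per detection).
#' @param config A [tracker_config()].
#' @return An object of class `association_matrix`: list with `scores`
#'   (the augmented matrix), `m` and `n`.
#' @export
build_association_matrix <- function(tracks, dets, config = tracker_config()) {
  m <- if (is.null(tracks)) 0L else nrow(tracks)
  n <- if (is.null(dets)) 0L else nrow(dets)
  scores <- matrix(0, m + n, n + m)
  if (m > 0L && n > 0L) {
    tb <- as.matrix(tracks[, c("x_min", "y_min", "x_max", "y_max")])
    db <- as.matrix(dets[, c("x_min", "y_min", "x_max", "y_max")])
    iou <- iou_cross(tb, db)
    adj <- .stage_adjacency[stage_ordinal(tracks$stage) + 1L,
                            stage_ordinal(dets$stage) + 1L, drop = FALSE]
    ok <- iou > config$iou_threshold & adj
    real <- ifelse(ok, iou, FORBIDDEN)
    scores[seq_len(m), seq_len(n)] <- real
  }
  structure(list(scores = scores, m = m, n = n), class = "association_matrix")
}

#' Solve the augmented assignment problem
#'
#' Finds a maximum-total-score perfect matching of the dummy-augmented
#' association matrix (Hungarian assignment) and returns only the real-real
#' pairs, i.e. actual track-detection associations. Each track and each
#' detection appears at most once; ties between equal-total matchings are
#' broken by a fixed deterministic solver order.
#'
#' @param A An `association_matrix` from [build_association_matrix()].
#' @return Tibble with columns `track` (row index into the candidate
#'   tracks), `det` (row index into the detections) and `score`.
#' @export
solve_matching <- function(A) {
  stopifnot(inherits(A, "association_matrix"))
  m <- A$m; n <- A$n
  if (m == 0L || n == 0L) {
    return(tibble(track = integer(), det = integer(), score = numeric()))
  }
  real <- A$scores[seq_len(m), seq_len(n), drop = FALSE]
  pairs <- max_weight_pairs(real)
  out <- tibble(
    track = as.integer(pairs[, 1L]),
    det = as.integer(pairs[, 2L]),
    score = real[pairs]
  )
  arrange(out, .data$track)
}

# Maximum-weight bipartite matching over the strictly positive entries of
# `real` (m x n). Entries <= 0 can never enter an optimal matching of the
# augmented problem, so the graph is first split into connected components
# of its positive edges and each component is solved as a square augmented
# assignment problem. Returns a 2-column integer matrix (track, det).
max_weight_pairs <- function(real) {
  m <- nrow(real); n <- ncol(real)
  pos <- which(real > 0, arr.ind = TRUE)
  if (nrow(pos) == 0L) return(matrix(integer(0), 0L, 2L))
  # connected components via union-find over track nodes 1..m, det nodes m+1..m+n
  parent <- seq_len(m + n)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  for (k in seq_len(nrow(pos))) {
    a <- find(pos[k, 1L]); b <- find(m + pos[k, 2L])
    if (a != b) parent[a] <- b
  }
  roots <- vapply(seq_len(m + n), find, integer(1))
  out <- vector("list", 0L)
  for (r in unique(roots[pos[, 1L]])) {
    tr <- which(roots[seq_len(m)] == r)
    dt <- which(roots[m + seq_len(n)] == r)
    sub <- real[tr, dt, drop = FALSE]
    if (length(tr) == 1L && length(dt) == 1L) {
      out[[length(out) + 1L]] <- cbind(tr, dt)
      next
    }
    sel <- solve_component(sub)
    if (nrow(sel)) {
      out[[length(out) + 1L]] <- cbind(tr[sel[, 1L]], dt[sel[, 2L]])
    }
  }
  res <- do.call(rbind, out)
  if (is.null(res)) matrix(integer(0), 0L, 2L) else res
}

# Solve one component: augment sub (mc x nc) with dummies to a square
# (mc+nc) matrix (dummy score 0), maximize via the Hungarian algorithm,
# return real-real selections with positive score.
solve_component <- function(sub) {
  mc <- nrow(sub); nc <- ncol(sub)
  size <- mc + nc
  aug <- matrix(0, size, size)
  aug[seq_len(mc), seq_len(nc)] <- sub
  assign <- lsap_min(max(aug) - aug)  # row -> col, maximization by reflection
  keep <- which(assign[seq_len(mc)] <= nc)
  keep <- keep[sub[cbind(keep, assign[keep])] > 0]
  cbind(keep, assign[keep])
}

# Square linear assignment (minimization) via the O(n^3) potentials /
# shortest augmenting path formulation. Finite costs required. Returns an
# integer vector: assign[i] = column assigned to row i. Deterministic:
# rows are inserted in order and column ties take the first minimum.
lsap_min <- function(cost) {
  n <- nrow(cost)
  stopifnot(ncol(cost) == n, all(is.finite(cost)))
  if (n == 0L) return(integer(0))
  u <- numeric(n)
  v <- numeric(n + 1L)       # index n+1 = virtual start column
  p <- integer(n + 1L)       # p[j] = row matched to column j (0 = free)
  way <- integer(n)
  for (i in seq_len(n)) {
    p[n + 1L] <- i
    j0 <- n + 1L
    minv <- rep(Inf, n)
    used <- logical(n + 1L)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]
      free <- which(!used[seq_len(n)])
      cur <- cost[i0, free] - u[i0] - v[free]
      upd <- cur < minv[free]
      if (any(upd)) {
        minv[free[upd]] <- cur[upd]
        way[free[upd]] <- j0
      }
      jrel <- which.min(minv[free])
      j1 <- free[jrel]
      delta <- minv[j1]
      ju <- which(used)
      u[p[ju]] <- u[p[ju]] + delta
      v[ju] <- v[ju] - delta
      jf <- which(!used[seq_len(n)])
      minv[jf] <- minv[jf] - delta
      j0 <- j1
      if (p[j0] == 0L) break
    }
    repeat {
      j1 <- way[j0]
      p[j0] <- p[j1]
      j0 <- j1
      if (j0 == n + 1L) break
    }
  }
  assign <- integer(n)
  assign[p[seq_len(n)]] <- seq_len(n)
  assign
}
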