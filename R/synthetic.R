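#' Rhythm presets for synthetic eclosion streams
#'
#' Encodes the circadian phenotypes used throughout the package's tests as
#' parameters of a raised-cosine inhomogeneous Poisson process,
#' `lambda(t) = baseline_rate * (1 + amplitude * cos(2*pi*(t - phase_h) / period_h))`
#' for `t >= onset_h` (zero before): wild-type `iso31` flies eclose with a
#' period of about 24 h in constant darkness, `per_short` mutants at 19 h,
#' `per_long` mutants at 28.3 h with a delayed onset of eclosion, and `per0`
#' mutants show no rhythm at all (amplitude 0). Eclosion begins only once
#' the first animals complete development, around day 4 (onset 96 h; 120 h
#' for the developmentally delayed `per_long`).
#'
#' @param name One of `"iso31"`, `"per_short"`, `"per_long"`, `"per0"`.
#' @param ... Field overrides (`period_h`, `amplitude`, `phase_h`,
#'   `baseline_rate`, `n_animals`, `duration_h`, `onset_h`).
#' @return List of class `rhythm_preset`.
#' @examples
#' rhythm_preset("iso31")$period_h       # 24
#' rhythm_preset("per_long")$onset_h     # 120
#' @export
rhythm_preset <- function(name = c("iso31", "per_short", "per_long", "per0"), ...) {
  name <- match.arg(name)
  base <- list(
    name = name,
    period_h = 24,
    amplitude = 0.8,
    phase_h = 0,
    baseline_rate = 0.5,
    n_animals = 50L,
    duration_h = 336,
    onset_h = 96
  )
  base <- switch(name,
    iso31 = base,
    per_short = utils::modifyList(base, list(period_h = 19)),
    per_long = utils::modifyList(base, list(period_h = 28.3, onset_h = 120)),
    per0 = utils::modifyList(base, list(amplitude = 0))
  )
  over <- list(...)
  bad <- setdiff(names(over), names(base))
  if (length(bad)) abort(paste0("unknown preset field(s): ", paste(bad, collapse = ", ")))
  p <- utils::modifyList(base, over)
  stopifnot(p$amplitude >= 0, p$amplitude <= 1, p$baseline_rate >= 0,
            p$period_h > 0, p$duration_h > p$onset_h)
  structure(p, class = "rhythm_preset")
}

# Eclosion intensity (events/h) of a preset at hours t.
preset_rate <- function(preset, t) {
  lam <- preset$baseline_rate *
    (1 + preset$amplitude * cos(2 * pi * (t - preset$phase_h) / preset$period_h))
  ifelse(t >= preset$onset_h & t <= preset$duration_h, pmax(lam, 0), 0)
}

#' Sample eclosion times from a rhythmic Poisson process
#'
#' Draws event times on `[onset_h, duration_h]` from the preset's
#' raised-cosine intensity by thinning a homogeneous Poisson process at the
#' peak rate. Identical seeds give identical draws.
#'
#' @param preset A [rhythm_preset()].
#' @param seed Optional integer seed.
#' @return Sorted numeric vector of event times in hours.
#' @export
sample_eclosion_times <- function(preset, seed = NULL) {
  stopifnot(inherits(preset, "rhythm_preset"))
  if (!is.null(seed)) set.seed(seed)
  lam_max <- preset$baseline_rate * (1 + preset$amplitude)
  if (lam_max <= 0) return(numeric(0))
  span <- preset$duration_h - preset$onset_h
  n_cand <- rpois(1L, lam_max * span)
  if (n_cand == 0L) return(numeric(0))
  cand <- runif(n_cand, preset$onset_h, preset$duration_h)
  keep <- runif(n_cand) < preset_rate(preset, cand) / lam_max
  sort(cand[keep])
}

# n iid draws from the density proportional to the preset intensity
# (event times conditioned on the count), by rejection.
sample_times_fixed_n <- function(preset, n) {
  lam_max <- preset$baseline_rate * (1 + preset$amplitude)
  out <- numeric(0)
  while (length(out) < n) {
    m <- 2L * (n - length(out)) + 10L
    cand <- runif(m, preset$onset_h, preset$duration_h)
    keep <- runif(m) < preset_rate(preset, cand) / lam_max
    out <- c(out, cand[keep])
  }
  sort(out[seq_len(n)])
}

#' Vial geometry for the synthetic colony
#'
#' Describes the imaged scene: up to three vertical rearing-vial strips in a
#' backlit frame. Units are pixels, origin top-left.
#'
#' @param width,height Frame size in pixels.
#' @param n_vials Number of vials, 1-3.
#' @param margin Inner margin (vial wall and food region) excluded from
#'   specimen placement, pixels.
#' @return List of class `vial_geometry` with a `rois` tibble
#'   (`vial`, `x_min`, `y_min`, `x_max`, `y_max`).
#' @export
vial_geometry <- function(width = 3900, height = 2800, n_vials = 3, margin = 100) {
  stopifnot(n_vials >= 1, n_vials <= 3, width > 0, height > 0)
  strip_w <- width / n_vials
  rois <- tibble(
    vial = seq_len(n_vials),
    x_min = (seq_len(n_vials) - 1) * strip_w + margin,
    y_min = margin,
    x_max = seq_len(n_vials) * strip_w - margin,
    y_max = height - margin
  )
  structure(list(width = width, height = height, n_vials = as.integer(n_vials),
                 margin = margin, strip_w = strip_w, rois = rois),
            class = "vial_geometry")
}

# box half-sizes per stage (px): wandering L3 larva, pupa (same case full or
# empty), adult fly. Chosen so that the larva -> pupa box change alone keeps
# IoU above the 60% association gate (concentric 92x36 vs 100x44 -> 0.75).
.box_half <- list(
  larva = c(46, 18),
  full_pupa = c(50, 22),
  empty_pupa = c(50, 22),
  adult = c(55, 25),
  out_of_focus = c(40, 20)
)

#' Simulate a ground-truth colony
#'
#' Generates per-frame ground-truth object records for a colony of
#' `preset$n_animals` specimens across the vials of `geometry`, sampled at
#' `config$frame_interval_min`. Each specimen ecloses at a time drawn from
#' the preset's rhythmic intensity; it pupariates `pupal_duration_h` earlier
#' at a fixed wall site (pupal boxes are stationary — the specimens do not
#' move during the pupal stage), wanders as a larva for the `wander_h` hours
#' before pupariation (a mean-reverting bounded-step walk around its site,
#' so consecutive-frame overlap always exceeds the tracker's IoU gate), and
#' at eclosion the full pupa becomes an empty pupa while a new adult object
#' appears, relocating to a random vial position every frame — adults move
#' far too fast to be trackable at a 10-minute frame interval. Pupation
#' sites are placed at least `min_separation` pixels apart so distinct
#' specimens can never overlap above the gate.
#'
#' @param preset A [rhythm_preset()].
#' @param seed Optional integer seed; all randomness flows through it.
#' @param geometry A [vial_geometry()].
#' @param config A [tracker_config()] (frame interval).
#' @param pupal_duration_h Hours from pupariation to eclosion (default 96).
#' @param wander_h Hours of visible larval wandering before pupariation
#'   (default 24; earlier instars stay in the food and are not modeled).
#' @param min_separation Minimum distance between pupation sites, pixels
#'   (default 150, far enough that distinct specimens never overlap).
#' @return List of class `colony_sim`: `truth` (tibble `object`, `specimen`,
#'   `frame`, `time_min`, boxes, `stage`, `vial`), `animals` (one row per
#'   specimen: site, vial, pupation/eclosion times and frames), `geometry`,
#'   `preset`, `config`.
#' @export
simulate_colony <- function(preset, seed = NULL, geometry = vial_geometry(),
                            config = tracker_config(),
                            pupal_duration_h = 96, wander_h = 24,
                            min_separation = 150) {
  stopifnot(inherits(preset, "rhythm_preset"), preset$n_animals >= 1)
  if (!is.null(seed)) set.seed(seed)
  n <- preset$n_animals
  interval_h <- config$frame_interval_min / 60
  n_frames <- as.integer(round(preset$duration_h / interval_h))
  frames <- 0:(n_frames - 1L)

  ecl_h <- sample_times_fixed_n(preset, n)
  ecl_h <- ecl_h[sample.int(n)]  # decouple eclosion order from site order
  pup_h <- pmax(ecl_h - pupal_duration_h, 0)
  onset_h <- pmax(pup_h - wander_h, 0)

  # pupation sites: rejection-sampled with minimum separation inside vials
  vial <- (seq_len(n) - 1L) %% geometry$n_vials + 1L
  site <- matrix(NA_real_, n, 2L)
  for (i in seq_len(n)) {
    roi <- geometry$rois[vial[i], ]
    inx <- min(60, 0.15 * (roi$x_max - roi$x_min))
    iny <- min(60, 0.15 * (roi$y_max - roi$y_min))
    placed <- FALSE
    for (try in 1:2000) {
      cand <- c(runif(1, roi$x_min + inx, roi$x_max - inx),
                runif(1, roi$y_min + iny, roi$y_max - iny))
      same <- which(vial == vial[i] & !is.na(site[, 1L]))
      if (!length(same) ||
          min(sqrt((site[same, 1L] - cand[1L])^2 + (site[same, 2L] - cand[2L])^2)) >= min_separation) {
        site[i, ] <- cand
        placed <- TRUE
        break
      }
    }
    if (!placed) abort("geometry too small for n_animals at the requested site separation")
  }

  pup_frame <- pmin(ceiling(pup_h / interval_h), n_frames)
  ecl_frame <- pmin(ceiling(ecl_h / interval_h), n_frames)
  onset_frame <- pmax(floor(onset_h / interval_h), 0L)

  blocks <- vector("list", 2L * n)
  for (i in seq_len(n)) {
    fr_all <- onset_frame[i]:(n_frames - 1L)
    nfr <- length(fr_all)
    stage <- character(nfr)
    stage[fr_all < pup_frame[i]] <- "larva"
    stage[fr_all >= pup_frame[i] & fr_all < ecl_frame[i]] <- "full_pupa"
    stage[fr_all >= ecl_frame[i]] <- "empty_pupa"
    # larval walk: displacement d around the site, OU-style pull with
    # bounded steps, reflected into |dx| <= 18, |dy| <= 12; the last 10 larval
    # frames descend linearly onto the site so the stage switch is seamless
    n_larva <- sum(stage == "larva")
    dx <- dy <- numeric(nfr)
    if (n_larva > 0L) {
      d <- c(runif(1, -18, 18), runif(1, -12, 12))
      for (k in seq_len(n_larva)) {
        d <- 0.97 * d + c(runif(1, -3.6, 3.6), runif(1, -2.4, 2.4))
        d[1L] <- .reflect(d[1L], 18); d[2L] <- .reflect(d[2L], 12)
        left <- n_larva - k
        shrink <- if (left < 10L) left / 10 else 1
        dx[k] <- d[1L] * shrink
        dy[k] <- d[2L] * shrink
      }
    }
    half <- matrix(0, nfr, 2L)
    half[stage == "larva", 1L] <- .box_half$larva[1L]
    half[stage == "larva", 2L] <- .box_half$larva[2L]
    half[stage != "larva", 1L] <- .box_half$full_pupa[1L]
    half[stage != "larva", 2L] <- .box_half$full_pupa[2L]
    cx <- site[i, 1L] + dx
    cy <- site[i, 2L] + dy
    blocks[[i]] <- tibble(
      object = i, specimen = i, frame = fr_all,
      x_min = cx - half[, 1L], y_min = cy - half[, 2L],
      x_max = cx + half[, 1L], y_max = cy + half[, 2L],
      stage = stage, vial = vial[i]
    )
    # adult object from eclosion onwards, teleporting inside its vial
    if (ecl_frame[i] <= n_frames - 1L) {
      fr_a <- ecl_frame[i]:(n_frames - 1L)
      roi <- geometry$rois[vial[i], ]
      inx <- min(60, 0.15 * (roi$x_max - roi$x_min))
      iny <- min(60, 0.15 * (roi$y_max - roi$y_min))
      ax <- runif(length(fr_a), roi$x_min + inx, roi$x_max - inx)
      ay <- runif(length(fr_a), roi$y_min + iny, roi$y_max - iny)
      blocks[[n + i]] <- tibble(
        object = n + i, specimen = i, frame = fr_a,
        x_min = ax - .box_half$adult[1L], y_min = ay - .box_half$adult[2L],
        x_max = ax + .box_half$adult[1L], y_max = ay + .box_half$adult[2L],
        stage = "adult", vial = vial[i]
      )
    }
  }
  truth <- bind_rows(blocks)
  truth$time_min <- truth$frame * config$frame_interval_min
  truth <- truth[order(truth$frame, truth$object),
                 c("object", "specimen", "frame", "time_min",
                   "x_min", "y_min", "x_max", "y_max", "stage", "vial")]
  animals <- tibble(
    specimen = seq_len(n), vial = vial,
    site_x = site[, 1L], site_y = site[, 2L],
    onset_h = onset_h, pupation_h = pup_h, eclosion_h = ecl_h,
    pupation_frame = as.integer(pup_frame), eclosion_frame = as.integer(ecl_frame)
  )
  structure(list(truth = as_tibble(truth), animals = animals,
                 geometry = geometry, preset = preset, config = config),
            class = "colony_sim")
}

.reflect <- function(x, lim) {
  if (x > lim) 2 * lim - x else if (x < -lim) -2 * lim - x else x
}

#' @export
print.colony_sim <- function(x, ...) {
  cat("<colony_sim>\n")
  cat(sprintf("  %d specimens in %d vial(s), %d frames (%s preset, period %.1f h)\n",
              nrow(x$animals), x$geometry$n_vials,
              length(unique(x$truth$frame)), x$preset$name, x$preset$period_h))
  invisible(x)
}

#' Detector noise model
#'
#' Emulates per-frame detector behavior: each true object is missed with a
#' per-class probability, otherwise its class is resampled from a confusion
#' row (a `background` outcome drops the detection, `out_of_focus` keeps the
#' box but marks it untrackable), its box corners are jittered, and spurious
#' out-of-focus detections are added at a per-frame rate. The default
#' confusion rows follow published per-class detector accuracies for this
#' kind of backlit vial imagery: full/empty pupae 95%/97%, adults 86% (12%
#' to out-of-focus), larvae 84% (8% to full pupae); off-diagonal mass not
#' individually reported is assigned to out-of-focus/background.
#'
#' @param preset `"detector"` (defaults above) or `"none"` (identity:
#'   detections equal ground truth).
#' @param miss Named per-class miss probabilities (applied before
#'   confusion; default 0 — misses are carried by the `background` column).
#' @param confusion Row-stochastic matrix, rows = true trackable classes,
#'   columns = `larva, full_pupa, empty_pupa, adult, out_of_focus,
#'   background`.
#' @param jitter_px Gaussian sd of corner jitter, pixels.
#' @param spurious_rate Expected spurious out-of-focus boxes per frame.
#' @return List of class `noise_model`.
#' @export
noise_model <- function(preset = c("detector", "none"), miss = NULL,
                        confusion = NULL, jitter_px = NULL, spurious_rate = NULL) {
  preset <- match.arg(preset)
  cls <- stage_levels()
  targets <- c(cls, "out_of_focus", "background")
  if (preset == "detector") {
    conf <- rbind(
      larva      = c(0.84, 0.08, 0.00, 0.00, 0.05, 0.03),
      full_pupa  = c(0.00, 0.95, 0.02, 0.00, 0.02, 0.01),
      empty_pupa = c(0.00, 0.01, 0.97, 0.00, 0.01, 0.01),
      adult      = c(0.00, 0.00, 0.01, 0.86, 0.12, 0.01)
    )
    def <- list(miss = stats::setNames(rep(0, 4), cls), confusion = conf,
                jitter_px = 1, spurious_rate = 2)
  } else {
    conf <- cbind(diag(4), matrix(0, 4, 2))
    rownames(conf) <- cls
    def <- list(miss = stats::setNames(rep(0, 4), cls), confusion = conf,
                jitter_px = 0, spurious_rate = 0)
  }
  nm <- def
  if (!is.null(miss)) nm$miss[names(miss)] <- miss
  if (!is.null(confusion)) nm$confusion <- confusion
  if (!is.null(jitter_px)) nm$jitter_px <- jitter_px
  if (!is.null(spurious_rate)) nm$spurious_rate <- spurious_rate
  colnames(nm$confusion) <- targets
  stopifnot(nrow(nm$confusion) == 4L,
            all(abs(rowSums(nm$confusion) - 1) < 1e-9),
            all(nm$confusion >= 0), all(nm$miss >= 0 & nm$miss <= 1),
            nm$jitter_px >= 0, nm$spurious_rate >= 0)
  structure(nm, class = "noise_model")
}

#' Corrupt ground truth into a noisy detection stream
#'
#' Applies a [noise_model()] to the per-frame ground-truth records of a
#' [simulate_colony()] result (or any truth-shaped tibble), yielding the
#' detection table the tracker consumes. Reproducible given a seed; the
#' `"none"` model returns the truth boxes unchanged (confidence 1).
#'
#' @param gt A `colony_sim` or a truth tibble.
#' @param noise A [noise_model()].
#' @param seed Optional integer seed.
#' @return Detection tibble: `frame`, `time_min`, boxes, `stage`,
#'   `confidence`, `vial`.
#' @export
corrupt_detections <- function(gt, noise = noise_model(), seed = NULL) {
  truth <- if (inherits(gt, "colony_sim")) gt$truth else gt
  stopifnot(is.data.frame(truth), inherits(noise, "noise_model"))
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(truth)
  keep <- runif(n) >= noise$miss[truth$stage]
  det <- truth[keep, , drop = FALSE]
  # class resampling, grouped by true class for vectorized draws
  new_stage <- det$stage
  for (cl in stage_levels()) {
    rows <- which(det$stage == cl)
    if (!length(rows)) next
    new_stage[rows] <- sample(colnames(noise$confusion), length(rows),
                              replace = TRUE, prob = noise$confusion[cl, ])
  }
  det <- det[new_stage != "background", , drop = FALSE]
  det$stage <- new_stage[new_stage != "background"]
  if (noise$jitter_px > 0 && nrow(det)) {
    for (col in c("x_min", "y_min", "x_max", "y_max")) {
      det[[col]] <- det[[col]] + rnorm(nrow(det), 0, noise$jitter_px)
    }
    # keep boxes valid after jitter
    bad <- det$x_max <= det$x_min
    det$x_max[bad] <- det$x_min[bad] + 1
    bad <- det$y_max <= det$y_min
    det$y_max[bad] <- det$y_min[bad] + 1
  }
  det$confidence <- if (noise$jitter_px == 0 && noise$spurious_rate == 0 &&
                        all(noise$confusion[cbind(1:4, 1:4)] == 1)) {
    rep(1, nrow(det))
  } else {
    runif(nrow(det), 0.5, 1)
  }
  out <- det[, c("frame", "time_min", "x_min", "y_min", "x_max", "y_max",
                 "stage", "confidence", "vial")]
  if (noise$spurious_rate > 0) {
    geom <- if (inherits(gt, "colony_sim")) gt$geometry else NULL
    frames <- sort(unique(truth$frame))
    n_spur <- rpois(length(frames), noise$spurious_rate)
    tot <- sum(n_spur)
    if (tot > 0) {
      W <- if (is.null(geom)) max(truth$x_max) else geom$width
      H <- if (is.null(geom)) max(truth$y_max) else geom$height
      fr <- rep(frames, n_spur)
      cx <- runif(tot, 50, W - 50); cy <- runif(tot, 25, H - 25)
      nz <- which(truth$frame > 0)
      interval <- if (inherits(gt, "colony_sim")) {
        gt$config$frame_interval_min
      } else if (length(nz)) {
        truth$time_min[nz[1]] / truth$frame[nz[1]]
      } else 10
      spur <- tibble(
        frame = fr, time_min = fr * interval,
        x_min = cx - .box_half$out_of_focus[1L], y_min = cy - .box_half$out_of_focus[2L],
        x_max = cx + .box_half$out_of_focus[1L], y_max = cy + .box_half$out_of_focus[2L],
        stage = "out_of_focus", confidence = runif(tot, 0.3, 0.8),
        vial = NA_integer_
      )
      out <- bind_rows(out, spur)
    }
  }
  out <- out[order(out$frame), , drop = FALSE]
  as_tibble(out)
}

#' Render a synthetic grayscale frame
#'
#' Draws the scene as a backlit image: light background, darker vertical
#' vial strips, dark ellipses at the specimen boxes of the requested frame.
#' Intended as a fixture for vial calibration.
#'
#' @param gt A `colony_sim` (or a `vial_geometry` for an empty scene).
#' @param frame Frame index to render (ignored for an empty scene).
#' @return Numeric matrix (rows = image rows, values in `[0, 1]`).
#' @export
render_frame <- function(gt, frame = 0L) {
  if (inherits(gt, "vial_geometry")) {
    geom <- gt
    boxes <- NULL
  } else {
    stopifnot(inherits(gt, "colony_sim"))
    geom <- gt$geometry
    boxes <- gt$truth[gt$truth$frame == frame, , drop = FALSE]
  }
  img <- matrix(0.9, nrow = geom$height, ncol = geom$width)
  for (v in seq_len(geom$n_vials)) {
    x0 <- max(1L, ceiling((v - 1) * geom$strip_w + geom$margin / 2))
    x1 <- min(geom$width, floor(v * geom$strip_w - geom$margin / 2))
    img[, x0:x1] <- 0.45
  }
  if (!is.null(boxes) && nrow(boxes)) {
    for (k in seq_len(nrow(boxes))) {
      cx <- (boxes$x_min[k] + boxes$x_max[k]) / 2
      cy <- (boxes$y_min[k] + boxes$y_max[k]) / 2
      rx <- (boxes$x_max[k] - boxes$x_min[k]) / 2
      ry <- (boxes$y_max[k] - boxes$y_min[k]) / 2
      xs <- max(1L, floor(cx - rx)):min(geom$width, ceiling(cx + rx))
      ys <- max(1L, floor(cy - ry)):min(geom$height, ceiling(cy + ry))
      ell <- outer(ys, xs, function(y, x) ((x - cx) / rx)^2 + ((y - cy) / ry)^2 <= 1)
      img[ys, xs][ell] <- 0.15
    }
  }
  img
}
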