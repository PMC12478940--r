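test_that("eclosion-time sampling matches Poisson expectations and is reproducible", {
  p <- rhythm_preset("per0", baseline_rate = 0.5)  # amplitude 0, flat rate
  ev <- sample_eclosion_times(p, seed = 71)
  expected <- 0.5 * (p$duration_h - p$onset_h)     # 120
  expect_lt(abs(length(ev) - expected), 4 * sqrt(expected))
  expect_true(all(ev >= p$onset_h & ev <= p$duration_h))
  expect_false(is.unsorted(ev))
  # zero rate -> no events
  expect_length(sample_eclosion_times(rhythm_preset("iso31", baseline_rate = 0), seed = 1), 0L)
  # same seed, same draw
  expect_identical(sample_eclosion_times(p, seed = 72), sample_eclosion_times(p, seed = 72))
})

test_that("the event rate follows the raised-cosine intensity", {
  p <- rhythm_preset("iso31", baseline_rate = 2, duration_h = 336 * 3)
  ev <- sample_eclosion_times(p, seed = 77)
  phase <- (ev - p$phase_h) %% p$period_h / p$period_h
  # events concentrate near phase 0 (peak of the cosine): the fraction within
  # a quarter period of the peak is well above the uniform 1/2
  near_peak <- mean(phase < 0.25 | phase > 0.75)
  expect_gt(near_peak, 0.6)
})

test_that("simulated colonies honor the developmental ground-truth invariants", {
  sim <- small_colony(seed = 51)
  truth <- sim$truth
  # per developmental object: larva -> full_pupa -> empty_pupa, monotone
  for (sub in split(truth[truth$stage != "adult", ], truth$object[truth$stage != "adult"])) {
    ords <- stage_ordinal(sub$stage[order(sub$frame)])
    expect_true(all(diff(ords) >= 0))
  }
  # pupal boxes stationary: IoU 1 frame to frame
  pup <- truth[truth$stage %in% c("full_pupa", "empty_pupa"), ]
  for (sub in split(pup, pup$object)) {
    expect_equal(length(unique(sub$x_min)), 1L)
    expect_equal(length(unique(sub$y_min)), 1L)
  }
  # an adult object appears at eclosion
  adults <- truth[truth$stage == "adult", ]
  first_adult <- vapply(split(adults, adults$specimen), function(s) min(s$frame), numeric(1))
  expect_equal(unname(first_adult),
               sim$animals$eclosion_frame[sort(unique(adults$specimen))])
  # eclosion frames are the first empty-pupa frames
  ep <- truth[truth$stage == "empty_pupa", ]
  first_ep <- vapply(split(ep, ep$specimen), function(s) min(s$frame), numeric(1))
  expect_equal(unname(first_ep), sim$animals$eclosion_frame[sort(unique(ep$specimen))])
  expect_error(
    simulate_colony(rhythm_preset("iso31", n_animals = 500L),
                    seed = 1, geometry = vial_geometry(width = 300, height = 200, n_vials = 1)),
    "too small"
  )
})

test_that("the zero-noise model reproduces ground truth exactly", {
  sim <- small_colony(seed = 61)
  dets <- corrupt_detections(sim, noise_model("none"))
  expect_equal(nrow(dets), nrow(sim$truth))
  expect_equal(dets$x_min, sim$truth$x_min[order(sim$truth$frame, sim$truth$object)])
  expect_true(all(dets$stage == sim$truth$stage[order(sim$truth$frame, sim$truth$object)]))
  expect_true(all(dets$confidence == 1))
  # miss probability 1 drops everything
  nm <- noise_model("none", miss = stats::setNames(rep(1, 4), stage_levels()))
  expect_equal(nrow(corrupt_detections(sim, nm)), 0L)
  # identical seeds give identical streams
  d1 <- corrupt_detections(sim, noise_model("detector"), seed = 3)
  d2 <- corrupt_detections(sim, noise_model("detector"), seed = 3)
  expect_identical(d1, d2)
})

test_that("class confusion frequencies match the configured rates", {
  # >= 10^4 larval ground-truth boxes, confusion row says 8% become full pupae
  sim <- simulate_colony(
    rhythm_preset("iso31", duration_h = 72, onset_h = 40, n_animals = 60L),
    seed = 81, pupal_duration_h = 10, wander_h = 30
  )
  n_larva <- sum(sim$truth$stage == "larva")
  expect_gte(n_larva, 1e4)
  dets <- corrupt_detections(sim, noise_model("detector", spurious_rate = 0,
                                              jitter_px = 0), seed = 82)
  # noise keeps boxes in place: identify source rows by box-center rounding
  truth_larva <- sim$truth[sim$truth$stage == "larva", ]
  key <- paste(dets$frame, round((dets$x_min + dets$x_max) / 2), sep = "|")
  tkey <- paste(truth_larva$frame,
                round((truth_larva$x_min + truth_larva$x_max) / 2), sep = "|")
  from_larva <- dets[key %in% tkey, ]
  frac_fp <- sum(from_larva$stage == "full_pupa") / n_larva
  ci <- qbinom(c(0.005, 0.995), n_larva, 0.08) / n_larva
  expect_gte(frac_fp, ci[1])
  expect_lte(frac_fp, ci[2])
})

test_that("rendered frames expose the vial strips for calibration", {
  geom <- vial_geometry(width = 450, height = 240, n_vials = 3, margin = 15)
  img <- render_frame(geom)
  prof <- colMeans(img < 0.7)
  r <- rle(prof > 0.5)
  expect_equal(sum(r$values), 3L)  # three plateaus
  # with specimens drawn, calibration still recovers the strips
  sim <- simulate_colony(
    rhythm_preset("iso31", n_animals = 3L, duration_h = 48, onset_h = 24),
    seed = 91, geometry = geom, pupal_duration_h = 12, wander_h = 6,
    min_separation = 40
  )
  layout <- calibrate_vials(render_frame(sim, frame = 100L))
  expect_equal(nrow(layout), 3L)
  centers_true <- (geom$rois$x_min + geom$rois$x_max) / 2
  centers_got <- (layout$x_min + layout$x_max) / 2
  expect_lt(max(abs(centers_got - centers_true)), geom$strip_w / 2)
})
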