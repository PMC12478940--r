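mk_track <- function(ords, id = 1L) {
  tibble::tibble(track_id = id, frame = seq_along(ords) - 1L,
                 stage = ordinal_stage(ords))
}

test_that("median smoothing removes isolated misclassifications and keeps transitions", {
  # ordinals 1,1,2,1,1 -> all 1 (window-5 medians; edges keep raw = 1)
  tr <- smooth_stages(mk_track(c(1L, 1L, 2L, 1L, 1L)))
  expect_equal(stage_ordinal(tr$stage_smoothed), rep(1L, 5))
  # constant sequences unchanged
  tr2 <- smooth_stages(mk_track(rep(2L, 9)))
  expect_equal(tr2$stage_smoothed, tr2$stage)
  # genuine transition survives everywhere (edges keep raw, interior medians)
  tr3 <- smooth_stages(mk_track(c(1L, 1L, 1L, 2L, 2L, 2L, 2L)))
  expect_equal(tr3$stage_smoothed, tr3$stage)
  # edge frames keep their raw labels even when noisy
  tr4 <- smooth_stages(mk_track(c(2L, 1L, 1L, 1L, 1L, 1L, 3L)))
  expect_equal(stage_ordinal(tr4$stage_smoothed)[c(1, 7)], c(2L, 3L))
  expect_equal(stage_ordinal(tr4$stage_smoothed)[2:6], rep(1L, 5))
})

test_that("smoothing is idempotent and never invents labels absent from the window", {
  set.seed(12)
  for (rep in 1:20) {
    ords <- sample(0:3, 40, replace = TRUE, prob = c(.3, .3, .3, .1))
    s1 <- smooth_stages(mk_track(ords))
    s2 <- smooth_stages(dplyr::mutate(s1, stage = stage_smoothed))
    # the median of an odd window is an element of that window
    o1 <- stage_ordinal(s1$stage_smoothed)
    for (t in 3:38) expect_true(o1[t] %in% ords[(t - 2):(t + 2)])
    # idempotence on sequences with no short runs
    runs <- rle(stage_ordinal(s1$stage_smoothed))
    if (all(runs$lengths >= 3)) {
      expect_equal(s2$stage_smoothed, s1$stage_smoothed)
    }
  }
})

test_that("short-track filtering keeps length >= 30 and preserves order", {
  tracks <- dplyr::bind_rows(
    mk_track(rep(1L, 29), id = 1L),
    mk_track(rep(1L, 30), id = 2L),
    mk_track(rep(1L, 100), id = 3L)
  )
  kept <- filter_short_tracks(tracks, 30)
  expect_setequal(unique(kept$track_id), c(2L, 3L))
  expect_equal(unique(kept$track_id), c(2L, 3L))  # order preserved
  expect_equal(nrow(filter_short_tracks(tracks[0, ], 30)), 0L)
  expect_equal(filter_short_tracks(tracks, 1), tracks, ignore_attr = TRUE)
})

test_that("the majority window marks eclosion/pupation at the documented early offset", {
  # full pupa at frames 0-9, empty pupa at 10-20: window [7,13] holds 4 EP
  tr <- smooth_stages(mk_track(c(rep(1L, 10), rep(2L, 11))))
  ev <- extract_events(tr, tau = 7)
  expect_equal(ev$event_type, "eclosion")  # starts pupated: no pupation event
  expect_equal(ev$frame, 7L)
  expect_equal(ev$time_min, 70)
  # larva 0-9, full pupa 10-40: pupation marked at frame 7
  tr2 <- smooth_stages(mk_track(c(rep(0L, 10), rep(1L, 31))))
  ev2 <- extract_events(tr2, tau = 7)
  expect_equal(ev2$event_type, "pupation")
  expect_equal(ev2$frame, 7L)
  # all-larva track: no events
  expect_equal(nrow(extract_events(smooth_stages(mk_track(rep(0L, 40))))), 0L)
  # full life history: both events, in developmental order
  tr3 <- smooth_stages(mk_track(c(rep(0L, 12), rep(1L, 20), rep(2L, 15))))
  ev3 <- extract_events(tr3, tau = 7)
  expect_equal(ev3$event_type, c("pupation", "eclosion"))
  expect_lte(ev3$frame[1], ev3$frame[2])
})

test_that("event records obey the per-track invariants on random sequences", {
  set.seed(33)
  for (rep in 1:30) {
    ords <- sort(sample(0:2, 60, replace = TRUE))  # monotone life histories
    noise <- sample(60, 5)
    ords[noise] <- sample(0:2, 5, replace = TRUE)
    ev <- extract_events(smooth_stages(mk_track(ords)))
    expect_lte(nrow(ev), 2L)
    expect_false(any(duplicated(ev$event_type)))
    if (nrow(ev) == 2L) {
      expect_equal(ev$event_type, c("pupation", "eclosion"))
      expect_lte(ev$frame[1], ev$frame[2])
    }
  }
})

test_that("collect_events concatenates, sorts and filters by type", {
  sim <- small_colony(seed = 41)
  dets <- corrupt_detections(sim, noise_model("none"))
  tr <- filter_short_tracks(smooth_stages(track_detections(dets)), 30)
  ev <- collect_events(tr)
  expect_true(all(diff(ev$time_min) >= 0))
  ecl <- collect_events(tr, event_type = "eclosion")
  expect_true(all(ecl$event_type == "eclosion"))
  expect_equal(nrow(ecl), nrow(sim$animals))
})
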