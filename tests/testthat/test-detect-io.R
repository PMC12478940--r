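test_that("jsonl detection files roundtrip losslessly", {
  set.seed(5)
  dets <- tibble::tibble(
    frame = rep(0:4, each = 3),
    time_min = rep(0:4, each = 3) * 10,
    x_min = runif(15, 0, 500), y_min = runif(15, 0, 300),
    x_max = NA_real_, y_max = NA_real_,
    stage = sample(stage_levels(trackable_only = FALSE), 15, replace = TRUE),
    confidence = round(runif(15), 3),
    vial = sample(1:3, 15, replace = TRUE)
  )
  dets$x_max <- dets$x_min + runif(15, 10, 100)
  dets$y_max <- dets$y_min + runif(15, 10, 50)
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_detections(dets, path)
  back <- read_detections(path, "jsonl")
  expect_equal(as.data.frame(back), as.data.frame(dets), tolerance = 1e-12)
})

test_that("jsonl reader counts frames/boxes and handles empty and malformed input", {
  path <- withr::local_tempfile(fileext = ".jsonl")
  writeLines(c(
    '{"frame":0,"time_min":0,"detections":[{"bbox":[0,0,10,10],"stage":"larva","confidence":0.9},{"bbox":[20,0,30,10],"stage":"adult","confidence":0.8}]}',
    '{"frame":1,"time_min":10,"detections":[{"bbox":[0,0,10,10],"stage":"larva","confidence":0.9}]}'
  ), path)
  d <- read_detections(path, "jsonl")
  expect_equal(nrow(d), 3L)
  expect_equal(length(unique(d$frame)), 2L)

  empty <- withr::local_tempfile(fileext = ".jsonl")
  file.create(empty)
  expect_equal(nrow(read_detections(empty, "jsonl")), 0L)

  bad <- withr::local_tempfile(fileext = ".jsonl")
  writeLines(c('{"frame":0,"detections":[]}', "{oops"), bad)
  expect_error(read_detections(bad, "jsonl"), ":2")

  unk <- withr::local_tempfile(fileext = ".jsonl")
  writeLines('{"frame":0,"detections":[{"bbox":[0,0,1,1],"stage":"imago","confidence":1}]}', unk)
  expect_error(read_detections(unk, "jsonl"), "unknown stage")
})

test_that("yolo_txt normalized coordinates convert to absolute corners", {
  dir <- withr::local_tempdir()
  yaml::write_yaml(list(image_width = 1000, image_height = 1000,
                        class_map = c("larva", "full_pupa", "empty_pupa",
                                      "adult", "out_of_focus"),
                        frame_interval_min = 10), file.path(dir, "meta.yaml"))
  writeLines("1 0.5 0.5 0.1 0.1", file.path(dir, "frame_000003.txt"))
  writeLines(c("0 0.25 0.25 0.5 0.5 0.88"), file.path(dir, "frame_000007.txt"))
  d <- read_detections(dir, "yolo_txt")
  expect_equal(nrow(d), 2L)
  expect_equal(d$frame, c(3L, 7L))
  r3 <- d[d$frame == 3L, ]
  expect_equal(unlist(r3[, c("x_min", "y_min", "x_max", "y_max")], use.names = FALSE),
               c(450, 450, 550, 550))
  expect_equal(r3$stage, "full_pupa")
  expect_equal(d$confidence[d$frame == 7L], 0.88)
  expect_equal(d$time_min, c(30, 70))

  writeLines("9 0.5 0.5 0.1 0.1", file.path(dir, "frame_000009.txt"))
  expect_error(read_detections(dir, "yolo_txt"), "class index")
})

test_that("vial calibration recovers rendered strips and rejects uniform images", {
  geom <- vial_geometry(width = 600, height = 300, n_vials = 3, margin = 20)
  img <- render_frame(geom)
  layout <- calibrate_vials(img)
  expect_equal(nrow(layout), 3L)
  truth_centers <- (geom$rois$x_min + geom$rois$x_max) / 2
  got_centers <- (layout$x_min + layout$x_max) / 2
  expect_lt(max(abs(sort(got_centers) - sort(truth_centers))), geom$strip_w / 2)
  expect_equal(layout$vial, 1:3)  # left-to-right ids

  expect_error(calibrate_vials(matrix(1, 50, 50)), "uniform")

  manual <- vial_layout(tibble::tibble(vial = 1:2, x_min = c(0, 300),
                                       y_min = 0, x_max = c(299, 600), y_max = 300))
  expect_identical(calibrate_vials(matrix(1, 5, 5), override = manual), manual)
})

test_that("vial assignment partitions detections by box center", {
  layout <- vial_layout(tibble::tibble(
    vial = 1:2, x_min = c(0, 100), y_min = 0, x_max = c(100, 200), y_max = 100))
  dets <- tibble::tibble(
    frame = 0L, time_min = 0,
    x_min = c(10, 140, 95, 400), y_min = 10,
    x_max = c(30, 160, 105, 420), y_max = 30,  # centers 20, 150, 100 (boundary), 410
    stage = "larva", confidence = 1, vial = NA_integer_
  )
  out <- assign_vials(dets, layout)
  expect_equal(nrow(out), 3L)           # center 410 dropped
  expect_equal(out$vial, c(1L, 2L, 1L)) # boundary center 100 -> lower vial id
})
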