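feeder <- function() test_zones()[1, ]
drinker <- function() test_zones()[2, ]

test_that("zone occupancy is the union fraction of the zone", {
  z <- feeder()  # 100 x 50 at (40, 20)
  full <- det_row(30, 10, 150, 80)
  expect_equal(zone_occupancy(full, z), 1)
  expect_equal(zone_occupancy(det_row(300, 200, 400, 250), z), 0)
  expect_equal(zone_occupancy(full[0, ], z), 0)
  # two boxes covering distinct halves -> 1; stacked on one half -> 0.5
  left <- det_row(40, 20, 90, 70); right <- det_row(90, 20, 140, 70)
  expect_equal(zone_occupancy(rbind(left, right), z), 1)
  expect_equal(zone_occupancy(rbind(left, left), z), 0.5)
  # union semantics: duplicating a detection changes nothing; adding one
  # never decreases occupancy
  set.seed(41)
  for (i in 1:20) {
    boxes <- cbind(class = "standing", random_boxes(3))
    oc2 <- zone_occupancy(boxes[1:2, ], z)
    expect_equal(zone_occupancy(rbind(boxes[1:2, ], boxes[2, ]), z), oc2)
    expect_gte(zone_occupancy(boxes, z) + 1e-12, oc2)
    expect_gte(oc2, 0); expect_lte(oc2, 1)
  }
  expect_error(zone_occupancy(full, px_rect(0, 0, 1, 1) * 0), "zone")
})

test_that("zone occupancy agrees with per-pixel rasterization on random frames", {
  set.seed(42)
  z <- feeder()
  for (i in 1:200) {
    boxes <- random_boxes(sample(1:4, 1))
    expect_equal(zone_occupancy(boxes, z), raster_occupancy(boxes, z))
  }
})

test_that("standing at an occupied feeder is eating only inside a feeding window", {
  zones <- test_zones()
  sched <- feeding_schedule(start = 1000, end = 2000)
  eat_box <- det_row(30, 10, 150, 80, "standing", 0.9)   # covers the feeder
  inside <- classify_frame(eat_box, zones, sched, timestamp = 1500)
  expect_equal(unname(inside$counts["eating"]), 1L)
  outside <- classify_frame(eat_box, zones, sched, timestamp = 2500)
  expect_equal(unname(outside$counts["standing"]), 1L)
  expect_equal(unname(outside$counts["eating"]), 0L)
  # drinking is recognised at any time
  drink_box <- det_row(500, 10, 590, 70, "standing", 0.9)
  any_time <- classify_frame(drink_box, zones, sched, timestamp = 2500)
  expect_equal(unname(any_time$counts["drinking"]), 1L)
})

test_that("lying boxes stay lying and inactive feeders never produce eating", {
  zones <- test_zones()
  sched <- feeding_schedule(start = 0, end = 86400)
  lying_on_drinker <- det_row(500, 10, 590, 70, "lying", 0.9)
  r <- classify_frame(lying_on_drinker, zones, sched, timestamp = 100)
  expect_equal(unname(r$counts["lying"]), 1L)
  on_unused <- det_row(250, 290, 370, 360, "standing", 0.9)
  r2 <- classify_frame(on_unused, zones, sched, timestamp = 100)
  expect_equal(unname(r2$counts["standing"]), 1L)
  expect_equal(unname(r2$counts["eating"]), 0L)
})

test_that("a detection qualifying for both zones goes to the larger overlap, ties to drinker", {
  zones <- data.frame(zone_id = c("f", "d"), role = c("feeder", "drinker"),
                      x0 = c(0, 60), y0 = c(0, 0), x1 = c(50, 110), y1 = c(50, 50),
                      stringsAsFactors = FALSE)
  sched <- feeding_schedule(start = 0, end = 86400)
  # box covers all of the drinker but only part of the feeder
  box <- det_row(10, 0, 110, 50, "standing", 0.9)
  r <- classify_frame(box, zones, sched, timestamp = 10)
  expect_equal(unname(r$counts["drinking"]), 1L)
  # symmetric overlap: tie broken towards drinker
  tie <- det_row(0, 0, 110, 50, "standing", 0.9)
  r2 <- classify_frame(tie, zones, sched, timestamp = 10)
  expect_equal(unname(r2$counts["drinking"]), 1L)
})

test_that("the per-detection rule thresholds on the box fraction inside the zone", {
  zones <- data.frame(zone_id = "f", role = "feeder",
                      x0 = 0, y0 = 0, x1 = 200, y1 = 200,
                      stringsAsFactors = FALSE)
  sched <- feeding_schedule(start = 0, end = 86400)
  # box 100x100, exactly half inside the (large) zone
  half_in <- det_row(-50 + 50, 0, 150, 100, "standing", 0.9)
  half_in$x0 <- 100; half_in$x1 <- 300  # 100..300, zone ends at 200
  r <- classify_frame(half_in, zones, sched, timestamp = 10, rule = "detection")
  expect_equal(unname(r$counts["eating"]), 1L)   # fraction = 0.5 >= 0.5
  mostly_out <- half_in; mostly_out$x0 <- 130; mostly_out$x1 <- 330
  r2 <- classify_frame(mostly_out, zones, sched, timestamp = 10,
                       rule = "detection")
  expect_equal(unname(r2$counts["standing"]), 1L)
  # under the zone rule the same lone box fails: it covers too little of it
  r3 <- classify_frame(half_in, zones, sched, timestamp = 10, rule = "zone")
  expect_equal(unname(r3$counts["standing"]), 1L)
})

test_that("every detection maps to exactly one behavior and eating needs a schedule", {
  zones <- test_zones()
  sched <- feeding_schedule(start = 0, end = 86400)
  empty_sched <- feeding_schedule(start = numeric(0), end = numeric(0))
  set.seed(43)
  for (i in 1:30) {
    n <- sample(1:6, 1)
    boxes <- random_boxes(n)
    cls <- sample(c("lying", "standing"), n, replace = TRUE)
    d <- do.call(rbind, lapply(seq_len(n), function(k)
      det_row(boxes$x0[k], boxes$y0[k], boxes$x1[k], boxes$y1[k],
              cls[k], 0.9)))
    r <- classify_frame(d, zones, sched, timestamp = 100)
    expect_equal(sum(r$counts), n)
    expect_equal(unname(r$counts["lying"]), sum(cls == "lying"))
    expect_equal(sum(r$counts[c("standing", "eating", "drinking")]),
                 sum(cls == "standing"))
    r0 <- classify_frame(d, zones, empty_sched, timestamp = 100)
    expect_equal(unname(r0$counts["eating"]), 0L)
  }
})

test_that("video inference accumulates frame counts and respects the span", {
  zones <- test_zones()
  sched <- feeding_schedule(start = 0, end = 86400)
  meta <- video_meta(fps = 25, n_frames = 50)
  empty <- det_row(0, 0, 1, 1)[0, ]
  empty <- cbind(data.frame(frame_index = integer(), timestamp = numeric()),
                 empty)
  r <- infer_video(empty, zones, sched, meta)
  expect_equal(unname(r$totals), c(0, 0, 0, 0))
  expect_equal(nrow(r$activity), 50)

  # 3 pigs lying in each of 40 frames
  frames <- do.call(rbind, lapply(0:39, function(f)
    do.call(rbind, lapply(1:3, function(p)
      det_row(50 * p, 200, 50 * p + 40, 240, "lying", 0.9,
              frame_index = f, timestamp = f / 25)))))
  r2 <- infer_video(frames, zones, sched, video_meta(fps = 25, n_frames = 40))
  expect_equal(unname(r2$totals["lying"]), 120)

  # scripted bout: the pig stands about, drinks for 100 frames, leaves
  drink <- do.call(rbind, lapply(0:299, function(f) {
    if (f >= 100 && f < 200) det_row(500, 10, 590, 70, "standing", 0.9,
                                     frame_index = f, timestamp = f / 25)
    else det_row(200, 150, 290, 210, "standing", 0.9,
                 frame_index = f, timestamp = f / 25)
  }))
  r3 <- infer_video(drink, zones, sched, video_meta(fps = 25, n_frames = 300))
  expect_equal(unname(r3$totals["drinking"]), 100)
  expect_equal(unname(r3$totals["standing"]), 200)

  bad <- frames; bad$timestamp[2] <- 99
  expect_error(infer_video(bad, zones, sched, meta), "duplicated frame_index")
  expect_error(classify_frame(det_row(0, 0, 10, 10, "lying"), zones, sched,
                              timestamp = 10,
                              meta = video_meta(fps = 25, n_frames = 50)),
               "outside video span")
})
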