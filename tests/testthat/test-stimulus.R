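test_that("visual angles match the printed stimulus geometry", {
  # Frisbee diameter, fixation target, and the two calibration target sizes
  expect_equal(round(visual_angle_deg(52, default_geom), 1), 2.6)
  expect_equal(round(visual_angle_deg(90, default_geom), 1), 4.5)
  expect_equal(round(visual_angle_deg(50, default_geom), 1), 2.5)
  expect_equal(round(visual_angle_deg(32, default_geom), 1), 1.6)
  expect_equal(visual_angle_deg(0, default_geom), 0)
})

test_that("visual angle is strictly increasing in pixel extent", {
  angles <- visual_angle_deg(seq(0, 1024, by = 32), default_geom)
  expect_true(all(diff(angles) > 0))
})

test_that("invalid geometry is rejected", {
  expect_error(viewing_geometry(distance_cm = 0), "distance")
  expect_error(viewing_geometry(video_px = c(-1, 768)), "video_px")
  expect_error(visual_angle_deg(10, geometry = list()), "geometry")
})

test_that("mirror_x is an involution with the screen centre fixed", {
  expect_equal(mirror_x(0, 1024), 1024)
  expect_equal(mirror_x(512, 1024), 512)
  x <- runif(100, -50, 1100)
  expect_equal(mirror_x(mirror_x(x, 1024), 1024), x)
})

test_that("position_at interpolates linearly and exactly at nodes", {
  tr <- linear_track()
  s <- tr$samples
  # exact at every node
  expect_equal(position_at(tr, s$t_ms)$x_px, s$x_px)
  # midpoint linearity
  mid <- position_at(tr, (s$t_ms[3] + s$t_ms[4]) / 2)
  expect_equal(mid$x_px, (s$x_px[3] + s$x_px[4]) / 2)
  # brute-force piecewise-linear oracle at random times
  set.seed(42)
  t_q <- runif(200, 0, 1000)
  brute <- vapply(t_q, function(tt) {
    i <- max(which(s$t_ms <= tt))
    if (i == nrow(s)) return(s$x_px[i])
    u <- (tt - s$t_ms[i]) / (s$t_ms[i + 1] - s$t_ms[i])
    s$x_px[i] + u * (s$x_px[i + 1] - s$x_px[i])
  }, numeric(1))
  expect_equal(position_at(tr, t_q)$x_px, brute, tolerance = 1e-9)
  expect_error(position_at(tr, -1), "span")
  expect_error(position_at(tr, 1001), "span")
})

test_that("an empty freeze-rewind edit leaves the track unchanged", {
  tr <- linear_track()
  out <- apply_freeze_rewind(tr, t_freeze_ms = 500, hold_ms = 0,
                             rewind_to_ms = 500)
  expect_equal(out$samples$t_ms, tr$samples$t_ms)
  expect_equal(out$samples$x_px, tr$samples$x_px)
})

test_that("freeze-rewind holds position, replays in reverse, and stays continuous", {
  tr <- linear_track(n = 41)
  out <- apply_freeze_rewind(tr, t_freeze_ms = 600, hold_ms = 1000,
                             rewind_to_ms = 200)
  s <- out$samples
  # zero variance over the hold window
  hold <- position_at(out, seq(600, 1600, by = 25))
  expect_equal(var(hold$x_px), 0)
  # rewound segment is the time-reverse of the original one
  probe <- seq(0, 400, by = 20)
  rewound <- position_at(out, 1600 + probe)$x_px
  original <- position_at(tr, 600 - probe)$x_px
  expect_equal(rewound, original)
  # continuation resumes the original track
  expect_equal(position_at(out, 2000 + 300)$x_px,
               position_at(tr, 200 + 300)$x_px)
  # no positional jumps: bounded by max flight speed x sample interval
  speed <- max(abs(diff(tr$samples$x_px) / diff(tr$samples$t_ms)))
  dtv <- diff(s$t_ms)
  expect_true(all(abs(diff(s$x_px)) <= speed * dtv + 1e-9))
  # duration grows by hold + 2 * rewound span
  expect_equal(max(s$t_ms), 1000 + 1000 + 2 * 400)
})

test_that("freeze-rewind preserves visited positions outside the edited interval", {
  tr <- linear_track(n = 21)
  out <- apply_freeze_rewind(tr, 600, 500, 300)
  pre <- tr$samples[tr$samples$t_ms < 600, ]
  expect_true(all(pre$x_px %in% out$samples$x_px))
  post <- tr$samples[tr$samples$t_ms > 300, ]
  expect_true(all(post$x_px %in% out$samples$x_px))
})

test_that("rewind target after the freeze point is rejected", {
  expect_error(apply_freeze_rewind(linear_track(), 500, 100, 700),
               "invalid edit")
})

test_that("exp1 timeline has 10 alternating throws with the frozen-catcher pattern", {
  tl <- build_timeline("exp1")
  expect_s3_class(tl, "stimulus_timeline")
  expect_equal(nrow(tl$throws), 10L)
  expect_equal(tl$duration_ms, 16000)
  expect_equal(tl$throws$event_index[tl$throws$catcher_frozen],
               c(2L, 5L, 7L, 10L))
  expect_equal(nrow(tl$edits), 0L)
  expect_true(all(diff(tl$throws$contact_time_ms) > 0))
  # forward catchers alternate sides
  sides <- tl$throws$catcher_side
  expect_true(all(sides[-1] != sides[-length(sides)]))
})

test_that("exp2 timeline has 14 catch-type events, 4 freezes and 4 rewinds over 24 s", {
  tl <- build_timeline("exp2")
  expect_equal(nrow(tl$throws), 14L)
  expect_equal(sum(tl$throws$playback == "forward"), 10L)
  expect_equal(sum(tl$throws$playback == "backward"), 4L)
  expect_equal(tl$duration_ms, 24000)
  expect_equal(sum(tl$edits$kind == "freeze"), 4L)
  expect_equal(sum(tl$edits$kind == "rewind"), 4L)
  expect_true(all(diff(tl$throws$contact_time_ms) > 0))
  # forward throws still alternate catcher sides in event order
  fwd <- tl$throws[tl$throws$playback == "forward", ]
  expect_true(all(fwd$catcher_side[-1] != fwd$catcher_side[-nrow(fwd)]))
  # the track holds still for the full 1000 ms of every freeze
  for (i in which(tl$edits$kind == "freeze")) {
    t0 <- tl$edits$t_start_ms[i]
    hold <- position_at(tl$track, seq(t0, t0 + tl$edits$hold_ms[i], by = 10))
    expect_equal(var(hold$x_px), 0)
    expect_equal(var(hold$y_px), 0)
  }
  # each backward event ends where its throw began (object back at thrower)
  bwd <- tl$throws[tl$throws$playback == "backward", ]
  for (i in seq_len(nrow(bwd))) {
    aoi <- tl$players[[bwd$catcher_side[i]]]
    xe <- position_at(tl$track, bwd$flight_end_ms[i])$x_px
    expect_gte(xe, aoi$x_min)
    expect_lte(xe, aoi$x_max)
  }
})

test_that("timeline track is continuous with positions inside the video area", {
  for (design in c("exp1", "exp2")) {
    tl <- build_timeline(design)
    s <- tl$track$samples
    expect_true(all(diff(s$t_ms) > 0))
    expect_true(all(s$x_px >= 0 & s$x_px <= 1024))
    expect_true(all(s$y_px >= 0 & s$y_px <= 768))
    expect_equal(s$t_ms[1], 0)
    expect_equal(s$t_ms[nrow(s)], tl$duration_ms)
    flight_speed <- (896 - 128) / 650   # px per ms between player centres
    expect_true(all(abs(diff(s$x_px)) <=
                      flight_speed * diff(s$t_ms) + 1e-9))
  }
})

test_that("inconsistent throw kinematics are rejected", {
  expect_error(timeline_config(cycle_ms = 600, flight_ms = 650),
               "inconsistent config")
})

test_that("player AOIs carry the inner boundary facing the screen centre", {
  expect_equal(player_aoi("left", 0, 256)$inner_boundary_x, 256)
  expect_equal(player_aoi("right", 768, 1024)$inner_boundary_x, 768)
  expect_error(player_aoi("left", 300, 200), "x_min")
})

test_that("timelines round-trip through YAML serialization", {
  dir <- withr::local_tempdir()
  for (design in c("exp1", "exp2")) {
    tl <- build_timeline(design)
    path <- file.path(dir, paste0(design, ".yaml"))
    write_timeline(tl, path)
    back <- read_timeline(path)
    expect_equal(back$duration_ms, tl$duration_ms)
    expect_equal(back$throws$contact_time_ms, tl$throws$contact_time_ms)
    expect_equal(back$throws$catcher_side, tl$throws$catcher_side)
    expect_equal(back$track$samples, tl$track$samples, tolerance = 1e-9)
    expect_equal(back$players$left$inner_boundary_x,
                 tl$players$left$inner_boundary_x)
    if (!is.null(tl$analysis_periods))
      expect_equal(back$analysis_periods$t_start_ms,
                   tl$analysis_periods$t_start_ms)
  }
})
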