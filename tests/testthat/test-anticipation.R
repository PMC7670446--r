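test_that("interest periods are centred on each event's contact frame", {
  tl1 <- build_timeline("exp1")
  p1 <- build_interest_periods(tl1)
  expect_equal(nrow(p1), 10L)
  expect_equal(p1$t_end_ms - p1$t_start_ms, rep(1300, 10))
  expect_equal((p1$t_start_ms + p1$t_end_ms) / 2, p1$contact_time_ms)

  tl2 <- build_timeline("exp2")
  expect_warning(p2 <- build_interest_periods(tl2), "overlap")
  expect_equal(nrow(p2), 14L)

  # degenerate zero-width windows observe nothing
  p0 <- build_interest_periods(tl1, half_window_ms = 0)
  rec <- make_recording(0:15999, x_px = 900)
  obs <- first_look_latency(rec, p0[2, ], tl1$players$left)
  expect_equal(obs$status, "no_look")
})

test_that("signed distance is positive inside the catcher AOI", {
  period <- make_period(contact = 1000, side = "right")
  rec <- make_recording(c(400, 500, 600), x_px = c(768, 512, 900))
  d <- signed_distance(rec, period, right_aoi)
  expect_equal(d$d_px, c(0, -256, 132))
  # left catcher flips the sign convention
  period_l <- make_period(contact = 1000, side = "left")
  d_l <- signed_distance(make_recording(c(400), x_px = 100), period_l,
                         left_aoi)
  expect_equal(d_l$d_px, 156)
  # AOI side must match the event
  expect_error(signed_distance(rec, period, left_aoi), "side")
  # invalid samples are omitted
  rec2 <- make_recording(c(400, 500), x_px = c(800, 900),
                         valid = c(TRUE, FALSE))
  expect_equal(nrow(signed_distance(rec2, period, right_aoi)), 1L)
})

test_that("signed distance matches a per-sample recomputation", {
  set.seed(23)
  period <- make_period(contact = 2000, side = "right")
  t <- seq(1350, 2649, by = 7)
  x <- runif(length(t), 0, 1024)
  rec <- make_recording(t, x_px = x)
  d <- signed_distance(rec, period, right_aoi)
  expect_equal(d$d_px, x - 768)
})

test_that("a constructed anticipatory trace yields its planted latency", {
  # gaze sits mid-screen, enters the catcher AOI 54 ms before contact
  period <- make_period(contact = 1000, side = "right")
  t <- seq(350, 1649)
  x <- ifelse(t < 946, 500, 800)
  rec <- make_recording(t, x_px = x)
  obs <- first_look_latency(rec, period, right_aoi, min_dwell_ms = 25)
  expect_equal(obs$status, "observed")
  expect_equal(obs$latency_ms, -54)
  # never entering the AOI is a no_look, not an error
  never <- make_recording(t, x_px = 500)
  expect_equal(first_look_latency(never, period, right_aoi)$status,
               "no_look")
})

test_that("the dwell guard suppresses single-sample AOI entries", {
  period <- make_period(contact = 1000, side = "right")
  t <- seq(350, 1649)
  x <- rep(500, length(t)); x[t == 900] <- 800
  rec <- make_recording(t, x_px = x)
  expect_equal(first_look_latency(rec, period, right_aoi, 25)$status,
               "no_look")
  # with a literal first-sample rule the same excursion counts
  expect_equal(first_look_latency(rec, period, right_aoi, 0)$latency_ms,
               -100)
  # an invalid stretch breaks a run: the 9 ms before it no longer counts,
  # so the first qualifying run starts only after the samples become valid
  x2 <- rep(800, length(t)); v <- rep(TRUE, length(t))
  v[t >= 360 & t < 380] <- FALSE
  rec2 <- make_recording(t, x_px = x2, valid = v)
  obs2 <- first_look_latency(rec2, period, right_aoi, 25)
  expect_equal(obs2$latency_ms, 380 - 1000)
})

test_that("the detector agrees with a naive per-sample scan on randomized traces", {
  set.seed(77)
  period <- make_period(contact = 1000, side = "right")
  for (i in 1:300) {
    n <- 130
    t <- seq(350, by = 10, length.out = n)
    x <- 768 + cumsum(rnorm(n, 0, 60))
    valid <- runif(n) > 0.1
    dwell <- sample(c(0, 25, 60), 1)
    rec <- make_recording(t, x_px = x, valid = valid)
    got <- first_look_latency(rec, period, right_aoi, dwell)
    want <- naive_first_look(rec$samples, period, right_aoi, dwell)
    if (is.na(want)) expect_equal(got$status, "no_look")
    else expect_equal(got$latency_ms, want)
  }
})

test_that("enlarging the dwell guard never converts a no_look into a look", {
  set.seed(13)
  period <- make_period(contact = 1000, side = "right")
  for (i in 1:50) {
    t <- seq(350, by = 5, length.out = 260)
    x <- 700 + cumsum(rnorm(260, 0, 30))
    rec <- make_recording(t, x_px = x, valid = runif(260) > 0.05)
    looked <- vapply(c(0, 10, 25, 50, 100), function(dw)
      first_look_latency(rec, period, right_aoi, dw)$status == "observed",
      logical(1))
    expect_true(all(diff(looked) <= 0))
  }
})

test_that("observed latencies stay inside the interest window", {
  tl <- build_timeline("exp1")
  cfg <- simulation_config(n_subjects = 4, seed = 31, rate_hz = 250)
  out <- cohort_candidates(tl, cfg)
  lat <- out$candidates$latency_ms[out$candidates$status == "observed"]
  expect_true(all(lat >= -650 & lat <= 650))
})

test_that("exclusion machinery yields the design's candidate-event counts", {
  tl1 <- build_timeline("exp1")
  cfg1 <- simulation_config(n_subjects = 11, seed = 41, rate_hz = 250)
  out1 <- cohort_candidates(tl1, cfg1)
  # 11 subjects x throws 2-10
  expect_equal(nrow(out1$candidates), 99L)
  expect_false(any(out1$candidates$event_index == 1L))

  tl2 <- build_timeline("exp2")
  cfg2 <- simulation_config(n_subjects = 9, seed = 42, rate_hz = 250)
  out2 <- cohort_candidates(tl2, cfg2)
  # 9 subjects x events 2-14
  expect_equal(nrow(out2$candidates), 117L)
})

test_that("gaze glued to the catcher across events is excluded as not_looked_away", {
  tl <- build_timeline("exp1")
  # subject stares at the right player for the whole video
  t <- seq(0, 16000, by = 4)
  rec <- make_recording(t, x_px = 900)
  obs <- extract_latencies(rec, tl)
  out <- apply_exclusions(obs, list(rec), tl)
  # events with right catcher (odd throws) never show a fresh look
  right_events <- out$event_index[out$catcher_side == "right"]
  expect_true(all(out$status[out$event_index %in% right_events] ==
                    "not_looked_away"))
  # left-catcher events are no_look (gaze never enters the left AOI)
  expect_true(all(out$status[out$catcher_side == "left"] == "no_look"))
})

test_that("latencies are identical for a mirrored twin after normalization", {
  tl <- build_timeline("exp1")
  cfg <- simulation_config(n_subjects = 2, seed = 55, rate_hz = 500)
  rec <- simulate_recording(tl, cfg, 1)$recording  # canonical orientation
  twin <- rec
  twin$samples$x_px <- mirror_x(twin$samples$x_px, 1024)
  twin$mirrored <- TRUE
  twin_norm <- normalize_orientation(twin, 1024)
  a <- extract_latencies(rec, tl)
  b <- extract_latencies(twin_norm, tl)
  expect_identical(a$latency_ms, b$latency_ms)
  expect_identical(a$status, b$status)
})
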