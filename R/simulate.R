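#' Simulation settings for synthetic gaze cohorts
#'
#' Parameters of the gaze simulator. The generator emulates the structure
#' the analysis assumes: smooth pursuit of the target with a per-subject
#' temporal lag plus Gaussian position jitter, a planted anticipatory-looking
#' trend (first looks at the catcher arriving earlier on later throws),
#' occasional predictive overshoot to the upcoming catcher while the video
#' is frozen, blinks as runs of invalid samples, and brief off-video
#' excursions. All draws run through one seeded generator, so a config's
#' output stream is fully reproducible.
#'
#' The planted population latency for event `e` is
#' `intercept + slope * (e - mean(2:K)) + backward_extra * backward(e)`,
#' with per-subject normal deviations on intercept and slope and an
#' event-level residual; `K` is the number of catch-type events, so the
#' intercept is the latency at the mean modelled event number. Latencies are
#' truncated to lie well inside the ±650 ms window so the planted value
#' stays recoverable. Each event produces a look with probability
#' `look_prob` (roughly the observed-look rates of 61/99 and 72/117 in the
#' data the defaults emulate); otherwise the subject keeps tracking without
#' entering the catcher area.
#'
#' @param n_subjects Number of subjects per cohort.
#' @param rate_hz Gaze sampling rate.
#' @param pursuit_lag_ms,pursuit_lag_sd_ms Mean and between-subject SD of
#'   the pursuit lag.
#' @param noise_sd_px SD of the Gaussian gaze jitter, in px.
#' @param blink_rate_per_s,blink_duration_ms Blink (invalid-run) process.
#' @param anticipation_intercept_ms Population latency at the mean event
#'   number (negative = anticipatory).
#' @param anticipation_slope_ms_per_throw Population latency change per
#'   event number (negative = earlier looks on later throws).
#' @param subject_sd_ms,subject_slope_sd_ms Between-subject SDs of the
#'   latency intercept and slope.
#' @param latency_noise_sd_ms Event-level latency residual SD.
#' @param backward_extra_ms Latency shift added to backward-playback
#'   (rewound) catch events.
#' @param look_prob Probability that an event elicits a look at the catcher.
#' @param saccade_duration_ms Duration of the linear saccade ramp from the
#'   AOI boundary to the player centre.
#' @param overshoot_prob Probability, per freeze, that gaze jumps to the
#'   upcoming catcher while the video is frozen.
#' @param off_video_rate_per_s,off_video_duration_ms Off-video excursion
#'   process (valid samples outside the video rectangle).
#' @param clamp_margin_px How far outside the catcher AOI pursuit saturates
#'   before a look is released; keeps pursuit noise from producing
#'   spurious AOI entries.
#' @param seed Integer seed fixing the full output stream.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(n_subjects = 11,
                              rate_hz = 1000,
                              pursuit_lag_ms = 120,
                              pursuit_lag_sd_ms = 40,
                              noise_sd_px = 30,
                              blink_rate_per_s = 0.2,
                              blink_duration_ms = 150,
                              anticipation_intercept_ms = -38,
                              anticipation_slope_ms_per_throw = -30,
                              subject_sd_ms = 60,
                              subject_slope_sd_ms = 10,
                              latency_noise_sd_ms = 120,
                              backward_extra_ms = 140,
                              look_prob = 0.65,
                              saccade_duration_ms = 30,
                              overshoot_prob = 0.3,
                              off_video_rate_per_s = 0.05,
                              off_video_duration_ms = 300,
                              clamp_margin_px = 60,
                              seed = 1L) {
  cfg <- as.list(environment())
  nonneg <- c("rate_hz", "pursuit_lag_ms", "pursuit_lag_sd_ms",
              "noise_sd_px", "blink_rate_per_s", "blink_duration_ms",
              "subject_sd_ms", "subject_slope_sd_ms", "latency_noise_sd_ms",
              "saccade_duration_ms", "off_video_rate_per_s",
              "off_video_duration_ms", "clamp_margin_px")
  for (nm in nonneg) {
    if (cfg[[nm]] < 0) stop("'", nm, "' must be non-negative", call. = FALSE)
  }
  if (cfg$rate_hz <= 0) stop("'rate_hz' must be positive", call. = FALSE)
  if (cfg$n_subjects < 1) stop("need at least one subject", call. = FALSE)
  if (cfg$look_prob < 0 || cfg$look_prob > 1 ||
      cfg$overshoot_prob < 0 || cfg$overshoot_prob > 1)
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  structure(cfg, class = "simulation_config")
}

with_local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  force(code)
}

subject_seed <- function(config, subject_index) {
  (abs(as.integer(config$seed)) + 1009L * as.integer(subject_index)) %%
    2147483647L
}

draw_subject_effects <- function(config) {
  list(lag_ms = max(0, stats::rnorm(1, config$pursuit_lag_ms,
                                    config$pursuit_lag_sd_ms)),
       intercept_ms = config$anticipation_intercept_ms +
         stats::rnorm(1, 0, config$subject_sd_ms),
       slope_ms = config$anticipation_slope_ms_per_throw +
         stats::rnorm(1, 0, config$subject_slope_sd_ms))
}

#' Simulate one subject's gaze recording
#'
#' Generates a raw gaze stream for one subject watching the given timeline,
#' together with the ground truth needed for recovery tests. Gaze follows
#' the target with the subject's pursuit lag plus jitter; inside each
#' event's interest window pursuit saturates just outside the catcher area
#' until the subject's scheduled look, which enters the AOI exactly at the
#' planted time (boundary first, then a linear ramp to the player centre
#' and a dwell there to the window's end). During freezes gaze holds on the
#' frozen target unless an overshoot jump to the upcoming catcher is drawn.
#' Blinks produce runs of invalid samples. Identical seeds give bitwise
#' identical output.
#'
#' @param timeline A `stimulus_timeline`.
#' @param config A [simulation_config()].
#' @param subject_index 1-based subject number (determines the subject's
#'   seed, effects, and mirrored assignment: even indices are mirrored).
#' @return A list with `recording` (a [gaze_recording()], already in the
#'   orientation shown to the subject) and `truth` (list with `subject` and
#'   per-event `events` data frame).
#' @export
simulate_recording <- function(timeline, config, subject_index) {
  with_local_seed(subject_seed(config, subject_index), {
    sim_recording_impl(timeline, config, subject_index)
  })
}

sim_recording_impl <- function(timeline, config, subject_index) {
  th <- timeline$throws
  hw <- 650
  if (any(th$contact_time_ms < 0 | th$contact_time_ms > timeline$duration_ms))
    stop("config/timeline mismatch: events outside the stimulus duration",
         call. = FALSE)
  eff <- draw_subject_effects(config)
  K <- nrow(th)
  center_ev <- mean(2:K)

  # per-event schedule
  looks <- stats::runif(K) < config$look_prob
  lat_mean <- eff$intercept_ms + eff$slope_ms * (th$event_index - center_ev) +
    ifelse(th$playback == "backward", config$backward_extra_ms, 0)
  lat <- lat_mean + stats::rnorm(K, 0, config$latency_noise_sd_ms)
  lat <- pmin(pmax(lat, -(hw - 50)), hw - 120)
  t_look <- th$contact_time_ms + lat

  dt <- 1000 / config$rate_hz
  t <- seq(0, timeline$duration_ms, by = dt)
  n <- length(t)
  span <- range(timeline$track$samples$t_ms)
  t_src <- pmin(pmax(t - eff$lag_ms, span[1]), span[2])
  pos <- position_at(timeline$track, t_src)
  x <- pos$x_px
  y <- pos$y_px

  w <- timeline$geometry$video_px[1]
  margin <- config$clamp_margin_px
  sacc <- config$saccade_duration_ms
  for (e in seq_len(K)) {
    aoi <- timeline$players[[th$catcher_side[e]]]
    win <- c(th$contact_time_ms[e] - hw, th$contact_time_ms[e] + hw)
    release <- if (looks[e]) t_look[e] else win[2]
    idx <- t >= win[1] & t < release
    if (aoi$side == "right") {
      x[idx] <- pmin(x[idx], aoi$inner_boundary_x - margin)
      ctr <- (aoi$x_min + aoi$x_max) / 2
    } else {
      x[idx] <- pmax(x[idx], aoi$inner_boundary_x + margin)
      ctr <- (aoi$x_min + aoi$x_max) / 2
    }
    if (looks[e]) {
      b <- aoi$inner_boundary_x
      ramp <- t >= t_look[e] & t < t_look[e] + sacc
      if (sacc > 0)
        x[ramp] <- b + (ctr - b) * (t[ramp] - t_look[e]) / sacc
      dwell <- t >= t_look[e] + sacc & t < win[2]
      x[dwell] <- ctr
    }
  }

  # overshoot to the upcoming catcher during whole-video freezes
  edits <- timeline$edits
  if (!is.null(edits) && nrow(edits) > 0L) {
    fr <- edits[edits$kind == "freeze", , drop = FALSE]
    for (i in seq_len(nrow(fr))) {
      if (stats::runif(1) >= config$overshoot_prob) next
      t0 <- fr$t_start_ms[i]
      dir <- sign(position_at(timeline$track, t0)$x_px -
                    position_at(timeline$track, max(t0 - 50, span[1]))$x_px)
      aoi <- if (dir >= 0) timeline$players$right else timeline$players$left
      jump <- t >= t0 + 200 & t < t0 + fr$hold_ms[i]
      x[jump] <- (aoi$x_min + aoi$x_max) / 2
    }
  }

  x <- x + stats::rnorm(n, 0, config$noise_sd_px)
  y <- y + stats::rnorm(n, 0, config$noise_sd_px)

  # off-video excursions (valid but outside the rectangle)
  n_off <- stats::rpois(1, config$off_video_rate_per_s *
                          timeline$duration_ms / 1000)
  if (n_off > 0) {
    starts <- stats::runif(n_off, 0, timeline$duration_ms)
    for (s0 in starts) {
      idx <- t >= s0 & t < s0 + config$off_video_duration_ms
      y[idx] <- -60
    }
  }

  # blinks: runs of invalid samples with no usable position
  valid <- rep(TRUE, n)
  n_blinks <- stats::rpois(1, config$blink_rate_per_s *
                             timeline$duration_ms / 1000)
  if (n_blinks > 0) {
    starts <- stats::runif(n_blinks, 0, timeline$duration_ms)
    for (s0 in starts) {
      valid[t >= s0 & t < s0 + config$blink_duration_ms] <- FALSE
    }
  }
  x[!valid] <- NA_real_
  y[!valid] <- NA_real_

  mirrored <- subject_index %% 2 == 0
  if (mirrored) x <- mirror_x(x, w)
  subject_id <- sprintf("S%02d", subject_index)
  recording <- gaze_recording(
    data.frame(t_ms = t, x_px = x, y_px = y, valid = valid),
    subject_id = subject_id, experiment = timeline$design,
    mirrored = mirrored, rate_hz = config$rate_hz)
  truth <- list(
    subject = data.frame(subject_id = subject_id, lag_ms = eff$lag_ms,
                         intercept_ms = eff$intercept_ms,
                         slope_ms = eff$slope_ms, mirrored = mirrored,
                         stringsAsFactors = FALSE),
    events = data.frame(subject_id = subject_id,
                        event_index = th$event_index,
                        playback = th$playback,
                        look_scheduled = looks,
                        planted_latency_ms = ifelse(looks, lat, NA_real_),
                        t_look_ms = ifelse(looks, t_look, NA_real_),
                        stringsAsFactors = FALSE))
  list(recording = recording, truth = truth)
}

#' Simulate a cohort of subjects
#'
#' Independent subjects on a shared timeline, each with its own seed
#' derived from the config seed, so the cohort is reproducible as a whole
#' and per subject. Even-indexed subjects are emitted in mirrored
#' orientation (their `mirrored` flag set), exercising the orientation
#' normalization step.
#'
#' @param timeline A `stimulus_timeline`.
#' @param config A [simulation_config()].
#' @return A list with `recordings` (list of [gaze_recording()]),
#'   `subject_truth` and `event_truth` data frames.
#' @export
simulate_cohort <- function(timeline, config) {
  sims <- lapply(seq_len(config$n_subjects), function(i)
    simulate_recording(timeline, config, i))
  list(
    recordings = lapply(sims, function(s) s$recording),
    subject_truth = do.call(rbind, lapply(sims, function(s)
      s$truth$subject)),
    event_truth = do.call(rbind, lapply(sims, function(s) s$truth$events)))
}

#' Write a cohort's ground-truth manifest
#'
#' @param cohort A [simulate_cohort()] result.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_ground_truth <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(cohort$subject_truth,
                     file.path(dir, "truth_subjects.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  utils::write.table(cohort$event_truth,
                     file.path(dir, "truth_events.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(dir)
}
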