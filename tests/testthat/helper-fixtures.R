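# Shared fixtures, all built in code.

default_geom <- viewing_geometry()

# straight left-to-right track: x from 100 to 900 over 0..1000 ms
linear_track <- function(n = 11, t_max = 1000) {
  t <- seq(0, t_max, length.out = n)
  target_track(data.frame(t_ms = t, x_px = 100 + 800 * t / t_max,
                          y_px = 384))
}

# recording from explicit vectors
make_recording <- function(t_ms, x_px, y_px = 384, valid = TRUE,
                           subject_id = "S01", experiment = "exp1",
                           mirrored = FALSE, rate_hz = 1000) {
  n <- length(t_ms)
  gaze_recording(
    data.frame(t_ms = t_ms, x_px = rep_len(x_px, n),
               y_px = rep_len(y_px, n), valid = rep_len(valid, n)),
    subject_id = subject_id, experiment = experiment, mirrored = mirrored,
    rate_hz = rate_hz)
}

# a single interest-period row without building a whole timeline
make_period <- function(contact = 1000, half = 650, side = "right",
                        event_index = 2L, playback = "forward",
                        frozen = FALSE) {
  data.frame(event_index = event_index, throw_number = event_index,
             catcher_side = side, playback = playback,
             catcher_frozen = frozen, contact_time_ms = contact,
             t_start_ms = contact - half, t_end_ms = contact + half,
             half_window_ms = half, stringsAsFactors = FALSE)
}

right_aoi <- player_aoi("right", 768, 1024)
left_aoi <- player_aoi("left", 0, 256)

# naive reference detector: scan every sample, find the first run of
# consecutive valid in-AOI samples spanning >= min_dwell
naive_first_look <- function(samples, period, aoi, min_dwell) {
  s <- samples[samples$t_ms >= period$t_start_ms &
                 samples$t_ms < period$t_end_ms, , drop = FALSE]
  if (nrow(s) == 0L) return(NA_real_)
  d <- if (aoi$side == "right") s$x_px - aoi$inner_boundary_x
       else aoi$inner_boundary_x - s$x_px
  inaoi <- s$valid & !is.na(d) & d >= 0
  i <- 1L
  while (i <= nrow(s)) {
    if (inaoi[i]) {
      j <- i
      while (j < nrow(s) && inaoi[j + 1L]) j <- j + 1L
      if (s$t_ms[j] - s$t_ms[i] >= min_dwell)
        return(s$t_ms[i] - period$contact_time_ms)
      i <- j + 1L
    } else i <- i + 1L
  }
  NA_real_
}

# quiet cohort simulation helpers used across test files
quiet_cohort <- function(timeline, config) {
  suppressWarnings(simulate_cohort(timeline, config))
}

# run simulate -> normalize -> latencies -> exclusions, return candidates
cohort_candidates <- function(timeline, config, min_dwell_ms = 25) {
  coh <- quiet_cohort(timeline, config)
  recs <- lapply(coh$recordings, normalize_orientation,
                 video_width_px = timeline$geometry$video_px[1])
  obs <- do.call(rbind, lapply(recs, extract_latencies, timeline,
                               min_dwell_ms = min_dwell_ms))
  list(candidates = apply_exclusions(obs, recs, timeline),
       recordings = recs, truth = coh)
}
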