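#' Viewing geometry of the presentation setup
#'
#' Describes the physical viewing situation needed to convert pixel extents on
#' the presentation screen into visual angles: the eye-to-screen distance, the
#' pixel size of the video area, and the full horizontal visual angle that the
#' video area subtends. The pixel-to-centimetre scale is derived from the
#' horizontal extent only, since all analysed gaze signals are horizontal.
#'
#' @param distance_cm Viewing distance from the eyes to the screen, in cm.
#' @param video_px Integer vector `c(width, height)` of the video area in px.
#' @param horizontal_extent_deg Full horizontal visual angle of the video
#'   area, in degrees.
#' @return An object of class `viewing_geometry`.
#' @examples
#' geom <- viewing_geometry()
#' visual_angle_deg(52, geom)  # ~2.6 degrees
#' @export
viewing_geometry <- function(distance_cm = 50,
                             video_px = c(1024L, 768L),
                             horizontal_extent_deg = 48.2) {
  if (!is.numeric(distance_cm) || length(distance_cm) != 1L || distance_cm <= 0)
    stop("invalid geometry: 'distance_cm' must be a single positive number",
         call. = FALSE)
  video_px <- as.integer(video_px)
  if (length(video_px) != 2L || any(is.na(video_px)) || any(video_px <= 0L))
    stop("invalid geometry: 'video_px' must be two positive integers",
         call. = FALSE)
  if (!is.numeric(horizontal_extent_deg) || horizontal_extent_deg <= 0 ||
      horizontal_extent_deg >= 180)
    stop("invalid geometry: 'horizontal_extent_deg' must be in (0, 180)",
         call. = FALSE)
  width_cm <- 2 * distance_cm * tan(horizontal_extent_deg / 2 * pi / 180)
  stopifnot(width_cm > 0)
  structure(
    list(distance_cm = distance_cm,
         video_px = video_px,
         horizontal_extent_deg = horizontal_extent_deg,
         cm_per_px = width_cm / video_px[1L]),
    class = "viewing_geometry"
  )
}

#' @export
print.viewing_geometry <- function(x, ...) {
  cat(sprintf(
    "<viewing_geometry> %g cm distance, %d x %d px video, %.1f deg horizontal (%.4f cm/px)\n",
    x$distance_cm, x$video_px[1], x$video_px[2], x$horizontal_extent_deg,
    x$cm_per_px))
  invisible(x)
}

#' Visual angle subtended by a pixel extent
#'
#' Converts an on-screen extent in pixels to the visual angle it subtends at
#' the observer's eye, `2 * atan(extent_cm / (2 * distance_cm))`, using the
#' horizontal cm-per-pixel scale of the geometry.
#'
#' @param extent_px Extent in pixels (vectorised, must be non-negative).
#' @param geometry A [viewing_geometry()] object.
#' @return Visual angle(s) in degrees.
#' @export
visual_angle_deg <- function(extent_px, geometry = viewing_geometry()) {
  if (!inherits(geometry, "viewing_geometry"))
    stop("invalid geometry: expected a 'viewing_geometry' object", call. = FALSE)
  if (any(extent_px < 0)) stop("'extent_px' must be non-negative", call. = FALSE)
  extent_cm <- extent_px * geometry$cm_per_px
  2 * atan(extent_cm / (2 * geometry$distance_cm)) * 180 / pi
}

#' Reflect a horizontal pixel coordinate
#'
#' Maps `x` to `video_width_px - x`, the left-right mirror of the coordinate
#' within the video area. Applying the function twice returns the input, which
#' is how recordings collected with a mirrored stimulus are folded back into
#' the common reference frame.
#'
#' @param x_px Horizontal coordinate(s) in pixels.
#' @param video_width_px Width of the video area in pixels.
#' @return Mirrored coordinate(s).
#' @export
mirror_x <- function(x_px, video_width_px) {
  video_width_px - x_px
}

#' Dynamic target track
#'
#' An ordered sequence of time-stamped positions of the moving object, as
#' recorded by a dynamic area-of-interest tool (one row per AOI keyframe),
#' plus the radius of the circular AOI around the object. Positions between
#' keyframes are obtained by linear interpolation ([position_at()]).
#'
#' @param samples A data frame with numeric columns `t_ms`, `x_px`, `y_px`.
#' @param radius_px AOI radius around the object centre, in px.
#' @return An object of class `target_track`.
#' @export
target_track <- function(samples, radius_px = 26) {
  need <- c("t_ms", "x_px", "y_px")
  if (!all(need %in% names(samples)))
    stop("track samples need columns t_ms, x_px, y_px", call. = FALSE)
  samples <- as.data.frame(samples)[need]
  if (nrow(samples) < 2L)
    stop("a target track needs at least two samples to span motion",
         call. = FALSE)
  if (any(diff(samples$t_ms) <= 0))
    stop("track timestamps must be strictly increasing", call. = FALSE)
  if (any(!is.finite(as.matrix(samples))))
    stop("track samples must be finite", call. = FALSE)
  structure(list(samples = samples, radius_px = radius_px),
            class = "target_track")
}

#' @export
print.target_track <- function(x, ...) {
  s <- x$samples
  cat(sprintf("<target_track> %d samples over [%g, %g] ms, AOI radius %g px\n",
              nrow(s), s$t_ms[1], s$t_ms[nrow(s)], x$radius_px))
  invisible(x)
}

#' Interpolated target position at arbitrary times
#'
#' Linear interpolation of the track between bracketing keyframes; exact at
#' keyframe timestamps. Needed to align a high-rate gaze stream (1,000 Hz)
#' with an AOI track sampled every ~55-61 ms.
#'
#' @param track A [target_track()].
#' @param t_ms Time(s) in ms; must lie within the track's span.
#' @return A data frame with columns `x_px`, `y_px` (one row per time).
#' @export
position_at <- function(track, t_ms) {
  s <- track$samples
  span <- range(s$t_ms)
  if (any(t_ms < span[1] | t_ms > span[2]))
    stop(sprintf("time out of track span [%g, %g] ms", span[1], span[2]),
         call. = FALSE)
  data.frame(
    x_px = stats::approx(s$t_ms, s$x_px, xout = t_ms, ties = "ordered")$y,
    y_px = stats::approx(s$t_ms, s$y_px, xout = t_ms, ties = "ordered")$y
  )
}

#' Apply a freeze-rewind edit to a target track
#'
#' Edits the track the way the stimulus videos were edited: playback runs
#' normally up to `t_freeze_ms`, the object then holds its position for
#' `hold_ms`, the segment `[rewind_to_ms, t_freeze_ms]` is replayed
#' time-reversed at the original playback speed, and the original track
#' continues forward again from `rewind_to_ms`. Positions are continuous
#' across all splice points. With `hold_ms = 0` and
#' `rewind_to_ms = t_freeze_ms` the edit is empty and the track is returned
#' unchanged (up to node insertion at `t_freeze_ms`).
#'
#' @param track A [target_track()].
#' @param t_freeze_ms Time at which playback freezes.
#' @param hold_ms Duration of the frozen hold, in ms (1,000 in the stimulus
#'   videos).
#' @param rewind_to_ms Earlier time the video is rewound to; must satisfy
#'   `rewind_to_ms <= t_freeze_ms`.
#' @return A new `target_track` whose duration is longer by
#'   `hold_ms + 2 * (t_freeze_ms - rewind_to_ms)`.
#' @export
apply_freeze_rewind <- function(track, t_freeze_ms, hold_ms, rewind_to_ms) {
  s <- track$samples
  span <- range(s$t_ms)
  if (rewind_to_ms > t_freeze_ms)
    stop("invalid edit: rewind target lies after the freeze point",
         call. = FALSE)
  if (hold_ms < 0) stop("invalid edit: negative hold", call. = FALSE)
  if (t_freeze_ms < span[1] || t_freeze_ms > span[2] || rewind_to_ms < span[1])
    stop("invalid edit: freeze/rewind point outside track span", call. = FALSE)

  p_f <- position_at(track, t_freeze_ms)
  p_r <- position_at(track, rewind_to_ms)
  back_ms <- t_freeze_ms - rewind_to_ms

  pre <- s[s$t_ms < t_freeze_ms, , drop = FALSE]
  pre <- rbind(pre, data.frame(t_ms = t_freeze_ms, x_px = p_f$x_px,
                               y_px = p_f$y_px))

  parts <- list(pre)
  t_cursor <- t_freeze_ms
  if (hold_ms > 0) {
    parts[[length(parts) + 1L]] <-
      data.frame(t_ms = t_freeze_ms + hold_ms, x_px = p_f$x_px,
                 y_px = p_f$y_px)
    t_cursor <- t_freeze_ms + hold_ms
  }
  if (back_ms > 0) {
    # interior keyframes of [rewind_to, t_freeze], replayed in reverse
    mid <- s[s$t_ms > rewind_to_ms & s$t_ms < t_freeze_ms, , drop = FALSE]
    rev_part <- data.frame(
      t_ms = t_cursor + (t_freeze_ms - rev(mid$t_ms)),
      x_px = rev(mid$x_px), y_px = rev(mid$y_px))
    rev_part <- rbind(rev_part,
                      data.frame(t_ms = t_cursor + back_ms, x_px = p_r$x_px,
                                 y_px = p_r$y_px))
    rev_part <- rev_part[rev_part$t_ms > t_cursor, , drop = FALSE]
    parts[[length(parts) + 1L]] <- rev_part
    t_cursor <- t_cursor + back_ms
  }
  # original continuation from rewind_to onward, shifted into the new frame
  post <- s[s$t_ms > rewind_to_ms, , drop = FALSE]
  post$t_ms <- post$t_ms - rewind_to_ms + t_cursor
  parts[[length(parts) + 1L]] <- post

  out <- do.call(rbind, parts)
  out <- out[!duplicated(out$t_ms), , drop = FALSE]
  out <- out[order(out$t_ms), , drop = FALSE]
  rownames(out) <- NULL
  target_track(out, radius_px = track$radius_px)
}

#' Static player area of interest
#'
#' The rectangular screen region occupied by one of the two players. The
#' inner boundary is the vertical edge facing the screen centre; signed gaze
#' distances in the anticipation analysis are measured relative to it.
#'
#' @param side `"left"` or `"right"`.
#' @param x_min,x_max Horizontal extent of the rectangle in px.
#' @return An object of class `player_aoi`.
#' @export
player_aoi <- function(side = c("left", "right"), x_min, x_max) {
  side <- match.arg(side)
  if (x_min >= x_max) stop("player AOI needs x_min < x_max", call. = FALSE)
  structure(
    list(side = side, x_min = x_min, x_max = x_max,
         inner_boundary_x = if (side == "left") x_max else x_min),
    class = "player_aoi"
  )
}

## ---- timeline construction -------------------------------------------------

frame_before_ms <- function(t_ms, frame_rate_hz) {
  # start time of the video frame preceding the frame in which physical
  # time t_ms falls (contact happens within its frame; the reference frame
  # is the one before it)
  frame_ms <- 1000 / frame_rate_hz
  (floor(t_ms / frame_ms) - 1) * frame_ms
}

#' Default timeline construction settings
#'
#' @param frame_rate_hz Video frame rate (60 fps in the stimulus videos).
#' @param cycle_ms Duration of one throw cycle (hold + flight + hold).
#' @param flight_ms Time the object is in the air per throw (~650 ms).
#' @param player_width_frac Fraction of the video width covered by each
#'   player rectangle, measured from the video edge.
#' @param freeze_hold_ms Freeze duration for the freeze-rewind edits.
#' @param freeze_frac Fraction of the flight completed when the video is
#'   frozen (0.5 = mid-air).
#' @param rewind_pause_ms Hold at the thrower after each rewind completes,
#'   before the throw is replayed.
#' @param track_dt_ms Nominal AOI sampling interval of the emitted track.
#' @param arc_px Peak vertical rise of the object during a flight, in px.
#' @param radius_px AOI radius around the object (half its ~52 px diameter).
#' @param geometry A [viewing_geometry()].
#' @return A named list of settings for [build_timeline()].
#' @export
timeline_config <- function(frame_rate_hz = 60,
                            cycle_ms = 1600,
                            flight_ms = 650,
                            player_width_frac = 0.25,
                            freeze_hold_ms = 1000,
                            freeze_frac = 0.5,
                            rewind_pause_ms = 350,
                            track_dt_ms = NULL,
                            arc_px = 60,
                            radius_px = 26,
                            geometry = viewing_geometry()) {
  if (flight_ms >= cycle_ms)
    stop("inconsistent config: flight longer than the throw cycle",
         call. = FALSE)
  list(frame_rate_hz = frame_rate_hz, cycle_ms = cycle_ms,
       flight_ms = flight_ms, player_width_frac = player_width_frac,
       freeze_hold_ms = freeze_hold_ms, freeze_frac = freeze_frac,
       rewind_pause_ms = rewind_pause_ms, track_dt_ms = track_dt_ms,
       arc_px = arc_px, radius_px = radius_px, geometry = geometry)
}

# Piecewise evaluation of the un-edited back-and-forth motion.
# Throw k occupies [(k-1) cycle + pre, (k-1) cycle + pre + flight] with
# pre = (cycle - flight) / 2; odd throws go left -> right.
base_position <- function(t_ms, cfg, x_left, x_right, y_mid, n_throws) {
  pre <- (cfg$cycle_ms - cfg$flight_ms) / 2
  k <- pmin(pmax(floor(t_ms / cfg$cycle_ms) + 1, 1), n_throws)
  t_in <- t_ms - (k - 1) * cfg$cycle_ms
  u <- (t_in - pre) / cfg$flight_ms
  u <- pmin(pmax(u, 0), 1)
  from <- ifelse(k %% 2 == 1, x_left, x_right)
  to <- ifelse(k %% 2 == 1, x_right, x_left)
  data.frame(x_px = from + u * (to - from),
             y_px = y_mid - cfg$arc_px * sin(pi * u))
}

build_base_track <- function(cfg, n_throws, dt_ms) {
  geom <- cfg$geometry
  w <- geom$video_px[1]
  y_mid <- geom$video_px[2] / 2
  aoi_w <- w * cfg$player_width_frac
  x_left <- aoi_w / 2
  x_right <- w - aoi_w / 2
  duration <- n_throws * cfg$cycle_ms
  pre <- (cfg$cycle_ms - cfg$flight_ms) / 2
  keyframes <- sort(unique(c(
    0, duration,
    (seq_len(n_throws) - 1) * cfg$cycle_ms + pre,                # flight starts
    (seq_len(n_throws) - 1) * cfg$cycle_ms + pre + cfg$flight_ms # contacts
  )))
  grid <- seq(0, duration, by = dt_ms)
  t <- sort(unique(c(keyframes, grid)))
  pos <- base_position(t, cfg, x_left, x_right, y_mid, n_throws)
  list(track = target_track(data.frame(t_ms = t, pos), cfg$radius_px),
       x_left = x_left, x_right = x_right, duration = duration, pre = pre)
}

#' Build a stimulus timeline
#'
#' Constructs the full timeline of one of the two stimulus designs: the
#' moving-object track, the schedule of catch-type events, the freeze/rewind
#' edits, the two player rectangles and the viewing geometry.
#'
#' * `"exp1"`: ten forward throws alternating between the two players over
#'   ~16 s; the catcher is frozen (a boolean covariate only) on throws 2, 5,
#'   7 and 10. No track edits.
#' * `"exp2"`: the same ten-throw base, with the whole video frozen mid-air
#'   and rewound to the thrower twice in a row at throw 4 and twice at throw
#'   9 (four freeze + four rewind edits), over ~24 s. Each completed rewind
#'   resembles a catching event at the thrower, giving 10 forward + 4
#'   backward catch-type events. Five longer analysis periods (before,
#'   first freeze-rewind pair, between, last pair, after) are attached for
#'   the period-wise tracking analysis.
#'
#' Every event's `contact_time_ms` is the start of the last full video frame
#' before the object reaches the catcher.
#'
#' @param design `"exp1"` or `"exp2"`.
#' @param config A [timeline_config()].
#' @return An object of class `stimulus_timeline` with elements `design`,
#'   `duration_ms`, `frame_rate_hz`, `track`, `throws` (one row per
#'   catch-type event), `edits`, `players`, `geometry`, `analysis_periods`.
#' @export
build_timeline <- function(design = c("exp1", "exp2"),
                           config = timeline_config()) {
  design <- match.arg(design)
  cfg <- config
  n_throws <- 10L
  dt <- if (!is.null(cfg$track_dt_ms)) cfg$track_dt_ms else
    if (design == "exp1") 61 else 55
  base <- build_base_track(cfg, n_throws, dt)
  w <- cfg$geometry$video_px[1]
  aoi_w <- w * cfg$player_width_frac
  players <- list(left = player_aoi("left", 0, aoi_w),
                  right = player_aoi("right", w - aoi_w, w))

  pre <- base$pre
  flight_start <- (seq_len(n_throws) - 1) * cfg$cycle_ms + pre
  flight_end <- flight_start + cfg$flight_ms
  catcher <- ifelse(seq_len(n_throws) %% 2 == 1, "right", "left")
  thrower <- ifelse(seq_len(n_throws) %% 2 == 1, "left", "right")

  if (design == "exp1") {
    throws <- data.frame(
      event_index = seq_len(n_throws),
      throw_number = seq_len(n_throws),
      catcher_side = catcher,
      playback = "forward",
      contact_time_ms = frame_before_ms(flight_end, cfg$frame_rate_hz),
      catcher_frozen = seq_len(n_throws) %in% c(2L, 5L, 7L, 10L),
      flight_start_ms = flight_start,
      flight_end_ms = flight_end,
      stringsAsFactors = FALSE)
    tl <- list(design = design, duration_ms = base$duration,
               frame_rate_hz = cfg$frame_rate_hz, track = base$track,
               throws = throws,
               edits = data.frame(kind = character(), t_start_ms = numeric(),
                                  hold_ms = numeric(), rewind_to_ms = numeric()),
               players = players, geometry = cfg$geometry,
               analysis_periods = NULL, config = cfg)
    return(structure(tl, class = "stimulus_timeline"))
  }

  ## exp2: splice two freeze-rewind pairs at throws 4 and 9
  track <- base$track
  half <- cfg$freeze_frac * cfg$flight_ms
  hold <- cfg$freeze_hold_ms
  pause <- cfg$rewind_pause_ms
  edits <- NULL
  backward <- NULL
  seq_spans <- NULL
  offset <- 0
  for (k in c(4L, 9L)) {
    fs <- flight_start[k] + offset       # flight start in current track time
    seq_start <- fs
    for (rep in 1:2) {
      t_f <- fs + half
      track <- apply_freeze_rewind(track, t_f, hold, fs)
      t_rewind_done <- t_f + hold + half
      edits <- rbind(edits,
        data.frame(kind = "freeze", t_start_ms = t_f, hold_ms = hold,
                   rewind_to_ms = NA_real_),
        data.frame(kind = "rewind", t_start_ms = t_f + hold, hold_ms = NA_real_,
                   rewind_to_ms = fs))
      backward <- rbind(backward, data.frame(
        throw_number = k, catcher_side = thrower[k],
        contact_time_ms = frame_before_ms(t_rewind_done, cfg$frame_rate_hz),
        flight_start_ms = t_f + hold, flight_end_ms = t_rewind_done))
      # pause at the thrower before the replay
      track <- apply_freeze_rewind(track, t_rewind_done, pause, t_rewind_done)
      fs <- t_rewind_done + pause        # replayed flight starts here
    }
    seq_spans <- rbind(seq_spans, data.frame(t_start = seq_start, t_end = fs))
    offset <- offset + 2 * (2 * half + hold + pause)  # time added per pair
  }
  added_per_pair <- 2 * (2 * half + hold + pause)
  shift4 <- added_per_pair
  shift9 <- 2 * added_per_pair
  duration <- base$duration + shift9

  fwd_shift <- ifelse(seq_len(n_throws) <= 3, 0,
                      ifelse(seq_len(n_throws) <= 8, shift4, shift9))
  fwd <- data.frame(
    throw_number = seq_len(n_throws), catcher_side = catcher,
    playback = "forward",
    contact_time_ms = frame_before_ms(flight_end + fwd_shift,
                                      cfg$frame_rate_hz),
    catcher_frozen = FALSE,
    flight_start_ms = flight_start + fwd_shift,
    flight_end_ms = flight_end + fwd_shift,
    stringsAsFactors = FALSE)
  bwd <- data.frame(
    throw_number = backward$throw_number, catcher_side = backward$catcher_side,
    playback = "backward", contact_time_ms = backward$contact_time_ms,
    catcher_frozen = FALSE, flight_start_ms = backward$flight_start_ms,
    flight_end_ms = backward$flight_end_ms, stringsAsFactors = FALSE)
  throws <- rbind(fwd, bwd)
  throws <- throws[order(throws$contact_time_ms), , drop = FALSE]
  throws <- cbind(event_index = seq_len(nrow(throws)), throws)
  rownames(throws) <- NULL

  periods <- data.frame(
    label = c("beginning", "freeze_rewind_1", "middle", "freeze_rewind_2",
              "end"),
    t_start_ms = c(0, seq_spans$t_start[1], seq_spans$t_end[1],
                   seq_spans$t_start[2], seq_spans$t_end[2]),
    t_end_ms = c(seq_spans$t_start[1], seq_spans$t_end[1],
                 seq_spans$t_start[2], seq_spans$t_end[2], duration),
    condition = c("forward", "backward", "forward", "backward", "forward"),
    period_within_condition = c(1L, 1L, 2L, 2L, 3L),
    stringsAsFactors = FALSE)

  structure(
    list(design = design, duration_ms = duration,
         frame_rate_hz = cfg$frame_rate_hz, track = track, throws = throws,
         edits = edits, players = players, geometry = cfg$geometry,
         analysis_periods = periods, config = cfg),
    class = "stimulus_timeline")
}

#' @export
print.stimulus_timeline <- function(x, ...) {
  cat(sprintf(
    "<stimulus_timeline> %s: %g ms at %g fps, %d catch-type events (%d forward, %d backward), %d edits\n",
    x$design, x$duration_ms, x$frame_rate_hz, nrow(x$throws),
    sum(x$throws$playback == "forward"), sum(x$throws$playback == "backward"),
    if (is.null(x$edits)) 0L else nrow(x$edits)))
  invisible(x)
}
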