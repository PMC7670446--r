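#' Event-locked interest periods
#'
#' One analysis window per catch-type event, centred on the event's contact
#' time (the frame before the object reaches the catcher) and extending
#' `half_window_ms` to either side — roughly the time the object is in the
#' air per throw. Windows are half-open `[t_start, t_end)`.
#'
#' @param timeline A `stimulus_timeline`.
#' @param half_window_ms Half-width of each window, in ms.
#' @param warn_overlap Warn when adjacent windows overlap (they can, around
#'   the freeze-rewind sequences of the 24-s design)?
#' @return A data frame with one row per event: the event descriptors plus
#'   `t_start_ms`, `t_end_ms`, `half_window_ms`.
#' @export
build_interest_periods <- function(timeline, half_window_ms = 650,
                                   warn_overlap = TRUE) {
  th <- timeline$throws
  out <- data.frame(
    event_index = th$event_index, throw_number = th$throw_number,
    catcher_side = th$catcher_side, playback = th$playback,
    catcher_frozen = th$catcher_frozen,
    contact_time_ms = th$contact_time_ms,
    t_start_ms = th$contact_time_ms - half_window_ms,
    t_end_ms = th$contact_time_ms + half_window_ms,
    half_window_ms = half_window_ms,
    stringsAsFactors = FALSE)
  if (warn_overlap && nrow(out) > 1L &&
      any(out$t_start_ms[-1] < out$t_end_ms[-nrow(out)]))
    warning("adjacent interest periods overlap", call. = FALSE)
  out
}

#' Signed horizontal gaze distance from the catcher AOI boundary
#'
#' For each valid gaze sample in an interest period, the signed horizontal
#' distance from the inner boundary of the catcher's rectangle: positive
#' values lie within the catcher area of interest, negative values lie
#' between the two players. For a right-side catcher
#' `d = x_gaze - inner_boundary`; for a left-side catcher
#' `d = inner_boundary - x_gaze`.
#'
#' @param recording A [gaze_recording()].
#' @param period One row of [build_interest_periods()].
#' @param catcher_aoi The [player_aoi()] on the event's catcher side.
#' @return A data frame `t_ms`, `d_px` (possibly zero rows).
#' @export
signed_distance <- function(recording, period, catcher_aoi) {
  if (catcher_aoi$side != period$catcher_side)
    stop("catcher AOI side does not match the event", call. = FALSE)
  s <- recording$samples
  keep <- s$valid & s$t_ms >= period$t_start_ms & s$t_ms < period$t_end_ms
  s <- s[keep, , drop = FALSE]
  d <- if (catcher_aoi$side == "right") s$x_px - catcher_aoi$inner_boundary_x
       else catcher_aoi$inner_boundary_x - s$x_px
  data.frame(t_ms = s$t_ms, d_px = d)
}

#' First-look latency to the catcher within an interest period
#'
#' The first time the subject looked at the catcher inside the window,
#' relative to the contact time; negative latencies are anticipatory. A
#' "look" is the first run of consecutive valid samples with signed
#' distance >= 0 spanning at least `min_dwell_ms`; the dwell guard
#' suppresses single-sample noise excursions (set it to 0 for a literal
#' first-sample rule). Invalid samples break a run. If no qualifying run
#' exists the observation has status `"no_look"`.
#'
#' @param recording A [gaze_recording()].
#' @param period One row of [build_interest_periods()].
#' @param catcher_aoi The [player_aoi()] on the event's catcher side.
#' @param min_dwell_ms Minimum sustained time inside the AOI, in ms.
#' @return A one-row data frame: `subject_id`, `event_index`,
#'   `throw_number`, `playback`, `catcher_frozen`, `catcher_side`,
#'   `latency_ms`, `status` (`"observed"` or `"no_look"`).
#' @export
first_look_latency <- function(recording, period, catcher_aoi,
                               min_dwell_ms = 25) {
  obs <- data.frame(
    subject_id = recording$subject_id, event_index = period$event_index,
    throw_number = period$throw_number, playback = period$playback,
    catcher_frozen = period$catcher_frozen,
    catcher_side = period$catcher_side,
    latency_ms = NA_real_, status = "no_look", stringsAsFactors = FALSE)
  s <- recording$samples
  keep <- s$t_ms >= period$t_start_ms & s$t_ms < period$t_end_ms
  s <- s[keep, , drop = FALSE]
  if (nrow(s) == 0L) return(obs)
  d <- if (catcher_aoi$side == "right")
    s$x_px - catcher_aoi$inner_boundary_x
  else catcher_aoi$inner_boundary_x - s$x_px
  in_aoi <- s$valid & !is.na(d) & d >= 0
  if (!any(in_aoi)) return(obs)
  runs <- rle(in_aoi)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  for (i in which(runs$values)) {
    span <- s$t_ms[ends[i]] - s$t_ms[starts[i]]
    if (span >= min_dwell_ms) {
      obs$latency_ms <- s$t_ms[starts[i]] - period$contact_time_ms
      obs$status <- "observed"
      break
    }
  }
  obs
}

#' Extract first-look latencies for every event of a recording
#'
#' @param recording A [gaze_recording()] (already orientation-normalized).
#' @param timeline A `stimulus_timeline`.
#' @param half_window_ms Interest-period half-width.
#' @param min_dwell_ms Dwell guard of [first_look_latency()].
#' @return A data frame with one row per catch-type event, plus an
#'   `experiment` column.
#' @export
extract_latencies <- function(recording, timeline, half_window_ms = 650,
                              min_dwell_ms = 25) {
  periods <- build_interest_periods(timeline, half_window_ms,
                                    warn_overlap = FALSE)
  rows <- lapply(seq_len(nrow(periods)), function(i) {
    p <- periods[i, , drop = FALSE]
    first_look_latency(recording, p, timeline$players[[p$catcher_side]],
                       min_dwell_ms = min_dwell_ms)
  })
  out <- do.call(rbind, rows)
  out <- cbind(experiment = recording$experiment, out,
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Apply the observation-level exclusion rules
#'
#' Two rules shape the model dataset:
#' * the first catch-type event is dropped for every subject (subjects tend
#'   to look back and forth between the players at video onset, so a "first
#'   look" there is uninterpretable), and
#' * an observation is marked `"not_looked_away"` when the subject's gaze
#'   never left the catcher rectangle between the previous event's contact
#'   time (video onset for event 2) and the start of the current window —
#'   the "first look" would simply be a continuation of the previous one.
#'   Absence of any valid sample over that span triggers the same status.
#'
#' The returned rows (all statuses) are the candidate events; rows with
#' status `"observed"` form the model dataset.
#'
#' @param observations Stacked [extract_latencies()] rows for one or more
#'   subjects.
#' @param recordings Named list of the corresponding [gaze_recording()]s
#'   (names or `subject_id`s must cover the observations).
#' @param timeline The `stimulus_timeline` the observations came from.
#' @param half_window_ms Interest-period half-width used at extraction.
#' @return `observations` minus event 1, with statuses updated.
#' @export
apply_exclusions <- function(observations, recordings, timeline,
                             half_window_ms = 650) {
  ids <- vapply(recordings, function(r) r$subject_id, character(1))
  names(recordings) <- ids
  periods <- build_interest_periods(timeline, half_window_ms,
                                    warn_overlap = FALSE)
  obs <- observations[observations$event_index != 1L, , drop = FALSE]
  for (i in seq_len(nrow(obs))) {
    ev <- obs$event_index[i]
    rec <- recordings[[obs$subject_id[i]]]
    p <- periods[periods$event_index == ev, , drop = FALSE]
    span_start <- if (ev == 2L) 0 else
      periods$contact_time_ms[periods$event_index == ev - 1L]
    s <- rec$samples
    keep <- s$valid & s$t_ms >= span_start & s$t_ms < p$t_start_ms
    s <- s[keep, , drop = FALSE]
    aoi <- timeline$players[[p$catcher_side]]
    away <- nrow(s) > 0L && any(s$x_px < aoi$x_min | s$x_px > aoi$x_max)
    if (!away) {
      obs$status[i] <- "not_looked_away"
      obs$latency_ms[i] <- NA_real_
    }
  }
  rownames(obs) <- NULL
  obs
}

#' Median and range of observed latencies
#'
#' @param observations Stacked observation rows.
#' @return A list with `median`, `min`, `max`, `n_observed`, `n_candidate`.
#' @export
summarize_latency <- function(observations) {
  lat <- observations$latency_ms[observations$status == "observed"]
  if (length(lat) == 0L)
    stop("no observed latencies to summarise", call. = FALSE)
  list(median = stats::median(lat), min = min(lat), max = max(lat),
       n_observed = length(lat), n_candidate = nrow(observations))
}

#' Write an observations table
#'
#' @param observations Stacked observation rows.
#' @param path Output path (tab-delimited text).
#' @return `path`, invisibly.
#' @export
write_observations <- function(observations, path) {
  out <- observations
  out$latency_ms <- ifelse(is.na(out$latency_ms), "",
                           formatC(out$latency_ms, digits = 3, format = "f"))
  utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
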