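#' Gaze recording container
#'
#' One subject's raw gaze sample stream: time from video onset, screen
#' position, and a per-sample validity flag (`FALSE` marks blinks / track
#' loss). No event detection (fixation or saccade parsing) is applied
#' anywhere in the package; all analyses consume raw samples.
#'
#' @param samples Data frame with columns `t_ms`, `x_px`, `y_px`, `valid`.
#'   Invalid samples may carry `NA` coordinates.
#' @param subject_id Subject identifier (coerced to character).
#' @param experiment `"exp1"` or `"exp2"`.
#' @param mirrored Was this subject shown the left-right mirrored video?
#' @param rate_hz Nominal sampling rate (1,000 Hz for the tower-mount
#'   tracker used to collect the original data).
#' @return An object of class `gaze_recording`.
#' @export
gaze_recording <- function(samples, subject_id, experiment = c("exp1", "exp2"),
                           mirrored = FALSE, rate_hz = 1000) {
  experiment <- match.arg(experiment)
  need <- c("t_ms", "x_px", "y_px", "valid")
  if (!all(need %in% names(samples)))
    stop("gaze samples need columns t_ms, x_px, y_px, valid", call. = FALSE)
  samples <- as.data.frame(samples)[need]
  samples$valid <- as.logical(samples$valid)
  bad_coord <- !is.finite(samples$x_px) | !is.finite(samples$y_px)
  samples$valid[bad_coord] <- FALSE
  if (is.unsorted(samples$t_ms))
    stop("gaze timestamps must be non-decreasing", call. = FALSE)
  if (rate_hz <= 0) stop("rate_hz must be positive", call. = FALSE)
  structure(
    list(subject_id = as.character(subject_id), experiment = experiment,
         mirrored = isTRUE(mirrored), rate_hz = rate_hz, samples = samples),
    class = "gaze_recording")
}

#' @export
print.gaze_recording <- function(x, ...) {
  s <- x$samples
  cat(sprintf(
    "<gaze_recording> subject %s (%s%s): %d samples at %g Hz, %.1f%% valid\n",
    x$subject_id, x$experiment, if (x$mirrored) ", mirrored" else "",
    nrow(s), x$rate_hz, 100 * mean(s$valid)))
  invisible(x)
}

#' Column-name dialect for gaze sample files
#'
#' Maps the four logical columns onto the header names used by a particular
#' export format, so native tracker sample reports can be read without code
#' changes. The default dialect matches the package's own writer.
#'
#' @param t,x,y,valid Header names holding time (ms), horizontal and
#'   vertical gaze position (px), and sample validity.
#' @return A named character vector usable as the `dialect` of [read_gaze()].
#' @export
gaze_dialect <- function(t = "t_ms", x = "x_px", y = "y_px",
                         valid = "valid") {
  c(t = t, x = x, y = y, valid = valid)
}

#' Read a gaze sample file
#'
#' Reads a delimited text file of raw gaze samples into a
#' [gaze_recording()]. Rows whose coordinates cannot be parsed (blank or
#' non-numeric fields, the usual encoding of blinks in sample reports)
#' become invalid samples; the row count is always preserved. If the file
#' has no validity column, validity is inferred from coordinate parsability.
#'
#' @param path Path to a delimited text file with a header.
#' @param dialect A [gaze_dialect()] naming the time/x/y/validity columns.
#' @param sep Field separator.
#' @param subject_id Subject id; defaults to a `subject_id` column if
#'   present, else the file name.
#' @param experiment,mirrored,rate_hz Recording metadata (see
#'   [gaze_recording()]).
#' @return A [gaze_recording()].
#' @export
read_gaze <- function(path, dialect = gaze_dialect(), sep = "\t",
                      subject_id = NULL, experiment = "exp1",
                      mirrored = FALSE, rate_hz = 1000) {
  if (!file.exists(path)) stop("gaze file not found: ", path, call. = FALSE)
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (nrow(raw) == 0L) stop("empty gaze file: ", path, call. = FALSE)
  for (col in dialect[c("t", "x", "y")]) {
    if (!col %in% names(raw))
      stop(sprintf("gaze file %s is missing required column '%s'", path, col),
           call. = FALSE)
  }
  num <- function(v) suppressWarnings(as.numeric(v))
  t_ms <- num(raw[[dialect[["t"]]]])
  if (any(is.na(t_ms)))
    stop("unparseable timestamps in ", path, call. = FALSE)
  x <- num(raw[[dialect[["x"]]]])
  y <- num(raw[[dialect[["y"]]]])
  if (dialect[["valid"]] %in% names(raw)) {
    v <- raw[[dialect[["valid"]]]]
    valid <- v %in% c("TRUE", "true", "T", "1")
  } else {
    valid <- !is.na(x) & !is.na(y)
  }
  valid <- valid & !is.na(x) & !is.na(y)
  if (is.null(subject_id)) {
    subject_id <- if ("subject_id" %in% names(raw)) raw$subject_id[1] else
      tools::file_path_sans_ext(basename(path))
  }
  gaze_recording(data.frame(t_ms = t_ms, x_px = x, y_px = y, valid = valid),
                 subject_id = subject_id, experiment = experiment,
                 mirrored = mirrored, rate_hz = rate_hz)
}

#' Write a gaze recording to a delimited text file
#'
#' @param recording A [gaze_recording()].
#' @param path Output path.
#' @param sep Field separator.
#' @return `path`, invisibly.
#' @export
write_gaze <- function(recording, path, sep = "\t") {
  s <- recording$samples
  out <- data.frame(subject_id = recording$subject_id, s)
  utils::write.table(out, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a dynamic AOI track file
#'
#' Reads a delimited file with header columns `time_ms`, `x_px`, `y_px`
#' (one row per AOI keyframe) into a [target_track()]. Duplicate timestamps
#' are collapsed to the last occurrence.
#'
#' @param path Path to the track file.
#' @param radius_px AOI radius to attach to the track.
#' @param sep Field separator.
#' @return A [target_track()].
#' @export
read_aoi_track <- function(path, radius_px = 26, sep = "\t") {
  if (!file.exists(path)) stop("AOI track file not found: ", path,
                               call. = FALSE)
  raw <- utils::read.table(path, header = TRUE, sep = sep)
  need <- c("time_ms", "x_px", "y_px")
  for (col in need) {
    if (!col %in% names(raw))
      stop(sprintf("AOI track %s is missing required column '%s'", path, col),
           call. = FALSE)
  }
  raw <- raw[!duplicated(raw$time_ms, fromLast = TRUE), , drop = FALSE]
  if (nrow(raw) >= 2L && any(diff(raw$time_ms) <= 0))
    stop("AOI track times are not increasing after collapsing duplicates",
         call. = FALSE)
  target_track(data.frame(t_ms = raw$time_ms, x_px = raw$x_px,
                          y_px = raw$y_px),
               radius_px = radius_px)
}

#' Write a target track as a dynamic AOI track file
#'
#' @param track A [target_track()].
#' @param path Output path.
#' @param sep Field separator.
#' @return `path`, invisibly.
#' @export
write_aoi_track <- function(track, path, sep = "\t") {
  s <- track$samples
  out <- data.frame(time_ms = s$t_ms, x_px = s$x_px, y_px = s$y_px)
  utils::write.table(out, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Fold a mirrored recording into the common reference frame
#'
#' Subjects shown the left-right mirrored stimulus are analysed after
#' reflecting their horizontal gaze coordinates back ([mirror_x()]); the
#' mirrored flag is then cleared. Recordings that are not mirrored are
#' returned unchanged. Validity flags and sample times are never altered.
#'
#' @param recording A [gaze_recording()].
#' @param video_width_px Width of the video area in px.
#' @return A [gaze_recording()] in the canonical orientation.
#' @export
normalize_orientation <- function(recording, video_width_px = 1024) {
  if (!recording$mirrored) return(recording)
  s <- recording$samples
  s$x_px <- mirror_x(s$x_px, video_width_px)
  out <- recording
  out$samples <- s
  out$mirrored <- FALSE
  out
}

## ---- timeline serialization ------------------------------------------------

#' Serialize a stimulus timeline to plain text
#'
#' Writes the timeline as a YAML config (geometry, players, events, edits,
#' analysis periods) plus a companion AOI track file next to it, so that a
#' timeline round-trips losslessly through [read_timeline()].
#'
#' @param timeline A [build_timeline()] result.
#' @param path Path of the YAML file to write; the track is written to the
#'   same name with extension `.track.tsv`.
#' @return `path`, invisibly.
#' @export
write_timeline <- function(timeline, path) {
  track_path <- paste0(tools::file_path_sans_ext(path), ".track.tsv")
  write_aoi_track(timeline$track, track_path)
  g <- timeline$geometry
  doc <- list(
    design = timeline$design,
    duration_ms = timeline$duration_ms,
    frame_rate_hz = timeline$frame_rate_hz,
    geometry = list(distance_cm = g$distance_cm,
                    video_px = as.integer(g$video_px),
                    horizontal_extent_deg = g$horizontal_extent_deg),
    radius_px = timeline$track$radius_px,
    players = lapply(timeline$players, function(p)
      list(side = p$side, x_min = p$x_min, x_max = p$x_max)),
    throws = lapply(seq_len(nrow(timeline$throws)), function(i)
      as.list(timeline$throws[i, , drop = FALSE])),
    edits = if (nrow(timeline$edits) == 0L) list() else
      lapply(seq_len(nrow(timeline$edits)), function(i)
        as.list(timeline$edits[i, , drop = FALSE])),
    analysis_periods = if (is.null(timeline$analysis_periods)) NULL else
      lapply(seq_len(nrow(timeline$analysis_periods)), function(i)
        as.list(timeline$analysis_periods[i, , drop = FALSE])),
    track_file = basename(track_path))
  yaml::write_yaml(doc, path, precision = 15)
  invisible(path)
}

#' Read a serialized stimulus timeline
#'
#' @param path Path to a YAML file written by [write_timeline()].
#' @return A `stimulus_timeline`.
#' @export
read_timeline <- function(path) {
  if (!file.exists(path)) stop("timeline file not found: ", path,
                               call. = FALSE)
  doc <- yaml::read_yaml(path)
  track <- read_aoi_track(file.path(dirname(path), doc$track_file),
                          radius_px = doc$radius_px)
  bindrows <- function(lst) {
    if (is.null(lst) || length(lst) == 0L) return(NULL)
    do.call(rbind, lapply(lst, as.data.frame))
  }
  throws <- bindrows(doc$throws)
  edits <- bindrows(doc$edits)
  if (is.null(edits))
    edits <- data.frame(kind = character(), t_start_ms = numeric(),
                        hold_ms = numeric(), rewind_to_ms = numeric())
  periods <- bindrows(doc$analysis_periods)
  geom <- viewing_geometry(doc$geometry$distance_cm,
                           unlist(doc$geometry$video_px),
                           doc$geometry$horizontal_extent_deg)
  players <- lapply(doc$players, function(p)
    player_aoi(p$side, p$x_min, p$x_max))
  structure(
    list(design = doc$design, duration_ms = doc$duration_ms,
         frame_rate_hz = doc$frame_rate_hz, track = track, throws = throws,
         edits = edits, players = players, geometry = geom,
         analysis_periods = periods, config = NULL),
    class = "stimulus_timeline")
}
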