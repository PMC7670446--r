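#' Fraction of valid gaze samples on the video area
#'
#' Proportion of a recording's valid samples whose position falls inside the
#' video rectangle. Used for the subject-level attention inclusion rule:
#' subjects who spent less than a threshold proportion (70% in the original
#' study design) looking at the video are excluded before any analysis.
#' The criterion operates on raw valid samples, consistent with the rest of
#' the pipeline, which applies no fixation detection.
#'
#' @param recording A [gaze_recording()].
#' @param video_rect Numeric `c(x_min, y_min, x_max, y_max)` of the video
#'   area in px.
#' @return A proportion in `[0, 1]`.
#' @export
attention_fraction <- function(recording,
                               video_rect = c(0, 0, 1024, 768)) {
  s <- recording$samples
  s <- s[s$valid, , drop = FALSE]
  if (nrow(s) == 0L)
    stop("attention fraction undefined: recording has no valid samples",
         call. = FALSE)
  inside <- s$x_px >= video_rect[1] & s$x_px <= video_rect[3] &
    s$y_px >= video_rect[2] & s$y_px <= video_rect[4]
  mean(inside)
}

#' Partition subjects by the attention inclusion rule
#'
#' Splits a list of recordings into included and excluded sets by comparing
#' each subject's [attention_fraction()] against the threshold (inclusive:
#' a fraction exactly at the threshold is kept). Input order is preserved
#' within both sets.
#'
#' @param recordings A list of [gaze_recording()] objects.
#' @param threshold Minimum on-video fraction for inclusion.
#' @param video_rect Video rectangle passed to [attention_fraction()].
#' @return A list with elements `included`, `excluded` (lists of
#'   recordings) and `report`, a data frame with one row per subject
#'   (`subject_id`, `fraction_on_video`, `threshold`, `included`).
#' @export
filter_subjects <- function(recordings, threshold = 0.70,
                            video_rect = c(0, 0, 1024, 768)) {
  frac <- vapply(recordings, attention_fraction, numeric(1),
                 video_rect = video_rect)
  keep <- frac >= threshold
  report <- data.frame(
    subject_id = vapply(recordings, function(r) r$subject_id, character(1)),
    fraction_on_video = frac,
    threshold = threshold,
    included = keep,
    stringsAsFactors = FALSE)
  rownames(report) <- NULL
  list(included = recordings[keep], excluded = recordings[!keep],
       report = report)
}

#' Write the subject exclusion report
#'
#' @param report The `report` element of [filter_subjects()].
#' @param path Output path (tab-delimited text).
#' @return `path`, invisibly.
#' @export
write_exclusion_report <- function(report, path) {
  out <- report
  out$fraction_on_video <- formatC(out$fraction_on_video, digits = 6,
                                   format = "f")
  utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
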