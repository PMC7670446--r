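#' Motion-tracking regression of gaze on target position
#'
#' Quantifies how well a subject followed the moving object: an ordinary
#' least-squares fit of horizontal gaze position on the horizontal target
#' position, paired sample-by-sample at the gaze timestamps (the target
#' track is linearly interpolated to each gaze time, so the full-rate gaze
#' stream remains the response). The coefficient of determination r-squared
#' is the proportion of variance in horizontal gaze explained by the target
#' motion and equals the squared Pearson correlation of the pairs.
#'
#' Invalid samples and samples outside the video rectangle are dropped
#' pairwise (set `on_video_only = FALSE` to keep off-screen valid samples).
#' A window whose target position is constant (e.g. an interval lying
#' entirely inside a freeze) has no defined r-squared; the fit is returned
#' with `r2 = NA` and flagged, never silently reported as 0.
#'
#' @param recording A [gaze_recording()].
#' @param track A [target_track()].
#' @param window Optional `c(t_start_ms, t_end_ms)`; samples with
#'   `t_start <= t < t_end` are used. Default: the whole overlap of
#'   recording and track.
#' @param video_rect Video rectangle for the on-video filter.
#' @param on_video_only Drop valid samples lying outside `video_rect`?
#' @param label Window label carried into reports.
#' @return An object of class `tracking_fit`: a one-row data frame with
#'   `subject_id`, `window`, `t_start_ms`, `t_end_ms`, `slope`, `intercept`,
#'   `r2`, `n`, `degenerate`.
#' @export
fit_tracking <- function(recording, track, window = NULL,
                         video_rect = c(0, 0, 1024, 768),
                         on_video_only = TRUE, label = "whole_video") {
  s <- recording$samples
  span <- range(track$samples$t_ms)
  if (is.null(window)) window <- c(max(min(s$t_ms), span[1]),
                                   min(max(s$t_ms), span[2]) + 1e-9)
  keep <- s$valid & s$t_ms >= window[1] & s$t_ms < window[2] &
    s$t_ms >= span[1] & s$t_ms <= span[2]
  if (on_video_only) {
    keep <- keep & s$x_px >= video_rect[1] & s$x_px <= video_rect[3] &
      s$y_px >= video_rect[2] & s$y_px <= video_rect[4]
  }
  s <- s[keep, , drop = FALSE]
  if (nrow(s) < 2L)
    stop("insufficient data: fewer than 2 usable gaze samples in window",
         call. = FALSE)
  target_x <- position_at(track, s$t_ms)$x_px
  out <- data.frame(subject_id = recording$subject_id, window = label,
                    t_start_ms = window[1], t_end_ms = window[2],
                    slope = NA_real_, intercept = NA_real_, r2 = NA_real_,
                    n = nrow(s), degenerate = FALSE,
                    stringsAsFactors = FALSE)
  if (stats::var(target_x) == 0) {
    out$degenerate <- TRUE
    class(out) <- c("tracking_fit", class(out))
    return(out)
  }
  fit <- stats::lm.fit(cbind(1, target_x), s$x_px)
  out$intercept <- fit$coefficients[1]
  out$slope <- fit$coefficients[2]
  tss <- sum((s$x_px - mean(s$x_px))^2)
  out$r2 <- if (tss == 0) 1 else 1 - sum(fit$residuals^2) / tss
  class(out) <- c("tracking_fit", class(out))
  out
}

#' Summarise r-squared across subjects
#'
#' Median and range of the tracking r-squared over a set of fits, the way
#' per-subject tracking performance is reported. Degenerate (undefined)
#' fits are excluded and counted.
#'
#' @param fits A list of [fit_tracking()] results, or a data frame of
#'   stacked fits.
#' @return A list with `median`, `min`, `max`, `n`, `n_undefined`.
#' @export
summarize_r2 <- function(fits) {
  if (is.data.frame(fits)) r2 <- fits$r2
  else r2 <- vapply(fits, function(f) f$r2, numeric(1))
  defined <- r2[!is.na(r2)]
  if (length(defined) == 0L)
    stop("empty summary: all tracking fits are undefined", call. = FALSE)
  list(median = stats::median(defined), min = min(defined),
       max = max(defined), n = length(defined),
       n_undefined = sum(is.na(r2)))
}

#' Per-period tracking fits for a timeline's analysis periods
#'
#' Fits the motion-tracking regression separately inside each of a
#' timeline's longer analysis periods (for the 24-s design: before, first
#' freeze-rewind pair, between, last pair, after).
#'
#' @param recording A [gaze_recording()].
#' @param timeline A `stimulus_timeline` with non-`NULL` `analysis_periods`.
#' @param ... Passed to [fit_tracking()].
#' @return A data frame of stacked `tracking_fit` rows, one per period.
#' @export
fit_tracking_periods <- function(recording, timeline, ...) {
  periods <- timeline$analysis_periods
  if (is.null(periods))
    stop("timeline has no analysis periods", call. = FALSE)
  rows <- lapply(seq_len(nrow(periods)), function(i) {
    fit_tracking(recording, timeline$track,
                 window = c(periods$t_start_ms[i], periods$t_end_ms[i]),
                 label = periods$label[i], ...)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a tracking report
#'
#' @param fits Data frame of stacked tracking fits.
#' @param path Output path (tab-delimited text).
#' @return `path`, invisibly.
#' @export
write_tracking_report <- function(fits, path) {
  out <- as.data.frame(fits)
  for (col in c("slope", "intercept", "r2"))
    out[[col]] <- formatC(out[[col]], digits = 6, format = "f")
  utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
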