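#' End-to-end run configuration
#'
#' Bundles every knob of an end-to-end analysis run: the stimulus design,
#' the input mode (simulate a cohort or ingest files), the analysis
#' thresholds with their standard defaults (attention 0.70, interest-period
#' half-width 650 ms, dwell guard 25 ms), the model set, the seed and the
#' output directory.
#'
#' In `"files"` mode, `manifest` points to a tab-delimited table with
#' columns `subject_id`, `path`, `mirrored`, and `timeline` points to a
#' YAML file written by [write_timeline()].
#'
#' @param design `"exp1"` or `"exp2"`.
#' @param mode `"simulate"` or `"files"`.
#' @param out_dir Output directory for the report bundle.
#' @param seed Seed for simulate mode.
#' @param n_subjects Cohort size for simulate mode.
#' @param sim_config Optional full [simulation_config()]; overrides `seed`
#'   and `n_subjects`.
#' @param manifest,timeline Input paths for files mode.
#' @param attention_threshold Minimum on-video fraction for inclusion.
#' @param half_window_ms Interest-period half-width.
#' @param min_dwell_ms Dwell guard for first-look detection.
#' @param models Which latency models to fit (subset of
#'   `"lmm01"`, `"lmm02"`, `"lmm03"`; defaults depend on the design).
#' @return A list of class `run_config`.
#' @export
run_config <- function(design = c("exp1", "exp2"),
                       mode = c("simulate", "files"),
                       out_dir = tempfile("dynaoi_run_"),
                       seed = 1L,
                       n_subjects = 14,
                       sim_config = NULL,
                       manifest = NULL,
                       timeline = NULL,
                       attention_threshold = 0.70,
                       half_window_ms = 650,
                       min_dwell_ms = 25,
                       models = NULL) {
  design <- match.arg(design)
  mode <- match.arg(mode)
  if (is.null(models))
    models <- if (design == "exp1") "lmm01" else c("lmm02", "lmm03")
  if (mode == "files") {
    if (is.null(manifest) || is.null(timeline))
      stop("files mode needs 'manifest' and 'timeline' paths", call. = FALSE)
  }
  structure(
    list(design = design, mode = mode, out_dir = out_dir, seed = seed,
         n_subjects = n_subjects, sim_config = sim_config,
         manifest = manifest, timeline = timeline,
         attention_threshold = attention_threshold,
         half_window_ms = half_window_ms, min_dwell_ms = min_dwell_ms,
         models = models),
    class = "run_config")
}

## ---- model data preparation ------------------------------------------------

#' Prepare the event-level model dataset
#'
#' Restricts candidate observations to those with an observed look,
#' z-standardizes the event number and codes the condition factor for the
#' event-level latency models: for the 16-s design, catcher movement with
#' reference level `"frozen"`; for the 24-s design, object movement
#' (playback direction) with reference level `"backward"`.
#'
#' @param observations Candidate observations ([apply_exclusions()] output).
#' @return A data frame with columns `subject_id`, `latency_ms`,
#'   `throw_z`, `movement`.
#' @export
prepare_event_model_data <- function(observations) {
  d <- observations[observations$status == "observed", , drop = FALSE]
  if (nrow(d) == 0L) stop("no observed latencies", call. = FALSE)
  exp1 <- all(d$experiment == "exp1")
  movement <- if (exp1)
    factor(ifelse(d$catcher_frozen, "frozen", "moving"),
           levels = c("frozen", "moving"))
  else factor(d$playback, levels = c("backward", "forward"))
  data.frame(subject_id = d$subject_id, latency_ms = d$latency_ms,
             throw_z = z_standardize(d$event_index), movement = movement,
             stringsAsFactors = FALSE)
}

#' Prepare the period-level model dataset
#'
#' Maps each catch-type event to the timeline's longer analysis period,
#' averages the observed latencies per subject and period, and codes the
#' covariates of the period-level model: movement condition (reference
#' `"backward"`) and the period number within condition, z-standardized.
#'
#' @param observations Candidate observations ([apply_exclusions()] output).
#' @param timeline The `stimulus_timeline` (must carry `analysis_periods`).
#' @return A data frame with `subject_id`, `mean_latency_ms`, `movement`,
#'   `period_z`, `period_within_condition`.
#' @export
prepare_period_model_data <- function(observations, timeline) {
  periods <- timeline$analysis_periods
  if (is.null(periods))
    stop("timeline has no analysis periods", call. = FALSE)
  d <- observations[observations$status == "observed", , drop = FALSE]
  if (nrow(d) == 0L) stop("no observed latencies", call. = FALSE)
  contact <- timeline$throws$contact_time_ms[
    match(d$event_index, timeline$throws$event_index)]
  p_idx <- findInterval(contact, periods$t_start_ms)
  d$condition <- periods$condition[p_idx]
  d$period_within_condition <- periods$period_within_condition[p_idx]
  agg <- stats::aggregate(latency_ms ~ subject_id + condition +
                            period_within_condition, data = d, FUN = mean)
  names(agg)[names(agg) == "latency_ms"] <- "mean_latency_ms"
  agg$movement <- factor(agg$condition, levels = c("backward", "forward"))
  agg$period_z <- stats::ave(agg$period_within_condition, agg$condition,
                             FUN = z_standardize)
  agg[order(agg$subject_id, agg$condition, agg$period_within_condition), ,
      drop = FALSE]
}

## ---- end-to-end run --------------------------------------------------------

read_manifest_recordings <- function(config) {
  if (!file.exists(config$manifest))
    stop("pipeline stage 'ingest': manifest file not found: ",
         config$manifest, call. = FALSE)
  man <- utils::read.table(config$manifest, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  lapply(seq_len(nrow(man)), function(i) {
    p <- man$path[i]
    if (!file.exists(p))
      stop("pipeline stage 'ingest': gaze file not found: ", p,
           call. = FALSE)
    read_gaze(p, subject_id = man$subject_id[i], experiment = config$design,
              mirrored = isTRUE(as.logical(man$mirrored[i])))
  })
}

#' Run the full analysis pipeline
#'
#' Executes the whole chain — simulate or ingest, normalize orientation,
#' apply the attention inclusion rule, fit the motion-tracking regressions
#' (whole video, plus the five analysis periods for the 24-s design),
#' extract first-look latencies, apply the observation exclusions, fit the
#' requested mixed models with stability ranges and VIFs — and writes the
#' report bundle as delimited text into `config$out_dir`: exclusion report,
#' tracking report, observations table, latency summary, one model table
#' per fitted model, and a run log recording the seed and every threshold.
#' Identical configs produce byte-identical bundles.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the timeline, recordings, reports and
#'   fitted models.
#' @export
run_pipeline <- function(config) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }
  timeline <- stage("timeline", {
    if (config$mode == "files") read_timeline(config$timeline)
    else build_timeline(config$design)
  })
  recordings <- stage("input", {
    if (config$mode == "files") read_manifest_recordings(config)
    else {
      sc <- config$sim_config
      if (is.null(sc))
        sc <- simulation_config(n_subjects = config$n_subjects,
                                seed = config$seed)
      simulate_cohort(timeline, sc)$recordings
    }
  })
  w <- timeline$geometry$video_px[1]
  h <- timeline$geometry$video_px[2]
  rect <- c(0, 0, w, h)
  recordings <- stage("normalize", lapply(recordings, normalize_orientation,
                                          video_width_px = w))
  filt <- stage("preprocess",
                filter_subjects(recordings, config$attention_threshold,
                                video_rect = rect))
  included <- filt$included
  if (length(included) == 0L)
    stop("pipeline stage 'preprocess' failed: no subject passed the ",
         "attention criterion", call. = FALSE)

  fits <- stage("tracking", {
    whole <- do.call(rbind, lapply(included, fit_tracking, timeline$track,
                                   video_rect = rect))
    if (!is.null(timeline$analysis_periods)) {
      per <- do.call(rbind, lapply(included, fit_tracking_periods, timeline,
                                   video_rect = rect))
      rbind(whole, per)
    } else whole
  })
  r2_summary <- summarize_r2(fits[fits$window == "whole_video", ])

  observations <- stage("anticipate", {
    obs <- do.call(rbind, lapply(included, extract_latencies, timeline,
                                 half_window_ms = config$half_window_ms,
                                 min_dwell_ms = config$min_dwell_ms))
    apply_exclusions(obs, included, timeline,
                     half_window_ms = config$half_window_ms)
  })
  lat_summary <- summarize_latency(observations)

  models <- list()
  if (any(c("lmm01", "lmm02") %in% config$models)) {
    dat <- stage("fit", prepare_event_model_data(observations))
    fit <- stage("fit", fit_lmm(dat, "latency_ms", c("movement", "throw_z")))
    fit <- stage("fit", stability_loso(fit))
    fit$vif <- vif_fixed(dat, c("movement", "throw_z"))
    models[[if ("lmm01" %in% config$models) "lmm01" else "lmm02"]] <- fit
  }
  if ("lmm03" %in% config$models) {
    dat3 <- stage("fit", prepare_period_model_data(observations, timeline))
    fit3 <- stage("fit", fit_lmm(dat3, "mean_latency_ms",
                                 c("movement", "period_z")))
    fit3 <- stage("fit", stability_loso(fit3))
    fit3$vif <- vif_fixed(dat3, c("movement", "period_z"))
    models$lmm03 <- fit3
  }

  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$out_dir, f)
  write_exclusion_report(filt$report, out("exclusions.tsv"))
  write_tracking_report(fits, out("tracking.tsv"))
  write_observations(observations, out("observations.tsv"))
  for (nm in names(models))
    write_lmm_report(models[[nm]], out(paste0(nm, ".tsv")))
  summary_lines <- c(
    sprintf("tracking_r2_median\t%.6f", r2_summary$median),
    sprintf("tracking_r2_min\t%.6f", r2_summary$min),
    sprintf("tracking_r2_max\t%.6f", r2_summary$max),
    sprintf("latency_median_ms\t%.3f", lat_summary$median),
    sprintf("latency_min_ms\t%.3f", lat_summary$min),
    sprintf("latency_max_ms\t%.3f", lat_summary$max),
    sprintf("n_observed\t%d", lat_summary$n_observed),
    sprintf("n_candidate\t%d", lat_summary$n_candidate))
  writeLines(summary_lines, out("summary.tsv"))
  writeLines(c(
    sprintf("package dynaoi %s",
            as.character(utils::packageVersion("dynaoi"))),
    sprintf("design\t%s", config$design),
    sprintf("mode\t%s", config$mode),
    sprintf("seed\t%d", as.integer(config$seed)),
    sprintf("attention_threshold\t%.2f", config$attention_threshold),
    sprintf("half_window_ms\t%g", config$half_window_ms),
    sprintf("min_dwell_ms\t%g", config$min_dwell_ms),
    sprintf("n_subjects_input\t%d", length(recordings)),
    sprintf("n_subjects_included\t%d", length(included))),
    out("run_log.txt"))

  invisible(list(timeline = timeline, recordings = recordings,
                 included = included, exclusion_report = filt$report,
                 tracking = fits, r2_summary = r2_summary,
                 observations = observations, latency_summary = lat_summary,
                 models = models, out_dir = config$out_dir))
}
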