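#' Simulate a complete synthetic session
#'
#' Convenience wrapper running \code{\link{simulate_trials}},
#' \code{\link{simulate_traces}} and \code{\link{simulate_pupil}} under
#' one configuration. Raw frames are not rendered by default (see
#' \code{\link{simulate_frames}}).
#'
#' @param config a \code{\link{sim_config}}.
#' @param pupil also simulate the pupil trace (default TRUE).
#' @return list with \code{trials}, \code{traces}, \code{ground_truth},
#'   and optionally \code{pupil}.
#' @export
simulate_session <- function(config, pupil = TRUE) {
  trials <- simulate_trials(config)
  sim <- simulate_traces(trials, config)
  out <- list(trials = trials, traces = sim$traces,
              ground_truth = sim$ground_truth, config = config)
  if (pupil) out$pupil <- simulate_pupil(trials, config)
  out
}

#' Run the full trace-to-statistics analysis on a session
#'
#' The core pipeline: slice ROI traces into trials, estimate the
#' rolling-median baseline F0 and convert to dF/F, detect transients
#' (threshold_k x baseline SD, > min_duration_ms), deduplicate branch
#' ROIs, apply the active-axon rule, and compute per-epoch event
#' probabilities and evoked amplitude/duration statistics split by
#' behavioral outcome, together with session behavioral metrics.
#'
#' @param traces a \code{trace_matrix}.
#' @param trials a \code{\link{trial_table}} with outcomes.
#' @param rolling_window F0 rolling-median window in trials.
#' @param threshold_k detection threshold in baseline-SD units.
#' @param min_duration_ms strict minimum event duration.
#' @param dedup run branch-ROI deduplication (default TRUE).
#' @param agreement_threshold,onset_tolerance_frames dedup parameters.
#' @param split_stimulus use the split stimulus/response windows.
#' @return a \code{session_analysis} object: list with \code{dff},
#'   \code{events}, \code{dedup}, \code{active_rois},
#'   \code{analysis_rois} (active, deduplicated), \code{windows},
#'   \code{probability} (per outcome), \code{probability_all} (pooled),
#'   \code{amplitude} (per outcome evoked stats), \code{behavior},
#'   \code{trials}.
#' @export
analyze_session <- function(traces, trials, rolling_window = 5,
                            threshold_k = 2, min_duration_ms = 200,
                            dedup = TRUE, agreement_threshold = 0.95,
                            onset_tolerance_frames = 2,
                            split_stimulus = FALSE) {
  tensor <- segment_trials(traces, trials)
  baseline <- compute_f0(tensor, rolling_window = rolling_window)
  dff <- compute_dff(tensor, baseline)
  events <- detect_events(dff, threshold_k = threshold_k,
                          min_duration_ms = min_duration_ms)
  dd <- if (dedup && nrow(trials) >= 2) {
    deduplicate_rois(events, trials,
                     agreement_threshold = agreement_threshold,
                     onset_tolerance_frames = onset_tolerance_frames)
  } else {
    structure(list(kept_roi_ids = dff$roi_ids,
                   removed_roi_ids = character(0),
                   duplicate_groups = list(), pairwise_agreement = NULL),
              class = "dedup_result")
  }
  active <- flag_active_rois(events)
  analysis_rois <- intersect(dd$kept_roi_ids, active)
  windows <- assign_epoch_windows(
    trials, epoch_definitions(split_stimulus = split_stimulus))
  kept_events <- events[events$roi_id %in% analysis_rois, ]
  prob <- event_probability(kept_events, windows, trials, analysis_rois,
                            by = "outcome")
  prob_all <- event_probability(kept_events, windows, trials,
                                analysis_rois, by = "all")
  amp <- evoked_amplitude_stats(kept_events, windows, trials,
                                analysis_rois, by = "outcome")
  beh <- tryCatch(behavior_metrics(trials), error = function(e) NULL)
  structure(list(dff = dff, events = events, dedup = dd,
                 active_rois = active, analysis_rois = analysis_rois,
                 windows = windows, probability = prob,
                 probability_all = prob_all, amplitude = amp,
                 behavior = beh, trials = trials),
            class = "session_analysis")
}

#' @export
print.session_analysis <- function(x, ...) {
  cat(sprintf(
    "Session analysis: %d trials, %d ROIs (%d active, %d analysed)\n",
    nrow(x$trials), length(x$dff$roi_ids), length(x$active_rois),
    length(x$analysis_rois)))
  cat(sprintf("  %d events; %d duplicate ROI(s) removed\n",
              nrow(x$events), length(x$dedup$removed_roi_ids)))
  if (!is.null(x$behavior)) {
    cat(sprintf("  behavior: d' = %.3f, correct fraction = %.3f%s\n",
                x$behavior$d_prime, x$behavior$correct_fraction,
                if (x$behavior$expert) " (expert)" else ""))
  }
  invisible(x)
}

#' @export
summary.session_analysis <- function(object, ...) {
  agg <- stats::aggregate(probability ~ epoch + outcome,
                          data = object$probability, FUN = mean)
  names(agg)[3] <- "mean_probability"
  cat("Mean event probability per trial (across ROIs):\n")
  print(agg, row.names = FALSE)
  invisible(agg)
}

#' Write the per-epoch statistics table as CSV
#'
#' Joins event probability with evoked amplitude/duration into the tidy
#' schema roi_id, epoch, outcome, probability, mean_peak_dff,
#' mean_duration_ms, n_trials, n_event_trials. Rows are sorted
#' deterministically, so identical analyses produce byte-identical files.
#'
#' @param analysis a \code{session_analysis}.
#' @param path file path.
#' @export
write_epoch_stats_csv <- function(analysis, path) {
  st <- merge(analysis$probability, analysis$amplitude,
              by = c("roi_id", "epoch", "outcome"), all.x = TRUE)
  st <- st[, c("roi_id", "epoch", "outcome", "probability",
               "mean_peak_dff", "mean_duration_ms", "n_trials",
               "n_event_trials.x")]
  names(st)[8] <- "n_event_trials"
  st <- st[order(st$roi_id, st$epoch, st$outcome), ]
  for (col in c("probability", "mean_peak_dff", "mean_duration_ms")) {
    st[[col]] <- sprintf("%.10g", st[[col]])
  }
  utils::write.csv(st, path, row.names = FALSE)
  invisible(path)
}
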