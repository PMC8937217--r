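#' Detect calcium transients in trial-aligned dF/F traces
#'
#' A transient is a maximal contiguous run of samples whose dF/F exceeds
#' the detection threshold for strictly longer than \code{min_duration_ms}.
#' The threshold implements the raw-fluorescence criterion
#' F0 + threshold_k x SD in dF/F space: per ROI and trial it equals
#' (threshold_k x baseline_sd) / F0(trial). Onset is the time of the first
#' suprathreshold sample, offset the time of the first sample back below
#' threshold (one sample period past the run's last sample at the trial
#' end), the peak is the maximum dF/F within the run, and duration =
#' offset - onset. At 30 Hz the "> 200 ms" rule therefore requires at
#' least 7 consecutive suprathreshold samples: a 6-sample (200 ms) run is
#' rejected. Missing samples split runs at the gap.
#'
#' @param dff a \code{dff_tensor} from \code{\link{compute_dff}} (carries
#'   its baseline), or a plain \code{trial_tensor} of dF/F if
#'   \code{baseline} is supplied.
#' @param baseline optional \code{baseline_series}; defaults to the one
#'   attached to \code{dff}.
#' @param threshold_k threshold in baseline-SD units (default 2).
#' @param min_duration_ms minimum (strict) event duration in ms
#'   (default 200).
#' @return an \code{event_table}: data.frame with columns \code{roi_id},
#'   \code{trial_id}, \code{onset_s}, \code{offset_s} (trial-relative
#'   seconds), \code{peak_dff}, \code{duration_ms}; the frame rate is
#'   attached as an attribute.
#' @export
detect_events <- function(dff, baseline = NULL, threshold_k = 2,
                          min_duration_ms = 200) {
  if (is.null(baseline)) baseline <- dff$baseline
  if (is.null(baseline)) stop("no baseline supplied or attached")
  sd_vec <- baseline$baseline_sd
  if (any(!is.finite(sd_vec)) || any(sd_vec <= 0)) {
    stop("baseline_sd must be positive for detection")
  }
  fr <- dff$frame_rate
  dt <- 1 / fr
  st <- dff$sample_times
  n_roi <- dim(dff$values)[1]; n_trial <- dim(dff$values)[2]
  # smallest n with n * dt strictly greater than the minimum duration
  min_samples <- floor(min_duration_ms / 1000 * fr + 1e-9) + 1L

  out <- vector("list", 256); n_out <- 0L
  for (r in seq_len(n_roi)) {
    for (i in seq_len(n_trial)) {
      thr <- threshold_k * sd_vec[r] / baseline$f0[r, i]
      if (!is.finite(thr)) next
      x <- dff$values[r, i, ]
      supra <- !is.na(x) & x > thr
      if (!any(supra)) next
      runs <- rle(supra)
      ends <- cumsum(runs$lengths)
      starts <- ends - runs$lengths + 1L
      sel <- which(runs$values & runs$lengths >= min_samples)
      for (s in sel) {
        a <- starts[s]; b <- ends[s]
        n_out <- n_out + 1L
        if (n_out > length(out)) out <- c(out, vector("list", length(out)))
        out[[n_out]] <- c(r, i, st[a], st[b] + dt, max(x[a:b]))
      }
    }
  }
  if (n_out == 0L) {
    ev <- data.frame(roi_id = character(0), trial_id = integer(0),
                     onset_s = numeric(0), offset_s = numeric(0),
                     peak_dff = numeric(0), duration_ms = numeric(0))
  } else {
    m <- do.call(rbind, out[seq_len(n_out)])
    ev <- data.frame(roi_id = dff$roi_ids[m[, 1]],
                     trial_id = dff$trial_ids[m[, 2]],
                     onset_s = m[, 3], offset_s = m[, 4],
                     peak_dff = m[, 5],
                     duration_ms = (m[, 4] - m[, 3]) * 1000,
                     stringsAsFactors = FALSE)
  }
  attr(ev, "frame_rate") <- fr
  attr(ev, "roi_ids") <- dff$roi_ids
  attr(ev, "trial_ids") <- dff$trial_ids
  class(ev) <- c("event_table", "data.frame")
  ev
}

#' Flag active ROIs
#'
#' An ROI is "active" if it reported at least one detected transient
#' anywhere in the session. Only active ROIs enter the probability
#' analyses; amplitude/duration statistics additionally require at least
#' one event in the analysed epoch (enforced by
#' \code{\link{evoked_amplitude_stats}}).
#'
#' @param events an \code{event_table}.
#' @param roi_ids optional full ROI set (defaults to the set detection
#'   ran over).
#' @return character vector of active ROI ids.
#' @export
flag_active_rois <- function(events, roi_ids = NULL) {
  if (is.null(roi_ids)) roi_ids <- attr(events, "roi_ids")
  active <- unique(events$roi_id)
  roi_ids[roi_ids %in% active]
}

#' Deduplicate ROIs that are branches of the same axon
#'
#' ROIs whose events coincide in more than \code{agreement_threshold} of
#' trials are presumed to be branches or boutons of one axon. For each
#' pair of ROIs with at least one event, trial agreement is 1 when both
#' have an event with onsets within \code{onset_tolerance_frames} frames
#' of each other, or both have no event in that trial, and 0 otherwise;
#' the pairwise agreement is the mean over trials. Pairs above threshold
#' are linked and connected components form duplicate groups; within each
#' group the ROI with the highest mean event peak amplitude is kept.
#' ROIs with no events at all are not candidates (they never enter any
#' analysis) and pass through unexamined.
#'
#' @param events an \code{event_table}.
#' @param trials a \code{\link{trial_table}} (defines the trial set over
#'   which agreement is averaged).
#' @param agreement_threshold fraction of agreeing trials above which a
#'   pair is linked (default 0.95, strict inequality).
#' @param onset_tolerance_frames onset coincidence tolerance in frames
#'   (default 2).
#' @param frame_rate frames per second; defaults to the event table's
#'   attribute.
#' @return a \code{dedup_result}: list with \code{kept_roi_ids},
#'   \code{removed_roi_ids}, \code{duplicate_groups} (list of character
#'   vectors), and \code{pairwise_agreement} (matrix over event-bearing
#'   ROIs).
#' @export
deduplicate_rois <- function(events, trials, agreement_threshold = 0.95,
                             onset_tolerance_frames = 2,
                             frame_rate = NULL) {
  if (is.null(frame_rate)) frame_rate <- attr(events, "frame_rate")
  all_rois <- attr(events, "roi_ids")
  if (is.null(all_rois)) all_rois <- unique(events$roi_id)
  if (nrow(trials) < 2) {
    warning("single-trial session: deduplication skipped")
    return(structure(list(kept_roi_ids = all_rois,
                          removed_roi_ids = character(0),
                          duplicate_groups = list(),
                          pairwise_agreement = NULL),
                     class = "dedup_result"))
  }
  rois <- sort(unique(events$roi_id))
  n <- length(rois)
  tol <- onset_tolerance_frames / frame_rate + 1e-9
  trial_ids <- trials$trial_id
  # onsets[[roi]][[trial]] lookup
  onsets <- lapply(rois, function(r) {
    sub <- events[events$roi_id == r, ]
    lapply(trial_ids, function(ti) sub$onset_s[sub$trial_id == ti])
  })
  names(onsets) <- rois
  agree <- matrix(1, n, n, dimnames = list(rois, rois))
  if (n >= 2) {
    for (a in seq_len(n - 1)) {
      for (b in (a + 1):n) {
        hits <- vapply(seq_along(trial_ids), function(ti) {
          oa <- onsets[[a]][[ti]]; ob <- onsets[[b]][[ti]]
          if (!length(oa) && !length(ob)) return(1)
          if (!length(oa) || !length(ob)) return(0)
          if (min(abs(outer(oa, ob, "-"))) <= tol) 1 else 0
        }, numeric(1))
        agree[a, b] <- agree[b, a] <- mean(hits)
      }
    }
  }
  linked <- agree > agreement_threshold
  # connected components by BFS
  comp <- rep(NA_integer_, n); cid <- 0L
  for (s in seq_len(n)) {
    if (!is.na(comp[s])) next
    cid <- cid + 1L
    queue <- s
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (!is.na(comp[v])) next
      comp[v] <- cid
      queue <- c(queue, which(linked[v, ] & is.na(comp)))
    }
  }
  groups <- split(rois, comp)
  dup_groups <- groups[vapply(groups, length, 1L) > 1]
  mean_peak <- vapply(rois, function(r)
    mean(events$peak_dff[events$roi_id == r]), numeric(1))
  removed <- character(0)
  for (g in dup_groups) {
    keep <- g[which.max(mean_peak[g])]
    removed <- c(removed, setdiff(g, keep))
  }
  structure(list(kept_roi_ids = setdiff(all_rois, removed),
                 removed_roi_ids = removed,
                 duplicate_groups = unname(dup_groups),
                 pairwise_agreement = agree),
            class = "dedup_result")
}

#' @export
print.dedup_result <- function(x, ...) {
  cat(sprintf(
    "Dedup: %d kept, %d removed in %d duplicate group(s)\n",
    length(x$kept_roi_ids), length(x$removed_roi_ids),
    length(x$duplicate_groups)))
  invisible(x)
}

#' Write detected events as CSV
#'
#' Columns: \code{roi_id}, \code{trial_id}, \code{onset_s},
#' \code{offset_s}, \code{peak_dff}, \code{duration_ms}.
#'
#' @param events an \code{event_table}.
#' @param path file path.
#' @export
write_events_csv <- function(events, path) {
  utils::write.csv(as.data.frame(events), path, row.names = FALSE)
  invisible(path)
}

#' Write a dedup report as JSON
#'
#' @param dedup a \code{dedup_result}.
#' @param path file path.
#' @export
write_dedup_json <- function(dedup, path) {
  jsonlite::write_json(list(kept_roi_ids = dedup$kept_roi_ids,
                            removed_roi_ids = dedup$removed_roi_ids,
                            duplicate_groups = dedup$duplicate_groups),
                       path, auto_unbox = FALSE, pretty = TRUE)
  invisible(path)
}
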