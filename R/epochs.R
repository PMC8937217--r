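#' Canonical behavioral epoch definitions
#'
#' The three headline epochs, each 1 s long: spontaneous activity
#' \[-2, -1) s relative to stimulus onset; response \[0, +1) s relative to
#' stimulus onset (the merged stimulus-plus-response window); reward
#' \[0, +1) s relative to reward delivery. With \code{split_stimulus} the
#' response window is subdivided into stimulus \[0, 0.5) and response
#' \[0.5, 1.0) s.
#'
#' @param split_stimulus subdivide the stimulus/response window.
#' @return data.frame with columns \code{name}, \code{anchor}
#'   (\code{"stimulus_onset"} or \code{"reward_delivery"}), \code{start},
#'   \code{end} (seconds relative to the anchor).
#' @export
epoch_definitions <- function(split_stimulus = FALSE) {
  if (split_stimulus) {
    data.frame(
      name = c("spontaneous", "stimulus", "response", "reward"),
      anchor = c("stimulus_onset", "stimulus_onset", "stimulus_onset",
                 "reward_delivery"),
      start = c(-2, 0, 0.5, 0), end = c(-1, 0.5, 1, 1),
      stringsAsFactors = FALSE)
  } else {
    data.frame(
      name = c("spontaneous", "response", "reward"),
      anchor = c("stimulus_onset", "stimulus_onset", "reward_delivery"),
      start = c(-2, 0, 0), end = c(-1, 1, 1), stringsAsFactors = FALSE)
  }
}

#' Resolve epoch windows per trial
#'
#' Anchors each epoch definition on the trial's stimulus onset (catch
#' trials use the virtual stimulus time, trial start + 3 s) or reward
#' delivery. Reward-anchored windows exist only on trials with a delivered
#' reward; on other trials they are omitted, never zero-filled.
#'
#' @param trials a \code{\link{trial_table}}.
#' @param defs epoch definitions (default \code{\link{epoch_definitions}()}).
#' @return data.frame with columns \code{trial_id}, \code{epoch},
#'   \code{start}, \code{end} in trial-relative seconds (half-open
#'   windows).
#' @export
assign_epoch_windows <- function(trials, defs = epoch_definitions()) {
  rows <- vector("list", nrow(defs))
  stim_rel <- trials$t_stimulus - trials$t_start
  for (k in seq_len(nrow(defs))) {
    d <- defs[k, ]
    if (d$anchor == "stimulus_onset") {
      rows[[k]] <- data.frame(trial_id = trials$trial_id, epoch = d$name,
                              start = stim_rel + d$start,
                              end = stim_rel + d$end)
    } else if (d$anchor == "reward_delivery") {
      sel <- which(!is.na(trials$t_reward))
      rew_rel <- trials$t_reward[sel] - trials$t_start[sel]
      rows[[k]] <- data.frame(trial_id = trials$trial_id[sel],
                              epoch = rep(d$name, length(sel)),
                              start = rew_rel + d$start,
                              end = rew_rel + d$end)
    } else stop("unknown anchor: ", d$anchor)
  }
  do.call(rbind, rows)
}

#' Per-epoch event probability by outcome
#'
#' The headline statistic: per ROI, epoch and outcome class, the fraction
#' of eligible trials that contain at least one event onset inside the
#' epoch window (a trial counts once however many onsets it holds, so the
#' statistic is a probability per trial, bounded by 1). Only ROIs in
#' \code{rois} (typically the active, deduplicated set) are reported.
#' Epochs with zero eligible trials for a class yield no row (missing,
#' never zero).
#'
#' @param events an \code{event_table}.
#' @param windows resolved windows from \code{\link{assign_epoch_windows}}.
#' @param trials a \code{\link{trial_table}}.
#' @param rois ROI ids to include.
#' @param by \code{"outcome"} for per-class statistics or \code{"all"} to
#'   pool every eligible trial.
#' @return an \code{epoch_stats} data.frame: \code{roi_id}, \code{epoch},
#'   \code{outcome}, \code{probability}, \code{n_trials},
#'   \code{n_event_trials}.
#' @export
event_probability <- function(events, windows, trials, rois,
                              by = c("outcome", "all")) {
  by <- match.arg(by)
  outcome_of <- stats::setNames(trials$outcome, trials$trial_id)
  res <- list()
  for (ep in unique(windows$epoch)) {
    w <- windows[windows$epoch == ep, ]
    start_of <- stats::setNames(w$start, w$trial_id)
    end_of <- stats::setNames(w$end, w$trial_id)
    elig <- as.character(w$trial_id)
    grp_of <- if (by == "outcome") outcome_of[elig] else
      stats::setNames(rep("all", length(elig)), elig)
    ev <- events[events$roi_id %in% rois &
                   as.character(events$trial_id) %in% elig, ]
    if (nrow(ev)) {
      tid <- as.character(ev$trial_id)
      inwin <- ev$onset_s >= start_of[tid] & ev$onset_s < end_of[tid]
      hits <- unique(ev[inwin, c("roi_id", "trial_id")])
    } else {
      hits <- data.frame(roi_id = character(0), trial_id = integer(0))
    }
    for (g in unique(grp_of)) {
      gtrials <- names(grp_of)[grp_of == g]
      n_tr <- length(gtrials)
      if (n_tr == 0) next
      n_ev <- table(factor(
        hits$roi_id[as.character(hits$trial_id) %in% gtrials],
        levels = rois))
      res[[length(res) + 1]] <- data.frame(
        roi_id = rois, epoch = ep, outcome = g,
        probability = as.numeric(n_ev) / n_tr, n_trials = n_tr,
        n_event_trials = as.numeric(n_ev), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, res)
  class(out) <- c("epoch_stats", "data.frame")
  out
}

#' Per-epoch evoked amplitude and duration
#'
#' Per ROI, epoch and outcome class: the mean peak dF/F and mean duration
#' of evoked events, taking the first event per trial-epoch when several
#' onsets fall in the window. ROIs with no event in an epoch are excluded
#' from that epoch's statistic (no row), mirroring the convention that
#' amplitude/duration are measured only where a transient was evoked.
#'
#' @inheritParams event_probability
#' @return data.frame: \code{roi_id}, \code{epoch}, \code{outcome},
#'   \code{mean_peak_dff}, \code{mean_duration_ms}, \code{n_event_trials}.
#' @export
evoked_amplitude_stats <- function(events, windows, trials, rois,
                                   by = c("outcome", "all")) {
  by <- match.arg(by)
  outcome_of <- stats::setNames(trials$outcome, trials$trial_id)
  res <- list()
  for (ep in unique(windows$epoch)) {
    w <- windows[windows$epoch == ep, ]
    start_of <- stats::setNames(w$start, w$trial_id)
    end_of <- stats::setNames(w$end, w$trial_id)
    elig <- as.character(w$trial_id)
    ev <- events[events$roi_id %in% rois &
                   as.character(events$trial_id) %in% elig, ]
    if (!nrow(ev)) next
    tid <- as.character(ev$trial_id)
    ev <- ev[ev$onset_s >= start_of[tid] & ev$onset_s < end_of[tid], ]
    if (!nrow(ev)) next
    # first event per ROI-trial
    ev <- ev[order(ev$roi_id, ev$trial_id, ev$onset_s), ]
    first <- !duplicated(ev[, c("roi_id", "trial_id")])
    ev <- ev[first, ]
    grp <- if (by == "outcome") outcome_of[as.character(ev$trial_id)] else
      rep("all", nrow(ev))
    agg <- stats::aggregate(
      cbind(peak_dff, duration_ms) ~ roi_id + grp, data =
        data.frame(ev[, c("roi_id", "peak_dff", "duration_ms")],
                   grp = grp),
      FUN = mean)
    cnt <- stats::aggregate(
      peak_dff ~ roi_id + grp,
      data = data.frame(ev[, c("roi_id", "peak_dff")], grp = grp),
      FUN = length)
    res[[length(res) + 1]] <- data.frame(
      roi_id = agg$roi_id, epoch = ep, outcome = agg$grp,
      mean_peak_dff = agg$peak_dff, mean_duration_ms = agg$duration_ms,
      n_event_trials = cnt$peak_dff, stringsAsFactors = FALSE)
  }
  out <- if (length(res)) do.call(rbind, res) else
    data.frame(roi_id = character(0), epoch = character(0),
               outcome = character(0), mean_peak_dff = numeric(0),
               mean_duration_ms = numeric(0), n_event_trials = integer(0))
  out
}

#' Trial-averaged dF/F per ROI
#'
#' @param dff a \code{dff_tensor}.
#' @param trial_ids trials to average over (default all).
#' @return matrix ROI x sample with the \code{sample_times} attribute.
#' @export
trial_average <- function(dff, trial_ids = NULL) {
  sel <- if (is.null(trial_ids)) seq_along(dff$trial_ids) else
    which(dff$trial_ids %in% trial_ids)
  if (!length(sel)) stop("no trials to average")
  avg <- apply(dff$values[, sel, , drop = FALSE], c(1, 3), mean,
               na.rm = TRUE)
  rownames(avg) <- dff$roi_ids
  attr(avg, "sample_times") <- dff$sample_times
  avg
}

#' Categorize axons by the epoch of their peak average activity
#'
#' Each ROI is labeled with the epoch whose window contains the global
#' maximum of its trial-averaged trace (typically averaged over HIT
#' trials). Ties are broken toward the earlier epoch in canonical order;
#' flat traces, or peaks outside every epoch window, are labeled
#' \code{"none"}.
#'
#' @param avg_traces ROI x sample matrix from \code{\link{trial_average}}.
#' @param windows per-trial epoch windows; the per-epoch window applied
#'   here is the modal (most common) window of each epoch across trials.
#' @return named character vector of epoch labels per ROI.
#' @export
categorize_axons_by_peak <- function(avg_traces, windows) {
  st <- attr(avg_traces, "sample_times")
  epochs <- intersect(c(canonical_epochs(), unique(windows$epoch)),
                      unique(windows$epoch))
  # modal window per epoch
  wins <- lapply(epochs, function(ep) {
    w <- windows[windows$epoch == ep, ]
    key <- paste(w$start, w$end)
    k <- names(which.max(table(key)))
    as.numeric(strsplit(k, " ")[[1]])
  })
  names(wins) <- epochs
  labels <- vapply(seq_len(nrow(avg_traces)), function(r) {
    x <- avg_traces[r, ]
    if (all(!is.finite(x)) || diff(range(x, na.rm = TRUE)) == 0) {
      return("none")
    }
    peak_t <- st[which.max(x)]
    for (ep in epochs) {
      if (peak_t >= wins[[ep]][1] && peak_t < wins[[ep]][2]) return(ep)
    }
    "none"
  }, character(1))
  names(labels) <- rownames(avg_traces)
  labels
}

#' Mass average trace
#'
#' Averages dF/F over trials within each ROI, then over ROIs; the SEM is
#' taken across ROIs. Used for population summaries that include every
#' axon whether or not it responded.
#'
#' @param dff a \code{dff_tensor}.
#' @param roi_ids ROI subset (default all).
#' @param trial_ids trial subset (default all).
#' @return data.frame \code{time}, \code{mean}, \code{sem}.
#' @export
mass_average <- function(dff, roi_ids = NULL, trial_ids = NULL) {
  rsel <- if (is.null(roi_ids)) seq_along(dff$roi_ids) else
    which(dff$roi_ids %in% roi_ids)
  if (!length(rsel)) stop("no ROIs selected")
  tsel <- if (is.null(trial_ids)) seq_along(dff$trial_ids) else
    which(dff$trial_ids %in% trial_ids)
  if (!length(tsel)) stop("no trials selected")
  per_roi <- apply(dff$values[rsel, tsel, , drop = FALSE], c(1, 3), mean,
                   na.rm = TRUE)
  m <- colMeans(per_roi)
  sem <- if (nrow(per_roi) > 1) {
    apply(per_roi, 2, stats::sd) / sqrt(nrow(per_roi))
  } else rep(0, ncol(per_roi))
  data.frame(time = dff$sample_times, mean = m, sem = sem)
}

#' Normalized, peak-sorted display matrix
#'
#' Divides each ROI's averaged trace by its maximum and orders rows by the
#' time of the peak (ascending; ties keep the incoming ROI order). Rows
#' with a non-positive maximum are dropped and reported in the
#' \code{dropped} attribute.
#'
#' @param avg_traces ROI x sample matrix from \code{\link{trial_average}}.
#' @return normalized matrix with rows reordered; attributes
#'   \code{sample_times} and \code{dropped}.
#' @export
display_matrix <- function(avg_traces) {
  st <- attr(avg_traces, "sample_times")
  mx <- apply(avg_traces, 1, max, na.rm = TRUE)
  keep <- which(mx > 0)
  dropped <- rownames(avg_traces)[mx <= 0]
  norm <- avg_traces[keep, , drop = FALSE] / mx[keep]
  peak_t <- apply(norm, 1, function(x) st[which.max(x)])
  ord <- order(peak_t)  # stable: ties keep incoming order
  out <- norm[ord, , drop = FALSE]
  attr(out, "sample_times") <- st
  attr(out, "dropped") <- dropped
  out
}
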