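#' Extract ROI fluorescence traces from a frame stack
#'
#' Each ROI's value in each frame is the mean pixel intensity over the
#' ROI's mask. Frames flagged by the registration step are marked missing
#' (NA) for every ROI.
#'
#' @param stack a \code{frame_stack} (ideally motion-corrected).
#' @param masks a \code{roi_mask_set}.
#' @param flagged optional logical vector (one per frame) of frames to
#'   mark missing, e.g. the \code{flagged} column from
#'   \code{\link{register_frames}}.
#' @return a \code{trace_matrix}.
#' @export
extract_traces <- function(stack, masks, flagged = NULL) {
  d <- dim(stack$frames)
  for (i in seq_along(masks)) {
    m <- masks[[i]]
    if (nrow(m) == 0) stop("empty ROI mask: ", names(masks)[i])
    if (any(m[, "row"] < 1 | m[, "row"] > d[2] |
            m[, "col"] < 1 | m[, "col"] > d[3])) {
      stop("mask outside frame bounds: ", names(masks)[i])
    }
  }
  values <- matrix(NA_real_, length(masks), d[1],
                   dimnames = list(names(masks), NULL))
  for (t in seq_len(d[1])) {
    fr <- stack$frames[t, , ]
    for (i in seq_along(masks)) {
      values[i, t] <- mean(fr[masks[[i]]])
    }
  }
  if (!is.null(flagged)) values[, flagged] <- NA_real_
  structure(list(values = values, frame_times = stack$frame_times,
                 roi_ids = names(masks), frame_rate = stack$frame_rate),
            class = "trace_matrix")
}

#' Slice ROI traces into per-trial windows
#'
#' Cuts each ROI trace into windows of \code{window_s} seconds starting at
#' each trial start, on a sample grid common to all trials (sample k of
#' every trial is the k-th frame at or after that trial's start). Trials
#' not fully covered by the recording are dropped with a logged reason.
#'
#' @param traces a \code{trace_matrix}.
#' @param trials a \code{\link{trial_table}}.
#' @param window_s trial window length in seconds; defaults to the
#'   \code{trial_window_s} attribute of \code{trials}.
#' @return a \code{trial_tensor}: list with \code{values} (array
#'   ROI x trial x sample of raw fluorescence), \code{sample_times}
#'   (seconds relative to trial start), \code{trial_ids}, \code{roi_ids},
#'   \code{frame_rate}, \code{dropped} (data.frame trial_id, reason).
#' @export
segment_trials <- function(traces, trials, window_s = NULL) {
  if (is.null(window_s)) window_s <- attr(trials, "trial_window_s")
  fr <- traces$frame_rate
  n_samp <- as.integer(floor(window_s * fr))
  n_frames <- length(traces$frame_times)
  keep <- integer(0); first_idx <- integer(0)
  dropped <- data.frame(trial_id = integer(0), reason = character(0))
  for (i in seq_len(nrow(trials))) {
    k0 <- match(TRUE, traces$frame_times >= trials$t_start[i])
    if (is.na(k0) || k0 + n_samp - 1 > n_frames) {
      dropped <- rbind(dropped, data.frame(
        trial_id = trials$trial_id[i],
        reason = "trial window extends past recording"))
      next
    }
    keep <- c(keep, i); first_idx <- c(first_idx, k0)
  }
  if (!length(keep)) stop("alignment error: no trial fully covered")
  vals <- array(NA_real_,
                dim = c(length(traces$roi_ids), length(keep), n_samp),
                dimnames = list(traces$roi_ids, NULL, NULL))
  for (j in seq_along(keep)) {
    idx <- first_idx[j] + seq_len(n_samp) - 1L
    vals[, j, ] <- traces$values[, idx, drop = FALSE]
  }
  structure(list(values = vals,
                 sample_times = (seq_len(n_samp) - 1) / fr,
                 trial_ids = trials$trial_id[keep],
                 roi_ids = traces$roi_ids, frame_rate = fr,
                 dropped = dropped),
            class = "trial_tensor")
}

#' Rolling-median baseline fluorescence (F0)
#'
#' For each ROI and trial, the mean raw fluorescence over the
#' \code{n_baseline} samples immediately preceding stimulus onset is
#' taken; F0 for a trial is the centered rolling median of these per-trial
#' means over \code{rolling_window} trials (the window truncates at the
#' session edges). The baseline noise estimate \code{baseline_sd} pools
#' all pre-stimulus raw samples of the ROI across trials.
#'
#' @param tensor a \code{trial_tensor} of raw fluorescence.
#' @param stimulus_onset_s stimulus onset relative to trial start
#'   (seconds; default 3).
#' @param n_baseline number of pre-stimulus samples averaged per trial
#'   (default 60, i.e. 2 s at 30 Hz).
#' @param rolling_window rolling-median window in trials (default 5,
#'   centered, truncated at edges).
#' @return a \code{baseline_series}: list with \code{f0} (ROI x trial
#'   matrix), \code{baseline_sd} (per ROI), \code{trial_means} (ROI x
#'   trial pre-stimulus means), \code{trial_ids}, \code{roi_ids}.
#' @export
compute_f0 <- function(tensor, stimulus_onset_s = 3, n_baseline = 60,
                       rolling_window = 5) {
  st <- tensor$sample_times
  pre <- which(st < stimulus_onset_s)
  if (length(pre) >= n_baseline) {
    pre <- utils::tail(pre, n_baseline)
    enough <- TRUE
  } else {
    enough <- FALSE
  }
  n_roi <- dim(tensor$values)[1]; n_trial <- dim(tensor$values)[2]
  means <- matrix(NA_real_, n_roi, n_trial,
                  dimnames = list(tensor$roi_ids, NULL))
  if (enough) {
    for (i in seq_len(n_trial)) {
      means[, i] <- rowMeans(tensor$values[, i, pre, drop = FALSE],
                             na.rm = TRUE)
    }
  }
  f0 <- matrix(NA_real_, n_roi, n_trial,
               dimnames = list(tensor$roi_ids, NULL))
  for (r in seq_len(n_roi)) {
    f0[r, ] <- rolling_median(means[r, ], rolling_window)
  }
  baseline_sd <- rep(NA_real_, n_roi)
  if (enough) {
    for (r in seq_len(n_roi)) {
      baseline_sd[r] <- stats::sd(as.vector(tensor$values[r, , pre]),
                                  na.rm = TRUE)
    }
  }
  names(baseline_sd) <- tensor$roi_ids
  structure(list(f0 = f0, baseline_sd = baseline_sd, trial_means = means,
                 trial_ids = tensor$trial_ids, roi_ids = tensor$roi_ids,
                 rolling_window = rolling_window),
            class = "baseline_series")
}

#' Centered rolling median with edge truncation
#'
#' The window is centered on each position and truncated at the ends of
#' the series; NA entries are skipped (all-NA windows give NA).
#'
#' @param x numeric vector.
#' @param window window length in elements (odd windows are symmetric).
#' @return numeric vector the same length as \code{x}.
#' @export
rolling_median <- function(x, window = 5) {
  n <- length(x)
  half <- (window - 1) %/% 2
  out <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    lo <- max(1, i - half); hi <- min(n, i + half)
    v <- x[lo:hi]
    if (!all(is.na(v))) out[i] <- stats::median(v, na.rm = TRUE)
  }
  out
}

#' Convert raw trial slices to dF/F
#'
#' Elementwise (F - F0(trial)) / F0(trial). ROIs whose F0 is not positive
#' on every trial are excluded (their exclusion is recorded in the
#' \code{excluded} component).
#'
#' @param tensor a \code{trial_tensor} of raw fluorescence.
#' @param baseline a \code{baseline_series} from \code{\link{compute_f0}}.
#' @return a \code{trial_tensor} of dF/F with the \code{baseline} attached
#'   and an \code{excluded} data.frame (roi_id, reason).
#' @export
compute_dff <- function(tensor, baseline) {
  stopifnot(identical(dim(tensor$values)[1:2], dim(baseline$f0)[1:2]))
  ok <- apply(baseline$f0 > 0, 1, all)
  ok[is.na(ok)] <- FALSE
  excluded <- data.frame(roi_id = tensor$roi_ids[!ok],
                         reason = rep("nonpositive F0", sum(!ok)))
  vals <- tensor$values[ok, , , drop = FALSE]
  f0 <- baseline$f0[ok, , drop = FALSE]
  for (i in seq_len(dim(vals)[2])) {
    vals[, i, ] <- (vals[, i, , drop = FALSE] - f0[, i]) / f0[, i]
  }
  structure(list(values = vals, sample_times = tensor$sample_times,
                 trial_ids = tensor$trial_ids,
                 roi_ids = tensor$roi_ids[ok],
                 frame_rate = tensor$frame_rate,
                 dropped = tensor$dropped, excluded = excluded,
                 baseline = list(
                   f0 = f0,
                   baseline_sd = baseline$baseline_sd[ok],
                   rolling_window = baseline$rolling_window)),
            class = c("dff_tensor", "trial_tensor"))
}

#' @export
print.trial_tensor <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("%s: %d ROIs x %d trials x %d samples at %g Hz\n",
              if (inherits(x, "dff_tensor")) "dF/F tensor"
              else "Trial tensor", d[1], d[2], d[3], x$frame_rate))
  if (nrow(x$dropped)) {
    cat(sprintf("  %d trial(s) dropped\n", nrow(x$dropped)))
  }
  invisible(x)
}
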