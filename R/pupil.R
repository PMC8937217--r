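#' Trial-aligned pupil epoch peaks
#'
#' Splits the session pupil trace into 11 s trial windows (4 s before
#' trial start to 7 s after), averages the aligned traces within each
#' outcome class, and measures the local maximum of the average trace in
#' three named windows: baseline \[-4, 0) s relative to trial start,
#' pre-tactile \[-3, 0) s relative to stimulus onset, and post-tactile
#' \[0, +4) s relative to stimulus onset. Artifact-flagged samples are
#' excluded from the averages, and a trial is dropped entirely when more
#' than \code{max_artifact_fraction} of any window's samples are flagged.
#'
#' @param trace a \code{pupil_trace}.
#' @param trials a \code{\link{trial_table}} with outcomes.
#' @param max_artifact_fraction per-window flagged-sample fraction above
#'   which a trial is dropped (default 0.2).
#' @return a list with \code{peaks} (data.frame \code{outcome},
#'   \code{baseline}, \code{pre_tac}, \code{post_tac} in mm,
#'   \code{n_trials}), \code{average} (matrix outcome x sample of the
#'   aligned average traces, \code{rel_times} attribute), and
#'   \code{dropped_trials}.
#' @export
pupil_epoch_peaks <- function(trace, trials,
                              max_artifact_fraction = 0.2) {
  sr <- trace$sample_rate
  pre_s <- 4; post_s <- 7  # 11 s trial window
  n_samp <- as.integer(round((pre_s + post_s) * sr))
  rel <- (seq_len(n_samp) - 1) / sr - pre_s  # relative to trial start
  stim_rel <- trials$t_stimulus - trials$t_start  # 3 s by construction
  wins <- list(baseline = c(-pre_s, 0),
               pre_tac = c(stim_rel[1] - 3, stim_rel[1]),
               post_tac = c(stim_rel[1], stim_rel[1] + 4))
  win_idx <- lapply(wins, function(w) which(rel >= w[1] & rel < w[2]))

  aligned <- matrix(NA_real_, nrow(trials), n_samp)
  dropped <- integer(0)
  for (i in seq_len(nrow(trials))) {
    k0 <- match(TRUE, trace$times >= trials$t_start[i] - pre_s)
    if (is.na(k0) || k0 + n_samp - 1 > length(trace$times)) {
      dropped <- c(dropped, trials$trial_id[i]); next
    }
    idx <- k0 + seq_len(n_samp) - 1L
    d <- trace$diameter[idx]
    fl <- trace$artifact_flags[idx]
    frac <- vapply(win_idx, function(w) mean(fl[w]), numeric(1))
    if (any(frac > max_artifact_fraction)) {
      dropped <- c(dropped, trials$trial_id[i]); next
    }
    d[fl] <- NA_real_
    aligned[i, ] <- d
  }
  keep <- which(!trials$trial_id %in% dropped)
  if (!length(keep)) stop("no usable trials for pupil analysis")

  classes <- unique(trials$outcome[keep])
  avg <- matrix(NA_real_, length(classes), n_samp,
                dimnames = list(classes, NULL))
  peaks <- data.frame(outcome = classes, baseline = NA_real_,
                      pre_tac = NA_real_, post_tac = NA_real_,
                      n_trials = NA_integer_, stringsAsFactors = FALSE)
  for (k in seq_along(classes)) {
    rows <- keep[trials$outcome[keep] == classes[k]]
    avg[k, ] <- colMeans(aligned[rows, , drop = FALSE], na.rm = TRUE)
    peaks$baseline[k] <- max(avg[k, win_idx$baseline], na.rm = TRUE)
    peaks$pre_tac[k] <- max(avg[k, win_idx$pre_tac], na.rm = TRUE)
    peaks$post_tac[k] <- max(avg[k, win_idx$post_tac], na.rm = TRUE)
    peaks$n_trials[k] <- length(rows)
  }
  attr(avg, "rel_times") <- rel
  list(peaks = peaks, average = avg,
       dropped_trials = dropped)
}
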