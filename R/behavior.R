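#' Classify trial outcomes from lick trains
#'
#' Applies the go/no-go outcome rules over the half-open response window
#' \[stimulus onset, onset + \code{response_window_s}). Action mode: a lick
#' inside the window on a stimulus trial is a HIT (else MISS); on a catch
#' trial a lick is a false alarm (FA), none is a correct rejection (CR).
#' Suppression mode: withholding licks for the full window on a stimulus
#' trial is a HIT, an early lick is a MISS; catch trials are classified as
#' in action mode. A lick at exactly the window end falls outside it.
#'
#' @param trials a \code{\link{trial_table}} (uses its \code{task_mode}
#'   attribute unless \code{task_mode} is given).
#' @param response_window_s response window length, seconds (default 1.5).
#' @param task_mode \code{"action"} or \code{"suppression"}.
#' @return the trial table with the \code{outcome} column (re)filled.
#' @export
classify_outcomes <- function(trials, response_window_s = 1.5,
                              task_mode = NULL) {
  if (is.null(task_mode)) task_mode <- attr(trials, "task_mode")
  if (is.null(task_mode) || !task_mode %in% c("action", "suppression")) {
    stop("unknown task_mode: ", if (is.null(task_mode)) "NULL" else
      task_mode)
  }
  lick_in_win <- vapply(seq_len(nrow(trials)), function(i) {
    l <- trials$lick_times[[i]] - trials$t_stimulus[i]
    any(l >= 0 & l < response_window_s)
  }, logical(1))
  out <- character(nrow(trials))
  stim <- trials$type == "stimulus"
  if (task_mode == "action") {
    out[stim] <- ifelse(lick_in_win[stim], "HIT", "MISS")
  } else {
    out[stim] <- ifelse(lick_in_win[stim], "MISS", "HIT")
  }
  out[!stim] <- ifelse(lick_in_win[!stim], "FA", "CR")
  trials$outcome <- out
  trials
}

#' Behavioral sensitivity (d-prime)
#'
#' d' = z(H) - z(F), with z the standard-normal quantile. Rates of exactly
#' 0 or 1 are adjusted by the 1/(2N) rule before the transform (0 becomes
#' 1/(2N), 1 becomes 1 - 1/(2N), N the relevant trial count).
#'
#' @param hit_rate,fa_rate hit and false-alarm rates in \[0, 1\].
#' @param n_stimulus,n_catch trial counts used by the extreme-rate
#'   adjustment; required only when the corresponding rate is 0 or 1.
#' @return list with \code{d_prime}, \code{z_hit}, \code{z_fa}.
#' @export
dprime <- function(hit_rate, fa_rate, n_stimulus = NULL, n_catch = NULL) {
  stopifnot(hit_rate >= 0, hit_rate <= 1, fa_rate >= 0, fa_rate <= 1)
  fix <- function(rate, n, what) {
    if (rate > 0 && rate < 1) return(rate)
    if (is.null(n) || n <= 0) {
      stop("extreme ", what, " rate needs a positive trial count")
    }
    max(1 / (2 * n), min(1 - 1 / (2 * n), rate))
  }
  h <- fix(hit_rate, n_stimulus, "hit")
  f <- fix(fa_rate, n_catch, "false-alarm")
  z_hit <- stats::qnorm(h)
  z_fa <- stats::qnorm(f)
  list(d_prime = z_hit - z_fa, z_hit = z_hit, z_fa = z_fa)
}

#' Fraction of correct trials
#'
#' (HIT + CR) / (stimulus + catch trials). Sessions at or above
#' \code{expert_criterion} are flagged expert.
#'
#' @param n_hit,n_cr,n_stimulus,n_catch outcome and trial counts.
#' @param expert_criterion expert threshold on the fraction (default 0.8).
#' @return list with \code{fraction} and \code{expert} (logical).
#' @export
correct_fraction <- function(n_hit, n_cr, n_stimulus, n_catch,
                             expert_criterion = 0.8) {
  stopifnot(n_hit >= 0, n_cr >= 0, n_stimulus >= 0, n_catch >= 0)
  denom <- n_stimulus + n_catch
  if (denom == 0) stop("zero trials")
  frac <- (n_hit + n_cr) / denom
  list(fraction = frac, expert = frac >= expert_criterion)
}

#' Behavioral metrics for a session
#'
#' Computes hit and false-alarm rates from the outcome counts, d-prime and
#' its z-scores, and the correct fraction.
#'
#' @param trials a classified \code{\link{trial_table}}.
#' @return list with \code{n} (outcome counts), \code{hit_rate},
#'   \code{fa_rate}, \code{d_prime}, \code{z_hit}, \code{z_fa},
#'   \code{correct_fraction}, \code{expert}.
#' @export
behavior_metrics <- function(trials) {
  n_stim <- sum(trials$type == "stimulus")
  n_catch <- sum(trials$type == "catch")
  n_hit <- sum(trials$outcome == "HIT")
  n_fa <- sum(trials$outcome == "FA")
  n_cr <- sum(trials$outcome == "CR")
  if (n_stim == 0 || n_catch == 0) {
    stop("need both stimulus and catch trials for behavioral metrics")
  }
  dp <- dprime(n_hit / n_stim, n_fa / n_catch, n_stim, n_catch)
  cf <- correct_fraction(n_hit, n_cr, n_stim, n_catch)
  list(n = c(stimulus = n_stim, catch = n_catch, HIT = n_hit,
             MISS = n_stim - n_hit, FA = n_fa, CR = n_cr),
       hit_rate = n_hit / n_stim, fa_rate = n_fa / n_catch,
       d_prime = dp$d_prime, z_hit = dp$z_hit, z_fa = dp$z_fa,
       correct_fraction = cf$fraction, expert = cf$expert)
}

#' Latency to the first lick after stimulus onset
#'
#' @param trials a \code{\link{trial_table}}.
#' @param stimulus_only restrict to stimulus trials (default TRUE).
#' @return data.frame \code{trial_id}, \code{latency_ms} (NA for trials
#'   without a post-stimulus lick).
#' @export
first_lick_latency <- function(trials, stimulus_only = TRUE) {
  sel <- if (stimulus_only) which(trials$type == "stimulus") else
    seq_len(nrow(trials))
  lat <- vapply(sel, function(i) {
    l <- trials$lick_times[[i]] - trials$t_stimulus[i]
    l <- l[l >= 0]
    if (length(l)) min(l) * 1000 else NA_real_
  }, numeric(1))
  data.frame(trial_id = trials$trial_id[sel], latency_ms = lat)
}

#' Lick frequency per trial per epoch
#'
#' Lick count inside each resolved epoch window divided by the window
#' length.
#'
#' @param trials a \code{\link{trial_table}}.
#' @param windows resolved windows from \code{\link{assign_epoch_windows}}
#'   (trial-relative seconds).
#' @return data.frame \code{trial_id}, \code{epoch}, \code{lick_hz}.
#' @export
lick_frequency <- function(trials, windows) {
  licks_rel <- stats::setNames(
    lapply(seq_len(nrow(trials)),
           function(i) trials$lick_times[[i]] - trials$t_start[i]),
    trials$trial_id)
  hz <- vapply(seq_len(nrow(windows)), function(k) {
    l <- licks_rel[[as.character(windows$trial_id[k])]]
    sum(l >= windows$start[k] & l < windows$end[k]) /
      (windows$end[k] - windows$start[k])
  }, numeric(1))
  data.frame(trial_id = windows$trial_id, epoch = windows$epoch,
             lick_hz = hz)
}

#' Rank correlation between lick frequency and axonal activity
#'
#' Spearman correlation across trials between the per-trial lick
#' frequency (over the whole trial window by default) and the per-trial
#' mean event occurrence across ROIs (fraction of ROIs with at least one
#' event in the trial). Returns a missing result when either series has
#' zero variance.
#'
#' @param lick_hz numeric vector of per-trial lick frequencies.
#' @param activity numeric vector of per-trial mean event occurrence,
#'   same length.
#' @return list with \code{rho}, \code{p_value}, \code{n}.
#' @export
lick_activity_correlation <- function(lick_hz, activity) {
  stopifnot(length(lick_hz) == length(activity))
  ok <- is.finite(lick_hz) & is.finite(activity)
  if (sum(ok) < 10) stop("need at least 10 paired trials")
  if (stats::sd(lick_hz[ok]) == 0 || stats::sd(activity[ok]) == 0) {
    return(list(rho = NA_real_, p_value = NA_real_, n = sum(ok)))
  }
  ct <- suppressWarnings(
    stats::cor.test(lick_hz[ok], activity[ok], method = "spearman"))
  list(rho = unname(ct$estimate), p_value = ct$p.value, n = sum(ok))
}

#' Per-trial mean event occurrence across ROIs
#'
#' Fraction of the given ROIs with at least one detected event in each
#' trial; the companion series to \code{\link{lick_activity_correlation}}.
#'
#' @param events an \code{event_table}.
#' @param trials a \code{\link{trial_table}}.
#' @param rois ROI ids entering the average.
#' @return numeric vector, one value per trial (in trial-table order).
#' @export
trial_activity <- function(events, trials, rois) {
  vapply(trials$trial_id, function(ti) {
    mean(rois %in% events$roi_id[events$trial_id == ti])
  }, numeric(1))
}
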