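# Independent brute-force transient oracle: walk the trace sample by
# sample, enumerate every maximal contiguous suprathreshold run (NA
# breaks a run), and keep runs strictly longer than min_duration_ms.
# Deliberately naive -- no rle, no vectorization -- so it shares no code
# path with the detector it checks.
oracle_events <- function(x, times, thr, dt, min_duration_ms = 200) {
  n <- length(x)
  res <- NULL
  i <- 1
  while (i <= n) {
    if (!is.na(x[i]) && x[i] > thr) {
      j <- i
      while (j < n && !is.na(x[j + 1]) && x[j + 1] > thr) j <- j + 1
      dur_ms <- (j - i + 1) * dt * 1000
      if (dur_ms > min_duration_ms + 1e-9) {
        peak <- -Inf
        for (k in i:j) peak <- max(peak, x[k])
        res <- rbind(res, c(onset = times[i], offset = times[j] + dt,
                            peak = peak))
      }
      i <- j + 1
    } else {
      i <- i + 1
    }
  }
  if (is.null(res)) {
    data.frame(onset = numeric(0), offset = numeric(0), peak = numeric(0))
  } else {
    as.data.frame(res)
  }
}

# wrap a ROI x trial x sample dF/F array as the tensor the detector
# expects, with a constant baseline (f0 = 1 so thresholds are k * sd)
make_dff_tensor <- function(vals, frame_rate = 30, baseline_sd = NULL) {
  n_roi <- dim(vals)[1]; n_trial <- dim(vals)[2]
  roi_ids <- sprintf("roi%03d", seq_len(n_roi))
  dimnames(vals)[[1]] <- roi_ids
  if (is.null(baseline_sd)) baseline_sd <- rep(0.1, n_roi)
  names(baseline_sd) <- roi_ids
  structure(list(
    values = vals,
    sample_times = (seq_len(dim(vals)[3]) - 1) / frame_rate,
    trial_ids = seq_len(n_trial), roi_ids = roi_ids,
    frame_rate = frame_rate,
    dropped = data.frame(trial_id = integer(0), reason = character(0)),
    baseline = list(f0 = matrix(1, n_roi, n_trial,
                                dimnames = list(roi_ids, NULL)),
                    baseline_sd = baseline_sd, rolling_window = 5)),
    class = c("dff_tensor", "trial_tensor"))
}

# compact session config for fast tests (dots override the quick defaults)
quick_config <- function(...) {
  args <- list(n_trials = 20, n_axons = 8, fov_shape = c(64L, 64L),
               max_shift_px = 0, seed = 42)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(sim_config, args)
}

# event table builder for hand-constructed dedup scenarios
make_events <- function(df, roi_ids, trial_ids, frame_rate = 30) {
  df$offset_s <- df$onset_s + 0.4
  df$duration_ms <- 400
  if (is.null(df$peak_dff)) df$peak_dff <- 1
  attr(df, "frame_rate") <- frame_rate
  attr(df, "roi_ids") <- roi_ids
  attr(df, "trial_ids") <- trial_ids
  class(df) <- c("event_table", "data.frame")
  df
}
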