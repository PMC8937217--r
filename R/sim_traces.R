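#' Calcium transient kernel
#'
#' Difference-of-exponentials impulse response, zero for t < 0 and
#' normalized to unit peak, emulating fast genetically encoded indicator
#' (GCaMP6f-like) kinetics.
#'
#' @param t time in seconds (vector).
#' @param rise_ms,kernel_decay_ms rise / decay time constants, ms.
#' @return kernel values, unit peak.
#' @export
ca_kernel <- function(t, rise_ms = 50, decay_ms = 400) {
  tr <- rise_ms / 1000
  td <- decay_ms / 1000
  stopifnot(tr > 0, td > tr)
  t_peak <- tr * td / (td - tr) * log(td / tr)
  peak <- exp(-t_peak / td) - exp(-t_peak / tr)
  k <- ifelse(t < 0, 0, (exp(-t / td) - exp(-t / tr)) / peak)
  k
}

# discrete kernel sampled on the frame grid, renormalized to unit peak so
# that an injected amplitude equals the max dF/F of the rendered transient
discrete_kernel <- function(frame_rate, rise_ms, decay_ms, tol = 1e-4) {
  td <- decay_ms / 1000
  t_max <- td * log(1 / tol) + 0.5
  t <- seq(0, t_max, by = 1 / frame_rate)
  k <- ca_kernel(t, rise_ms, decay_ms)
  k / max(k)
}

# look up the injection probability for one epoch on a trial with the
# given outcome: scalar entries apply to all outcomes, named vectors are
# keyed by outcome (missing outcome -> 0)
epoch_prob_for <- function(epoch_event_prob, epoch, outcome) {
  p <- epoch_event_prob[[epoch]]
  if (length(p) == 1 && is.null(names(p))) return(as.numeric(p))
  if (outcome %in% names(p)) as.numeric(p[[outcome]]) else 0
}

#' Simulate ROI fluorescence traces for a session
#'
#' For each axon, each trial and each canonical epoch, a transient is
#' injected with the configured probability (at most one per epoch per
#' trial). Onsets are drawn uniformly over the epoch window, snapped to the
#' frame grid, and kept at least 0.1 s clear of the window end so that the
#' detector's threshold-crossing latency cannot move an event across the
#' epoch boundary. Amplitudes are lognormal with the configured mean and
#' SD. The impulse train is convolved with the discrete transient kernel,
#' scaled by the baseline level, and slow sinusoidal drift plus white noise
#' are added. Branch ROIs of an axon share the parent's event train and
#' amplitudes but carry independent noise.
#'
#' @param trials a \code{\link{trial_table}} from \code{simulate_trials}.
#' @param config a \code{\link{sim_config}}.
#' @param seed optional integer overriding \code{config$seed + 1}.
#' @return a list with components \code{traces} (a \code{trace_matrix}:
#'   \code{values} ROI x frame, \code{frame_times}, \code{roi_ids},
#'   \code{frame_rate}) and \code{ground_truth} (class
#'   \code{ground_truth}: \code{true_events} data.frame with roi_id,
#'   trial_id, epoch, onset_s (absolute), amplitude; \code{duplicate_map}
#'   ROI -> axon; \code{injected_probs}; \code{outcome_labels};
#'   \code{shift_series} filled by \code{\link{simulate_frames}}).
#' @export
simulate_traces <- function(trials, config, seed = NULL) {
  if (nrow(trials) == 0) stop("trials must be nonempty")
  if (!setequal(names(config$epoch_event_prob), canonical_epochs())) {
    stop("epoch_event_prob must cover exactly the canonical epochs")
  }
  if (!is.null(seed)) set.seed(seed) else set.seed(config$seed + 1L)

  fr <- config$frame_rate
  session_end <- max(trials$t_start) + trial_window_s(config)
  n_frames <- as.integer(ceiling(session_end * fr)) + 1L
  frame_times <- (seq_len(n_frames) - 1) / fr
  margin <- 0.1

  n_ax <- config$n_axons
  nb <- config$branches_per_axon
  roi_ids <- as.vector(t(outer(seq_len(n_ax), seq_len(nb),
                               function(a, b) sprintf("ax%02d_b%d", a, b))))
  duplicate_map <- stats::setNames(rep(seq_len(n_ax), each = nb), roi_ids)

  # per-axon impulse trains: one Bernoulli draw per axon x trial x epoch
  ml <- log(config$amplitude_mean^2 /
              sqrt(config$amplitude_mean^2 + config$amplitude_sd^2))
  sl <- sqrt(log(1 + (config$amplitude_sd / config$amplitude_mean)^2))
  n_trial <- nrow(trials)
  b <- config$baseline_s
  ev_list <- list()
  for (ep in canonical_epochs()) {
    w_start <- switch(ep, spontaneous = rep(b - 2, n_trial),
                      stimulus = rep(b, n_trial),
                      response = rep(b + 0.5, n_trial),
                      reward = trials$t_reward - trials$t_start)
    w_end <- switch(ep, spontaneous = rep(b - 1, n_trial),
                    stimulus = rep(b + 0.5, n_trial),
                    response = rep(b + 1, n_trial),
                    reward = trials$t_reward - trials$t_start + 1)
    p_trial <- vapply(trials$outcome, function(o)
      epoch_prob_for(config$epoch_event_prob, ep, o), numeric(1))
    p_trial[is.na(w_start)] <- 0
    draws <- matrix(stats::runif(n_ax * n_trial), n_ax, n_trial)
    hit <- which(draws < rep(p_trial, each = n_ax))
    if (!length(hit)) next
    ax <- ((hit - 1) %% n_ax) + 1L
    ti <- ((hit - 1) %/% n_ax) + 1L
    onset <- stats::runif(length(hit), w_start[ti],
                          pmax(w_start[ti], w_end[ti] - margin))
    abs_onset <- round((trials$t_start[ti] + onset) * fr) / fr  # on grid
    amp <- if (config$amplitude_sd > 0)
      stats::rlnorm(length(hit), ml, sl) else
        rep(config$amplitude_mean, length(hit))
    ev_list[[ep]] <- data.frame(axon = ax,
                                trial_id = trials$trial_id[ti],
                                epoch = ep, onset_s = abs_onset,
                                amplitude = amp,
                                stringsAsFactors = FALSE)
  }
  axon_ev <- if (length(ev_list)) do.call(rbind, ev_list) else
    data.frame(axon = integer(0), trial_id = integer(0),
               epoch = character(0), onset_s = numeric(0),
               amplitude = numeric(0))
  impulses <- matrix(0, nrow = n_ax, ncol = n_frames)
  if (nrow(axon_ev)) {
    fidx <- as.integer(round(axon_ev$onset_s * fr)) + 1L
    keep_ev <- fidx <= n_frames
    axon_ev <- axon_ev[keep_ev, , drop = FALSE]
    fidx <- fidx[keep_ev]
    for (k in seq_along(fidx)) {
      impulses[axon_ev$axon[k], fidx[k]] <-
        impulses[axon_ev$axon[k], fidx[k]] + axon_ev$amplitude[k]
    }
  }

  kern <- discrete_kernel(fr, config$kernel_rise_ms, config$kernel_decay_ms)
  # causal FIR convolution via zero-padded FFT (power-of-2 length so the
  # transform stays fast for any session length)
  L <- stats::nextn(n_frames + length(kern) - 1L, 2)
  K <- stats::fft(c(kern, rep(0, L - length(kern))))
  signal <- matrix(0, nrow = n_ax, ncol = n_frames)
  for (a in seq_len(n_ax)) {
    if (!any(impulses[a, ] != 0)) next
    X <- stats::fft(c(impulses[a, ], rep(0, L - n_frames)))
    conv <- Re(stats::fft(X * K, inverse = TRUE)) / L
    signal[a, ] <- conv[seq_len(n_frames)]
  }

  drift <- config$drift_amplitude * sin(2 * pi * frame_times / 300)
  values <- matrix(0, nrow = length(roi_ids), ncol = n_frames,
                   dimnames = list(roi_ids, NULL))
  for (r in seq_along(roi_ids)) {
    a <- duplicate_map[[r]]
    noise <- if (config$noise_sd > 0)
      stats::rnorm(n_frames, 0, config$noise_sd) else 0
    values[r, ] <- config$f0_level * (1 + signal[a, ]) + drift + noise
  }

  axon_events <- axon_ev[order(axon_ev$axon, axon_ev$trial_id,
                               axon_ev$onset_s), , drop = FALSE]
  # expand per ROI (branches share the parent's train)
  if (nrow(axon_events)) {
    per_roi <- do.call(rbind, lapply(seq_along(roi_ids), function(r) {
      sub <- axon_events[axon_events$axon == duplicate_map[[r]], , drop = FALSE]
      if (!nrow(sub)) return(NULL)
      data.frame(roi_id = roi_ids[r], sub[-1], stringsAsFactors = FALSE)
    }))
  } else {
    per_roi <- data.frame(roi_id = character(0), trial_id = integer(0),
                          epoch = character(0), onset_s = numeric(0),
                          amplitude = numeric(0))
  }

  traces <- structure(list(values = values, frame_times = frame_times,
                           roi_ids = roi_ids, frame_rate = fr),
                      class = "trace_matrix")
  gt <- structure(list(true_events = per_roi,
                       duplicate_map = duplicate_map,
                       injected_probs = config$epoch_event_prob,
                       outcome_labels = trials$outcome,
                       shift_series = NULL),
                  class = "ground_truth")
  stopifnot(all(per_roi$onset_s >= 0), all(per_roi$onset_s <= session_end))
  list(traces = traces, ground_truth = gt)
}

#' @export
print.trace_matrix <- function(x, ...) {
  cat(sprintf("Trace matrix: %d ROIs x %d frames at %g Hz (%.1f s)\n",
              nrow(x$values), ncol(x$values), x$frame_rate,
              max(x$frame_times)))
  invisible(x)
}

#' Write / read ROI traces as long-format CSV
#'
#' Columns: \code{roi_id}, \code{frame_time}, \code{value}.
#'
#' @param traces a \code{trace_matrix}.
#' @param path file path.
#' @return \code{read_traces_csv} returns a \code{trace_matrix}.
#' @export
write_traces_csv <- function(traces, path) {
  long <- data.frame(
    roi_id = rep(traces$roi_ids, each = length(traces$frame_times)),
    frame_time = rep(traces$frame_times, times = length(traces$roi_ids)),
    value = as.vector(t(traces$values)))
  utils::write.csv(long, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_traces_csv
#' @export
read_traces_csv <- function(path) {
  long <- utils::read.csv(path, stringsAsFactors = FALSE)
  roi_ids <- unique(long$roi_id)
  frame_times <- sort(unique(long$frame_time))
  values <- matrix(NA_real_, length(roi_ids), length(frame_times),
                   dimnames = list(roi_ids, NULL))
  for (r in roi_ids) {
    sub <- long[long$roi_id == r, ]
    values[r, ] <- sub$value[order(sub$frame_time)]
  }
  fr <- 1 / stats::median(diff(frame_times))
  structure(list(values = values, frame_times = frame_times,
                 roi_ids = roi_ids, frame_rate = fr),
            class = "trace_matrix")
}
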