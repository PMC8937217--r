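#' Configuration for a synthetic imaging session
#'
#' Bundles every tunable of the synthetic-session generator: task structure
#' (trial counts, catch fraction, task mode), imaging geometry and clock,
#' the event model (per-epoch transient probabilities, lognormal amplitudes,
#' indicator kinetics), and the noise model (shot noise, slow drift, rigid
#' motion). Defaults emulate a typical expert session: ~300 trials with 40%
#' catch trials, a 512 x 512 px field of view imaged at 30 Hz, ~19 axonal
#' ROIs, and GCaMP6f-like transient kinetics.
#'
#' Trials have a fixed internal anatomy: a 3 s baseline, a 500 ms tactile
#' stimulus, a 1.5 s response window, a 2 s reward-retrieval window, and a
#' 2 s tail so post-reward frames always exist; consecutive trials are
#' separated by an inter-trial interval drawn uniformly from 4--7 s.
#'
#' @param n_trials number of trials in the session.
#' @param catch_fraction fraction of trials without a tactile stimulus
#'   (catch trials), in \[0, 1\].
#' @param frame_rate imaging frame rate in Hz.
#' @param fov_shape integer vector of length 2, field of view in pixels
#'   (rows, cols).
#' @param n_axons number of distinct axons in the field of view.
#' @param branches_per_axon number of ROIs drawn per axon (>= 1); branches
#'   beyond the first share the parent axon's event train and differ only
#'   in noise, emulating boutons/branches of one neuron.
#' @param epoch_event_prob named list mapping the canonical epochs
#'   (\code{spontaneous}, \code{stimulus}, \code{response}, \code{reward})
#'   to the per-trial probability of injecting one transient in that epoch.
#'   Each entry is either a single probability applied to every trial, or a
#'   named numeric vector keyed by outcome (\code{HIT}, \code{MISS},
#'   \code{FA}, \code{CR}) for outcome-dependent rates.
#' @param amplitude_mean,amplitude_sd mean and standard deviation of
#'   injected transient amplitudes, in dF/F units; amplitudes are drawn
#'   from the lognormal distribution with these moments.
#' @param kernel_rise_ms,kernel_decay_ms rise and decay time constants of
#'   the transient kernel in milliseconds (difference of exponentials,
#'   normalized to unit peak).
#' @param noise_sd white-noise standard deviation in raw fluorescence units.
#' @param f0_level baseline fluorescence level in raw units.
#' @param drift_amplitude amplitude of the slow sinusoidal baseline drift,
#'   raw fluorescence units.
#' @param max_shift_px maximum rigid frame shift in pixels applied when
#'   rendering raw frames.
#' @param task_mode \code{"action"} (lick to report) or
#'   \code{"suppression"} (withhold licking to report).
#' @param hit_rate,fa_rate probabilities used to sample trial outcomes
#'   (HIT on stimulus trials, FA on catch trials). Outcomes are inputs to
#'   the analysis, not produced by a behavioral model.
#' @param pupil_baseline_mm,pupil_bump_mm,pupil_noise_sd_mm,pupil_artifact_rate
#'   pupil model: baseline diameter, post-stimulus dilation amplitude,
#'   slow-noise SD (all mm), and per-sample probability of an eyelid
#'   artifact dropout.
#' @param seed integer seed making the whole session reproducible.
#'
#' @return an object of class \code{sim_config} (a validated list).
#' @export
sim_config <- function(n_trials = 300,
                       catch_fraction = 0.4,
                       frame_rate = 30,
                       fov_shape = c(512L, 512L),
                       n_axons = 19,
                       branches_per_axon = 1,
                       epoch_event_prob = list(spontaneous = 0.08,
                                               stimulus = 0,
                                               response = 0.32,
                                               reward = 0.12),
                       amplitude_mean = 1.0,
                       amplitude_sd = 0.25,
                       kernel_rise_ms = 50,
                       kernel_decay_ms = 400,
                       noise_sd = 8,
                       f0_level = 100,
                       drift_amplitude = 2,
                       max_shift_px = 8,
                       task_mode = c("action", "suppression"),
                       hit_rate = 0.87,
                       fa_rate = 0.15,
                       pupil_baseline_mm = 0.32,
                       pupil_bump_mm = 0.12,
                       pupil_noise_sd_mm = 0.01,
                       pupil_artifact_rate = 0,
                       seed = 1L) {
  task_mode <- match.arg(task_mode)
  stopifnot(
    is.numeric(n_trials), length(n_trials) == 1, n_trials >= 0,
    is.numeric(catch_fraction), catch_fraction >= 0, catch_fraction <= 1,
    is.numeric(frame_rate), frame_rate > 0,
    length(fov_shape) == 2, all(fov_shape >= 1),
    n_axons >= 1, branches_per_axon >= 1,
    kernel_rise_ms > 0, kernel_decay_ms > 0,
    kernel_rise_ms < kernel_decay_ms,
    noise_sd >= 0, f0_level > 0, drift_amplitude >= 0, max_shift_px >= 0,
    hit_rate >= 0, hit_rate <= 1, fa_rate >= 0, fa_rate <= 1,
    amplitude_mean > 0, amplitude_sd >= 0
  )
  if (!is.list(epoch_event_prob) ||
      !setequal(names(epoch_event_prob), canonical_epochs())) {
    stop("epoch_event_prob must be a named list over the canonical epochs: ",
         paste(canonical_epochs(), collapse = ", "))
  }
  for (nm in names(epoch_event_prob)) {
    p <- epoch_event_prob[[nm]]
    if (!is.numeric(p) || any(p < 0) || any(p > 1)) {
      stop("epoch_event_prob[['", nm, "']] must be probabilities in [0, 1]")
    }
    if (length(p) > 1 &&
        !all(names(p) %in% c("HIT", "MISS", "FA", "CR"))) {
      stop("per-outcome probabilities must be named HIT/MISS/FA/CR")
    }
  }
  cfg <- list(
    n_trials = as.integer(n_trials), catch_fraction = catch_fraction,
    frame_rate = frame_rate, fov_shape = as.integer(fov_shape),
    n_axons = as.integer(n_axons),
    branches_per_axon = as.integer(branches_per_axon),
    epoch_event_prob = epoch_event_prob,
    amplitude_mean = amplitude_mean, amplitude_sd = amplitude_sd,
    kernel_rise_ms = kernel_rise_ms, kernel_decay_ms = kernel_decay_ms,
    noise_sd = noise_sd, f0_level = f0_level,
    drift_amplitude = drift_amplitude, max_shift_px = max_shift_px,
    task_mode = task_mode, hit_rate = hit_rate, fa_rate = fa_rate,
    pupil_baseline_mm = pupil_baseline_mm, pupil_bump_mm = pupil_bump_mm,
    pupil_noise_sd_mm = pupil_noise_sd_mm,
    pupil_artifact_rate = pupil_artifact_rate,
    seed = as.integer(seed),
    # fixed trial anatomy (seconds)
    baseline_s = 3, stimulus_s = 0.5, response_window_s = 1.5,
    retrieval_s = 2, tail_s = 2, iti_range_s = c(4, 7)
  )
  class(cfg) <- "sim_config"
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic session config:\n")
  cat(sprintf("  %d trials (%.0f%% catch), task mode '%s'\n",
              x$n_trials, 100 * x$catch_fraction, x$task_mode))
  cat(sprintf("  %d axons x %d branch(es), %g Hz, FOV %dx%d px\n",
              x$n_axons, x$branches_per_axon, x$frame_rate,
              x$fov_shape[1], x$fov_shape[2]))
  p <- vapply(x$epoch_event_prob, function(v) paste(signif(v, 3),
                                                    collapse = "/"), "")
  cat("  epoch event prob:", paste(names(p), p, sep = "=", collapse = ", "),
      "\n")
  invisible(x)
}

# canonical epoch names, in temporal order within a trial
canonical_epochs <- function() c("spontaneous", "stimulus", "response",
                                 "reward")

# duration of one trial's recorded window (trial start -> reward window
# end + tail), seconds
trial_window_s <- function(config) {
  config$baseline_s + config$response_window_s + config$retrieval_s +
    config$tail_s
}

#' Read / write a generator configuration as YAML
#'
#' @param config a \code{sim_config}.
#' @param path file path.
#' @return \code{read_sim_config} returns a \code{sim_config}.
#' @export
write_sim_config <- function(config, path) {
  keep <- setdiff(names(config),
                  c("baseline_s", "stimulus_s", "response_window_s",
                    "retrieval_s", "tail_s", "iti_range_s"))
  vals <- unclass(config)[keep]
  # named per-outcome vectors must become YAML maps, not bare sequences
  vals$epoch_event_prob <- lapply(vals$epoch_event_prob, function(v)
    if (!is.null(names(v))) as.list(v) else v)
  yaml::write_yaml(vals, path)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  vals <- yaml::read_yaml(path)
  if (!is.null(vals$epoch_event_prob)) {
    vals$epoch_event_prob <- lapply(vals$epoch_event_prob, function(v)
      if (is.list(v)) unlist(v) else v)
  }
  if (!is.null(vals$fov_shape)) vals$fov_shape <- unlist(vals$fov_shape)
  do.call(sim_config, vals)
}
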