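#' Simulate a trial-locked pupil diameter trace
#'
#' Generates a session-long pupil diameter series at \code{sample_rate} Hz:
#' a constant baseline plus smoothed slow noise, with a smooth dilation
#' bump (raised-cosine rise, exponential decay) added after stimulus onset
#' on engaged trials (trials where the animal licked, plus HIT trials).
#' Brief eyelid-closure dropouts can be injected at a configurable rate;
#' dropout samples have diameter 0 and are flagged.
#'
#' @param trials a \code{\link{trial_table}}.
#' @param config a \code{\link{sim_config}} (pupil_* fields).
#' @param sample_rate sampling rate in Hz (pupil cameras are slower than
#'   the imaging clock; default 15 Hz).
#' @param seed optional integer overriding \code{config$seed + 4}.
#' @return a \code{pupil_trace}: list with \code{times} (s),
#'   \code{diameter} (mm), \code{artifact_flags} (logical), and
#'   \code{sample_rate}; ground-truth dropout windows are attached as the
#'   \code{dropouts} attribute.
#' @export
simulate_pupil <- function(trials, config, sample_rate = 15, seed = NULL) {
  if (nrow(trials) == 0) stop("trials must be nonempty")
  if (!is.null(seed)) set.seed(seed) else set.seed(config$seed + 4L)
  # cover the 4 s pre-trial baseline of the first trial and the 11 s
  # trial window of the last
  t0 <- trials$t_start[1] - 4.5
  t1 <- max(trials$t_start) + 7.5
  times <- seq(t0, t1, by = 1 / sample_rate)
  n <- length(times)

  diam <- rep(config$pupil_baseline_mm, n)
  if (config$pupil_noise_sd_mm > 0) {
    raw <- stats::rnorm(n, 0, config$pupil_noise_sd_mm)
    k <- rep(1 / 15, 15)  # ~1 s boxcar -> slow noise
    diam <- diam + as.numeric(stats::filter(raw, k, sides = 2,
                                            circular = TRUE))
  }

  if (config$pupil_bump_mm > 0) {
    engaged <- vapply(seq_len(nrow(trials)), function(i) {
      trials$outcome[i] == "HIT" || length(trials$lick_times[[i]]) > 0
    }, logical(1))
    # raised-cosine rise to the peak 1 s after stimulus onset, then a
    # raised-cosine relaxation back to baseline by +4 s, so dilation is
    # confined to the post-tactile analysis window
    rise <- 1.0; fall <- 3.0
    for (i in which(engaged)) {
      dt <- times - trials$t_stimulus[i]
      sel <- dt >= 0 & dt < rise + fall
      d <- dt[sel]
      bump <- ifelse(d < rise, 0.5 * (1 - cos(pi * d / rise)),
                     0.5 * (1 + cos(pi * (d - rise) / fall)))
      diam[sel] <- diam[sel] + config$pupil_bump_mm * bump
    }
  }

  flags <- rep(FALSE, n)
  dropouts <- NULL
  if (config$pupil_artifact_rate > 0) {
    starts <- which(stats::runif(n) < config$pupil_artifact_rate /
                      sample_rate)
    for (s in starts) {
      len <- sample(2:5, 1)  # 0.13-0.33 s blinks
      idx <- s:min(n, s + len - 1)
      flags[idx] <- TRUE
      diam[idx] <- 0
      dropouts <- rbind(dropouts, c(times[idx[1]], times[idx[length(idx)]]))
    }
  }
  structure(list(times = times, diameter = diam, artifact_flags = flags,
                 sample_rate = sample_rate),
            class = "pupil_trace", dropouts = dropouts)
}

#' @export
print.pupil_trace <- function(x, ...) {
  cat(sprintf(
    "Pupil trace: %d samples at %g Hz, %.1f s, %d flagged artifact\n",
    length(x$times), x$sample_rate, diff(range(x$times)),
    sum(x$artifact_flags)))
  invisible(x)
}

#' Write / read a pupil trace as CSV
#'
#' Columns: \code{time_s}, \code{diameter_mm}, \code{artifact} (0/1).
#'
#' @param trace a \code{pupil_trace}.
#' @param path file path.
#' @return \code{read_pupil_csv} returns a \code{pupil_trace}.
#' @export
write_pupil_csv <- function(trace, path) {
  utils::write.csv(data.frame(time_s = trace$times,
                              diameter_mm = trace$diameter,
                              artifact = as.integer(trace$artifact_flags)),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_pupil_csv
#' @export
read_pupil_csv <- function(path) {
  df <- utils::read.csv(path)
  sr <- 1 / stats::median(diff(df$time_s))
  structure(list(times = df$time_s, diameter = df$diameter_mm,
                 artifact_flags = df$artifact == 1, sample_rate = sr),
            class = "pupil_trace")
}
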