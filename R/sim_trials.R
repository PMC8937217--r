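#' Simulate the trial structure of a go/no-go session
#'
#' Draws a sequence of stimulus and catch trials with the task's fixed
#' timing: each trial starts with a 3 s baseline, the tactile stimulus (or,
#' on catch trials, a virtual stimulus time) occurs 3 s after trial start,
#' licking in the following 1.5 s response window determines the outcome,
#' and rewarded trials have the reward delivered at the end of that window.
#' Consecutive trial starts are separated by the trial window plus a
#' uniformly random 4--7 s inter-trial interval.
#'
#' Outcomes are sampled from \code{config$hit_rate} / \code{config$fa_rate}
#' (they are inputs to the analysis, not the product of a behavioral model)
#' and lick trains are then generated to be consistent with the sampled
#' outcome under the session's task mode:
#' \itemize{
#'   \item action mode: HIT = at least one lick inside the response window
#'     (first-lick latency ~ 350 ms), MISS = no lick; on catch trials FA =
#'     lick in window, CR = none.
#'   \item suppression mode: HIT = licking withheld for the full 1.5 s
#'     window (reward follows, with retrieval licks), MISS = an early lick
#'     inside the window aborts the trial.
#' }
#'
#' @param config a \code{\link{sim_config}}.
#' @param seed optional integer overriding \code{config$seed}.
#' @return a \code{trial_table}: a data.frame with columns \code{trial_id},
#'   \code{type} ("stimulus"/"catch"), \code{t_start}, \code{t_stimulus},
#'   \code{t_reward} (NA when unrewarded), \code{outcome}, and a
#'   list-column \code{lick_times} (absolute seconds); attributes
#'   \code{task_mode} and \code{trial_window_s}.
#' @export
simulate_trials <- function(config, seed = NULL) {
  if (config$n_trials == 0) stop("empty session: n_trials must be >= 1")
  if (!is.null(seed)) set.seed(seed) else set.seed(config$seed)

  n <- config$n_trials
  win <- trial_window_s(config)
  iti <- stats::runif(n, config$iti_range_s[1], config$iti_range_s[2])
  t_start <- cumsum(c(0, (win + iti)[-n]))
  type <- ifelse(stats::runif(n) < config$catch_fraction,
                 "catch", "stimulus")
  t_stimulus <- t_start + config$baseline_s
  rw <- config$response_window_s

  outcome <- character(n)
  t_reward <- rep(NA_real_, n)
  lick_times <- vector("list", n)
  for (i in seq_len(n)) {
    if (type[i] == "stimulus") {
      hit <- stats::runif(1) < config$hit_rate
      outcome[i] <- if (hit) "HIT" else "MISS"
    } else {
      outcome[i] <- if (stats::runif(1) < config$fa_rate) "FA" else "CR"
    }
    licks <- numeric(0)
    licked_in_window <- switch(config$task_mode,
      action = outcome[i] %in% c("HIT", "FA"),
      suppression = outcome[i] %in% c("MISS", "FA"))
    if (licked_in_window) {
      # first lick ~350 ms after the (virtual) stimulus, then a short bout
      first <- min(0.35 + stats::rexp(1, rate = 1 / 0.15), rw - 1 / 60)
      bout <- first + cumsum(c(0, stats::rexp(5, rate = 6)))
      licks <- bout[bout < rw]
    }
    rewarded <- switch(config$task_mode,
      action = outcome[i] == "HIT",
      suppression = type[i] == "stimulus" && outcome[i] == "HIT")
    if (rewarded) {
      t_reward[i] <- t_stimulus[i] + rw
      # retrieval licking after reward delivery
      retr <- rw + 0.1 + cumsum(stats::rexp(8, rate = 7))
      licks <- c(licks, retr[retr < rw + config$retrieval_s])
    }
    lick_times[[i]] <- t_stimulus[i] + licks
  }

  tt <- data.frame(trial_id = seq_len(n), type = type, t_start = t_start,
                   t_stimulus = t_stimulus, t_reward = t_reward,
                   outcome = outcome, stringsAsFactors = FALSE)
  tt$lick_times <- lick_times
  attr(tt, "task_mode") <- config$task_mode
  attr(tt, "trial_window_s") <- win
  attr(tt, "frame_rate") <- config$frame_rate
  class(tt) <- c("trial_table", "data.frame")
  tt
}

#' @export
print.trial_table <- function(x, ...) {
  cat(sprintf("Trial table: %d trials (%d stimulus, %d catch), mode '%s'\n",
              nrow(x), sum(x$type == "stimulus"), sum(x$type == "catch"),
              attr(x, "task_mode")))
  print(table(outcome = x$outcome))
  invisible(x)
}

#' Write / read a trial table as CSV
#'
#' Lick times are serialized as a semicolon-separated string so the table
#' round-trips through a plain-text file.
#'
#' @param trials a \code{trial_table}.
#' @param path file path.
#' @return \code{read_trials_csv} returns a \code{trial_table}.
#' @export
write_trials_csv <- function(trials, path) {
  out <- as.data.frame(trials[setdiff(names(trials), "lick_times")])
  out$lick_times <- vapply(trials$lick_times,
                           function(v) paste(sprintf("%.6f", v),
                                             collapse = ";"), "")
  out$task_mode <- attr(trials, "task_mode")
  out$trial_window_s <- attr(trials, "trial_window_s")
  out$frame_rate <- attr(trials, "frame_rate")
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trials_csv
#' @export
read_trials_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  lt <- lapply(strsplit(ifelse(is.na(df$lick_times), "", df$lick_times),
                        ";", fixed = TRUE),
               function(v) as.numeric(v[nzchar(v)]))
  tt <- df[setdiff(names(df), c("lick_times", "task_mode",
                                "trial_window_s", "frame_rate"))]
  tt$lick_times <- lt
  attr(tt, "task_mode") <- df$task_mode[1]
  attr(tt, "trial_window_s") <- df$trial_window_s[1]
  attr(tt, "frame_rate") <- df$frame_rate[1]
  class(tt) <- c("trial_table", "data.frame")
  tt
}
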