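mini_trials <- function() {
  tt <- data.frame(trial_id = 1:4,
                   type = c("stimulus", "stimulus", "catch", "stimulus"),
                   t_start = c(0, 20, 40, 60),
                   t_stimulus = c(3, 23, 43, 63),
                   t_reward = c(4.5, NA, NA, 64.5),
                   outcome = c("HIT", "MISS", "CR", "HIT"))
  tt$lick_times <- list(3.4, numeric(0), numeric(0), 63.35)
  attr(tt, "task_mode") <- "action"
  attr(tt, "trial_window_s") <- 8.5
  class(tt) <- c("trial_table", "data.frame")
  tt
}

test_that("epoch windows resolve to the canonical trial-relative spans", {
  tt <- mini_trials()
  w <- assign_epoch_windows(tt)
  sp <- w[w$epoch == "spontaneous" & w$trial_id == 1, ]
  expect_equal(c(sp$start, sp$end), c(1, 2))
  rs <- w[w$epoch == "response" & w$trial_id == 1, ]
  expect_equal(c(rs$start, rs$end), c(3, 4))
  rw <- w[w$epoch == "reward", ]
  # reward at +4.5 s -> window [4.5, 5.5); only on rewarded trials
  expect_equal(rw$trial_id, c(1L, 4L))
  expect_equal(rw$start, c(4.5, 4.5))
  expect_equal(rw$end, c(5.5, 5.5))
  # catch trials anchor on the virtual stimulus time
  cs <- w[w$epoch == "response" & w$trial_id == 3, ]
  expect_equal(c(cs$start, cs$end), c(3, 4))
  # split windows subdivide the first post-stimulus second
  w2 <- assign_epoch_windows(tt, epoch_definitions(split_stimulus = TRUE))
  st <- w2[w2$epoch == "stimulus" & w2$trial_id == 1, ]
  expect_equal(c(st$start, st$end), c(3, 3.5))
})

test_that("event probability is event-trials over eligible trials", {
  n <- 40
  tt <- data.frame(trial_id = 1:n, type = "stimulus", t_start = (0:39) * 20,
                   t_stimulus = (0:39) * 20 + 3, t_reward = NA_real_,
                   outcome = "HIT")
  attr(tt, "trial_window_s") <- 8.5
  class(tt) <- c("trial_table", "data.frame")
  # 12 trials with one response-window onset; one trial with two onsets
  ev <- make_events(data.frame(
    roi_id = "a",
    trial_id = c(1:12, 12L),
    onset_s = c(rep(3.5, 12), 3.8)),
    roi_ids = "a", trial_ids = 1:n)
  w <- assign_epoch_windows(tt)
  st <- event_probability(ev, w, tt, rois = "a")
  resp <- st[st$epoch == "response" & st$outcome == "HIT", ]
  expect_equal(resp$probability, 12 / 40)  # multi-onset trials count once
  expect_equal(resp$n_event_trials, 12)
  sp <- st[st$epoch == "spontaneous", ]
  expect_equal(sp$probability, 0)
  # no reward window anywhere -> no reward rows (missing, not zero)
  expect_false("reward" %in% st$epoch)
})

test_that("probabilities are bounded and invariant to duplicating trials", {
  cfg <- quick_config()
  sess <- simulate_session(cfg, pupil = FALSE)
  an <- analyze_session(sess$traces, sess$trials, dedup = FALSE)
  expect_true(all(an$probability$probability >= 0 &
                    an$probability$probability <= 1))
  # duplicating every trial leaves the per-ROI probability unchanged
  ev <- an$events
  tt <- sess$trials
  ev2 <- ev
  ev2$trial_id <- ev2$trial_id + nrow(tt)
  both <- rbind(as.data.frame(ev), as.data.frame(ev2))
  attr(both, "frame_rate") <- attr(ev, "frame_rate")
  class(both) <- class(ev)
  tt2 <- as.data.frame(tt[, setdiff(names(tt), "lick_times")])
  tt2 <- rbind(tt2, transform(tt2, trial_id = trial_id + nrow(tt)))
  tt2$lick_times <- c(tt$lick_times, tt$lick_times)
  class(tt2) <- class(tt)
  w1 <- assign_epoch_windows(tt)
  w2 <- assign_epoch_windows(tt2)
  rois <- an$analysis_rois
  p1 <- event_probability(ev, w1, tt, rois, by = "all")
  p2 <- event_probability(both, w2, tt2, rois, by = "all")
  m <- merge(p1, p2, by = c("roi_id", "epoch"))
  expect_equal(m$probability.x, m$probability.y)
})

test_that("evoked amplitude stats average the first event per trial", {
  tt <- mini_trials()
  w <- assign_epoch_windows(tt)
  ev <- make_events(data.frame(
    roi_id = c("a", "a", "a"),
    trial_id = c(1L, 4L, 4L),
    onset_s = c(3.5, 3.2, 3.8),
    peak_dff = c(0.5, 1.5, 9)),
    roi_ids = c("a", "b"), trial_ids = 1:4)
  st <- evoked_amplitude_stats(ev, w, tt, rois = c("a", "b"))
  resp <- st[st$epoch == "response" & st$outcome == "HIT", ]
  # first event per trial: peaks 0.5 and 1.5 -> mean 1.0
  expect_equal(resp$mean_peak_dff, 1.0)
  expect_equal(resp$n_event_trials, 2)
  # ROI b has no events: excluded, not zero
  expect_false("b" %in% st$roi_id)
})

test_that("injected amplitudes are recovered at high SNR", {
  cfg <- sim_config(n_trials = 40, n_axons = 30, noise_sd = 4,
                    drift_amplitude = 0, seed = 19)
  sess <- simulate_session(cfg, pupil = FALSE)
  an <- analyze_session(sess$traces, sess$trials, dedup = FALSE)
  amp <- an$amplitude
  resp <- amp[amp$epoch == "response", ]
  est <- mean(resp$mean_peak_dff)
  gt <- sess$ground_truth$true_events
  inj <- mean(gt$amplitude[gt$epoch %in% c("stimulus", "response")])
  se <- sd(resp$mean_peak_dff) / sqrt(nrow(resp)) +
    cfg$amplitude_sd / sqrt(nrow(gt))
  expect_lt(abs(est - inj), max(2 * se, 0.08))
})

test_that("axons are categorized by the epoch of their average peak", {
  st <- seq(0, 8.49, by = 1 / 30)
  n <- length(st)
  mk <- function(peak_t, amp = 1) {
    x <- numeric(n); x[which.min(abs(st - peak_t))] <- amp
    stats::filter(x, rep(1 / 3, 3), sides = 2, circular = TRUE)
  }
  avg <- rbind(resp = as.numeric(mk(3.4)),
               spont = as.numeric(mk(1.5)),
               rew = as.numeric(mk(4.8)),
               flat = numeric(n))
  attr(avg, "sample_times") <- st
  tt <- mini_trials()
  w <- assign_epoch_windows(tt)
  labels <- categorize_axons_by_peak(avg, w)
  expect_equal(unname(labels),
               c("response", "spontaneous", "reward", "none"))
})

test_that("mass average is linear with SEM across ROIs", {
  vals <- array(0, c(2, 3, 50))
  vals[1, , ] <- 0; vals[2, , ] <- 1
  tens <- structure(list(values = vals, sample_times = (0:49) / 30,
                         trial_ids = 1:3, roi_ids = c("a", "b"),
                         frame_rate = 30,
                         dropped = data.frame()),
                    class = c("dff_tensor", "trial_tensor"))
  ma <- mass_average(tens)
  expect_true(all(ma$mean == 0.5))
  expect_equal(ma$sem, rep(sd(c(0, 1)) / sqrt(2), 50))
  # identical traces -> SEM 0
  vals2 <- vals; vals2[2, , ] <- 0
  tens$values <- vals2
  expect_true(all(mass_average(tens)$sem == 0))
  # linearity in the data
  tens$values <- vals * 3
  expect_equal(mass_average(tens)$mean, ma$mean * 3)
})

test_that("display matrix normalizes rows and sorts by peak time", {
  st <- (0:99) / 30
  avg <- rbind(a = dnorm(st, 3, 0.2), b = dnorm(st, 1, 0.2),
               c = dnorm(st, 2, 0.2), d = rep(-1, 100))
  attr(avg, "sample_times") <- st
  dm <- display_matrix(avg)
  expect_equal(rownames(dm), c("b", "c", "a"))
  expect_equal(unname(apply(dm, 1, max)), rep(1, 3))
  expect_equal(attr(dm, "dropped"), "d")
  # equal peak times: stable order by incoming (roi id) order
  avg2 <- rbind(z = dnorm(st, 2, 0.2), y = dnorm(st, 2, 0.2))
  attr(avg2, "sample_times") <- st
  expect_equal(rownames(display_matrix(avg2)), c("z", "y"))
})
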