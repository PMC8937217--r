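test_that("a flat trace yields no events", {
  vals <- array(0, c(1, 2, 120))
  ev <- detect_events(make_dff_tensor(vals))
  expect_equal(nrow(ev), 0)
})

test_that("the strict >200 ms rule rejects 6-sample and keeps 7-sample
           pulses at 30 Hz", {
  vals <- array(0, c(1, 2, 120))
  vals[1, 1, 20:25] <- 1   # 6 samples = 200 ms -> rejected
  vals[1, 2, 20:26] <- 1   # 7 samples = 233 ms -> one event
  ev <- detect_events(make_dff_tensor(vals))
  expect_equal(nrow(ev), 1)
  expect_equal(ev$trial_id, 2)
  expect_equal(ev$onset_s, 19 / 30)
  expect_equal(ev$offset_s, 26 / 30)
  expect_equal(ev$duration_ms, 7000 / 30, tolerance = 1e-9)
  expect_equal(ev$peak_dff, 1)
})

test_that("events report onset at threshold crossing and peak within run", {
  vals <- array(0, c(1, 1, 120))
  ramp <- c(seq(0.1, 1.2, length.out = 10), seq(1.1, 0.05,
                                                length.out = 12))
  vals[1, 1, 31:52] <- ramp
  ev <- detect_events(make_dff_tensor(vals))  # threshold 0.2
  sup <- which(vals[1, 1, ] > 0.2)
  expect_equal(ev$onset_s, (sup[1] - 1) / 30)
  expect_equal(ev$offset_s, sup[length(sup)] / 30)
  expect_equal(ev$peak_dff, max(ramp))
})

test_that("missing samples split suprathreshold runs at the gap", {
  vals <- array(0, c(1, 1, 120))
  vals[1, 1, 11:40] <- 1
  vals[1, 1, 25] <- NA
  ev <- detect_events(make_dff_tensor(vals))
  expect_equal(nrow(ev), 2)
  expect_equal(ev$onset_s, c(10, 25) / 30)
})

test_that("the detector matches the brute-force oracle on random traces", {
  set.seed(101)
  n_roi <- 20; n_trial <- 10; n_samp <- 240
  vals <- array(0, c(n_roi, n_trial, n_samp))
  sd_vec <- runif(n_roi, 0.05, 0.3)
  for (r in seq_len(n_roi)) {
    for (i in seq_len(n_trial)) {
      x <- rnorm(n_samp, 0, sd_vec[r])
      for (k in seq_len(rpois(1, 2))) {
        onset <- sample(1:(n_samp - 40), 1)
        amp <- runif(1, 0.2, 1.5)
        dur <- sample(4:30, 1)
        x[onset:(onset + dur)] <- x[onset:(onset + dur)] + amp
      }
      if (runif(1) < 0.2) x[sample(n_samp, 3)] <- NA
      vals[r, i, ] <- x
    }
  }
  tens <- make_dff_tensor(vals, baseline_sd = sd_vec)
  ev <- detect_events(tens)
  st <- tens$sample_times
  n_checked <- 0
  for (r in seq_len(n_roi)) {
    for (i in seq_len(n_trial)) {
      ora <- oracle_events(vals[r, i, ], st, 2 * sd_vec[r], 1 / 30)
      got <- ev[ev$roi_id == tens$roi_ids[r] & ev$trial_id == i, ]
      expect_equal(nrow(got), nrow(ora))
      if (nrow(ora)) {
        expect_equal(got$onset_s, ora$onset)
        expect_equal(got$offset_s, ora$offset)
        expect_equal(got$peak_dff, ora$peak)
      }
      n_checked <- n_checked + 1
    }
  }
  expect_equal(n_checked, n_roi * n_trial)
})

test_that("detection count is monotone in injected amplitude", {
  counts <- vapply(c(0.3, 0.6, 1.2), function(a) {
    cfg <- quick_config(amplitude_mean = a, amplitude_sd = 0,
                        noise_sd = 12, seed = 21)
    sess <- simulate_session(cfg, pupil = FALSE)
    an <- analyze_session(sess$traces, sess$trials, dedup = FALSE)
    nrow(an$events)
  }, numeric(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("the active-axon rule keeps exactly the ROIs with events", {
  ev <- make_events(data.frame(roi_id = c("a", "a", "c"),
                               trial_id = c(1L, 2L, 1L),
                               onset_s = c(3.5, 3.6, 1.2)),
                    roi_ids = c("a", "b", "c"), trial_ids = 1:3)
  expect_equal(flag_active_rois(ev), c("a", "c"))
})

test_that("most ROIs carrying injected events are flagged active", {
  cfg <- sim_config(n_trials = 40, n_axons = 40, seed = 33)
  sess <- simulate_session(cfg, pupil = FALSE)
  an <- analyze_session(sess$traces, sess$trials, dedup = FALSE)
  with_truth <- unique(sess$ground_truth$true_events$roi_id)
  recovered <- mean(with_truth %in% an$active_rois)
  expect_gte(recovered, 0.95)
})

test_that("an exact copy of an event train is removed as duplicate", {
  trials <- data.frame(trial_id = 1:10)
  ev <- make_events(data.frame(
    roi_id = rep(c("a", "a2"), each = 5),
    trial_id = rep(c(1L, 3L, 5L, 7L, 9L), 2),
    onset_s = rep(c(3.5, 3.6, 3.4, 3.55, 3.45), 2),
    peak_dff = c(rep(1, 5), rep(0.8, 5))),
    roi_ids = c("a", "a2"), trial_ids = 1:10)
  dd <- deduplicate_rois(ev, trials)
  expect_equal(dd$pairwise_agreement["a", "a2"], 1)
  expect_equal(dd$duplicate_groups, list(c("a", "a2")))
  expect_equal(dd$kept_roi_ids, "a")  # higher mean peak survives
  expect_equal(dd$removed_roi_ids, "a2")
})

test_that("independent ROIs at moderate rates are both kept", {
  set.seed(77)
  n_trials <- 200
  trials <- data.frame(trial_id = seq_len(n_trials))
  rows <- NULL
  for (r in c("x", "y")) {
    has <- runif(n_trials) < 0.3
    rows <- rbind(rows, data.frame(roi_id = r,
                                   trial_id = which(has),
                                   onset_s = 3.5))
  }
  ev <- make_events(rows, roi_ids = c("x", "y"),
                    trial_ids = seq_len(n_trials))
  dd <- deduplicate_rois(ev, trials)
  # expected agreement 0.3^2 + 0.7^2 = 0.58, far below threshold
  expect_equal(dd$pairwise_agreement["x", "y"], 0.58, tolerance = 0.15)
  expect_setequal(dd$kept_roi_ids, c("x", "y"))
})

test_that("three branches form one duplicate group with one survivor", {
  trials <- data.frame(trial_id = 1:20)
  onsets <- seq(3.4, 3.9, length.out = 20)
  rows <- do.call(rbind, lapply(c("b1", "b2", "b3"), function(r)
    data.frame(roi_id = r, trial_id = 1:20,
               onset_s = onsets + (match(r, c("b1", "b2", "b3")) - 2) /
                 60)))
  rows$peak_dff <- ifelse(rows$roi_id == "b2", 1.4, 0.9)
  ev <- make_events(rows, roi_ids = c("b1", "b2", "b3"), trial_ids = 1:20)
  dd <- deduplicate_rois(ev, trials)
  expect_length(dd$duplicate_groups, 1)
  expect_setequal(dd$duplicate_groups[[1]], c("b1", "b2", "b3"))
  expect_equal(dd$kept_roi_ids, "b2")
})

test_that("single-trial sessions skip deduplication with a warning", {
  trials <- data.frame(trial_id = 1L)
  ev <- make_events(data.frame(roi_id = "a", trial_id = 1L, onset_s = 3.5),
                    roi_ids = c("a", "b"), trial_ids = 1L)
  expect_warning(dd <- deduplicate_rois(ev, trials), "single-trial")
  expect_setequal(dd$kept_roi_ids, c("a", "b"))
})

test_that("removing duplicates does not alter kept ROIs' events", {
  cfg <- quick_config(branches_per_axon = 2, n_axons = 5)
  sess <- simulate_session(cfg, pupil = FALSE)
  an <- analyze_session(sess$traces, sess$trials)
  kept_before <- an$events[an$events$roi_id %in% an$dedup$kept_roi_ids, ]
  an2 <- analyze_session(sess$traces, sess$trials, dedup = FALSE)
  kept_after <- an2$events[an2$events$roi_id %in% an$dedup$kept_roi_ids, ]
  expect_equal(kept_before, kept_after, ignore_attr = TRUE)
})
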