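lick_trials <- function(mode, licks, types = NULL) {
  n <- length(licks)
  if (is.null(types)) types <- rep("stimulus", n)
  tt <- data.frame(trial_id = seq_len(n), type = types,
                   t_start = (seq_len(n) - 1) * 20,
                   t_stimulus = (seq_len(n) - 1) * 20 + 3,
                   t_reward = NA_real_, outcome = "")
  tt$lick_times <- lapply(seq_len(n), function(i) tt$t_stimulus[i] +
                            licks[[i]])
  attr(tt, "task_mode") <- mode
  attr(tt, "trial_window_s") <- 8.5
  class(tt) <- c("trial_table", "data.frame")
  tt
}

test_that("action-mode outcomes follow the half-open response window", {
  tt <- lick_trials("action",
                    list(0.4, numeric(0), 1.5, 1.4999, c(-0.5, 2)),
                    types = c("stimulus", "stimulus", "stimulus",
                              "stimulus", "stimulus"))
  out <- classify_outcomes(tt)$outcome
  # lick at exactly +1.5 s falls outside the window
  expect_equal(out, c("HIT", "MISS", "MISS", "HIT", "MISS"))
  ct <- lick_trials("action", list(0.3, numeric(0)),
                    types = c("catch", "catch"))
  expect_equal(classify_outcomes(ct)$outcome, c("FA", "CR"))
})

test_that("suppression-mode inverts the stimulus-trial rule", {
  tt <- lick_trials("suppression", list(0.4, numeric(0), 1.6),
                    types = c("stimulus", "stimulus", "stimulus"))
  expect_equal(classify_outcomes(tt)$outcome, c("MISS", "HIT", "HIT"))
  ct <- lick_trials("suppression", list(0.3), types = "catch")
  expect_equal(classify_outcomes(ct)$outcome, "FA")
  bad <- tt; attr(bad, "task_mode") <- "bogus"
  expect_error(classify_outcomes(bad), "task_mode")
})

test_that("outcomes partition trials by type", {
  cfg <- quick_config()
  tt <- classify_outcomes(simulate_trials(cfg))
  stim <- tt$type == "stimulus"
  expect_true(all(tt$outcome[stim] %in% c("HIT", "MISS")))
  expect_true(all(tt$outcome[!stim] %in% c("FA", "CR")))
  expect_equal(sum(tt$outcome %in% c("HIT", "MISS")), sum(stim))
})

test_that("d-prime matches the closed-form normal-quantile difference", {
  dp <- dprime(0.9, 0.1)
  expect_equal(dp$d_prime, qnorm(0.9) - qnorm(0.1), tolerance = 1e-12)
  expect_equal(dp$d_prime, 2.5631, tolerance = 1e-4)
  expect_equal(dp$z_hit, 1.28155, tolerance = 1e-5)
  # chance performance
  expect_equal(dprime(0.5, 0.5)$d_prime, 0)
  # antisymmetry
  expect_equal(dprime(0.8, 0.3)$d_prime, -dprime(0.3, 0.8)$d_prime,
               tolerance = 1e-12)
})

test_that("extreme rates are adjusted by the 1/(2N) rule", {
  dp <- dprime(1, 0, n_stimulus = 50, n_catch = 40)
  expect_equal(dp$z_hit, qnorm(1 - 1 / 100))
  expect_equal(dp$z_fa, qnorm(1 / 80))
  expect_error(dprime(1, 0.2), "trial count")
})

test_that("correct fraction and the expert criterion", {
  cf <- correct_fraction(40, 30, 50, 40)
  expect_equal(cf$fraction, 70 / 90)
  expect_false(cf$expert)
  expect_true(correct_fraction(45, 38, 50, 40)$expert)
  expect_equal(correct_fraction(50, 40, 50, 40)$fraction, 1)
  expect_error(correct_fraction(0, 0, 0, 0), "zero trials")
})

test_that("first-lick latency is measured from stimulus onset", {
  tt <- lick_trials("action", list(c(0.35, 0.6), numeric(0), c(-1, 0.2)))
  lat <- first_lick_latency(tt)
  expect_equal(lat$latency_ms, c(350, NA, 200))
})

test_that("generator lick latencies are recovered on average", {
  cfg <- sim_config(n_trials = 200, catch_fraction = 0, hit_rate = 1,
                    seed = 5)
  tt <- simulate_trials(cfg)
  lat <- first_lick_latency(tt)
  # generator draws latency as 350 ms plus an exponential(150 ms) tail
  expect_equal(mean(lat$latency_ms, na.rm = TRUE), 500, tolerance = 0.1)
})

test_that("lick frequency is count over window length", {
  tt <- lick_trials("action", list(c(0.1, 0.4, 0.9), numeric(0)))
  w <- data.frame(trial_id = c(1L, 1L, 2L), epoch = c("response", "wide",
                                                      "response"),
                  start = c(3, 3, 3), end = c(4, 5, 4))
  lf <- lick_frequency(tt, w)
  expect_equal(lf$lick_hz, c(3, 1.5, 0))
})

test_that("lick-activity correlation behaves at the extremes", {
  x <- c(1, 4, 2, 8, 5, 7, 3, 6, 9, 10, 2.5, 4.5)
  r <- lick_activity_correlation(x, x)
  expect_equal(r$rho, 1)
  r2 <- lick_activity_correlation(x, -x)
  expect_equal(r2$rho, -1)
  r3 <- lick_activity_correlation(x, rep(1, 12))
  expect_true(is.na(r3$rho))
  expect_error(lick_activity_correlation(x[1:5], x[1:5]), "10 paired")
})

test_that("activity independent of licking gives null correlations", {
  set.seed(8)
  pvals <- replicate(40, {
    lick <- runif(40)
    act <- runif(40)
    lick_activity_correlation(lick, act)$p_value
  })
  # p-values roughly uniform: around 5% below 0.05, mean near 0.5
  expect_lt(mean(pvals < 0.05), 0.2)
  expect_gt(mean(pvals), 0.3)
})

test_that("session behavior metrics tie together counts and d-prime", {
  cfg <- quick_config()
  tt <- simulate_trials(cfg)
  bm <- behavior_metrics(tt)
  expect_equal(bm$d_prime, bm$z_hit - bm$z_fa)
  expect_equal(bm$correct_fraction,
               (bm$n[["HIT"]] + bm$n[["CR"]]) /
                 (bm$n[["stimulus"]] + bm$n[["catch"]]))
})
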