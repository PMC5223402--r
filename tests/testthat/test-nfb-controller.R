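ratio_powers <- function(c3, cp3, c4, cp4, base = 10) {
  list(powers = c(C3 = c3 * base, CP3 = cp3 * base, C4 = c4 * base,
                  CP4 = cp4 * base),
       baseline = c(C3 = base, CP3 = base, C4 = base, CP4 = base))
}

test_that("the difficulty table reproduces the published rows", {
  tab <- difficulty_table()
  expect_equal(tab$level, -1:15)
  expect_true(all(tab$lw == 1))
  expect_true(all(tab$rw[tab$level <= 4] == 0))
  expect_equal(tab$rw[tab$level %in% 5:13], (5:13 - 4) / 10)
  expect_true(all(tab$rw[tab$level >= 14] == 1))
  expect_true(all(tab$lower <= tab$upper))

  r <- difficulty_params(1)
  expect_equal(c(r$lw, r$rw, r$lower, r$upper), c(1, 0, -4, 0))
  r <- difficulty_params(9)
  expect_equal(c(r$rw, r$lower, r$upper), c(0.5, 2, 6))
  r <- difficulty_params(15)
  expect_equal(c(r$lower, r$upper), c(2, 2))
  r <- difficulty_params(-1)
  expect_equal(c(r$lower, r$upper), c(-8, -4))
  expect_error(difficulty_params(16), "level")
})

test_that("the feedback score is monotone in lateralized power", {
  row <- difficulty_params(9)  # lw = 1, rw = 0.5
  set.seed(21)
  for (i in 1:25) {
    rr <- runif(4, 0.2, 3)
    x <- ratio_powers(rr[1], rr[2], rr[3], rr[4])
    s0 <- compute_nfb_score(x$powers, x$baseline, row)
    # lowering left-hemisphere power can never lower the score
    less_left <- x$powers
    less_left[c("C3", "CP3")] <- less_left[c("C3", "CP3")] * runif(1, 0.1, 1)
    expect_gte(compute_nfb_score(less_left, x$baseline, row), s0)
    # raising right-hemisphere power can never lower it while rw > 0
    more_right <- x$powers
    more_right[c("C4", "CP4")] <- more_right[c("C4", "CP4")] * runif(1, 1, 5)
    expect_gte(compute_nfb_score(more_right, x$baseline, row), s0)
  }
  expect_error(
    compute_nfb_score(ratio_powers(1, 1, 1, 1)$powers,
                      c(C3 = 0, CP3 = 1, C4 = 1, CP4 = 1), row),
    "positive")
})

test_that("the EMG gate uses a strict baseline-mean + 2 SD rule", {
  base <- structure(list(emg_mean = c(EMG_flex = 2, EMG_ext = 2),
                         emg_sd = c(EMG_flex = 0.5, EMG_ext = 0.5)),
                    class = "nfb_baseline")
  expect_true(emg_gate(c(EMG_flex = 2 + 2.5 * 0.5, EMG_ext = 0), base))
  expect_false(emg_gate(c(EMG_flex = 2, EMG_ext = 2), base))
  expect_false(emg_gate(c(EMG_flex = 3, EMG_ext = 3), base))  # exactly +2 SD
  expect_true(emg_gate(c(EMG_flex = 0, EMG_ext = 3.001), base))
})

test_that("the video score steps by one with lockout and EMG reset", {
  row <- difficulty_params(3)   # thresholds [0, 4]
  st <- feedback_state()
  st$video_score <- 3L
  up <- step_video_score(st, 5, row)
  expect_equal(up$video_score, 4L)
  expect_equal(up$lockout_remaining, 4L)
  # frozen during lockout even under an extreme score
  fr <- step_video_score(up, 100, row)
  expect_equal(fr$video_score, 4L)
  expect_equal(fr$lockout_remaining, 3L)
  # floor at 1 without starting a lockout
  st$video_score <- 1L
  lo <- step_video_score(st, -10, row)
  expect_equal(lo$video_score, 1L)
  expect_equal(lo$lockout_remaining, 0L)
  # EMG reset dominates and restarts the lockout
  st$video_score <- 5L
  st$lockout_remaining <- 2L
  em <- step_video_score(st, 100, row, emg_flag = TRUE)
  expect_equal(em$video_score, 1L)
  expect_equal(em$lockout_remaining, 4L)
})

test_that("video-score trajectories respect bounds, step size and spacing", {
  row <- difficulty_params(1)
  set.seed(31)
  st <- feedback_state()
  traj <- integer(400)
  emg <- runif(400) < 0.02
  for (i in 1:400) {
    st <- step_video_score(st, rnorm(1, sd = 6), row, emg[i])
    traj[i] <- st$video_score
  }
  expect_true(all(traj >= 1 & traj <= 6))
  expect_true(all(abs(diff(traj)) <= 1 | emg[-1]))
  changes <- which(diff(traj) != 0 & !emg[-1])
  if (length(changes) > 1)
    expect_true(all(diff(changes) >= 4 | emg[changes[-1] + 1]))
})

test_that("end-of-trial titration follows the 20-s mean video score", {
  cfg <- engine_config()
  mk <- function(level, streak = 0L) {
    st <- feedback_state(level)
    st$level1_streak <- streak
    st
  }
  vs <- function(m) rep(m, 100)   # constant stream with the target mean
  expect_equal(end_of_trial_update(vs(4.5), mk(3L), cfg)$level, 4L)
  expect_equal(end_of_trial_update(vs(1.5), mk(3L), cfg)$level, 2L)
  expect_equal(end_of_trial_update(vs(3), mk(3L), cfg)$level, 3L)
  # boundary means hold the level (strict comparisons)
  expect_equal(end_of_trial_update(vs(4), mk(3L), cfg)$level, 3L)
  expect_equal(end_of_trial_update(vs(2), mk(3L), cfg)$level, 3L)
  # demotion below level 1 requires three consecutive level-1 trials
  expect_equal(end_of_trial_update(vs(1.5), mk(1L, 1L), cfg)$level, 1L)
  expect_equal(end_of_trial_update(vs(1.5), mk(1L, 3L), cfg)$level, 0L)
  expect_equal(end_of_trial_update(vs(1.5), mk(0L), cfg)$level, -1L)
  expect_equal(end_of_trial_update(vs(1.5), mk(-1L), cfg)$level, -1L)
  expect_equal(end_of_trial_update(vs(5), mk(15L), cfg)$level, 15L)
  # only the final titration window counts
  mixed <- c(rep(6, 60), rep(1, 40))
  expect_equal(end_of_trial_update(mixed, mk(3L), cfg)$level, 2L)
  expect_error(end_of_trial_update(rep(3, 10), mk(3L), cfg), "titration")
})

test_that("sessions start at level 1 and trials present score 1 first", {
  sim <- default_sim()
  log <- sim$log
  expect_equal(log$trials$level_before[1], 1L)
  first_ticks <- !duplicated(log$ticks$trial)
  expect_true(all(log$ticks$video_score[first_ticks] == 1L))
  expect_true(all(log$ticks$video_score >= 1 & log$ticks$video_score <= 6))
  expect_true(all(log$ticks$level >= -1 & log$ticks$level <= 15))
  expect_true(all(abs(diff(log$trials$level_after)) <= 1))
})

test_that("a config with a titration window longer than the trial is refused", {
  expect_error(engine_config(trial = 10, titration_window = 20), "titration")
})
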